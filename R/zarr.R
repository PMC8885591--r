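# Minimal Zarr v2 store (directory layout) for unsigned integer 3D arrays:
# a .zarray JSON descriptor plus one zlib-compressed C-order file per chunk,
# keyed "i.j.k" over the (z, y, x) shape. This is the chunk-file format the
# volumetric ingest path reads and the phantom writer emits; it
# interoperates with the Python `zarr`/`numcodecs` stack (codec id "zlib").

zarr_dtype_str <- function(dtype) {
  switch(dtype, uint8 = "|u1", uint16 = "<u2", uint64 = "<u8",
         vox_abort(sprintf("no zarr dtype for '%s'", dtype), "validation"))
}

#' Write a 3D array as a Zarr v2 directory
#'
#' @param x Dense array, `dim` in (x, y, z) order.
#' @param path Output directory (created; must not already contain an array).
#' @param dtype Voxel dtype (`uint8`, `uint16`, `uint64`).
#' @param chunks Chunk shape in (x, y, z) order; default the whole array.
#' @param level zlib compression level, or `NA` for uncompressed chunks.
#' @return Invisibly, `path`.
#' @export
write_zarr <- function(x, path, dtype, chunks = dim(x), level = 6L) {
  shape <- as.double(dim(x))
  if (length(shape) != 3) vox_abort("write_zarr expects a 3D array", "validation")
  chunks <- as.double(chunks)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    zarr_format = 2L,
    shape = rev(shape),          # stored C-order: (z, y, x)
    chunks = rev(chunks),
    dtype = zarr_dtype_str(dtype),
    compressor = if (is.na(level)) NULL else list(id = "zlib", level = as.integer(level)),
    fill_value = 0L,
    order = "C",
    filters = NULL
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(path, ".zarray"))
  nchunks <- ceiling(shape / chunks)
  for (ccz in seq_len(nchunks[3]) - 1) {
    for (ccy in seq_len(nchunks[2]) - 1) {
      for (ccx in seq_len(nchunks[1]) - 1) {
        x0 <- ccx * chunks[1]; y0 <- ccy * chunks[2]; z0 <- ccz * chunks[3]
        sub <- array(0, chunks)
        xs <- seq_len(min(chunks[1], shape[1] - x0))
        ys <- seq_len(min(chunks[2], shape[2] - y0))
        zs <- seq_len(min(chunks[3], shape[3] - z0))
        sub[xs, ys, zs] <- x[x0 + xs, y0 + ys, z0 + zs]
        bytes <- array_to_raw(sub, dtype)
        if (!is.na(level)) bytes <- memCompress(bytes, type = "gzip")
        writeBin(bytes, file.path(path, paste(ccz, ccy, ccx, sep = ".")))
      }
    }
  }
  invisible(path)
}

#' Read a Zarr v2 directory into a 3D array
#'
#' Supports uncompressed and zlib-compressed C-order chunks (the subset
#' [write_zarr()] produces, plus NumPy-written equivalents). Missing chunk
#' files read as the fill value.
#'
#' @param path Zarr array directory.
#' @return List with `data` (array, `dim` in x/y/z order), `dtype`, `shape`.
#' @export
read_zarr <- function(path) {
  zf <- file.path(path, ".zarray")
  if (!file.exists(zf)) vox_abort(sprintf("no .zarray in '%s'", path), "format")
  meta <- jsonlite::read_json(zf, simplifyVector = TRUE)
  if (!is.null(meta$compressor) && !identical(meta$compressor$id, "zlib")) {
    vox_abort(sprintf("unsupported zarr compressor '%s'", meta$compressor$id), "format")
  }
  if (!identical(meta$order, "C")) vox_abort("only C-order zarr arrays supported", "format")
  dtype <- descr_dtype(meta$dtype)
  shape <- rev(as.double(meta$shape))    # -> (x, y, z)
  chunks <- rev(as.double(meta$chunks))
  fill <- as.double(meta$fill_value %||% 0)
  out <- array(fill, shape)
  nchunks <- ceiling(shape / chunks)
  for (ccz in seq_len(nchunks[3]) - 1) {
    for (ccy in seq_len(nchunks[2]) - 1) {
      for (ccx in seq_len(nchunks[1]) - 1) {
        f <- file.path(path, paste(ccz, ccy, ccx, sep = "."))
        if (!file.exists(f)) next
        bytes <- readBin(f, raw(), n = file.size(f))
        if (!is.null(meta$compressor)) bytes <- memDecompress(bytes, type = "gzip")
        sub <- array(raw_to_vector(bytes, dtype, prod(chunks)), chunks)
        x0 <- ccx * chunks[1]; y0 <- ccy * chunks[2]; z0 <- ccz * chunks[3]
        xs <- seq_len(min(chunks[1], shape[1] - x0))
        ys <- seq_len(min(chunks[2], shape[2] - y0))
        zs <- seq_len(min(chunks[3], shape[3] - z0))
        out[x0 + xs, y0 + ys, z0 + zs] <- sub[xs, ys, zs]
      }
    }
  }
  list(data = out, dtype = dtype, shape = shape)
}
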