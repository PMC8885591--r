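# Cutout service: arbitrary-volume reads and writes against the cuboid
# store, the 2D image (slice) service, and cutout serialization.
#
# Coordinates are 0-based half-open [start, stop) per axis, addressed as
# x/y/z. Arrays carry dim = (nx, ny, nz); since R arrays are column-major,
# this memory layout is exactly a C-order (z, y, x) array, the store's
# canonical serialization order.

check_cutout_args <- function(store, channel, range, resolution, t) {
  if (!inherits(channel, "vox_channel")) {
    vox_abort("channel must be a vox_channel handle", "validation")
  }
  if (resolution < 0 || resolution >= channel$num_hierarchy_levels) {
    vox_abort(sprintf("resolution %s outside channel hierarchy [0, %d)",
                      resolution, channel$num_hierarchy_levels), "validation")
  }
  ext <- channel_extent(channel, resolution)
  if (range$x[2] > ext[1] || range$y[2] > ext[2] || range$z[2] > ext[3]) {
    vox_abort(sprintf("range exceeds level-%s extent %s", resolution,
                      paste(ext, collapse = "x")), "validation")
  }
  if (t < 0 || t >= channel$frame$time_extent) {
    vox_abort(sprintf("time index %s outside frame time extent %s", t,
                      channel$frame$time_extent), "validation")
  }
}

get_cuboid_or_zero <- function(store, key) {
  d <- vox_get_cuboid(store, key)
  if (is.null(d)) array(0, key$channel$cuboid_shape) else d
}

#' Read an arbitrary sub-volume
#'
#' Decomposes the request on the cuboid grid, copies voxels from every
#' existing cuboid into place, and fills voxels belonging to never-written
#' cuboids with 0 (black imagery / background annotation).
#'
#' @param store A [vox_store()].
#' @param channel A `vox_channel` handle.
#' @param range A [vox_range()] within the frame extents at `resolution`.
#' @param resolution Resolution level (default 0).
#' @param t Time index (default 0).
#' @return Dense array with `dim(range)`, voxel values as doubles.
#' @export
#' @examples
#' \dontrun{
#' cut <- vox_read_cutout(st, ch, vox_range(c(0, 1024), c(0, 512), c(0, 10)))
#' }
vox_read_cutout <- function(store, channel, range, resolution = 0, t = 0) {
  check_cutout_args(store, channel, range, resolution, t)
  out <- array(0, dim(range))
  plan <- cuboids_for_range(range, channel$cuboid_shape)
  shape <- channel$cuboid_shape
  origin <- c(range$x[1], range$y[1], range$z[1])
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    key <- cuboid_key(channel, resolution, row$morton, t)
    if (!vox_contains(store, key)) next
    cub <- vox_get_cuboid(store, key)
    corner <- c(row$cx, row$cy, row$cz) * shape
    lx <- seq.int(row$x0 - corner[1] + 1, row$x1 - corner[1])
    ly <- seq.int(row$y0 - corner[2] + 1, row$y1 - corner[2])
    lz <- seq.int(row$z0 - corner[3] + 1, row$z1 - corner[3])
    out[seq.int(row$x0 - origin[1] + 1, row$x1 - origin[1]),
        seq.int(row$y0 - origin[2] + 1, row$y1 - origin[2]),
        seq.int(row$z0 - origin[3] + 1, row$z1 - origin[3])] <- cub[lx, ly, lz]
  }
  out
}

mark_stale <- function(store, channel, range, resolution) {
  if (channel$num_hierarchy_levels <= resolution + 1) return(invisible(NULL))
  key <- channel$path
  cur <- store$stale[[key]] %||% list()
  cur[[length(cur) + 1L]] <- list(resolution = resolution,
                                  x = range$x, y = range$y, z = range$z)
  store$stale[[key]] <- cur
  invisible(NULL)
}

#' Stale downsample footprint of a channel
#'
#' Ranges written since the last (partial) downsample, at their write
#' resolution. [vox_partial_downsample()] consumes and clears this list.
#'
#' @param store A [vox_store()].
#' @param channel A `vox_channel`.
#' @return List of [vox_range()] objects (possibly empty).
#' @export
vox_stale_ranges <- function(store, channel) {
  lapply(store$stale[[channel$path]] %||% list(),
         function(s) vox_range(s$x, s$y, s$z))
}

#' Write an arbitrary sub-volume
#'
#' Performs a read-modify-write on every cuboid the range intersects: absent
#' cuboids materialize zero-filled, receive their overlap, and are stored.
#' Semantics are last-writer-wins per voxel. Writes to annotation channels
#' atomically maintain the forward/reverse annotation indices; resolution
#' levels above the write resolution are marked stale over the written
#' footprint (see [vox_partial_downsample()]).
#'
#' @inheritParams vox_read_cutout
#' @param data Dense array with `dim(range)` and values valid for the channel
#'   datatype.
#' @export
vox_write_cutout <- function(store, channel, range, data, resolution = 0, t = 0) {
  check_cutout_args(store, channel, range, resolution, t)
  if (!identical(as.double(dim(data)), as.double(dim(range)))) {
    vox_abort(sprintf("data shape %s does not match range shape %s",
                      paste(dim(data), collapse = "x"),
                      paste(dim(range), collapse = "x")), "validation")
  }
  plan <- cuboids_for_range(range, channel$cuboid_shape)
  shape <- channel$cuboid_shape
  origin <- c(range$x[1], range$y[1], range$z[1])
  is_ann <- channel$channel_type == "annotation"
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    key <- cuboid_key(channel, resolution, row$morton, t)
    cub <- get_cuboid_or_zero(store, key)
    corner <- c(row$cx, row$cy, row$cz) * shape
    lx <- seq.int(row$x0 - corner[1] + 1, row$x1 - corner[1])
    ly <- seq.int(row$y0 - corner[2] + 1, row$y1 - corner[2])
    lz <- seq.int(row$z0 - corner[3] + 1, row$z1 - corner[3])
    cub[lx, ly, lz] <- data[seq.int(row$x0 - origin[1] + 1, row$x1 - origin[1]),
                            seq.int(row$y0 - origin[2] + 1, row$y1 - origin[2]),
                            seq.int(row$z0 - origin[3] + 1, row$z1 - origin[3])]
    vox_put_cuboid(store, key, cub)
    if (is_ann) update_indices(store, key, cub)
  }
  mark_stale(store, channel, range, resolution)
  invisible(NULL)
}

#' Extract a 2D orthogonal slice
#'
#' Serves the image service: a single section along one of the three
#' orthogonal planes, equal to a thickness-1 cutout with the orthogonal axis
#' squeezed out. `region` selects a sub-rectangle in the plane's in-plane
#' axes; in fixed-tile mode (`tile_size` set) the region is
#' `tile_size`-shaped starting at `tile_origin` and is zero-padded where it
#' leaves the frame, which is the contract tiled viewers expect.
#'
#' @param store A [vox_store()].
#' @param channel A `vox_channel` (annotation channels are returned as raw
#'   labels, not colorized).
#' @param plane `"XY"`, `"XZ"`, or `"YZ"`.
#' @param index 0-based index along the orthogonal axis (z, y, x
#'   respectively).
#' @param region Optional list of two half-open pairs (in-plane axes, in
#'   plane order); default whole plane.
#' @param resolution,t As in [vox_read_cutout()].
#' @param tile_size Optional integer pair for fixed-tile mode.
#' @param tile_origin In-plane origin of the fixed tile (default `c(0, 0)`).
#' @return A 2D matrix, first in-plane axis along rows.
#' @export
vox_slice <- function(store, channel, plane, index, region = NULL,
                      resolution = 0, t = 0, tile_size = NULL,
                      tile_origin = c(0, 0)) {
  plane <- toupper(plane)
  if (!plane %in% c("XY", "XZ", "YZ")) {
    vox_abort(sprintf("plane must be XY, XZ or YZ (got '%s')", plane), "validation")
  }
  ext <- channel_extent(channel, resolution)
  axes <- switch(plane, XY = c(1, 2, 3), XZ = c(1, 3, 2), YZ = c(2, 3, 1))
  ortho_ext <- ext[axes[3]]
  if (index < 0 || index >= ortho_ext) {
    vox_abort(sprintf("%s slice index %s outside [0, %s)", plane, index, ortho_ext),
              "validation")
  }
  if (!is.null(tile_size)) {
    want <- list(c(tile_origin[1], tile_origin[1] + tile_size[1]),
                 c(tile_origin[2], tile_origin[2] + tile_size[2]))
    clip <- list(c(want[[1]][1], min(want[[1]][2], ext[axes[1]])),
                 c(want[[2]][1], min(want[[2]][2], ext[axes[2]])))
    if (clip[[1]][1] >= clip[[1]][2] || clip[[2]][1] >= clip[[2]][2]) {
      return(matrix(0, tile_size[1], tile_size[2]))
    }
    inner <- vox_slice(store, channel, plane, index, region = clip,
                       resolution = resolution, t = t)
    out <- matrix(0, tile_size[1], tile_size[2])
    out[seq_len(nrow(inner)), seq_len(ncol(inner))] <- inner
    return(out)
  }
  region <- region %||% list(c(0, ext[axes[1]]), c(0, ext[axes[2]]))
  bounds <- vector("list", 3)
  bounds[[axes[1]]] <- region[[1]]
  bounds[[axes[2]]] <- region[[2]]
  bounds[[axes[3]]] <- c(index, index + 1)
  cut <- vox_read_cutout(store, channel,
                         vox_range(bounds[[1]], bounds[[2]], bounds[[3]]),
                         resolution, t)
  perm <- aperm(cut, c(axes[1:2], axes[3]))
  matrix(perm, dim(perm)[1], dim(perm)[2])
}

#' Save a 2D slice as an image file
#'
#' PNG supports uint8 output; TIFF supports uint8 and uint16, losslessly.
#'
#' @param slice Matrix of integer voxel values (first axis = image x).
#' @param file Output path; format chosen by extension (`.png`, `.tif(f)`).
#' @param dtype `"uint8"` or `"uint16"`.
#' @export
vox_save_slice <- function(slice, file, dtype = "uint8") {
  info <- dtype_info(dtype)
  if (dtype == "uint64") vox_abort("label slices have no image encoding", "validation")
  ext <- tolower(tools::file_ext(file))
  img <- t(slice) / info$max  # image rows = y
  if (ext == "png") {
    if (dtype != "uint8") {
      vox_abort("PNG output supports uint8 only; use TIFF for uint16", "validation")
    }
    png::writePNG(img, file)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, file, bits.per.sample = if (dtype == "uint16") 16L else 8L)
  } else {
    vox_abort(sprintf("unsupported image format '.%s'", ext), "negotiation")
  }
  invisible(file)
}

#' Read a 2D slice image file
#'
#' @param file PNG or TIFF file written by [vox_save_slice()] (or any 8/16-bit
#'   single-channel image).
#' @param dtype Target dtype for rescaling.
#' @return Matrix of integer voxel values (first axis = image x).
#' @export
vox_load_slice <- function(file, dtype = "uint8") {
  info <- dtype_info(dtype)
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") {
    png::readPNG(file)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(file)
  } else {
    vox_abort(sprintf("unsupported image format '.%s'", ext), "negotiation")
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  t(round(img * info$max))
}

#' Serialize / deserialize a cutout
#'
#' Formats: `"blob"` — the store's native compressed C-order container with
#' the range, resolution and time recorded as header attributes; `"npy"` — an
#' NPY v1.0 array file (C-order shape `(z, y, x)`) readable by any NumPy-
#' compatible tool, with a JSON sidecar-free payload (range metadata is
#' carried only by the blob format). Both round-trip bit-exactly.
#'
#' @param data Dense cutout array (`dim` = range shape).
#' @param dtype Voxel dtype.
#' @param format `"blob"` or `"npy"`.
#' @param range Optional [vox_range()] recorded in the blob header.
#' @param resolution,t Recorded in the blob header.
#' @return `vox_encode_cutout`: raw vector; `vox_decode_cutout`: list with
#'   `data`, `dtype` and (blob format) `attrs`.
#' @export
vox_encode_cutout <- function(data, dtype, format = c("blob", "npy"),
                              range = NULL, resolution = 0, t = 0) {
  format <- match.arg(format)
  if (format == "blob") {
    attrs <- list(resolution = resolution, t = t)
    if (!is.null(range)) {
      attrs$range <- list(x = range$x, y = range$y, z = range$z)
    }
    vox_compress(data, dtype, attrs = attrs)
  } else {
    npy_encode(data, dtype)
  }
}

#' @rdname vox_encode_cutout
#' @param bytes Raw vector produced by `vox_encode_cutout`.
#' @export
vox_decode_cutout <- function(bytes, format = c("blob", "npy")) {
  format <- match.arg(format)
  if (format == "blob") {
    dec <- vox_decompress(bytes)
    list(data = dec$data, dtype = dec$dtype, attrs = dec$attrs)
  } else {
    dec <- npy_decode(bytes)
    list(data = dec$data, dtype = dec$dtype, attrs = NULL)
  }
}
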