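# Minimal NPY v1.0 reader/writer for unsigned integer arrays.
# The R array dim (x, y, z) is column-major, which is byte-identical to a
# C-order array of shape (z, y, x); NPY headers therefore carry the reversed
# shape with fortran_order False, making the files directly NumPy-compatible.

npy_descr <- function(dtype) {
  switch(dtype, uint8 = "|u1", uint16 = "<u2", uint64 = "<u8",
         vox_abort(sprintf("no NPY descr for dtype '%s'", dtype), "validation"))
}

descr_dtype <- function(descr) {
  switch(descr, "|u1" = "uint8", "<u2" = "uint16", "<u8" = "uint64",
         vox_abort(sprintf("unsupported NPY descr '%s'", descr), "format"))
}

npy_encode <- function(x, dtype) {
  shape <- rev(dim(x) %||% length(x))
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    npy_descr(dtype),
                    paste0(paste(format(shape, scientific = FALSE, trim = TRUE),
                                 collapse = ", "),
                           if (length(shape) == 1) "," else ""))
  # pad header with spaces so that 10 + header length is a multiple of 64
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L)),
    writeBin(nchar(header), raw(), size = 2L, endian = "little"),
    charToRaw(header), array_to_raw(x, dtype))
}

npy_decode <- function(bytes) {
  if (length(bytes) < 10L || !identical(bytes[1:6], c(as.raw(0x93), charToRaw("NUMPY")))) {
    vox_abort("not an NPY payload (bad magic)", "format")
  }
  hlen <- readBin(bytes[9:10], "integer", size = 2L, signed = FALSE, endian = "little")
  if (length(bytes) < 10L + hlen) vox_abort("truncated NPY header", "format")
  header <- rawToChar(bytes[11:(10L + hlen)])
  descr <- regmatches(header, regexec("'descr':\\s*'([^']+)'", header))[[1]][2]
  fortran <- regmatches(header, regexec("'fortran_order':\\s*(True|False)", header))[[1]][2]
  shape_str <- regmatches(header, regexec("'shape':\\s*\\(([^)]*)\\)", header))[[1]][2]
  if (is.na(descr) || is.na(fortran) || is.na(shape_str)) {
    vox_abort("unparseable NPY header", "format")
  }
  if (fortran == "True") vox_abort("fortran-order NPY payloads are unsupported", "format")
  shape <- as.double(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  dtype <- descr_dtype(descr)
  n <- prod(shape)
  v <- raw_to_vector(bytes[(11L + hlen):length(bytes)], dtype, n)
  data <- if (length(shape) > 1) array(v, dim = rev(shape)) else v
  list(data = data, dtype = dtype, shape = shape)
}

#' Read and write NPY array files
#'
#' Standalone helpers around the NPY v1.0 codec used by
#' [vox_encode_cutout()]; files interoperate with NumPy (`np.load`/`np.save`)
#' for uint8/uint16/uint64 arrays.
#'
#' @param x Dense array; `file` path to write/read.
#' @param dtype Voxel dtype.
#' @param file Path.
#' @return `read_npy`: list with `data` (array, `dim` in x/y/z order) and
#'   `dtype`.
#' @export
write_npy <- function(x, file, dtype) {
  writeBin(npy_encode(x, dtype), file)
  invisible(file)
}

#' @rdname write_npy
#' @export
read_npy <- function(file) {
  npy_decode(readBin(file, raw(), n = file.size(file)))
}
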