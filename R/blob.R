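# Blob container: the serialized form of one cuboid (or cutout payload).
# Layout: 16-byte magic+version block, 4-byte little-endian header length,
# JSON header (codec, dtype, shape, endianness, optional attributes), then
# the (optionally compressed) little-endian C-order voxel payload.

BLOB_MAGIC <- c(charToRaw("VOXBLOB"), as.raw(1L), as.raw(rep(0L, 8L)))

#' Serialize an array to a compressed blob
#'
#' Produces a self-describing byte container for a dense voxel array. The
#' header (codec, dtype, shape, endianness) is readable without decompressing
#' the payload; decompression is bit-lossless for every supported dtype.
#'
#' @param x Dense numeric array (or vector with `shape`).
#' @param dtype Voxel data type (see [dtype_info()]).
#' @param codec `"zlib"` or `"none"`.
#' @param shape Array shape `(x, y, z)`; defaults to `dim(x)`.
#' @param attrs Optional named list of extra header attributes (used by the
#'   cutout encoder to record range/resolution).
#' @return A raw vector.
#' @seealso [vox_decompress()]
#' @export
#' @examples
#' blob <- vox_compress(array(0, c(4, 4, 2)), "uint8")
#' dim(vox_decompress(blob)$data)
vox_compress <- function(x, dtype, codec = "zlib", shape = dim(x), attrs = NULL) {
  if (is.null(shape)) shape <- length(x)
  payload <- array_to_raw(x, dtype)
  body <- switch(codec,
    zlib = memCompress(payload, type = "gzip"),
    none = payload,
    vox_abort(sprintf("unknown codec '%s'", codec), "validation")
  )
  header <- list(codec = codec, dtype = dtype, shape = as.double(shape),
                 endianness = "little", order = "C")
  if (!is.null(attrs)) header <- c(header, list(attrs = attrs))
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  c(BLOB_MAGIC,
    writeBin(length(hjson), raw(), size = 4L, endian = "little"),
    hjson, body)
}

# Parse header without touching the payload.
blob_header <- function(blob) {
  if (length(blob) < 20L || !identical(blob[1:8], BLOB_MAGIC[1:8])) {
    vox_abort("not a voxstore blob (bad magic)", "format")
  }
  hlen <- readBin(blob[17:20], "integer", size = 4L, endian = "little")
  if (length(blob) < 20L + hlen) vox_abort("truncated blob header", "format")
  header <- jsonlite::fromJSON(rawToChar(blob[21:(20L + hlen)]),
                               simplifyVector = TRUE)
  header$payload_offset <- 20L + hlen
  header
}

#' Deserialize a blob
#'
#' @param blob Raw vector produced by [vox_compress()].
#' @return A list with `data` (array of the recorded shape), `dtype`, `shape`,
#'   and `attrs` (possibly `NULL`).
#' @export
vox_decompress <- function(blob) {
  h <- blob_header(blob)
  if (!h$codec %in% c("zlib", "none")) {
    vox_abort(sprintf("unknown codec '%s' in blob header", h$codec), "format")
  }
  body <- blob[(h$payload_offset + 1L):length(blob)]
  payload <- tryCatch(
    switch(h$codec,
      zlib = memDecompress(body, type = "gzip"),
      none = body
    ),
    error = function(e) vox_abort("corrupt blob payload", "format")
  )
  n <- prod(h$shape)
  v <- raw_to_vector(payload, h$dtype, n)
  data <- if (length(h$shape) > 1) array(v, dim = h$shape) else v
  list(data = data, dtype = h$dtype, shape = h$shape, attrs = h$attrs)
}
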