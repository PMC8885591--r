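# Internal utilities: condition classes, dtype byte codecs, voxel ranges,
# and path-pattern templating shared across the package.

vox_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("vox_error_", class), "vox_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Supported voxel data types
#'
#' The store supports two image data types (`uint8`, `uint16`) and one
#' annotation data type (`uint64`). Voxel values are held in R as doubles;
#' uint64 labels are exact for values below 2^53, far beyond any realistic
#' object-id budget. Serialization writes true fixed-width little-endian
#' unsigned integers.
#'
#' @param dtype Data type name, one of `"uint8"`, `"uint16"`, `"uint64"`.
#' @return A list with elements `name`, `size` (bytes per voxel) and `max`
#'   (largest representable value).
#' @export
#' @examples
#' dtype_info("uint16")$max
dtype_info <- function(dtype) {
  switch(dtype,
    uint8  = list(name = "uint8",  size = 1L, max = 255),
    uint16 = list(name = "uint16", size = 2L, max = 65535),
    uint64 = list(name = "uint64", size = 8L, max = 2^53),
    vox_abort(sprintf("unsupported dtype '%s'", dtype), "validation")
  )
}

# Dense numeric vector/array -> little-endian raw bytes of the given dtype.
array_to_raw <- function(x, dtype) {
  v <- as.vector(x)
  info <- dtype_info(dtype)
  if (anyNA(v)) vox_abort("NA voxel values are not representable", "validation")
  if (any(v < 0) || any(v > info$max) || any(v != floor(v))) {
    vox_abort(sprintf("values out of range for %s", dtype), "validation")
  }
  switch(dtype,
    uint8 = writeBin(as.integer(v), raw(), size = 1L, endian = "little"),
    uint16 = writeBin(as.integer(v), raw(), size = 2L, endian = "little"),
    uint64 = {
      lo <- v %% 4294967296
      hi <- v %/% 4294967296
      # reinterpret as signed 32-bit for writeBin
      lo <- as.integer(lo - 4294967296 * (lo >= 2147483648))
      hi <- as.integer(hi - 4294967296 * (hi >= 2147483648))
      words <- integer(2L * length(v))
      words[c(TRUE, FALSE)] <- lo
      words[c(FALSE, TRUE)] <- hi
      writeBin(words, raw(), size = 4L, endian = "little")
    }
  )
}

# Inverse of array_to_raw; returns a plain double vector of length n.
raw_to_vector <- function(bytes, dtype, n) {
  info <- dtype_info(dtype)
  if (length(bytes) != n * info$size) {
    vox_abort(sprintf(
      "payload has %d bytes, expected %d for %d %s voxels",
      length(bytes), n * info$size, n, dtype
    ), "format")
  }
  switch(dtype,
    uint8 = as.double(readBin(bytes, "integer", n = n, size = 1L,
                              signed = FALSE, endian = "little")),
    uint16 = as.double(readBin(bytes, "integer", n = n, size = 2L,
                               signed = FALSE, endian = "little")),
    uint64 = {
      words <- readBin(bytes, "integer", n = 2L * n, size = 4L,
                       signed = TRUE, endian = "little")
      w <- as.double(words)
      w <- w + 4294967296 * (w < 0)
      w[c(TRUE, FALSE)] + 4294967296 * w[c(FALSE, TRUE)]
    }
  )
}

#' Construct a half-open voxel range
#'
#' Ranges are 0-based and half-open per axis: `[x0, x1) x [y0, y1) x [z0, z1)`,
#' matching the slicing convention of array-style volumetric APIs.
#'
#' @param x,y,z Length-2 integer vectors `c(start, stop)` per axis.
#' @return An object of class `vox_range`.
#' @export
#' @examples
#' vox_range(c(0, 512), c(0, 512), c(0, 16))
vox_range <- function(x, y, z) {
  for (a in list(x = x, y = y, z = z)) {
    if (length(a) != 2 || anyNA(a) || any(a < 0) || any(a != floor(a))) {
      vox_abort("range axes must be non-negative integer pairs", "validation")
    }
  }
  if (x[1] >= x[2] || y[1] >= y[2] || z[1] >= z[2]) {
    vox_abort("empty voxel range: need start < stop on every axis", "validation")
  }
  structure(list(x = as.double(x), y = as.double(y), z = as.double(z)),
            class = "vox_range")
}

#' @export
print.vox_range <- function(x, ...) {
  cat(sprintf("<vox_range x[%d,%d) y[%d,%d) z[%d,%d)>\n",
              x$x[1], x$x[2], x$y[1], x$y[2], x$z[1], x$z[2]))
  invisible(x)
}

#' @export
dim.vox_range <- function(x) {
  c(x$x[2] - x$x[1], x$y[2] - x$y[1], x$z[2] - x$z[1])
}

range_volume <- function(r) prod(dim(r))

range_intersect <- function(a, b) {
  x <- c(max(a$x[1], b$x[1]), min(a$x[2], b$x[2]))
  y <- c(max(a$y[1], b$y[1]), min(a$y[2], b$y[2]))
  z <- c(max(a$z[1], b$z[1]), min(a$z[2], b$z[2]))
  if (x[1] >= x[2] || y[1] >= y[2] || z[1] >= z[2]) return(NULL)
  vox_range(x, y, z)
}

range_union <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  vox_range(c(min(a$x[1], b$x[1]), max(a$x[2], b$x[2])),
            c(min(a$y[1], b$y[1]), max(a$y[2], b$y[2])),
            c(min(a$z[1], b$z[1]), max(a$z[2], b$z[2])))
}

range_contains <- function(outer, inner) {
  outer$x[1] <= inner$x[1] && inner$x[2] <= outer$x[2] &&
    outer$y[1] <= inner$y[1] && inner$y[2] <= outer$y[2] &&
    outer$z[1] <= inner$z[1] && inner$z[2] <= outer$z[2]
}

# R index sequences (1-based) for placing `r` relative to an origin.
rel_idx <- function(r, origin) {
  list(
    x = seq.int(r$x[1] - origin[1] + 1, r$x[2] - origin[1]),
    y = seq.int(r$y[1] - origin[2] + 1, r$y[2] - origin[2]),
    z = seq.int(r$z[1] - origin[3] + 1, r$z[2] - origin[3])
  )
}

#' Fill a path pattern with task coordinates
#'
#' Patterns contain placeholders `{x}`, `{y}`, `{z}`, `{t}` with an optional
#' zero-padding width, e.g. `"tiles/z{z:04d}/y{y}_x{x}.png"`.
#'
#' @param pattern Template string.
#' @param fields Named list/vector of integer values (`x`, `y`, `z`, `t`, ...).
#' @return The formatted path.
#' @export
#' @examples
#' format_path("tiles/z{z:04d}/y{y}_x{x}.png", list(x = 1, y = 2, z = 3))
format_path <- function(pattern, fields) {
  out <- pattern
  m <- gregexpr("\\{([a-zA-Z_]+)(:0([0-9]+)d)?\\}", pattern, perl = TRUE)
  toks <- regmatches(pattern, m)[[1]]
  for (tok in unique(toks)) {
    parts <- regmatches(tok, regexec("\\{([a-zA-Z_]+)(:0([0-9]+)d)?\\}", tok))[[1]]
    nm <- parts[2]
    if (is.null(fields[[nm]])) {
      vox_abort(sprintf("pattern field '%s' missing from task", nm), "validation")
    }
    val <- fields[[nm]]
    rep_str <- if (nzchar(parts[3])) {
      formatC(val, width = as.integer(parts[4]), flag = "0", format = "d")
    } else {
      format(val, scientific = FALSE, trim = TRUE)
    }
    out <- gsub(tok, rep_str, out, fixed = TRUE)
  }
  out
}

# identifier strings must be URI-safe
check_identifier <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || is.na(x) || !grepl("^[A-Za-z0-9_-]+$", x)) {
    vox_abort(sprintf("%s must match [A-Za-z0-9_-]+ (got '%s')", what, x), "validation")
  }
  x
}
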