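# Morton-order (z-order) addressing of cuboid chunks and decomposition of
# voxel ranges into the cuboids they intersect.

# Exact double arithmetic bounds the code below 2^51, keeping every code an
# exact integer in an R double (doubles lose exactness at 2^53).
MORTON_COORD_BITS <- 17L
MORTON_COORD_MAX <- 2^17

#' Morton (z-order) encoding of chunk coordinates
#'
#' Interleaves the bits of the three chunk coordinates into a single integer
#' code so that nearby chunks receive nearby codes. The bit convention places
#' `cx` in bit positions `3i` (least significant), `cy` in `3i + 1`, and `cz`
#' in `3i + 2`.
#'
#' Coordinates must be below 2^17 per axis so that every code is an exact
#' integer in a double (codes stay below 2^51). At the default cuboid shape
#' this addresses volumes beyond 10^7 voxels per axis.
#'
#' @param cx,cy,cz Non-negative chunk coordinates (vectorized).
#' @return Numeric vector of Morton codes.
#' @seealso [morton_decode()]
#' @export
#' @examples
#' morton_encode(1, 2, 3)  # 53
#' morton_decode(53)
morton_encode <- function(cx, cy, cz) {
  n <- max(length(cx), length(cy), length(cz))
  cx <- rep_len(as.double(cx), n); cy <- rep_len(as.double(cy), n)
  cz <- rep_len(as.double(cz), n)
  if (anyNA(cx) || anyNA(cy) || anyNA(cz) ||
      any(cx < 0 | cy < 0 | cz < 0) ||
      any(cx != floor(cx) | cy != floor(cy) | cz != floor(cz))) {
    vox_abort("chunk coordinates must be non-negative integers", "validation")
  }
  if (any(cx >= MORTON_COORD_MAX | cy >= MORTON_COORD_MAX | cz >= MORTON_COORD_MAX)) {
    vox_abort(sprintf("chunk coordinates must be < 2^%d", MORTON_COORD_BITS), "range")
  }
  code <- numeric(n)
  for (i in 0:(MORTON_COORD_BITS - 1L)) {
    p <- 2^i
    code <- code +
      (cx %/% p %% 2) * 2^(3 * i) +
      (cy %/% p %% 2) * 2^(3 * i + 1) +
      (cz %/% p %% 2) * 2^(3 * i + 2)
  }
  code
}

#' Morton (z-order) decoding
#'
#' Exact inverse of [morton_encode()].
#'
#' @param code Numeric vector of Morton codes.
#' @return A data.frame with columns `cx`, `cy`, `cz`.
#' @export
morton_decode <- function(code) {
  code <- as.double(code)
  if (anyNA(code) || any(code < 0) || any(code != floor(code))) {
    vox_abort("Morton codes must be non-negative integers", "validation")
  }
  if (any(code >= 2^(3 * MORTON_COORD_BITS))) {
    vox_abort(sprintf("Morton codes must be < 2^%d", 3L * MORTON_COORD_BITS), "range")
  }
  cx <- numeric(length(code)); cy <- cx; cz <- cx
  for (i in 0:(MORTON_COORD_BITS - 1L)) {
    cx <- cx + (code %/% 2^(3 * i) %% 2) * 2^i
    cy <- cy + (code %/% 2^(3 * i + 1) %% 2) * 2^i
    cz <- cz + (code %/% 2^(3 * i + 2) %% 2) * 2^i
  }
  data.frame(cx = cx, cy = cy, cz = cz)
}

#' Decompose a voxel range into the cuboids it intersects
#'
#' Splits an arbitrary half-open voxel range on the cuboid grid. The returned
#' intersections are pairwise disjoint and tile the request exactly; rows are
#' ordered by ascending Morton code.
#'
#' @param range A [vox_range()].
#' @param shape Cuboid shape, integer triple (voxels per cuboid per axis).
#' @return A data.frame with one row per intersected cuboid: chunk coordinates
#'   (`cx`, `cy`, `cz`), `morton` code, the global-coordinate intersection
#'   bounds (`x0`,`x1`,`y0`,`y1`,`z0`,`z1`, half-open), and the destination
#'   offsets (`dx`,`dy`,`dz`) of the intersection inside the requested range.
#' @export
#' @examples
#' cuboids_for_range(vox_range(c(500, 530), c(0, 1), c(15, 17)), c(512, 512, 16))
cuboids_for_range <- function(range, shape) {
  if (!inherits(range, "vox_range")) vox_abort("range must be a vox_range", "validation")
  shape <- as.double(shape)
  if (length(shape) != 3 || any(shape < 1) || any(shape != floor(shape))) {
    vox_abort("cuboid shape must be three positive integers", "validation")
  }
  cx <- seq.int(range$x[1] %/% shape[1], (range$x[2] - 1) %/% shape[1])
  cy <- seq.int(range$y[1] %/% shape[2], (range$y[2] - 1) %/% shape[2])
  cz <- seq.int(range$z[1] %/% shape[3], (range$z[2] - 1) %/% shape[3])
  g <- expand.grid(cx = cx, cy = cy, cz = cz)
  x0 <- pmax(g$cx * shape[1], range$x[1]); x1 <- pmin((g$cx + 1) * shape[1], range$x[2])
  y0 <- pmax(g$cy * shape[2], range$y[1]); y1 <- pmin((g$cy + 1) * shape[2], range$y[2])
  z0 <- pmax(g$cz * shape[3], range$z[1]); z1 <- pmin((g$cz + 1) * shape[3], range$z[2])
  out <- data.frame(
    cx = g$cx, cy = g$cy, cz = g$cz,
    morton = morton_encode(g$cx, g$cy, g$cz),
    x0 = x0, x1 = x1, y0 = y0, y1 = y1, z0 = z0, z1 = z1,
    dx = x0 - range$x[1], dy = y0 - range$y[1], dz = z0 - range$z[1]
  )
  out[order(out$morton), , drop = FALSE]
}
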