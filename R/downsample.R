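# Multi-resolution hierarchy: anisotropy-aware factor schedule, image and
# annotation reduction, full hierarchy builds, and partial rebuilds of
# changed footprints.

#' Anisotropy-aware downsample factor schedule
#'
#' Derives the per-level downsampling factor triples for a coordinate frame.
#' Volumes with anisotropic voxels (e.g. 4 x 4 x 40 nm serial-section EM) are
#' reduced in the image plane only — factors (2, 2, 1) — while the z/xy voxel
#' size ratio at the source level is at least 2; once near-isotropy is
#' reached, reduction proceeds equally in all dimensions with (2, 2, 2).
#' Isotropic frames use (2, 2, 2) throughout. For a 4/4/40 nm frame this
#' yields 8, 16 and 32 nm in-plane at levels 1-3 with z fixed at 40 nm, after
#' which the residual anisotropy shrinks at every further level.
#'
#' Extents follow `extent[L+1] = ceiling(extent[L] / factors)` and voxel
#' sizes `size[L+1] = size[L] * factors`; both are derived, never stored.
#'
#' @param frame A [coord_frame()].
#' @param levels Number of level transitions (hierarchy has `levels + 1`
#'   levels including native level 0).
#' @return A data.frame with one row per level 0..levels: the factor triple
#'   applied to reach the level (`fx`, `fy`, `fz`; 1s at level 0), the voxel
#'   sizes (`size_x`, `size_y`, `size_z`, nm) and extents (`ext_x`, `ext_y`,
#'   `ext_z`). An `extent` list-column carries the extent triples.
#' @export
#' @examples
#' factor_schedule(coord_frame(c(2048, 2048, 128), c(4, 4, 40)), levels = 4)
factor_schedule <- function(frame, levels) {
  if (!inherits(frame, "vox_coord_frame")) {
    vox_abort("frame must be a coord_frame()", "validation")
  }
  if (levels < 0) vox_abort("levels must be >= 0", "validation")
  size <- frame$voxel_size
  ext <- frame$extent
  rows <- vector("list", levels + 1)
  rows[[1]] <- list(level = 0, fx = 1, fy = 1, fz = 1,
                    size_x = size[1], size_y = size[2], size_z = size[3],
                    ext_x = ext[1], ext_y = ext[2], ext_z = ext[3])
  if (levels >= 1) {
    for (L in seq_len(levels)) {
      xy <- (size[1] + size[2]) / 2
      f <- if (size[3] / xy >= 2) c(2, 2, 1) else c(2, 2, 2)
      size <- size * f
      ext <- ceiling(ext / f)
      rows[[L + 1]] <- list(level = L, fx = f[1], fy = f[2], fz = f[3],
                            size_x = size[1], size_y = size[2], size_z = size[3],
                            ext_x = ext[1], ext_y = ext[2], ext_z = ext[3])
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$extent <- lapply(rows, function(r) c(r$ext_x, r$ext_y, r$ext_z))
  out
}

#' Reduce one factor-shaped block to a scalar
#'
#' The per-voxel reduction operator of the hierarchy. Image channels take the
#' arithmetic mean rounded half-up; annotation channels take the mode of the
#' nonzero labels with ties broken toward the smallest id, returning 0 only
#' for an all-background block (thin objects therefore survive reduction
#' better than under corner sampling, and builds are deterministic).
#'
#' @param block Dense array whose `dim` equals the factor triple.
#' @param channel_type `"image"` or `"annotation"`.
#' @param factors The expected factor triple (validated against the block).
#' @return A scalar voxel value.
#' @export
#' @examples
#' reduce_block(array(c(1, 2, 3, 4), c(2, 2, 1)), "image")       # 3
#' reduce_block(array(c(0, 7, 7, 9), c(2, 2, 1)), "annotation")  # 7
reduce_block <- function(block, channel_type, factors = dim(block)) {
  if (!identical(as.double(dim(block)), as.double(factors))) {
    vox_abort("block shape does not match the factor triple", "validation")
  }
  v <- as.vector(block)
  if (channel_type == "image") {
    floor(mean(v) + 0.5)
  } else {
    v <- v[v != 0]
    if (!length(v)) return(0)
    tab <- table(v)
    ids <- as.double(names(tab))
    ids[order(-as.vector(tab), ids)][1]
  }
}

# Vectorized reduction of an array whose dims are multiples of f.
# `valid` is an optional 0/1 array marking in-frame voxels; image means are
# taken over valid voxels only so frame-edge padding never dilutes them.
reduce_array <- function(a, f, channel_type, valid = NULL) {
  d <- dim(a)
  td <- d / f
  k <- prod(f)
  cols <- matrix(0, prod(td), k)
  vcols <- if (is.null(valid)) NULL else matrix(0, prod(td), k)
  m <- 0L
  for (oz in seq_len(f[3])) for (oy in seq_len(f[2])) for (ox in seq_len(f[1])) {
    m <- m + 1L
    sx <- seq.int(ox, d[1], f[1]); sy <- seq.int(oy, d[2], f[2])
    sz <- seq.int(oz, d[3], f[3])
    cols[, m] <- a[sx, sy, sz]
    if (!is.null(vcols)) vcols[, m] <- valid[sx, sy, sz]
  }
  if (channel_type == "image") {
    if (is.null(vcols)) {
      out <- floor(rowMeans(cols) + 0.5)
    } else {
      cnt <- rowSums(vcols)
      cnt[cnt == 0] <- 1
      out <- floor(rowSums(cols * vcols) / cnt + 0.5)
    }
  } else {
    ids <- sort(unique(as.vector(cols)))
    ids <- ids[ids != 0]
    if (!length(ids)) {
      out <- numeric(nrow(cols))
    } else {
      counts <- vapply(ids, function(id) rowSums(cols == id), numeric(nrow(cols)))
      counts <- matrix(counts, nrow = nrow(cols))
      best <- max.col(counts, ties.method = "first")  # ids ascending -> smallest wins
      out <- ids[best]
      out[rowSums(counts) == 0] <- 0
    }
  }
  array(out, td)
}

# Recompute one target cuboid at level L+1 from level-L data.
# Returns TRUE if the cuboid was written.
build_target_cuboid <- function(store, channel, L, f, src_ext, tgt_ext, row, t) {
  shape <- channel$cuboid_shape
  corner <- c(row$cx, row$cy, row$cz) * shape
  tgt_hi <- pmin(corner + shape, tgt_ext)
  tdim <- tgt_hi - corner
  src_lo <- corner * f
  src_hi <- pmin(tgt_hi * f, src_ext)
  src_range <- vox_range(c(src_lo[1], src_hi[1]), c(src_lo[2], src_hi[2]),
                         c(src_lo[3], src_hi[3]))
  src_plan <- cuboids_for_range(src_range, shape)
  any_src <- FALSE
  for (j in seq_len(nrow(src_plan))) {
    if (vox_contains(store, cuboid_key(channel, L, src_plan$morton[j], t))) {
      any_src <- TRUE
      break
    }
  }
  tkey <- cuboid_key(channel, L + 1, row$morton, t)
  if (!any_src && !vox_contains(store, tkey)) return(FALSE)
  src <- vox_read_cutout(store, channel, src_range, L, t)
  need <- tdim * f
  sd <- dim(src)
  padded <- array(0, need)
  valid <- NULL
  if (any(sd < need)) {
    padded[seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3])] <- src
    valid <- array(0, need)
    valid[seq_len(sd[1]), seq_len(sd[2]), seq_len(sd[3])] <- 1
  } else {
    padded <- src
  }
  red <- reduce_array(padded, f, channel$channel_type, valid)
  cub <- array(0, shape)
  cub[seq_len(tdim[1]), seq_len(tdim[2]), seq_len(tdim[3])] <- red
  vox_put_cuboid(store, tkey, cub)
  if (channel$channel_type == "annotation") update_indices(store, tkey, cub)
  TRUE
}

#' Build the resolution hierarchy of a channel
#'
#' Iteratively populates levels 1..`levels` by reducing the level below with
#' the frame's factor schedule. Absent source cuboids are treated as
#' background; regions with no stored source data stay absent at higher
#' levels, so sparse channels stay sparse. Annotation levels gain their own
#' spatial indices as they are built.
#'
#' @param store A [vox_store()].
#' @param channel A `vox_channel` with `num_hierarchy_levels > 1`.
#' @param levels Highest level to build (default: the channel's top level).
#' @export
vox_downsample <- function(store, channel, levels = NULL) {
  levels <- levels %||% (channel$num_hierarchy_levels - 1)
  if (levels < 1) return(invisible(NULL))
  if (levels >= channel$num_hierarchy_levels) {
    vox_abort(sprintf("channel reserves %d level(s); cannot build level %d",
                      channel$num_hierarchy_levels, levels), "validation")
  }
  sched <- factor_schedule(channel$frame, levels)
  for (L in 0:(levels - 1)) {
    f <- c(sched$fx[L + 2], sched$fy[L + 2], sched$fz[L + 2])
    src_ext <- sched$extent[[L + 1]]
    tgt_ext <- sched$extent[[L + 2]]
    full <- vox_range(c(0, tgt_ext[1]), c(0, tgt_ext[2]), c(0, tgt_ext[3]))
    plan <- cuboids_for_range(full, channel$cuboid_shape)
    for (t in 0:(channel$frame$time_extent - 1)) {
      for (i in seq_len(nrow(plan))) {
        build_target_cuboid(store, channel, L, f, src_ext, tgt_ext, plan[i, ], t)
      }
    }
  }
  store$stale[[channel$path]] <- list()
  invisible(NULL)
}

#' Partially rebuild the hierarchy over a changed footprint
#'
#' Recomputes only the ancestors of cuboids intersecting the changed ranges
#' at each level; the result is bit-identical to a full [vox_downsample()]
#' run. With `changed_range = NULL`, the footprints recorded by
#' [vox_write_cutout()] since the last (partial) downsample are used and then
#' cleared.
#'
#' @param store A [vox_store()].
#' @param channel A `vox_channel` whose hierarchy has been built.
#' @param changed_range A [vox_range()] at base resolution, a list of them,
#'   or `NULL` for the recorded stale footprint.
#' @param t Time index.
#' @export
vox_partial_downsample <- function(store, channel, changed_range = NULL, t = 0) {
  levels <- channel$num_hierarchy_levels - 1
  if (levels < 1) vox_abort("channel has no hierarchy to rebuild", "state")
  ranges <- if (is.null(changed_range)) {
    vox_stale_ranges(store, channel)
  } else if (inherits(changed_range, "vox_range")) {
    list(changed_range)
  } else {
    changed_range
  }
  if (!length(ranges)) {
    store$stale[[channel$path]] <- list()
    return(invisible(NULL))
  }
  sched <- factor_schedule(channel$frame, levels)
  for (L in 0:(levels - 1)) {
    f <- c(sched$fx[L + 2], sched$fy[L + 2], sched$fz[L + 2])
    src_ext <- sched$extent[[L + 1]]
    tgt_ext <- sched$extent[[L + 2]]
    seen <- new.env(parent = emptyenv())
    for (r in ranges) {
      # map a base-resolution range down to level L+1 chunk space
      lo <- c(r$x[1], r$y[1], r$z[1])
      hi <- c(r$x[2], r$y[2], r$z[2])
      for (M in 0:L) {
        fm <- c(sched$fx[M + 2], sched$fy[M + 2], sched$fz[M + 2])
        lo <- lo %/% fm
        hi <- ceiling(hi / fm)
      }
      hi <- pmin(hi, tgt_ext)
      if (any(lo >= hi)) next
      tr <- vox_range(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3]))
      plan <- cuboids_for_range(tr, channel$cuboid_shape)
      for (i in seq_len(nrow(plan))) {
        mk <- sprintf("m%.0f", plan$morton[i])
        if (!is.null(seen[[mk]])) next
        seen[[mk]] <- TRUE
        build_target_cuboid(store, channel, L, f, src_ext, tgt_ext, plan[i, ], t)
      }
    }
  }
  if (is.null(changed_range)) store$stale[[channel$path]] <- list()
  invisible(NULL)
}
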