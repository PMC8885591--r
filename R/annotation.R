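# Annotation spatial indices: per annotation channel and resolution level the
# store maintains a forward map (cuboid -> set of nonzero labels present) and
# its exact transpose, a reverse map (label -> set of cuboid Morton codes).
# Both are kept in memory and journalled to a JSON-lines sidecar
# (<root>/index/<collection>.<experiment>.<channel>.jsonl, last line wins per
# cuboid) so they survive restarts and can be rebuilt by a full scan.

ann_sidecar_path <- function(store, channel) {
  file.path(store$root, "index",
            paste0(channel$collection, ".", channel$experiment, ".",
                   channel$name, ".jsonl"))
}

fwd_key <- function(resolution, t, morton) sprintf("%d/t%d/m%.0f", resolution, t, morton)
rev_key <- function(resolution, t, id) sprintf("%d/t%d/i%.0f", resolution, t, id)

get_ann_idx <- function(store, channel) {
  idx <- store$ann_idx[[channel$path]]
  if (!is.null(idx)) return(idx)
  idx <- new.env(parent = emptyenv())
  idx$forward <- new.env(parent = emptyenv())
  idx$reverse <- new.env(parent = emptyenv())
  sc <- ann_sidecar_path(store, channel)
  if (file.exists(sc)) {
    for (line in readLines(sc, warn = FALSE)) {
      if (!nzchar(line)) next
      rec <- jsonlite::fromJSON(line)
      apply_index_record(idx, rec$resolution, rec$t, rec$morton,
                         as.double(unlist(rec$ids)))
    }
  }
  store$ann_idx[[channel$path]] <- idx
  idx
}

# replace the forward set of one cuboid and mirror the delta into the reverse map
apply_index_record <- function(idx, resolution, t, morton, new_ids) {
  fk <- fwd_key(resolution, t, morton)
  old_ids <- idx$forward[[fk]] %||% numeric()
  for (id in setdiff(old_ids, new_ids)) {
    rk <- rev_key(resolution, t, id)
    left <- setdiff(idx$reverse[[rk]] %||% numeric(), morton)
    if (length(left)) idx$reverse[[rk]] <- left
    else if (!is.null(idx$reverse[[rk]])) rm(list = rk, envir = idx$reverse)
  }
  for (id in setdiff(new_ids, old_ids)) {
    rk <- rev_key(resolution, t, id)
    idx$reverse[[rk]] <- sort(c(idx$reverse[[rk]] %||% numeric(), morton))
  }
  if (length(new_ids)) idx$forward[[fk]] <- sort(new_ids)
  else if (!is.null(idx$forward[[fk]])) rm(list = fk, envir = idx$forward)
  invisible(NULL)
}

check_annotation <- function(channel) {
  if (channel$channel_type != "annotation") {
    vox_abort(sprintf("'%s' is not an annotation channel", channel$path), "type")
  }
}

# called by vox_write_cutout / downsample for every written annotation cuboid
update_indices <- function(store, key, new_cuboid) {
  idx <- get_ann_idx(store, key$channel)
  new_ids <- sort(unique(as.vector(new_cuboid)))
  new_ids <- new_ids[new_ids != 0]
  fk <- fwd_key(key$resolution, key$t, key$morton)
  if (identical(idx$forward[[fk]] %||% numeric(), new_ids)) return(invisible(NULL))
  apply_index_record(idx, key$resolution, key$t, key$morton, new_ids)
  line <- jsonlite::toJSON(list(resolution = key$resolution, t = key$t,
                                morton = key$morton, ids = new_ids),
                           auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = ann_sidecar_path(store, key$channel),
      append = TRUE)
  invisible(NULL)
}

#' Annotation ids present in one cuboid
#'
#' Index-only lookup of the distinct nonzero labels stored in a cuboid.
#'
#' @param store A [vox_store()].
#' @param channel An annotation `vox_channel`.
#' @param morton Morton code of the cuboid.
#' @param resolution,t Level and time index.
#' @return Sorted numeric vector of label ids (possibly empty).
#' @export
vox_ids_in_cuboid <- function(store, channel, morton, resolution = 0, t = 0) {
  check_annotation(channel)
  idx <- get_ann_idx(store, channel)
  idx$forward[[fwd_key(resolution, t, morton)]] %||% numeric()
}

#' Cuboids containing an annotation id
#'
#' Index-only reverse lookup: the Morton codes of every cuboid in which the
#' label occurs at the given level.
#'
#' @inheritParams vox_ids_in_cuboid
#' @param id Nonzero annotation label.
#' @return Sorted numeric vector of Morton codes (possibly empty).
#' @export
vox_cuboids_of_id <- function(store, channel, id, resolution = 0, t = 0) {
  check_annotation(channel)
  if (id == 0) vox_abort("label 0 is reserved background", "validation")
  idx <- get_ann_idx(store, channel)
  idx$reverse[[rev_key(resolution, t, id)]] %||% numeric()
}

#' Annotation ids present in a region
#'
#' Exact by default: candidate labels come from the forward index of every
#' intersected cuboid; cuboids only partially covered by the region are then
#' voxel-filtered, so a label living exclusively outside the requested range
#' within a straddling cuboid is excluded. `fast = TRUE` skips the voxel
#' filter and returns the (cheaper) cuboid-level superset.
#'
#' @param store A [vox_store()].
#' @param channel An annotation `vox_channel`.
#' @param range A [vox_range()].
#' @param resolution,t Level and time index.
#' @param fast If `TRUE`, return the cuboid-aligned superset without reading
#'   voxels.
#' @return Sorted numeric vector of label ids.
#' @export
vox_ids_in_region <- function(store, channel, range, resolution = 0, t = 0,
                              fast = FALSE) {
  check_annotation(channel)
  check_cutout_args(store, channel, range, resolution, t)
  idx <- get_ann_idx(store, channel)
  plan <- cuboids_for_range(range, channel$cuboid_shape)
  ext <- channel_extent(channel, resolution)
  shape <- channel$cuboid_shape
  ids <- numeric()
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    cand <- idx$forward[[fwd_key(resolution, t, row$morton)]] %||% numeric()
    if (!length(cand)) next
    # the in-frame voxel extent of this cuboid
    full <- c(row$x0 == row$cx * shape[1], row$x1 == min((row$cx + 1) * shape[1], ext[1]),
              row$y0 == row$cy * shape[2], row$y1 == min((row$cy + 1) * shape[2], ext[2]),
              row$z0 == row$cz * shape[3], row$z1 == min((row$cz + 1) * shape[3], ext[3]))
    if (fast || all(full)) {
      ids <- c(ids, cand)
    } else {
      part <- vox_read_cutout(store, channel,
                              vox_range(c(row$x0, row$x1), c(row$y0, row$y1),
                                        c(row$z0, row$z1)), resolution, t)
      ids <- c(ids, intersect(cand, unique(as.vector(part))))
    }
  }
  sort(unique(ids))
}

#' Bounding box of an annotation
#'
#' `mode = "loose"` answers from the index alone: the union of the voxel
#' extents of every cuboid containing the id (cuboid-aligned, no voxel
#' reads). `mode = "tight"` reads those candidate cuboids and returns the
#' minimal half-open range containing every voxel equal to the id; the tight
#' box is always contained in the loose box.
#'
#' @inheritParams vox_cuboids_of_id
#' @param mode `"tight"` or `"loose"`.
#' @return A [vox_range()].
#' @export
vox_bounding_box <- function(store, channel, id, mode = c("tight", "loose"),
                             resolution = 0, t = 0) {
  mode <- match.arg(mode)
  check_annotation(channel)
  if (id == 0) vox_abort("label 0 is reserved background", "validation")
  mortons <- vox_cuboids_of_id(store, channel, id, resolution, t)
  if (!length(mortons)) {
    vox_abort(sprintf("id %.0f not present in '%s' at level %d", id,
                      channel$path, resolution), "not_found")
  }
  shape <- channel$cuboid_shape
  ext <- channel_extent(channel, resolution)
  cc <- morton_decode(mortons)
  if (mode == "loose") {
    x0 <- min(cc$cx) * shape[1]; x1 <- min(max(cc$cx + 1) * shape[1], ext[1])
    y0 <- min(cc$cy) * shape[2]; y1 <- min(max(cc$cy + 1) * shape[2], ext[2])
    z0 <- min(cc$cz) * shape[3]; z1 <- min(max(cc$cz + 1) * shape[3], ext[3])
    return(vox_range(c(x0, x1), c(y0, y1), c(z0, z1)))
  }
  lo <- c(Inf, Inf, Inf); hi <- c(-Inf, -Inf, -Inf)
  for (i in seq_len(nrow(cc))) {
    key <- cuboid_key(channel, resolution, mortons[i], t)
    cub <- vox_get_cuboid(store, key)
    if (is.null(cub)) next
    w <- which(cub == id)
    if (!length(w)) next
    pos <- arrayInd(w, dim(cub))  # 1-based local coords
    corner <- c(cc$cx[i], cc$cy[i], cc$cz[i]) * shape
    lo <- pmin(lo, corner + apply(pos, 2, min) - 1)
    hi <- pmax(hi, corner + apply(pos, 2, max))
  }
  if (!is.finite(lo[1])) {
    vox_abort(sprintf("id %.0f indexed but not found in voxels (stale index?)", id),
              "corruption")
  }
  vox_range(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3]))
}

#' Rebuild annotation indices by full scan
#'
#' Recomputes the forward and reverse maps of an annotation channel from the
#' stored cuboids and rewrites the JSON-lines sidecar — the recovery path
#' after a crash between a cuboid write and its index update.
#'
#' @param store A [vox_store()].
#' @param channel An annotation `vox_channel`.
#' @export
vox_reindex <- function(store, channel) {
  check_annotation(channel)
  prefix <- paste0(channel$collection, "/", channel$experiment, "/",
                   channel$name, "/")
  all_keys <- vox_list_cuboids(store)
  okeys <- all_keys[startsWith(all_keys, prefix)]
  idx <- new.env(parent = emptyenv())
  idx$forward <- new.env(parent = emptyenv())
  idx$reverse <- new.env(parent = emptyenv())
  store$ann_idx[[channel$path]] <- idx
  sc <- ann_sidecar_path(store, channel)
  if (file.exists(sc)) unlink(sc)
  for (okey in okeys) {
    parts <- strsplit(sub(prefix, "", okey, fixed = TRUE), "/")[[1]]
    resolution <- as.integer(parts[1])
    t <- as.integer(sub("^t", "", parts[2]))
    morton <- as.double(sub("^m", "", parts[3]))
    key <- cuboid_key(channel, resolution, morton, t)
    cub <- vox_get_cuboid(store, key)
    update_indices(store, key, cub)
  }
  invisible(NULL)
}
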