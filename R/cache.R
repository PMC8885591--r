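# Tiered storage: an in-memory LRU cuboid cache over the on-disk object
# store, the cuboid-existence index, and instrumentation counters.
#
# The object store is a directory tree keyed by the stable object key string
# <collection>/<experiment>/<channel>/<resolution>/t<t>/m<morton>, mirroring
# immutable put/get-by-key object storage semantics on the local filesystem.

#' Address one stored cuboid
#'
#' @param channel A `vox_channel` handle.
#' @param resolution Resolution level (0 = native).
#' @param t Time index (default 0).
#' @param morton Morton code of the cuboid's chunk coordinate.
#' @return A `vox_cuboid_key`.
#' @export
cuboid_key <- function(channel, resolution, morton, t = 0) {
  if (resolution < 0 || t < 0 || morton < 0) {
    vox_abort("resolution, t and morton must be non-negative", "validation")
  }
  structure(list(channel = channel, resolution = as.double(resolution),
                 t = as.double(t), morton = as.double(morton)),
            class = "vox_cuboid_key")
}

# the documented stable object key string
object_key <- function(key) {
  sprintf("%s/%s/%s/%d/t%d/m%.0f",
          key$channel$collection, key$channel$experiment, key$channel$name,
          key$resolution, key$t, key$morton)
}

object_path <- function(store, key) file.path(store$root, "objects", object_key(key))

bump <- function(store, counter, by = 1) {
  store$counters[[counter]] <- store$counters[[counter]] + by
}

#' Cache and object-store instrumentation
#'
#' Returns the operation counters of a store: cache hits/misses and
#' object-store reads/writes. Useful for verifying cache behaviour (a repeat
#' read must not touch the object store) and write amplification.
#'
#' @param store A [vox_store()].
#' @return Named list of counters.
#' @export
vox_counters <- function(store) {
  as.list(store$counters)
}

cache_entry_count <- function(store) length(ls(store$cache))

touch <- function(store, okey) {
  store$clock <- store$clock + 1
  store$cache[[okey]]$atime <- store$clock
}

flush_entry <- function(store, okey) {
  e <- store$cache[[okey]]
  if (isTRUE(e$dirty)) {
    write_object(store, e$key, e$data)
    store$cache[[okey]]$dirty <- FALSE
  }
}

write_object <- function(store, key, data) {
  blob <- vox_compress(data, key$channel$datatype, codec = store$config$codec)
  p <- object_path(store, key)
  dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
  writeBin(blob, p)
  store$cuboid_index[[object_key(key)]] <- TRUE
  bump(store, "store_writes")
}

ensure_capacity <- function(store) {
  n <- cache_entry_count(store) - store$config$cache_capacity
  if (n > 0) vox_evict(store, n)
}

#' Store one cuboid
#'
#' Inserts a full cuboid (shape must equal the channel's cuboid shape) into
#' the cache and — under the default write-through policy — immediately into
#' the compressed object store. The cuboid-existence index is updated so that
#' later reads of other keys can short-circuit without touching the disk.
#'
#' @param store A [vox_store()].
#' @param key A [cuboid_key()].
#' @param data Dense array whose `dim` equals the channel's cuboid shape.
#' @export
vox_put_cuboid <- function(store, key, data) {
  ch <- key$channel
  if (!identical(as.double(dim(data)), ch$cuboid_shape)) {
    vox_abort(sprintf("cuboid shape %s does not match channel shape %s",
                      paste(dim(data), collapse = "x"),
                      paste(ch$cuboid_shape, collapse = "x")), "validation")
  }
  info <- dtype_info(ch$datatype)
  rng <- range(data)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > info$max || any(data != floor(data))) {
    vox_abort(sprintf("voxel values out of range for %s", ch$datatype), "validation")
  }
  okey <- object_key(key)
  check_perm(store, "write", ch$path)
  if (store$config$write_back) {
    # index membership tracks on-disk blobs only; a dirty cached cuboid is
    # found through the cache until its flush adds it to the index
    store$cache[[okey]] <- list(key = key, data = data, dirty = TRUE)
  } else {
    write_object(store, key, data)
    store$cache[[okey]] <- list(key = key, data = data, dirty = FALSE)
  }
  touch(store, okey)
  ensure_capacity(store)
  invisible(NULL)
}

#' Fetch one cuboid
#'
#' Cache hits are served from memory without any object-store access. On a
#' miss the blob is read, decompressed, and promoted into the cache. Keys
#' absent from the cuboid index return `NULL` (the absent-marker) without an
#' object-store read attempt.
#'
#' @param store A [vox_store()].
#' @param key A [cuboid_key()].
#' @return The cuboid array, or `NULL` if the cuboid was never written.
#' @export
vox_get_cuboid <- function(store, key) {
  okey <- object_key(key)
  check_perm(store, "read", key$channel$path)
  e <- store$cache[[okey]]
  if (!is.null(e)) {
    bump(store, "cache_hits")
    touch(store, okey)
    return(e$data)
  }
  if (is.null(store$cuboid_index[[okey]])) return(NULL)
  bump(store, "cache_misses")
  p <- object_path(store, key)
  blob <- tryCatch(readBin(p, raw(), n = file.size(p)),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(blob)) {
    vox_abort(sprintf("cuboid index lists %s but its blob is unreadable", okey),
              "corruption")
  }
  dec <- tryCatch(vox_decompress(blob), error = function(e) {
    vox_abort(sprintf("cuboid blob %s is corrupt: %s", okey,
                      conditionMessage(e)), "corruption")
  })
  bump(store, "store_reads")
  data <- dec$data
  store$cache[[okey]] <- list(key = key, data = data, dirty = FALSE)
  touch(store, okey)
  ensure_capacity(store)
  data
}

#' Does a cuboid exist in the store?
#'
#' Explicitly written all-zero cuboids count as present; never-written keys do
#' not.
#'
#' @inheritParams vox_get_cuboid
#' @return Logical.
#' @export
vox_contains <- function(store, key) {
  okey <- object_key(key)
  !is.null(store$cache[[okey]]) || !is.null(store$cuboid_index[[okey]])
}

#' Evict cuboids from the cache
#'
#' Removes up to `n` cuboids in least-recently-used order. Clean cuboids are
#' dropped first; dirty cuboids (write-back mode) are flushed to the object
#' store before eviction, so an eviction never loses data.
#'
#' @param store A [vox_store()].
#' @param n Maximum number of cuboids to evict.
#' @return Invisibly, the character vector of evicted object keys.
#' @export
vox_evict <- function(store, n) {
  keys <- ls(store$cache)
  if (length(keys) == 0 || n < 1) return(invisible(character()))
  atimes <- vapply(keys, function(k) store$cache[[k]]$atime, numeric(1))
  dirty <- vapply(keys, function(k) isTRUE(store$cache[[k]]$dirty), logical(1))
  # clean-first, then LRU within each class
  ord <- keys[order(dirty, atimes)]
  victims <- utils::head(ord, n)
  for (k in victims) {
    flush_entry(store, k)
    rm(list = k, envir = store$cache)
  }
  invisible(victims)
}

#' Flush dirty cuboids to the object store
#'
#' A no-op under the default write-through policy; in write-back mode this
#' persists every dirty cached cuboid.
#'
#' @param store A [vox_store()].
#' @export
vox_flush <- function(store) {
  for (k in ls(store$cache)) flush_entry(store, k)
  invisible(NULL)
}

#' Drop the entire cache
#'
#' Flushes dirty entries, then empties the cache. Subsequent reads are served
#' from the object store; used by durability checks.
#'
#' @param store A [vox_store()].
#' @export
vox_drop_cache <- function(store) {
  vox_flush(store)
  rm(list = ls(store$cache), envir = store$cache)
  invisible(NULL)
}

#' List stored cuboid object keys
#'
#' @param store A [vox_store()].
#' @return Character vector of object keys currently in the cuboid index.
#' @export
vox_list_cuboids <- function(store) {
  sort(ls(store$cuboid_index))
}
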