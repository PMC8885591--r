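# Core data model: the store handle, the collection/experiment/channel
# catalog, coordinate frames, URI addressing, and per-resource metadata.
#
# The catalog is persisted as one JSON document per collection under
# <root>/catalog/, so the whole state of a store is inspectable with a text
# editor and survives process restarts.

#' Open (or create) a voxel store
#'
#' A store is a directory tree holding a JSON catalog of resources, a
#' compressed cuboid object store, annotation-index sidecars, and ingest job
#' state. The returned handle carries an in-memory LRU cuboid cache over the
#' on-disk objects.
#'
#' @param root Directory for the store; created if missing.
#' @param cache_capacity Maximum number of cuboids held in the in-memory
#'   cache (default 64).
#' @param codec Compression codec for cuboid blobs; currently `"zlib"` (the
#'   default) or `"none"`.
#' @param write_back If `FALSE` (default) cuboid writes go straight through to
#'   the object store; if `TRUE` dirty cuboids are persisted on eviction or
#'   [vox_flush()].
#' @param permission_hook Function `(action, path) -> logical` consulted before
#'   every catalog or data operation. Defaults to allow-all; supply your own
#'   to integrate an external authorization layer.
#' @return A `vox_store` handle (an environment).
#' @export
#' @examples
#' st <- vox_store(tempfile("vox"))
vox_store <- function(root, cache_capacity = 64L, codec = "zlib",
                      write_back = FALSE, permission_hook = NULL) {
  if (!codec %in% c("zlib", "none")) {
    vox_abort(sprintf("unknown codec '%s'", codec), "validation")
  }
  if (cache_capacity < 1) vox_abort("cache_capacity must be >= 1", "validation")
  dir.create(file.path(root, "catalog"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "objects"), showWarnings = FALSE)
  dir.create(file.path(root, "index"), showWarnings = FALSE)
  dir.create(file.path(root, "ingest"), showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$root <- normalizePath(root)
  st$config <- list(cache_capacity = as.integer(cache_capacity),
                    codec = codec, write_back = isTRUE(write_back))
  st$catalog <- new.env(parent = emptyenv())
  st$cache <- new.env(parent = emptyenv())
  st$clock <- 0
  st$counters <- new.env(parent = emptyenv())
  for (k in c("cache_hits", "cache_misses", "store_reads", "store_writes",
              "cuboidify_calls")) st$counters[[k]] <- 0
  st$cuboid_index <- new.env(parent = emptyenv())
  st$ann_idx <- new.env(parent = emptyenv())
  st$stale <- new.env(parent = emptyenv())
  st$perm <- permission_hook %||% function(action, path) TRUE
  class(st) <- "vox_store"
  # restore catalog and cuboid index from disk
  for (f in list.files(file.path(st$root, "catalog"), pattern = "\\.json$",
                       full.names = TRUE)) {
    coll <- jsonlite::read_json(f, simplifyVector = FALSE)
    st$catalog[[coll$name]] <- coll
  }
  objs <- list.files(file.path(st$root, "objects"), recursive = TRUE)
  for (k in objs) st$cuboid_index[[k]] <- TRUE
  st
}

#' @export
print.vox_store <- function(x, ...) {
  colls <- ls(x$catalog)
  cat(sprintf("<vox_store %s: %d collection(s), %d cuboid(s) stored>\n",
              x$root, length(colls), length(ls(x$cuboid_index))))
  invisible(x)
}

check_perm <- function(store, action, path) {
  if (!isTRUE(store$perm(action, path))) {
    vox_abort(sprintf("permission denied: %s on %s", action, path), "permission")
  }
}

save_collection <- function(store, coll_name) {
  jsonlite::write_json(store$catalog[[coll_name]],
                       file.path(store$root, "catalog", paste0(coll_name, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Define a coordinate frame
#'
#' A coordinate frame is the named voxel grid of an experiment: per-axis voxel
#' extents at native resolution (level 0) and physical voxel sizes in
#' nanometres. The ratio of z to xy voxel size drives the anisotropic
#' downsample schedule ([factor_schedule()]). Voxel sizes at higher levels are
#' always derived from the level-0 sizes, never stored.
#'
#' @param extent Integer triple: voxel counts `(x, y, z)` at resolution 0.
#' @param voxel_size Numeric triple: physical voxel size `(x, y, z)` in nm.
#' @param time_extent Number of time samples (default 1).
#' @return An object of class `vox_coord_frame`.
#' @export
#' @examples
#' coord_frame(c(2048, 2048, 512), voxel_size = c(4, 4, 40))
coord_frame <- function(extent, voxel_size = c(1, 1, 1), time_extent = 1L) {
  extent <- as.double(extent)
  if (length(extent) != 3 || any(extent < 1) || any(extent != floor(extent))) {
    vox_abort("extent must be three positive integers", "validation")
  }
  voxel_size <- as.double(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    vox_abort("voxel sizes must be three positive reals (nm)", "validation")
  }
  if (time_extent < 1 || time_extent != floor(time_extent)) {
    vox_abort("time_extent must be a positive integer", "validation")
  }
  structure(list(extent = extent, voxel_size = voxel_size,
                 time_extent = as.double(time_extent)),
            class = "vox_coord_frame")
}

split_path <- function(path) {
  segs <- strsplit(path, "/", fixed = TRUE)[[1]]
  segs <- segs[nzchar(segs)]
  if (length(segs) < 1 || length(segs) > 3) {
    vox_abort(sprintf("resource path '%s' must have 1-3 segments", path), "validation")
  }
  for (s in segs) check_identifier(s, "resource identifier")
  segs
}

#' Create a collection, experiment, or channel
#'
#' Resources form a three-level hierarchy addressed by slash-separated paths:
#' `collection`, `collection/experiment`, `collection/experiment/channel`.
#' Experiments own a coordinate frame; channels are typed volumes within it.
#'
#' @param store A [vox_store()].
#' @param path Resource path with 1-3 `/`-separated URI-safe identifiers.
#' @param coord_frame A [coord_frame()] (required when creating an experiment).
#' @param type Channel type, `"image"` or `"annotation"`.
#' @param datatype `"uint8"`/`"uint16"` for image channels, `"uint64"` for
#'   annotation channels (the default is inferred: `uint8` / `uint64`).
#' @param num_hierarchy_levels Number of resolution levels reserved for the
#'   channel (level 0 is native; default 1).
#' @param base_resolution Resolution level at which writes land (default 0).
#' @param cuboid_shape Chunk shape for this channel, default `c(512, 512, 16)`.
#' @param source_channel For annotation channels, the path of the image
#'   channel they label (optional).
#' @return Invisibly, the created resource record (a `vox_channel` for
#'   channel paths).
#' @export
#' @examples
#' st <- vox_store(tempfile("vox"))
#' vox_create(st, "col")
#' vox_create(st, "col/exp", coord_frame = coord_frame(c(1024, 1024, 64)))
#' vox_create(st, "col/exp/em", type = "image", datatype = "uint8")
vox_create <- function(store, path, coord_frame = NULL, type = "image",
                       datatype = NULL, num_hierarchy_levels = 1L,
                       base_resolution = 0L, cuboid_shape = c(512L, 512L, 16L),
                       source_channel = NULL) {
  segs <- split_path(path)
  check_perm(store, "create", path)
  if (length(segs) == 1L) {
    if (!is.null(store$catalog[[segs[1]]])) {
      vox_abort(sprintf("collection '%s' already exists", segs[1]), "already_exists")
    }
    store$catalog[[segs[1]]] <- list(name = segs[1], meta = list(),
                                     experiments = list())
    save_collection(store, segs[1])
    return(invisible(store$catalog[[segs[1]]]))
  }
  coll <- store$catalog[[segs[1]]]
  if (is.null(coll)) {
    vox_abort(sprintf("collection '%s' not found", segs[1]), "not_found")
  }
  if (length(segs) == 2L) {
    if (!is.null(coll$experiments[[segs[2]]])) {
      vox_abort(sprintf("experiment '%s' already exists", path), "already_exists")
    }
    if (is.null(coord_frame)) {
      vox_abort("creating an experiment requires a coord_frame", "validation")
    }
    if (!inherits(coord_frame, "vox_coord_frame")) {
      vox_abort("coord_frame must be built with coord_frame()", "validation")
    }
    coll$experiments[[segs[2]]] <- list(
      name = segs[2], meta = list(),
      coord_frame = unclass(coord_frame), channels = list()
    )
    store$catalog[[segs[1]]] <- coll
    save_collection(store, segs[1])
    return(invisible(coll$experiments[[segs[2]]]))
  }
  exp <- coll$experiments[[segs[2]]]
  if (is.null(exp)) {
    vox_abort(sprintf("experiment '%s/%s' not found", segs[1], segs[2]), "not_found")
  }
  if (!is.null(exp$channels[[segs[3]]])) {
    vox_abort(sprintf("channel '%s' already exists", path), "already_exists")
  }
  if (!type %in% c("image", "annotation")) {
    vox_abort("channel type must be 'image' or 'annotation'", "validation")
  }
  datatype <- datatype %||% if (type == "annotation") "uint64" else "uint8"
  if (type == "annotation" && datatype != "uint64") {
    vox_abort("annotation channels must be uint64", "validation")
  }
  if (type == "image" && !datatype %in% c("uint8", "uint16")) {
    vox_abort("image channels must be uint8 or uint16", "validation")
  }
  cuboid_shape <- as.double(cuboid_shape)
  if (length(cuboid_shape) != 3 || any(cuboid_shape < 1) ||
      any(cuboid_shape != floor(cuboid_shape))) {
    vox_abort("cuboid_shape must be three positive integers", "validation")
  }
  if (num_hierarchy_levels < 1) vox_abort("num_hierarchy_levels must be >= 1", "validation")
  if (base_resolution < 0) vox_abort("base_resolution must be >= 0", "validation")
  if (!is.null(source_channel)) split_path(source_channel)
  exp$channels[[segs[3]]] <- list(
    name = segs[3], meta = list(),
    channel_type = type, datatype = datatype,
    base_resolution = as.double(base_resolution),
    num_hierarchy_levels = as.double(num_hierarchy_levels),
    cuboid_shape = cuboid_shape,
    source_channel = source_channel
  )
  coll$experiments[[segs[2]]] <- exp
  store$catalog[[segs[1]]] <- coll
  save_collection(store, segs[1])
  invisible(vox_channel(store, path))
}

#' Fetch a channel handle by path
#'
#' @param store A [vox_store()].
#' @param path `collection/experiment/channel` path (three segments).
#' @return A `vox_channel` handle embedding the channel attributes and its
#'   experiment's coordinate frame.
#' @export
vox_channel <- function(store, path) {
  segs <- split_path(path)
  if (length(segs) != 3) vox_abort("a channel path has three segments", "validation")
  coll <- store$catalog[[segs[1]]]
  if (is.null(coll)) vox_abort(sprintf("collection '%s' not found", segs[1]), "not_found")
  exp <- coll$experiments[[segs[2]]]
  if (is.null(exp)) {
    vox_abort(sprintf("experiment '%s/%s' not found", segs[1], segs[2]), "not_found")
  }
  ch <- exp$channels[[segs[3]]]
  if (is.null(ch)) vox_abort(sprintf("channel '%s' not found", path), "not_found")
  frame <- exp$coord_frame
  structure(list(
    collection = segs[1], experiment = segs[2], name = segs[3],
    path = paste(segs, collapse = "/"),
    channel_type = ch$channel_type, datatype = ch$datatype,
    base_resolution = as.double(ch$base_resolution),
    num_hierarchy_levels = as.double(ch$num_hierarchy_levels),
    cuboid_shape = as.double(unlist(ch$cuboid_shape)),
    source_channel = ch$source_channel,
    frame = coord_frame(as.double(unlist(frame$extent)),
                        as.double(unlist(frame$voxel_size)),
                        as.double(frame$time_extent))
  ), class = "vox_channel")
}

#' @export
print.vox_channel <- function(x, ...) {
  cat(sprintf("<vox_channel %s: %s %s, extent %s, %d level(s)>\n",
              x$path, x$channel_type, x$datatype,
              paste(x$frame$extent, collapse = "x"), x$num_hierarchy_levels))
  invisible(x)
}

#' URI addressing of channels
#'
#' Channels are addressable as `bossdb://<collection>/<experiment>/<channel>`.
#' `format_uri` renders a channel's URI; `vox_resolve_uri` parses one and
#' returns the channel handle.
#'
#' @param store A [vox_store()].
#' @param uri A `bossdb://` URI with exactly three path segments.
#' @return `vox_resolve_uri`: a `vox_channel`; `format_uri`: a string.
#' @export
#' @examples
#' \dontrun{
#' ch <- vox_resolve_uri(st, "bossdb://test_collection/test_experiment/test_channel")
#' }
vox_resolve_uri <- function(store, uri) {
  if (!is.character(uri) || length(uri) != 1 || !grepl("^bossdb://", uri)) {
    vox_abort(sprintf("malformed URI '%s': expected bossdb://", uri), "parse")
  }
  rest <- sub("^bossdb://", "", uri)
  segs <- strsplit(rest, "/", fixed = TRUE)[[1]]
  if (length(segs) != 3 || any(!nzchar(segs))) {
    vox_abort(sprintf("URI '%s' must have exactly three path segments", uri), "parse")
  }
  vox_channel(store, paste(segs, collapse = "/"))
}

#' @rdname vox_resolve_uri
#' @param channel A `vox_channel`.
#' @export
format_uri <- function(channel) {
  paste0("bossdb://", channel$collection, "/", channel$experiment, "/", channel$name)
}

# ---- per-resource key-value metadata ---------------------------------------

get_resource_rec <- function(store, path) {
  segs <- split_path(path)
  coll <- store$catalog[[segs[1]]]
  if (is.null(coll)) vox_abort(sprintf("resource '%s' not found", path), "not_found")
  if (length(segs) == 1) return(list(segs = segs, meta = coll$meta))
  exp <- coll$experiments[[segs[2]]]
  if (is.null(exp)) vox_abort(sprintf("resource '%s' not found", path), "not_found")
  if (length(segs) == 2) return(list(segs = segs, meta = exp$meta))
  ch <- exp$channels[[segs[3]]]
  if (is.null(ch)) vox_abort(sprintf("resource '%s' not found", path), "not_found")
  list(segs = segs, meta = ch$meta)
}

put_resource_meta <- function(store, path, meta) {
  segs <- split_path(path)
  coll <- store$catalog[[segs[1]]]
  if (length(segs) == 1) {
    coll$meta <- meta
  } else if (length(segs) == 2) {
    coll$experiments[[segs[2]]]$meta <- meta
  } else {
    coll$experiments[[segs[2]]]$channels[[segs[3]]]$meta <- meta
  }
  store$catalog[[segs[1]]] <- coll
  save_collection(store, segs[1])
}

#' Key-value metadata on resources
#'
#' Arbitrary string key-value pairs can be attached to any collection,
#' experiment, or channel — e.g. voxel size provenance, specimen information,
#' or the algorithm that produced an annotation channel. Keys are unique per
#' resource; `vox_set_meta` upserts.
#'
#' @param store A [vox_store()].
#' @param path Resource path (1-3 segments).
#' @param key,value Metadata key and value strings.
#' @return `vox_get_meta` returns the stored value; `vox_list_meta` a
#'   character vector of keys.
#' @export
#' @examples
#' st <- vox_store(tempfile("vox"))
#' vox_create(st, "col")
#' vox_set_meta(st, "col", "voxel_size", "4x4x40nm")
#' vox_get_meta(st, "col", "voxel_size")
vox_set_meta <- function(store, path, key, value) {
  check_perm(store, "set_meta", path)
  if (!is.character(key) || !nzchar(key)) vox_abort("key must be a non-empty string", "validation")
  rec <- get_resource_rec(store, path)
  meta <- rec$meta
  meta[[key]] <- as.character(value)
  put_resource_meta(store, path, meta)
  invisible(NULL)
}

#' @rdname vox_set_meta
#' @export
vox_get_meta <- function(store, path, key) {
  rec <- get_resource_rec(store, path)
  if (is.null(rec$meta[[key]])) {
    vox_abort(sprintf("metadata key '%s' not found on '%s'", key, path), "not_found")
  }
  rec$meta[[key]]
}

#' @rdname vox_set_meta
#' @export
vox_list_meta <- function(store, path) {
  rec <- get_resource_rec(store, path)
  names(rec$meta) %||% character()
}

#' @rdname vox_set_meta
#' @export
vox_delete_meta <- function(store, path, key) {
  check_perm(store, "delete_meta", path)
  rec <- get_resource_rec(store, path)
  if (is.null(rec$meta[[key]])) {
    vox_abort(sprintf("metadata key '%s' not found on '%s'", key, path), "not_found")
  }
  meta <- rec$meta
  meta[[key]] <- NULL
  put_resource_meta(store, path, meta)
  invisible(NULL)
}

# extent of a channel at a given resolution level (derived via the schedule)
channel_extent <- function(channel, resolution = 0) {
  if (resolution >= channel$num_hierarchy_levels) {
    vox_abort(sprintf("resolution %d outside hierarchy (%d level(s))",
                      resolution, channel$num_hierarchy_levels), "validation")
  }
  if (resolution == 0) return(channel$frame$extent)
  sched <- factor_schedule(channel$frame, channel$num_hierarchy_levels - 1)
  unlist(sched$extent[[resolution + 1L]])
}
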