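# Ingest pipelines: tile and volumetric-chunk ingest jobs with a file-backed
# at-least-once task queue (visibility-timeout leases), per-cuboid-region
# arrival tracking that triggers cuboidification exactly once, and plug-in
# readers mapping tasks to files on disk.

PLUGIN_REGISTRY <- new.env(parent = emptyenv())

#' Configure an ingest job
#'
#' @param channel_uri Target channel as a `bossdb://` URI.
#' @param ingest_type `"tile"` (stacked 2D images) or `"volumetric"` (3D
#'   chunk files).
#' @param extent Integer triple: size `(X, Y, Z)` of the upload region.
#' @param offset Integer triple: region origin, cuboid-aligned (default 0).
#' @param tile_size Integer pair `(tx, ty)` for tile jobs (default: the
#'   channel cuboid footprint).
#' @param chunk_size Integer triple for volumetric jobs; must be a multiple
#'   of the cuboid shape per axis.
#' @param t_range Half-open time range (default `c(0, 1)`).
#' @param plugin Name of a registered reader plug-in (see
#'   [vox_register_plugin()]).
#' @param plugin_params Named list handed to the plug-in (e.g. `dir`,
#'   `pattern`, `path`, `dtype`).
#' @return A `vox_ingest_config`.
#' @export
ingest_config <- function(channel_uri, ingest_type = c("tile", "volumetric"),
                          extent, offset = c(0, 0, 0), tile_size = NULL,
                          chunk_size = NULL, t_range = c(0, 1),
                          plugin = NULL, plugin_params = list()) {
  ingest_type <- match.arg(ingest_type)
  extent <- as.double(extent); offset <- as.double(offset)
  if (length(extent) != 3 || any(extent < 1)) {
    vox_abort("extent must be three positive integers", "validation")
  }
  if (length(offset) != 3 || any(offset < 0)) {
    vox_abort("offset must be three non-negative integers", "validation")
  }
  structure(list(channel_uri = channel_uri, ingest_type = ingest_type,
                 extent = extent, offset = offset,
                 tile_size = if (!is.null(tile_size)) as.double(tile_size),
                 chunk_size = if (!is.null(chunk_size)) as.double(chunk_size),
                 t_range = as.double(t_range), plugin = plugin,
                 plugin_params = plugin_params),
            class = "vox_ingest_config")
}

#' Read / write an ingest job configuration JSON file
#'
#' The on-disk analogue of an ingest-job configuration document: channel URI,
#' region extents/offset, tile or chunk size, plug-in name and parameters.
#'
#' @param config A [ingest_config()] (for writing).
#' @param file Path to a JSON file.
#' @return `read_ingest_config` returns a `vox_ingest_config`.
#' @export
write_ingest_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname write_ingest_config
#' @export
read_ingest_config <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  ingest_config(raw$channel_uri, raw$ingest_type, unlist(raw$extent),
                unlist(raw$offset),
                tile_size = if (!is.null(raw$tile_size)) unlist(raw$tile_size),
                chunk_size = if (!is.null(raw$chunk_size)) unlist(raw$chunk_size),
                t_range = unlist(raw$t_range), plugin = raw$plugin,
                plugin_params = as.list(raw$plugin_params))
}

job_dir <- function(store, job_id) file.path(store$root, "ingest", job_id)

read_job <- function(store, job_id) {
  f <- file.path(job_dir(store, job_id), "job.json")
  if (!file.exists(f)) vox_abort(sprintf("ingest job '%s' not found", job_id), "not_found")
  jsonlite::read_json(f, simplifyVector = FALSE)
}

write_job <- function(store, job_id, job) {
  jsonlite::write_json(job, file.path(job_dir(store, job_id), "job.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

read_tasks <- function(store, job_id) {
  jsonlite::read_json(file.path(job_dir(store, job_id), "tasks.json"),
                      simplifyVector = FALSE)
}

write_tasks <- function(store, job_id, tasks) {
  jsonlite::write_json(tasks, file.path(job_dir(store, job_id), "tasks.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

read_arrivals <- function(store, job_id) {
  f <- file.path(job_dir(store, job_id), "arrivals.json")
  if (!file.exists(f)) return(list())
  jsonlite::read_json(f, simplifyVector = FALSE)
}

write_arrivals <- function(store, job_id, arr) {
  jsonlite::write_json(arr, file.path(job_dir(store, job_id), "arrivals.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

ranges_overlap <- function(o1, e1, o2, e2) {
  all(o1 < o2 + e2) && all(o2 < o1 + e1)
}

#' Create an ingest job
#'
#' Validates the configuration against the target channel, enumerates every
#' upload task (one per tile position and z-slice, or one per chunk), and
#' persists the job under the store root. Two active jobs may not target
#' overlapping regions of the same channel.
#'
#' @param store A [vox_store()].
#' @param config A [ingest_config()].
#' @return The job id (character).
#' @export
vox_create_job <- function(store, config) {
  ch <- vox_resolve_uri(store, config$channel_uri)
  shape <- ch$cuboid_shape
  ext <- channel_extent(ch, ch$base_resolution)
  if (any(config$offset %% shape != 0)) {
    vox_abort("ingest offset must be cuboid-aligned", "validation")
  }
  if (any(config$offset + config$extent > ext)) {
    vox_abort("ingest region exceeds the coordinate frame", "validation")
  }
  if (config$ingest_type == "volumetric") {
    if (is.null(config$chunk_size)) vox_abort("volumetric jobs need chunk_size", "validation")
    if (any(config$chunk_size %% shape != 0)) {
      vox_abort("chunk_size must be a multiple of the cuboid shape (grid-aligned)",
                "validation")
    }
  }
  # conflict with any active job on an overlapping region of this channel
  for (other in list.dirs(file.path(store$root, "ingest"), recursive = FALSE)) {
    oj <- jsonlite::read_json(file.path(other, "job.json"), simplifyVector = FALSE)
    if (identical(oj$config$channel_uri, config$channel_uri) &&
        oj$status %in% c("ready", "active") &&
        ranges_overlap(unlist(oj$config$offset), unlist(oj$config$extent),
                       config$offset, config$extent)) {
      vox_abort(sprintf("active job '%s' overlaps the requested region", oj$id),
                "conflict")
    }
  }
  tasks <- list()
  ts <- seq.int(config$t_range[1], config$t_range[2] - 1)
  if (config$ingest_type == "tile") {
    tsz <- config$tile_size %||% shape[1:2]
    ntx <- ceiling(config$extent[1] / tsz[1])
    nty <- ceiling(config$extent[2] / tsz[2])
    for (t in ts) for (z in seq.int(config$offset[3], config$offset[3] + config$extent[3] - 1)) {
      for (ty in seq_len(nty) - 1) for (tx in seq_len(ntx) - 1) {
        tasks[[length(tasks) + 1L]] <- list(
          id = sprintf("tile-t%d-z%d-y%d-x%d", t, z, ty, tx),
          kind = "tile", x = tx, y = ty, z = z, t = t,
          state = "pending", deliveries = 0, lease_expiry = 0)
      }
    }
    config$tile_size <- tsz
  } else {
    csz <- config$chunk_size
    nc <- ceiling(config$extent / csz)
    for (t in ts) for (cz in seq_len(nc[3]) - 1) for (cy in seq_len(nc[2]) - 1) {
      for (cx in seq_len(nc[1]) - 1) {
        tasks[[length(tasks) + 1L]] <- list(
          id = sprintf("chunk-t%d-z%d-y%d-x%d", t, cz, cy, cx),
          kind = "chunk", x = cx, y = cy, z = cz, t = t,
          state = "pending", deliveries = 0, lease_expiry = 0)
      }
    }
  }
  n_existing <- length(list.dirs(file.path(store$root, "ingest"), recursive = FALSE))
  job_id <- sprintf("job%04d", n_existing + 1L)
  dir.create(file.path(job_dir(store, job_id), "staging"), recursive = TRUE)
  write_job(store, job_id, list(id = job_id, status = "ready",
                                config = unclass(config)))
  write_tasks(store, job_id, tasks)
  job_id
}

job_config <- function(job) {
  cfg <- job$config
  ingest_config(cfg$channel_uri, cfg$ingest_type, unlist(cfg$extent),
                unlist(cfg$offset),
                tile_size = if (!is.null(cfg$tile_size)) unlist(cfg$tile_size),
                chunk_size = if (!is.null(cfg$chunk_size)) unlist(cfg$chunk_size),
                t_range = unlist(cfg$t_range), plugin = cfg$plugin,
                plugin_params = lapply(cfg$plugin_params, function(p) {
                  if (is.list(p)) unlist(p) else p
                }))
}

#' Lease the next upload task
#'
#' Tasks are delivered under visibility-timeout leases: a leased task whose
#' worker never completes it re-enters the queue when the lease expires
#' (at-least-once delivery — every handler downstream is idempotent).
#' Multiple workers may draw from the same job concurrently.
#'
#' @param store A [vox_store()].
#' @param job_id Job id from [vox_create_job()].
#' @param worker Worker name recorded on the lease.
#' @param lease Lease duration in seconds.
#' @return A task record (list with `id`, `kind`, `x`, `y`, `z`, `t`,
#'   `deliveries`), or `NULL` when no task is available.
#' @export
vox_next_task <- function(store, job_id, worker = "worker", lease = 60) {
  job <- read_job(store, job_id)
  if (job$status %in% c("cancelled", "complete")) return(NULL)
  tasks <- read_tasks(store, job_id)
  now <- as.numeric(Sys.time())
  for (i in seq_along(tasks)) {
    tk <- tasks[[i]]
    if (identical(tk$state, "pending") ||
        (identical(tk$state, "leased") && tk$lease_expiry <= now)) {
      tasks[[i]]$state <- "leased"
      tasks[[i]]$worker <- worker
      tasks[[i]]$lease_expiry <- now + lease
      tasks[[i]]$deliveries <- tk$deliveries + 1
      write_tasks(store, job_id, tasks)
      if (identical(job$status, "ready")) {
        job$status <- "active"
        write_job(store, job_id, job)
      }
      return(tasks[[i]])
    }
  }
  NULL
}

mark_task <- function(store, job_id, task_id, state) {
  tasks <- read_tasks(store, job_id)
  for (i in seq_along(tasks)) {
    if (identical(tasks[[i]]$id, task_id)) {
      tasks[[i]]$state <- state
      break
    }
  }
  write_tasks(store, job_id, tasks)
  if (state == "done" && all(vapply(tasks, function(t) identical(t$state, "done"),
                                    logical(1)))) {
    job <- read_job(store, job_id)
    job$status <- "complete"
    write_job(store, job_id, job)
  }
}

#' Job status and progress
#'
#' @param store A [vox_store()].
#' @param job_id Job id.
#' @return List with `status`, task counts (`total`, `done`, `pending`,
#'   `leased`), and cuboid-region progress (`regions_built`,
#'   `regions_pending`).
#' @export
vox_job_status <- function(store, job_id) {
  job <- read_job(store, job_id)
  tasks <- read_tasks(store, job_id)
  states <- vapply(tasks, function(t) t$state, character(1))
  arr <- read_arrivals(store, job_id)
  built <- sum(vapply(arr, function(a) identical(a$state, "built"), logical(1)))
  list(status = job$status, total = length(tasks),
       done = sum(states == "done"), pending = sum(states == "pending"),
       leased = sum(states == "leased"),
       regions_built = built, regions_pending = length(arr) - built)
}

#' Cancel a job
#'
#' Drains the queue: pending and leased tasks are dropped and
#' [vox_next_task()] returns `NULL` from then on.
#'
#' @param store A [vox_store()].
#' @param job_id Job id.
#' @export
vox_cancel_job <- function(store, job_id) {
  job <- read_job(store, job_id)
  job$status <- "cancelled"
  write_job(store, job_id, job)
  tasks <- read_tasks(store, job_id)
  for (i in seq_along(tasks)) {
    if (!identical(tasks[[i]]$state, "done")) tasks[[i]]$state <- "cancelled"
  }
  write_tasks(store, job_id, tasks)
  invisible(NULL)
}

# global voxel footprint of a tile task
tile_footprint <- function(config, task) {
  tsz <- config$tile_size
  x0 <- config$offset[1] + task$x * tsz[1]
  x1 <- min(x0 + tsz[1], config$offset[1] + config$extent[1])
  y0 <- config$offset[2] + task$y * tsz[2]
  y1 <- min(y0 + tsz[2], config$offset[2] + config$extent[2])
  list(x = c(x0, x1), y = c(y0, y1), z = task$z)
}

staged_tile_path <- function(store, job_id, task) {
  file.path(job_dir(store, job_id), "staging",
            sprintf("t%d_z%d_y%d_x%d.blob", task$t, task$z, task$y, task$x))
}

region_key <- function(cx, cy, cz, t) sprintf("r%d_%d_%d_t%d", cx, cy, cz, t)

# every (tx, ty, z) tile triple whose footprint intersects one cuboid region
region_required_tiles <- function(config, channel, cx, cy, cz, t) {
  shape <- channel$cuboid_shape
  tsz <- config$tile_size
  rx <- c(cx * shape[1], (cx + 1) * shape[1])
  ry <- c(cy * shape[2], (cy + 1) * shape[2])
  jx <- c(config$offset[1], config$offset[1] + config$extent[1])
  jy <- c(config$offset[2], config$offset[2] + config$extent[2])
  jz <- c(config$offset[3], config$offset[3] + config$extent[3])
  ix <- c(max(rx[1], jx[1]), min(rx[2], jx[2]))
  iy <- c(max(ry[1], jy[1]), min(ry[2], jy[2]))
  iz <- c(max(cz * shape[3], jz[1]), min((cz + 1) * shape[3], jz[2]))
  if (ix[1] >= ix[2] || iy[1] >= iy[2] || iz[1] >= iz[2]) return(data.frame())
  txs <- seq.int((ix[1] - jx[1]) %/% tsz[1], (ix[2] - 1 - jx[1]) %/% tsz[1])
  tys <- seq.int((iy[1] - jy[1]) %/% tsz[2], (iy[2] - 1 - jy[1]) %/% tsz[2])
  zs <- seq.int(iz[1], iz[2] - 1)
  g <- expand.grid(x = txs, y = tys, z = zs)
  g$t <- t
  g
}

#' Upload a decoded tile
#'
#' Stages one 2D tile, records its arrival idempotently (re-delivered
#' duplicates never double-count), and — once every z-slice tile covering a
#' cuboid region has arrived — triggers cuboidification of that region
#' exactly once.
#'
#' @param store A [vox_store()].
#' @param job_id Job id.
#' @param task A tile task from [vox_next_task()].
#' @param tile 2D numeric matrix of the tile's voxels (edge tiles are the
#'   clipped size).
#' @export
vox_upload_tile <- function(store, job_id, task, tile) {
  job <- read_job(store, job_id)
  config <- job_config(job)
  if (config$ingest_type != "tile") vox_abort("not a tile job", "validation")
  ch <- vox_resolve_uri(store, config$channel_uri)
  fp <- tile_footprint(config, task)
  want <- c(fp$x[2] - fp$x[1], fp$y[2] - fp$y[1])
  if (!identical(as.double(dim(tile)), want)) {
    vox_abort(sprintf("tile is %s, expected %s for task %s",
                      paste(dim(tile), collapse = "x"),
                      paste(want, collapse = "x"), task$id), "validation")
  }
  writeBin(vox_compress(tile, ch$datatype, shape = dim(tile)),
           staged_tile_path(store, job_id, task))
  mark_task(store, job_id, task$id, "done")
  # record the arrival against every cuboid region the tile touches
  shape <- ch$cuboid_shape
  arr <- read_arrivals(store, job_id)
  cxs <- seq.int(fp$x[1] %/% shape[1], (fp$x[2] - 1) %/% shape[1])
  cys <- seq.int(fp$y[1] %/% shape[2], (fp$y[2] - 1) %/% shape[2])
  cz <- task$z %/% shape[3]
  fire <- character()
  for (cx in cxs) for (cy in cys) {
    rk <- region_key(cx, cy, cz, task$t)
    rec <- arr[[rk]] %||% list(state = "pending", arrived = list(),
                               cx = cx, cy = cy, cz = cz, t = task$t)
    if (identical(rec$state, "built")) next
    akey <- sprintf("z%d-y%d-x%d", task$z, task$y, task$x)
    if (!akey %in% unlist(rec$arrived)) {
      rec$arrived <- c(rec$arrived, akey)
    }
    req <- region_required_tiles(config, ch, cx, cy, cz, task$t)
    if (length(rec$arrived) >= nrow(req)) {
      rec$state <- "built"
      fire <- c(fire, rk)
    }
    arr[[rk]] <- rec
  }
  write_arrivals(store, job_id, arr)
  for (rk in fire) {
    rec <- read_arrivals(store, job_id)[[rk]]
    cuboidify(store, job_id, rec$cx, rec$cy, rec$cz, rec$t)
  }
  invisible(NULL)
}

# assemble all staged tiles of one cuboid region and write it into the store
cuboidify <- function(store, job_id, cx, cy, cz, t) {
  job <- read_job(store, job_id)
  config <- job_config(job)
  ch <- vox_resolve_uri(store, config$channel_uri)
  shape <- ch$cuboid_shape
  req <- region_required_tiles(config, ch, cx, cy, cz, t)
  jx <- c(config$offset[1], config$offset[1] + config$extent[1])
  jy <- c(config$offset[2], config$offset[2] + config$extent[2])
  jz <- c(config$offset[3], config$offset[3] + config$extent[3])
  rng <- vox_range(c(max(cx * shape[1], jx[1]), min((cx + 1) * shape[1], jx[2])),
                   c(max(cy * shape[2], jy[1]), min((cy + 1) * shape[2], jy[2])),
                   c(max(cz * shape[3], jz[1]), min((cz + 1) * shape[3], jz[2])))
  data <- array(0, dim(rng))
  deletable <- character()
  for (i in seq_len(nrow(req))) {
    task <- list(x = req$x[i], y = req$y[i], z = req$z[i], t = t)
    p <- staged_tile_path(store, job_id, task)
    if (!file.exists(p)) {
      # reset the region so re-arrival can retrigger assembly
      arr <- read_arrivals(store, job_id)
      rk <- region_key(cx, cy, cz, t)
      arr[[rk]]$state <- "pending"
      write_arrivals(store, job_id, arr)
      vox_abort(sprintf("staged tile missing at assembly: %s", basename(p)), "state")
    }
    tile <- vox_decompress(readBin(p, raw(), n = file.size(p)))$data
    fp <- tile_footprint(config, task)
    ox <- max(fp$x[1], rng$x[1]); x1 <- min(fp$x[2], rng$x[2])
    oy <- max(fp$y[1], rng$y[1]); y1 <- min(fp$y[2], rng$y[2])
    data[seq.int(ox - rng$x[1] + 1, x1 - rng$x[1]),
         seq.int(oy - rng$y[1] + 1, y1 - rng$y[1]),
         task$z - rng$z[1] + 1] <-
      tile[seq.int(ox - fp$x[1] + 1, x1 - fp$x[1]),
           seq.int(oy - fp$y[1] + 1, y1 - fp$y[1])]
    deletable <- c(deletable, p)
  }
  vox_write_cutout(store, ch, rng, data, resolution = ch$base_resolution, t = t)
  bump(store, "cuboidify_calls")
  arr <- read_arrivals(store, job_id)
  rk <- region_key(cx, cy, cz, t)
  arr[[rk]]$state <- "built"
  arr[[rk]]$deletable <- as.list(deletable)
  write_arrivals(store, job_id, arr)
  invisible(NULL)
}

#' Ingest one volumetric chunk
#'
#' Splits a cuboid-grid-aligned 3D chunk on the cuboid grid and merges it
#' into the store (read-modify-write per cuboid). Re-delivery of the same
#' task is idempotent: the final stored bytes are identical.
#'
#' @param store A [vox_store()].
#' @param job_id Job id.
#' @param task A chunk task from [vox_next_task()].
#' @param chunk Dense 3D array of the chunk's voxels (edge chunks are the
#'   clipped size).
#' @export
vox_ingest_chunk <- function(store, job_id, task, chunk) {
  job <- read_job(store, job_id)
  config <- job_config(job)
  if (config$ingest_type != "volumetric") vox_abort("not a volumetric job", "validation")
  ch <- vox_resolve_uri(store, config$channel_uri)
  csz <- config$chunk_size
  lo <- config$offset + c(task$x, task$y, task$z) * csz
  hi <- pmin(lo + csz, config$offset + config$extent)
  if (any(lo %% ch$cuboid_shape != 0)) {
    vox_abort("chunk origin misaligned to the cuboid grid", "validation")
  }
  if (!identical(as.double(dim(chunk)), hi - lo)) {
    vox_abort(sprintf("chunk is %s, expected %s for task %s",
                      paste(dim(chunk), collapse = "x"),
                      paste(hi - lo, collapse = "x"), task$id), "validation")
  }
  rng <- vox_range(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3]))
  vox_write_cutout(store, ch, rng, chunk, resolution = ch$base_resolution,
                   t = task$t)
  mark_task(store, job_id, task$id, "done")
  invisible(NULL)
}

#' Garbage-collect staged ingest tiles
#'
#' Removes staged tiles that cuboidification marked deletable. Deferring the
#' sweep (rather than deleting at assembly time) keeps crash recovery simple.
#'
#' @param store A [vox_store()].
#' @param job_id Job id.
#' @return Invisibly, the number of files removed.
#' @export
vox_gc <- function(store, job_id) {
  arr <- read_arrivals(store, job_id)
  n <- 0L
  for (rk in names(arr)) {
    for (p in unlist(arr[[rk]]$deletable)) {
      if (file.exists(p)) {
        unlink(p)
        n <- n + 1L
      }
    }
  }
  invisible(n)
}

# ---- plug-in readers --------------------------------------------------------

#' Register or load an ingest reader plug-in
#'
#' A plug-in is a function `(task, params) -> array` responsible for locating
#' the file a task refers to (usually via [format_path()] templating) and
#' decoding it. Built-ins: `"png_tile"`, `"tiff_tile"` (2D tiles; params
#' `dir`, `pattern`, `dtype`) and `"zarr_chunk"` (3D chunks; params `path`).
#'
#' @param name Plug-in name.
#' @param reader Function `(task, params)` returning a decoded array.
#' @export
vox_register_plugin <- function(name, reader) {
  if (!is.function(reader)) vox_abort("reader must be a function", "config")
  PLUGIN_REGISTRY[[name]] <- reader
  invisible(NULL)
}

#' @rdname vox_register_plugin
#' @param params Named list of plug-in parameters; bound into the returned
#'   reader.
#' @return `vox_load_plugin`: a function `(task) -> array`.
#' @export
vox_load_plugin <- function(name, params = list()) {
  reader <- PLUGIN_REGISTRY[[name]]
  if (is.null(reader)) vox_abort(sprintf("unknown plug-in '%s'", name), "config")
  function(task) reader(task, params)
}

# zarr volumes opened by the chunk plug-in, cached per path
ZARR_CACHE <- new.env(parent = emptyenv())

register_builtin_plugins <- function() {
  tile_reader <- function(task, params) {
    p <- file.path(params$dir, format_path(params$pattern, task))
    vox_load_slice(p, params$dtype %||% "uint8")
  }
  vox_register_plugin("png_tile", tile_reader)
  vox_register_plugin("tiff_tile", tile_reader)
  vox_register_plugin("zarr_chunk", function(task, params) {
    key <- normalizePath(params$path)
    z <- ZARR_CACHE[[key]]
    if (is.null(z)) {
      z <- read_zarr(params$path)
      ZARR_CACHE[[key]] <- z
    }
    csz <- as.double(params$chunk_size)
    lo <- c(task$x, task$y, task$z) * csz
    hi <- pmin(lo + csz, z$shape)
    z$data[seq.int(lo[1] + 1, hi[1]), seq.int(lo[2] + 1, hi[2]),
           seq.int(lo[3] + 1, hi[3]), drop = FALSE]
  })
}

#' Run an ingest worker loop
#'
#' Draws tasks from the job queue and dispatches them through the job's
#' plug-in until the queue is empty: tile tasks are decoded and uploaded via
#' [vox_upload_tile()], chunk tasks via [vox_ingest_chunk()]. A reader error
#' fails the task, returning it to the queue at lease expiry.
#'
#' @param store A [vox_store()].
#' @param job_id Job id.
#' @param worker Worker name.
#' @param lease Task lease seconds.
#' @param max_tasks Stop after this many tasks (default: run to completion).
#' @return Invisibly, the number of tasks processed.
#' @export
vox_run_ingest <- function(store, job_id, worker = "worker", lease = 300,
                           max_tasks = Inf) {
  job <- read_job(store, job_id)
  config <- job_config(job)
  if (is.null(config$plugin)) vox_abort("job has no reader plug-in", "config")
  params <- config$plugin_params
  ch <- vox_resolve_uri(store, config$channel_uri)
  params$dtype <- params$dtype %||% ch$datatype
  params$chunk_size <- params$chunk_size %||% config$chunk_size
  reader <- vox_load_plugin(config$plugin, params)
  n <- 0L
  while (n < max_tasks) {
    task <- vox_next_task(store, job_id, worker, lease)
    if (is.null(task)) break
    arr <- tryCatch(reader(task), error = function(e) e)
    if (inherits(arr, "error")) {
      # task failure: leave the lease to expire so the task is redelivered
      next
    }
    if (identical(task$kind, "tile")) {
      vox_upload_tile(store, job_id, task, arr)
    } else {
      vox_ingest_chunk(store, job_id, task, arr)
    }
    n <- n + 1L
  }
  invisible(n)
}
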