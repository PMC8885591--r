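# Ingest pipelines: task enumeration, lease queue semantics, arrival
# tracking, cuboidification, chunk splitting, plug-ins.

make_tile_job <- function(ctx, dir, extent = c(128, 128, 32),
                          tile_size = c(64, 64), format = "png") {
  cfg <- ingest_config(format_uri(ctx$img), "tile", extent = extent,
                       tile_size = tile_size,
                       plugin = paste0(format, "_tile"),
                       plugin_params = list(
                         dir = dir,
                         pattern = paste0("z{z:04d}/y{y}_x{x}.",
                                          if (format == "png") "png" else "tif")))
  vox_create_job(ctx$store, cfg)
}

test_that("job creation enumerates ceil(X/tx) * ceil(Y/ty) * Z * T tile tasks", {
  ctx <- make_channel_pair(extent = c(1024, 1024, 32), cuboid_shape = c(512, 512, 16))
  cfg <- ingest_config(format_uri(ctx$img), "tile", extent = c(1024, 1024, 32),
                       tile_size = c(512, 512))
  job <- vox_create_job(ctx$store, cfg)
  expect_equal(vox_job_status(ctx$store, job)$total, 2 * 2 * 32)
  # volumetric: one chunk task for a chunk-sized region
  ctx2 <- make_channel_pair(extent = c(512, 512, 64), cuboid_shape = c(512, 512, 16))
  cfg2 <- ingest_config(format_uri(ctx2$img), "volumetric",
                        extent = c(512, 512, 64), chunk_size = c(512, 512, 64))
  job2 <- vox_create_job(ctx2$store, cfg2)
  expect_equal(vox_job_status(ctx2$store, job2)$total, 1)
  # misalignment and conflicts
  expect_error(vox_create_job(ctx2$store,
    ingest_config(format_uri(ctx2$img), "volumetric", extent = c(512, 512, 64),
                  chunk_size = c(500, 512, 64))),
    class = "vox_error_validation")
  expect_error(vox_create_job(ctx$store,
    ingest_config(format_uri(ctx$img), "tile", extent = c(512, 512, 16),
                  tile_size = c(512, 512))),
    class = "vox_error_conflict")
})

test_that("the queue leases tasks at-least-once with visibility timeouts", {
  ctx <- make_channel_pair(extent = c(64, 64, 16), cuboid_shape = c(32, 32, 8))
  cfg <- ingest_config(format_uri(ctx$img), "tile", extent = c(64, 64, 16),
                       tile_size = c(32, 32))
  job <- vox_create_job(ctx$store, cfg)
  t1 <- vox_next_task(ctx$store, job, worker = "w1", lease = 300)
  t2 <- vox_next_task(ctx$store, job, worker = "w2", lease = 300)
  expect_false(identical(t1$id, t2$id))  # disjoint leases
  expect_equal(t1$deliveries, 1)
  # a zero-length lease expires immediately: the task is redelivered
  t3 <- vox_next_task(ctx$store, job, worker = "w3", lease = 0)
  Sys.sleep(0.01)
  t4 <- vox_next_task(ctx$store, job, worker = "w4", lease = 300)
  expect_equal(t4$id, t3$id)
  expect_equal(t4$deliveries, 2)
  # cancel drains the queue
  vox_cancel_job(ctx$store, job)
  expect_null(vox_next_task(ctx$store, job))
})

test_that("cuboidify fires exactly once per region when its tile set completes", {
  ctx <- make_channel_pair(extent = c(32, 32, 8), cuboid_shape = c(32, 32, 8))
  st <- ctx$store
  cfg <- ingest_config(format_uri(ctx$img), "tile", extent = c(32, 32, 8),
                       tile_size = c(32, 32))
  job <- vox_create_job(st, cfg)
  set.seed(2)
  tiles <- lapply(1:8, function(z) {
    matrix(as.double(sample(0:255, 32 * 32, TRUE)), 32, 32)
  })
  # upload 7 of 8 slices: region still pending, nothing written
  for (z in 0:6) {
    task <- list(id = sprintf("tile-t0-z%d-y0-x0", z), kind = "tile",
                 x = 0, y = 0, z = z, t = 0)
    vox_upload_tile(st, job, task, tiles[[z + 1]])
  }
  expect_equal(vox_counters(st)$cuboidify_calls, 0)
  expect_equal(vox_job_status(st, job)$regions_pending, 1)
  expect_false(vox_contains(st, cuboid_key(ctx$img, 0, 0)))
  # duplicate upload of an already-seen slice does not complete the region
  vox_upload_tile(st, job, list(id = "tile-t0-z3-y0-x0", kind = "tile",
                                x = 0, y = 0, z = 3, t = 0), tiles[[4]])
  expect_equal(vox_counters(st)$cuboidify_calls, 0)
  # the 8th slice completes the region exactly once
  vox_upload_tile(st, job, list(id = "tile-t0-z7-y0-x0", kind = "tile",
                                x = 0, y = 0, z = 7, t = 0), tiles[[8]])
  expect_equal(vox_counters(st)$cuboidify_calls, 1)
  expect_equal(vox_job_status(st, job)$regions_built, 1)
  # re-delivered upload after the build is a no-op
  vox_upload_tile(st, job, list(id = "tile-t0-z7-y0-x0", kind = "tile",
                                x = 0, y = 0, z = 7, t = 0), tiles[[8]])
  expect_equal(vox_counters(st)$cuboidify_calls, 1)
  got <- vox_read_cutout(st, ctx$img, full_range(c(32, 32, 8)))
  for (z in 1:8) expect_identical(got[, , z], tiles[[z]])
  # wrong tile dimensions are a validation error
  expect_error(vox_upload_tile(st, job, list(id = "tile-t0-z0-y0-x0",
                                             kind = "tile", x = 0, y = 0,
                                             z = 0, t = 0),
                               matrix(0, 16, 16)),
               class = "vox_error_validation")
  expect_gt(vox_gc(st, job), 0)
})

test_that("volumetric chunks split on the cuboid grid and re-deliver idempotently", {
  ctx <- make_channel_pair(extent = c(512, 512, 64), cuboid_shape = c(512, 512, 16))
  st <- ctx$store
  cfg <- ingest_config(format_uri(ctx$img), "volumetric",
                       extent = c(512, 512, 64), chunk_size = c(512, 512, 64))
  job <- vox_create_job(st, cfg)
  task <- vox_next_task(st, job)
  set.seed(8)
  chunk <- random_volume(c(512, 512, 64))
  w0 <- vox_counters(st)$store_writes
  vox_ingest_chunk(st, job, task, chunk)
  expect_equal(vox_counters(st)$store_writes - w0, 4)  # 64/16 cuboids
  expect_equal(vox_job_status(st, job)$status, "complete")
  # re-delivery leaves the stored bytes identical
  vox_ingest_chunk(st, job, task, chunk)
  expect_identical(vox_read_cutout(st, ctx$img, full_range(c(512, 512, 64))), chunk)
  expect_error(vox_ingest_chunk(st, job, task, chunk[1:10, , ]),
               class = "vox_error_validation")
})

test_that("path templating fills zero-padded placeholders", {
  expect_equal(format_path("tiles/z{z:04d}/y{y}_x{x}.png", list(x = 1, y = 2, z = 3)),
               "tiles/z0003/y2_x1.png")
  expect_equal(format_path("c{x}_{x}", list(x = 12)), "c12_12")
  expect_error(format_path("{q}", list(x = 1)), class = "vox_error_validation")
  expect_error(vox_load_plugin("no_such_plugin"), class = "vox_error_config")
})

test_that("tile ingest round-trips PNG and 16-bit TIFF stacks bit-exactly", {
  set.seed(14)
  for (case in list(list(fmt = "png", dtype = "uint8"),
                    list(fmt = "tiff", dtype = "uint16"))) {
    ext <- c(96, 64, 16)
    ctx <- make_channel_pair(extent = ext, cuboid_shape = c(32, 32, 8),
                             dtype = case$dtype)
    vol <- random_volume(ext, case$dtype)
    td <- tempfile("tiles-")
    write_tiles(vol, td, case$dtype, case$fmt, tile_size = c(48, 48))
    job <- make_tile_job(ctx, td, extent = ext, tile_size = c(48, 48),
                         format = case$fmt)
    vox_run_ingest(ctx$store, job)
    expect_equal(vox_job_status(ctx$store, job)$status, "complete")
    expect_identical(vox_read_cutout(ctx$store, ctx$img, full_range(ext)), vol)
  }
})

test_that("zarr chunk ingest round-trips an annotation volume and its indices", {
  set.seed(15)
  ext <- c(96, 64, 32)
  ctx <- make_channel_pair(extent = ext, cuboid_shape = c(32, 32, 8))
  vol <- array(sample(c(0, 0, 7, 2^40 + 3), prod(ext), TRUE), ext)
  zd <- tempfile("zarr-")
  write_chunks(vol, zd, "uint64", chunk_size = c(32, 64, 16))
  cfg <- ingest_config(format_uri(ctx$seg), "volumetric", extent = ext,
                       chunk_size = c(32, 64, 16), plugin = "zarr_chunk",
                       plugin_params = list(path = zd))
  job <- vox_create_job(ctx$store, cfg)
  vox_run_ingest(ctx$store, job)
  expect_identical(vox_read_cutout(ctx$store, ctx$seg, full_range(ext)), vol)
  expect_equal(vox_ids_in_region(ctx$store, ctx$seg, full_range(ext)),
               c(7, 2^40 + 3))
})

test_that("duplicate task re-delivery during a worker run never corrupts data", {
  set.seed(16)
  ext <- c(64, 64, 16)
  ctx <- make_channel_pair(extent = ext, cuboid_shape = c(32, 32, 8))
  vol <- random_volume(ext, "uint8")
  td <- tempfile("tiles-")
  write_tiles(vol, td, "uint8", "png", tile_size = c(32, 32))
  job <- make_tile_job(ctx, td, extent = ext, tile_size = c(32, 32))
  # lease a handful of tasks with instant expiry so they are re-delivered to
  # the main worker run after being processed once here
  reader <- vox_load_plugin("png_tile",
                            list(dir = td, pattern = "z{z:04d}/y{y}_x{x}.png",
                                 dtype = "uint8"))
  done_once <- character()
  for (i in 1:5) {
    tk <- vox_next_task(ctx$store, job, worker = "dup", lease = 0)
    vox_upload_tile(ctx$store, job, tk, reader(tk))
    done_once <- c(done_once, tk$id)
  }
  # simulate a crashed ack: force the processed tasks back into the queue so
  # the worker run re-delivers and re-processes them
  tasks <- voxstore:::read_tasks(ctx$store, job)
  for (i in seq_along(tasks)) {
    if (tasks[[i]]$id %in% done_once) tasks[[i]]$state <- "pending"
  }
  voxstore:::write_tasks(ctx$store, job, tasks)
  vox_run_ingest(ctx$store, job)
  expect_identical(vox_read_cutout(ctx$store, ctx$img, full_range(ext)), vol)
  expect_equal(vox_counters(ctx$store)$cuboidify_calls, 2 * 2 * 2)
})
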