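# Downsample hierarchy: factor schedule, reduction operators, full and
# partial rebuilds.

test_that("anisotropic EM frame follows the in-plane-until-near-isotropy rule", {
  fr <- coord_frame(c(2048, 2048, 512), c(4, 4, 40))
  s <- factor_schedule(fr, 5)
  # in-plane (2,2,1) transitions while z/xy >= 2
  expect_equal(s$fz[2:4], c(1, 1, 1))
  expect_equal(s$fx[2:4], c(2, 2, 2))
  # third downsample reaches 32 nm in-plane with z still 40 nm
  expect_equal(s$size_x[s$level == 3], 32)
  expect_equal(s$size_y[s$level == 3], 32)
  expect_equal(s$size_z[s$level == 3], 40)
  # anisotropy shrinks across the in-plane phase, then reduction turns isotropic
  expect_lt(s$size_z[4] / s$size_x[4], s$size_z[2] / s$size_x[2])
  expect_equal(c(s$fx[5], s$fy[5], s$fz[5]), c(2, 2, 2))
})

test_that("isotropic and mildly anisotropic frames pick the right factors", {
  iso <- factor_schedule(coord_frame(c(512, 512, 512), c(8, 8, 8)), 3)
  expect_true(all(iso$fz[-1] == 2))
  mild <- factor_schedule(coord_frame(c(512, 512, 128), c(4, 4, 12)), 2)
  expect_equal(c(mild$fx[2], mild$fy[2], mild$fz[2]), c(2, 2, 1))  # ratio 3
  expect_equal(c(mild$fx[3], mild$fy[3], mild$fz[3]), c(2, 2, 2))  # ratio 1.5
  # extents follow ceil division
  expect_equal(unlist(mild$extent[[2]]), c(256, 256, 128))
  expect_equal(unlist(mild$extent[[3]]), c(128, 128, 64))
  ceil <- factor_schedule(coord_frame(c(1023, 1025, 17), c(8, 8, 8)), 1)
  expect_equal(unlist(ceil$extent[[2]]), c(512, 513, 9))
})

test_that("block reduction: mean rounded half-up, nonzero mode with smallest-id ties", {
  expect_equal(reduce_block(array(c(1, 2, 3, 4), c(2, 2, 1)), "image"), 3)
  expect_equal(reduce_block(array(c(1, 1, 2, 2), c(2, 2, 1)), "image"), 2)
  expect_equal(reduce_block(array(0, c(2, 2, 2)), "image"), 0)
  expect_equal(reduce_block(array(c(0, 7, 7, 9), c(2, 2, 1)), "annotation"), 7)
  expect_equal(reduce_block(array(c(7, 9, 0, 0), c(2, 2, 1)), "annotation"), 7)
  expect_equal(reduce_block(array(c(9, 9, 7, 0), c(2, 2, 1)), "annotation"), 9)
  expect_equal(reduce_block(array(0, c(2, 2, 1)), "annotation"), 0)
  expect_error(reduce_block(array(0, c(2, 2, 1)), "image", factors = c(2, 2, 2)),
               class = "vox_error_validation")
})

test_that("vectorized reduction agrees with the scalar operator", {
  set.seed(3)
  for (ctype in c("image", "annotation")) {
    f <- c(2, 2, 2)
    a <- array(sample(c(0, 1, 7, 9, 200), 8 * 6 * 4, TRUE), c(8, 6, 4))
    red <- voxstore:::reduce_array(a, f, ctype)
    for (i in 1:4) for (j in 1:3) for (k in 1:2) {
      block <- a[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
      expect_equal(red[i, j, k], reduce_block(block, ctype))
    }
  }
})

test_that("constant volumes stay constant at every level, even at odd extents", {
  ext <- c(100, 75, 20)
  ctx <- make_channel_pair(extent = ext, voxel_size = c(4, 4, 40),
                           cuboid_shape = c(32, 32, 8), levels = 3)
  vox_write_cutout(ctx$store, ctx$img, full_range(ext), array(5, ext))
  vox_downsample(ctx$store, ctx$img)
  sched <- factor_schedule(ctx$img$frame, 2)
  for (L in 1:2) {
    e <- unlist(sched$extent[[L + 1]])
    v <- vox_read_cutout(ctx$store, ctx$img, full_range(e), resolution = L)
    expect_true(all(v == 5))
  }
})

test_that("levels preserve the mean and keep annotation labels a subset", {
  set.seed(29)
  ext <- c(64, 64, 16)
  ctx <- make_channel_pair(extent = ext, voxel_size = c(4, 4, 40),
                           cuboid_shape = c(32, 32, 8), levels = 2)
  img_vol <- random_volume(ext, "uint8")
  vox_write_cutout(ctx$store, ctx$img, full_range(ext), img_vol)
  ann_vol <- array(sample(c(0, 0, 3, 7, 2^33), prod(ext), TRUE), ext)
  vox_write_cutout(ctx$store, ctx$seg, full_range(ext), ann_vol)
  vox_downsample(ctx$store, ctx$img)
  vox_downsample(ctx$store, ctx$seg)
  l1 <- vox_read_cutout(ctx$store, ctx$img, full_range(c(32, 32, 16)), resolution = 1)
  expect_lt(abs(mean(l1) - mean(img_vol)), 0.5)
  ids0 <- vox_ids_in_region(ctx$store, ctx$seg, full_range(ext))
  ids1 <- vox_ids_in_region(ctx$store, ctx$seg, full_range(c(32, 32, 16)),
                            resolution = 1)
  expect_true(all(ids1 %in% ids0))
  expect_gt(length(ids1), 0)
})

test_that("a sphere's level-1 bbox is the level-0 bbox halved in-plane", {
  ext <- c(96, 96, 16)
  ph <- generate_phantom(phantom_spec(ext, seed = 6, objects = list(
    phantom_sphere(c(48, 48, 8), 14, label = 7))))
  ctx <- make_channel_pair(extent = ext, voxel_size = c(4, 4, 40),
                           cuboid_shape = c(32, 32, 8), levels = 2)
  vox_write_cutout(ctx$store, ctx$seg, full_range(ext), ph$annotation)
  vox_downsample(ctx$store, ctx$seg)
  b0 <- vox_bounding_box(ctx$store, ctx$seg, 7, "tight", resolution = 0)
  b1 <- vox_bounding_box(ctx$store, ctx$seg, 7, "tight", resolution = 1)
  for (ax in c("x", "y")) {
    expect_lte(abs(b1[[ax]][1] - floor(b0[[ax]][1] / 2)), 1)
    expect_lte(abs(b1[[ax]][2] - ceiling(b0[[ax]][2] / 2)), 1)
  }
  expect_equal(b1$z, b0$z)  # (2,2,1) transition leaves z untouched
})

test_that("partial downsample after edits is bit-identical to a full rebuild", {
  set.seed(41)
  ext <- c(128, 96, 32)
  shape <- c(32, 32, 8)
  build <- function() {
    ctx <- make_channel_pair(extent = ext, voxel_size = c(4, 4, 40),
                             cuboid_shape = shape, levels = 3)
    ctx
  }
  base_img <- random_volume(ext, "uint8")
  base_ann <- array(sample(c(0, 0, 5, 9, 31), prod(ext), TRUE), ext)
  edits <- lapply(1:4, function(i) {
    r <- random_range(ext, c(60, 40, 16))
    list(r = r, img = random_volume(dim(r), "uint8"),
         ann = array(sample(c(0, 5, 77), prod(dim(r)), TRUE), dim(r)))
  })

  partial <- build()
  vox_write_cutout(partial$store, partial$img, full_range(ext), base_img)
  vox_write_cutout(partial$store, partial$seg, full_range(ext), base_ann)
  vox_downsample(partial$store, partial$img)
  vox_downsample(partial$store, partial$seg)
  for (e in edits) {
    vox_write_cutout(partial$store, partial$img, e$r, e$img)
    vox_write_cutout(partial$store, partial$seg, e$r, e$ann)
  }
  vox_partial_downsample(partial$store, partial$img)
  vox_partial_downsample(partial$store, partial$seg)

  full <- build()
  fi <- base_img; fa <- base_ann
  for (e in edits) {
    fi <- apply_write_ref(fi, e$r, e$img)
    fa <- apply_write_ref(fa, e$r, e$ann)
  }
  vox_write_cutout(full$store, full$img, full_range(ext), fi)
  vox_write_cutout(full$store, full$seg, full_range(ext), fa)
  vox_downsample(full$store, full$img)
  vox_downsample(full$store, full$seg)

  sched <- factor_schedule(partial$img$frame, 2)
  for (L in 1:2) {
    e <- unlist(sched$extent[[L + 1]])
    expect_identical(
      vox_read_cutout(partial$store, partial$img, full_range(e), resolution = L),
      vox_read_cutout(full$store, full$img, full_range(e), resolution = L))
    expect_identical(
      vox_read_cutout(partial$store, partial$seg, full_range(e), resolution = L),
      vox_read_cutout(full$store, full$seg, full_range(e), resolution = L))
  }
})

test_that("partial rebuild touches only ancestors of the changed footprint", {
  ext <- c(128, 64, 16)
  ctx <- make_channel_pair(extent = ext, voxel_size = c(8, 8, 8),
                           cuboid_shape = c(32, 32, 8), levels = 2)
  vox_write_cutout(ctx$store, ctx$img, full_range(ext), random_volume(ext))
  vox_downsample(ctx$store, ctx$img)
  w0 <- vox_counters(ctx$store)$store_writes
  # an edit spanning two cuboid columns at x = 30..40
  r <- vox_range(c(30, 40), c(0, 8), c(0, 8))
  vox_write_cutout(ctx$store, ctx$img, r, random_volume(dim(r)))
  w_edit <- vox_counters(ctx$store)$store_writes - w0
  expect_equal(w_edit, 2)  # two level-0 cuboids rewritten
  vox_partial_downsample(ctx$store, ctx$img)
  # level-1 footprint x[15,20) fits one 32-wide chunk column -> 1 parent write
  w_ds <- vox_counters(ctx$store)$store_writes - w0 - w_edit
  expect_equal(w_ds, 1)
  # no stale ranges remain
  expect_length(vox_stale_ranges(ctx$store, ctx$img), 0)
  # empty changed footprint rewrites nothing
  w1 <- vox_counters(ctx$store)$store_writes
  vox_partial_downsample(ctx$store, ctx$img, list())
  expect_equal(vox_counters(ctx$store)$store_writes, w1)
})

test_that("partial rebuild without a hierarchy is a state error", {
  ctx <- make_channel_pair(levels = 1)
  expect_error(vox_partial_downsample(ctx$store, ctx$img),
               class = "vox_error_state")
})
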