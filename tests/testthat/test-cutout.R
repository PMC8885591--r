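# Cutout service: arbitrary-volume I/O, slices, serialization.

test_that("reads of never-written data are zero-filled at the requested shape", {
  ctx <- make_channel_pair()
  r <- vox_range(c(3, 60), c(10, 90), c(0, 20))
  out <- vox_read_cutout(ctx$store, ctx$img, r)
  expect_equal(dim(out), c(57, 80, 20))
  expect_true(all(out == 0))
})

test_that("write/read round-trips across cuboid boundaries, both dtypes", {
  for (nm in c("img", "seg")) {
    ctx <- make_channel_pair()
    ch <- ctx[[nm]]
    dtype <- ch$datatype
    r <- vox_range(c(20, 100), c(30, 127), c(3, 30))  # straddles 32x32x8 grid
    x <- random_volume(dim(r), dtype)
    vox_write_cutout(ctx$store, ch, r, x)
    expect_identical(vox_read_cutout(ctx$store, ch, r), x)
    # neighbouring voxels untouched
    full <- vox_read_cutout(ctx$store, ch, full_range(c(128, 128, 32)))
    expect_true(all(full[1:20, , ] == 0))
    expect_true(all(full[, , 31:32] == 0))
  }
})

test_that("overlapping writes behave as last-writer-wins per voxel", {
  ctx <- make_channel_pair()
  st <- ctx$store
  ra <- vox_range(c(0, 64), c(0, 64), c(0, 16))
  rb <- vox_range(c(30, 90), c(20, 50), c(8, 24))
  A <- array(1, dim(ra)); B <- array(2, dim(rb))
  vox_write_cutout(st, ctx$img, ra, A)
  vox_write_cutout(st, ctx$img, rb, B)
  ref <- apply_write_ref(apply_write_ref(dense_ref(c(128, 128, 32)), ra, A), rb, B)
  expect_identical(vox_read_cutout(st, ctx$img, full_range(c(128, 128, 32))), ref)
})

test_that("randomized cutout interleavings match a dense-array reference", {
  set.seed(17)
  ext <- c(96, 96, 48)
  for (dtype in c("uint8", "uint64")) {
    ctx <- make_channel_pair(extent = ext, cuboid_shape = c(32, 32, 8),
                             dtype = if (dtype == "uint8") "uint8" else "uint8")
    ch <- if (dtype == "uint8") ctx$img else ctx$seg
    ref <- dense_ref(ext)
    for (i in 1:60) {
      r <- random_range(ext, max_size = c(50, 50, 20))
      if (i %% 3 == 0) {
        expect_identical(vox_read_cutout(ctx$store, ch, r), read_ref(ref, r))
      } else {
        x <- random_volume(dim(r), dtype)
        vox_write_cutout(ctx$store, ch, r, x)
        ref <- apply_write_ref(ref, r, x)
      }
    }
    expect_identical(vox_read_cutout(ctx$store, ch, full_range(ext)),
                     read_ref(ref, full_range(ext)))
  }
})

test_that("reading a region equals concatenating reads of a partition of it", {
  set.seed(23)
  ctx <- make_channel_pair()
  r <- vox_range(c(10, 90), c(5, 100), c(2, 28))
  x <- random_volume(dim(r))
  vox_write_cutout(ctx$store, ctx$img, r, x)
  whole <- vox_read_cutout(ctx$store, ctx$img, r)
  cutx <- sample(seq.int(r$x[1] + 1, r$x[2] - 1), 1)
  left <- vox_read_cutout(ctx$store, ctx$img,
                          vox_range(c(r$x[1], cutx), r$y, r$z))
  right <- vox_read_cutout(ctx$store, ctx$img,
                           vox_range(c(cutx, r$x[2]), r$y, r$z))
  glued <- array(0, dim(whole))
  glued[seq_len(dim(left)[1]), , ] <- left
  glued[dim(left)[1] + seq_len(dim(right)[1]), , ] <- right
  expect_identical(whole, glued)
})

test_that("out-of-range requests and shape mismatches are rejected", {
  ctx <- make_channel_pair()
  expect_error(vox_read_cutout(ctx$store, ctx$img,
                               vox_range(c(0, 129), c(0, 8), c(0, 8))),
               class = "vox_error_validation")
  expect_error(vox_read_cutout(ctx$store, ctx$img,
                               vox_range(c(0, 8), c(0, 8), c(0, 8)),
                               resolution = 1),
               class = "vox_error_validation")
  expect_error(vox_write_cutout(ctx$store, ctx$img,
                                vox_range(c(0, 8), c(0, 8), c(0, 8)),
                                array(0, c(4, 8, 8))),
               class = "vox_error_validation")
  expect_error(vox_write_cutout(ctx$store, ctx$img,
                                vox_range(c(0, 8), c(0, 8), c(0, 8)),
                                array(4096, c(8, 8, 8))),
               class = "vox_error_validation")
})

test_that("slices equal thickness-1 cutouts on all three planes", {
  set.seed(31)
  ext <- c(96, 64, 32)
  ctx <- make_channel_pair(extent = ext)
  # z-gradient volume: voxel value = its z index
  vol <- array(rep(0:(ext[3] - 1), each = ext[1] * ext[2]), ext)
  vox_write_cutout(ctx$store, ctx$img, full_range(ext), vol)
  s5 <- vox_slice(ctx$store, ctx$img, "XY", 5)
  expect_true(all(s5 == 5))
  expect_equal(dim(s5), ext[1:2])
  for (i in 1:25) {
    plane <- sample(c("XY", "XZ", "YZ"), 1)
    axes <- switch(plane, XY = c(1, 2, 3), XZ = c(1, 3, 2), YZ = c(2, 3, 1))
    idx <- sample(0:(ext[axes[3]] - 1), 1)
    sl <- vox_slice(ctx$store, ctx$img, plane, idx)
    bounds <- vector("list", 3)
    bounds[[axes[1]]] <- c(0, ext[axes[1]])
    bounds[[axes[2]]] <- c(0, ext[axes[2]])
    bounds[[axes[3]]] <- c(idx, idx + 1)
    cut <- vox_read_cutout(ctx$store, ctx$img,
                           vox_range(bounds[[1]], bounds[[2]], bounds[[3]]))
    expect_identical(sl, matrix(aperm(cut, c(axes[1:2], axes[3])),
                                ext[axes[1]], ext[axes[2]]))
  }
  expect_error(vox_slice(ctx$store, ctx$img, "XY", ext[3]),
               class = "vox_error_validation")
  expect_error(vox_slice(ctx$store, ctx$img, "QQ", 0),
               class = "vox_error_validation")
})

test_that("fixed-tile slice requests beyond the extent are zero-padded", {
  ctx <- make_channel_pair(extent = c(40, 40, 8))
  vol <- array(9, c(40, 40, 8))
  vox_write_cutout(ctx$store, ctx$img, full_range(c(40, 40, 8)), vol)
  tile <- vox_slice(ctx$store, ctx$img, "XY", 0, tile_size = c(64, 64))
  expect_equal(dim(tile), c(64, 64))
  expect_true(all(tile[1:40, 1:40] == 9))
  expect_true(all(tile[41:64, ] == 0))
  expect_true(all(tile[, 41:64] == 0))
  far <- vox_slice(ctx$store, ctx$img, "XY", 0, tile_size = c(64, 64),
                   tile_origin = c(64, 0))
  expect_true(all(far == 0))
})

test_that("cutout serialization round-trips in both formats", {
  set.seed(37)
  for (dtype in c("uint8", "uint16", "uint64")) {
    x <- random_volume(c(6, 5, 4), dtype)
    for (fmt in c("blob", "npy")) {
      enc <- vox_encode_cutout(x, dtype, fmt,
                               range = vox_range(c(0, 6), c(0, 5), c(0, 4)))
      dec <- vox_decode_cutout(enc, fmt)
      expect_identical(dec$data, x)
      expect_equal(dec$dtype, dtype)
    }
  }
  # blob header carries the range metadata
  enc <- vox_encode_cutout(array(0, c(2, 2, 2)), "uint8", "blob",
                           range = vox_range(c(4, 6), c(0, 2), c(8, 10)),
                           resolution = 1)
  at <- vox_decode_cutout(enc, "blob")$attrs
  expect_equal(unlist(at$range$x), c(4, 6))
  expect_equal(at$resolution, 1)
  # raw payload arithmetic: 2x2x2 uint8 encodes 8 payload bytes after header
  enc2 <- vox_encode_cutout(array(1, c(2, 2, 2)), "uint8", "blob")
  h <- voxstore:::blob_header(enc2)
  expect_equal(length(memDecompress(enc2[(h$payload_offset + 1):length(enc2)],
                                    type = "gzip")), 8)
  expect_error(vox_decode_cutout(enc2[1:25], "blob"), class = "vox_error_format")
  expect_error(vox_encode_cutout(array(1, c(2, 2, 2)), "uint8", "hdf"),
               label = "unknown format tag")
})
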