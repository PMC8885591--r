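# Shared fixtures: stores and channels are built in code under tempdirs; no
# binary fixtures are shipped.

new_test_store <- function(..., root = tempfile("voxstore-test-")) {
  vox_store(root, ...)
}

# store with one experiment frame and an image + annotation channel pair,
# using a small cuboid shape so requests cross chunk boundaries cheaply
make_channel_pair <- function(extent = c(128, 128, 32),
                              voxel_size = c(4, 4, 40),
                              cuboid_shape = c(32, 32, 8),
                              levels = 1, dtype = "uint8", ...) {
  st <- new_test_store(...)
  vox_create(st, "col")
  vox_create(st, "col/exp", coord_frame = coord_frame(extent, voxel_size))
  vox_create(st, "col/exp/img", type = "image", datatype = dtype,
             num_hierarchy_levels = levels, cuboid_shape = cuboid_shape)
  vox_create(st, "col/exp/seg", type = "annotation",
             num_hierarchy_levels = levels, cuboid_shape = cuboid_shape)
  list(store = st,
       img = vox_channel(st, "col/exp/img"),
       seg = vox_channel(st, "col/exp/seg"))
}

full_range <- function(extent) {
  vox_range(c(0, extent[1]), c(0, extent[2]), c(0, extent[3]))
}

random_range <- function(extent, max_size = extent) {
  lo <- hi <- numeric(3)
  for (a in 1:3) {
    w <- sample.int(min(max_size[a], extent[a]), 1)
    lo[a] <- sample.int(extent[a] - w + 1, 1) - 1
    hi[a] <- lo[a] + w
  }
  vox_range(c(lo[1], hi[1]), c(lo[2], hi[2]), c(lo[3], hi[3]))
}

random_volume <- function(dims, dtype = "uint8",
                          values = NULL) {
  vals <- values %||% switch(dtype,
    uint8 = 0:255,
    uint16 = 0:65535,
    uint64 = c(0, 1, 7, 9, 255, 2^32, 2^40 + 3)
  )
  array(as.double(sample(vals, prod(dims), replace = TRUE)), dims)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense-array reference used as the cutout/cache oracle
dense_ref <- function(extent) array(0, extent)

apply_write_ref <- function(ref, range, data) {
  ref[seq.int(range$x[1] + 1, range$x[2]),
      seq.int(range$y[1] + 1, range$y[2]),
      seq.int(range$z[1] + 1, range$z[2])] <- data
  ref
}

read_ref <- function(ref, range) {
  ref[seq.int(range$x[1] + 1, range$x[2]),
      seq.int(range$y[1] + 1, range$y[2]),
      seq.int(range$z[1] + 1, range$z[2]), drop = FALSE]
}
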