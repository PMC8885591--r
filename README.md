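# voxstore

An embedded, single-machine datastore for large volumetric neuroimaging
data — the kind of multi-terabyte electron-microscopy (EM) and X-ray
microtomography volumes produced in connectomics, together with their
voxel-wise segmentations. Cloud-native volumetric databases solve this
problem at petabyte scale with object stores, in-memory caches, and
serverless indexing; `voxstore` re-implements that storage model as an
in-process R library over a plain directory tree, so the same access
semantics (arbitrary cutouts, annotation queries, resolution hierarchies,
tile/chunk ingest) are available to desk-scale analyses and to tests, with
no services to run.

It is written for image-analysis researchers who need random access into
volumes far larger than memory, and for method developers who need a
faithful local stand-in for a chunked volumetric store.

## The storage model

**Cuboids and Morton order.** A channel's voxels are split into fixed-shape
*cuboids* (default 512 × 512 × 16 voxels) stored as compressed C-order
arrays. Each cuboid's chunk coordinate (c\_x, c\_y, c\_z) is mapped to a
single integer key by bit interleaving — the Morton (z-order) space-filling
curve

&nbsp;&nbsp;&nbsp;&nbsp;code = Σᵢ ( x\_i·2^{3i} + y\_i·2^{3i+1} + z\_i·2^{3i+2} ),

so spatially nearby chunks receive nearby keys. A cutout request for the
half-open box \[x₀,x₁) × \[y₀,y₁) × \[z₀,z₁) is decomposed into the cuboids
it intersects, served through a two-tier hierarchy: an in-memory LRU cache
over the on-disk object store. Never-written cuboids read as 0.

**Annotation indices.** Annotation channels hold uint64 labels (0 =
background; each nonzero value one object). Every cuboid write maintains a
forward index (cuboid → labels present) and its transpose (label → cuboids),
which answer `vox_ids_in_region()` (exact, voxel-filtered) and
`vox_bounding_box()` (index-only *loose* box, or voxel-exact *tight* box).

**Anisotropic downsampling.** Serial-section EM voxels are typically
anisotropic (e.g. 4 × 4 × 40 nm). The resolution hierarchy reduces in-plane
only — factors (2, 2, 1) — while the z/xy voxel-size ratio is ≥ 2, then
switches to isotropic (2, 2, 2): a 4/4/40 nm frame reaches 32/32/40 nm at
level 3 before z reduction begins. Image levels average (rounded half-up);
annotation levels take the nonzero mode with smallest-id ties. After edits,
`vox_partial_downsample()` rebuilds only the ancestors of changed cuboids,
bit-identically to a full rebuild.

**Ingest.** Tile stacks (PNG/TIFF) and chunked volumes (Zarr) are ingested
through jobs with file-backed, at-least-once task queues; arrival tracking
reassembles tiles into cuboids exactly once per region even under duplicate
task delivery. Plug-in readers map tasks to files via path templates like
`z{z:04d}/y{y}_x{x}.png`.

## Worked example

```r
library(voxstore)

st <- vox_store(tempfile("vox-demo-"))
vox_create(st, "cortex")
vox_create(st, "cortex/em1",
           coord_frame = coord_frame(c(2048, 2048, 128), voxel_size = c(4, 4, 40)))
vox_create(st, "cortex/em1/synapses", type = "annotation", num_hierarchy_levels = 4)

seg <- vox_resolve_uri(st, "bossdb://cortex/em1/synapses")
#> <vox_channel cortex/em1/synapses: annotation uint64, extent 2048x2048x128, 4 level(s)>

ph <- generate_phantom(phantom_spec(c(1024, 1024, 64), seed = 42, objects = list(
  phantom_sphere(c(300, 420, 30), 18, label = 101),
  phantom_sphere(c(700, 150, 12), 11, label = 205))))
vox_write_cutout(st, seg, vox_range(c(0, 1024), c(0, 1024), c(0, 64)), ph$annotation)

vox_ids_in_region(st, seg, vox_range(c(256, 768), c(0, 1024), c(0, 64)))
#> [1] 101 205
vox_bounding_box(st, seg, 101, mode = "tight")
#> <vox_range x[282,319) y[402,439) z[12,49)>
vox_bounding_box(st, seg, 101, mode = "loose")
#> <vox_range x[0,512) y[0,512) z[0,64)>
```

The tight box is the minimal half-open range containing every voxel of
label 101 (a radius-18 sphere at (300, 420, 30)); the loose box is the
union of the 512 × 512 × 16 cuboids that contain it, answered from the
index without reading voxels. Building the hierarchy and asking again two
levels up halves x/y twice while z is untouched (the (2, 2, 1) phase):

```r
vox_downsample(st, seg)
vox_bounding_box(st, seg, 101, mode = "tight", resolution = 2)
#> <vox_range x[70,80) y[100,110) z[12,49)>

factor_schedule(seg$frame, 4)[, c("level", "fx", "fy", "fz", "size_x", "size_y", "size_z")]
#>   level fx fy fz size_x size_y size_z
#> 1     0  1  1  1      4      4     40
#> 2     1  2  2  1      8      8     40
#> 3     2  2  2  1     16     16     40
#> 4     3  2  2  1     32     32     40
#> 5     4  2  2  2     64     64     80
```

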