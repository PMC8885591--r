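---
title: "voxstore: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{voxstore: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxstore)
```

`voxstore` is an embedded datastore for chunked volumetric image and
annotation data. This vignette explains the model it implements, the
parameters that matter, the numerical conventions, and the design choices
made where more than one reasonable option existed — together with what the
package's synthetic-data tests do and do not demonstrate about real data.

## The data model

Resources form a three-level hierarchy — *collection / experiment /
channel* — addressed by paths and by `bossdb://` URIs with exactly those
three segments. An experiment owns a **coordinate frame**: per-axis voxel
extents at native resolution and physical voxel sizes in nanometres.
Frames are scoped to experiments (not shared across collections); channels
within one experiment are co-registered by construction, which is the
common case of imagery plus its segmentations.

A **channel** is a typed volume: image channels are `uint8` or `uint16`,
annotation channels are `uint64` with 0 reserved as background and each
nonzero value naming one object. The type/dtype pairing is enforced at
creation. Arbitrary string key-value metadata can be attached to any
resource; the catalog (and the metadata) is persisted as one JSON document
per collection, so a store is fully inspectable with a text editor and
needs no database process.

Voxel values are held in R doubles. For `uint64` labels this is exact up to
2^53, far beyond any realistic object-id budget; serialization always
writes true fixed-width little-endian unsigned integers, so on-disk
payloads are byte-correct for external tools.

## Cuboids, Morton order, and precision

The unit of storage is the **cuboid**, a fixed-shape chunk (default
512 × 512 × 16 voxels, configurable per channel and fixed once data is
written). Edge cuboids are stored full-size and zero-padded: uniform blob
sizes keep compression and arrival tracking simple, and the padding is
invisible through the API because reads are clipped to the frame.

Cuboids are keyed by the Morton (z-order) curve. The bit convention — x in
bit positions 3i, y in 3i+1, z in 3i+2 — is fixed and documented; encode
and decode are exact inverses, so the choice is internally consistent
everywhere a key is formed. The time index is *not* folded into the code:
time series are optional, and keeping t a separate key component preserves
the curve's spatial locality. Chunk coordinates are bounded at 2^17 per
axis so every code stays below 2^51 and is therefore an exact integer in an
R double; at the default cuboid shape that addresses over 6 × 10^7 voxels
per axis, far beyond desk scale.

## The storage hierarchy

Reads and writes go through a two-tier hierarchy: an in-memory cuboid cache
over a filesystem object store keyed by the stable string
`collection/experiment/channel/resolution/t<t>/m<morton>` — the same
immutable put/get-by-key discipline as a cloud object store, which keeps
the door open for a remote backend. Blobs carry a self-describing header
(codec, dtype, shape, endianness) ahead of a zlib-compressed C-order
payload; decompression is bit-lossless, and a corrupt or missing blob
behind an index entry raises an error rather than reading as zeros.

Cache parameters: `cache_capacity` (cuboids resident, default 64 — at the
default shape roughly 2 GB of uint64 or 256 MB of uint8 worst case) and the
write policy. Write-through is the default contract: a put is durable when
it returns. Write-back (`write_back = TRUE`) defers persistence to eviction
or `vox_flush()`; dirty cuboids are always flushed before eviction, so
eviction never loses data. Eviction is LRU with clean entries preferred —
evicting a clean cuboid costs a re-read, evicting a dirty one costs a write
plus a re-read. A cuboid-existence index short-circuits reads of
never-written keys without touching the disk; explicit all-zero cuboids are
distinct from absent ones.

## Cutouts and slices

Cutout coordinates are 0-based, half-open `[start, stop)`, addressed
x/y/z. In memory a cutout has `dim = (nx, ny, nz)`; R's column-major layout
makes this byte-identical to a C-order `(z, y, x)` array, which is the
store's canonical serialization order and matches NumPy-style
`dataset[z0:z1, y0:y1, x0:x1]` indexing on the Python side. Writes are
read-modify-write per intersected cuboid with last-writer-wins semantics
per voxel; there is no versioning. Absent data reads as 0 on both channel
kinds — black imagery, background annotation.

The image service is defined *by* the cutout service: a slice is a
thickness-1 cutout with the orthogonal axis squeezed, on any of the XY, XZ,
YZ planes, with an optional fixed-tile mode that zero-pads beyond the frame
(the contract tiled viewers expect). PNG output covers `uint8` and TIFF
covers `uint8`/`uint16`, both lossless; no lossy image codec is offered, so
every supported encoding round-trips bit-exactly. Cutout payloads
serialize either as the native blob container (with range/resolution
attributes in the header) or as NPY v1.0 arrays readable by any
NumPy-compatible tool; a minimal Zarr v2 reader/writer handles chunked
volumes on disk. Single-`t` requests only: 4D cutouts are out of scope.

## Annotation indices

Two maps are maintained per annotation channel and resolution level: the
forward map (cuboid → distinct nonzero labels present) and the reverse map
(label → Morton codes), exact transposes of each other. They are updated
synchronously with every cuboid write from the written array itself, and
journalled to a JSON-lines sidecar replayed last-line-wins at open;
`vox_reindex()` rebuilds both from a full scan, which is the recovery path
if a crash lands between a cuboid write and its index append.

`vox_ids_in_region()` is exact by default: index candidates are
voxel-filtered in cuboids only partially covered by the query, so a label
living just outside the range is excluded. The cheaper cuboid-level
superset remains available behind `fast = TRUE`, labelled as such, because
for large viewport-style queries the superset is often sufficient.
Bounding boxes come in both flavours: *loose* (cuboid-aligned union,
index-only) and *tight* (voxel-exact, reads only the candidate cuboids);
tight ⊆ loose always.

## The downsample hierarchy

The factor schedule derives per-level reduction triples from the frame's
voxel sizes: while the z/xy size ratio at the source level is at least 2,
the transition is in-plane (2, 2, 1); below that threshold it is isotropic
(2, 2, 2). The threshold of 2 reproduces the canonical serial-section EM
progression — a 4/4/40 nm frame passes 8, 16, 32 nm in-plane with z fixed
at 40 nm, then reduces isotropically with the residual 32-vs-40 anisotropy
shrinking no further in ratio but becoming irrelevant at viewing scales.
Extents follow `ceiling(extent / factors)`; voxel sizes multiply by the
factors and are always derived from level 0, never stored.

Reduction operators: image blocks take the arithmetic mean rounded half-up
(documented so levels are bit-reproducible); annotation blocks take the
mode of nonzero labels with ties broken toward the smallest id, returning 0
only for all-background blocks. Mode preserves thin objects better than
corner sampling, and the deterministic tie-break makes rebuilds
reproducible. At frame edges the image mean is taken over in-frame voxels
only, so padding never dilutes it and constant volumes stay exactly
constant at every level — a property the test suite asserts. One practical
note: the vectorized annotation reducer builds a per-distinct-label count
matrix, so its memory scales with the number of labels present in a
region; phantom-scale and typical segmentation densities are unproblematic,
but a region with millions of distinct ids would be better reduced
per-cuboid.

Writes land at the base resolution; higher levels are read-only except
through the downsample operations. Every write records its footprint, and
`vox_partial_downsample()` recomputes only the ancestors of cuboids
intersecting the recorded (or explicitly given) ranges — by construction
through the same per-target-cuboid code path as the full rebuild, so
partial and full results are bit-identical, which the suite verifies on
randomized edit sequences.

## Ingest

Ingest jobs are declarative JSON configurations: target channel URI, region
extent/offset, tile or chunk size, and a reader plug-in with parameters.
Task queues are file-backed with visibility-timeout leases, mimicking
cloud queue semantics locally: delivery is at-least-once, so every handler
is idempotent — duplicate tile uploads are deduplicated by arrival keys,
and re-delivered chunk tasks rewrite identical bytes.

Tile ingest tracks arrivals per cuboid region (one cuboid's z-extent per
footprint, the natural reassembly unit); when the last covering tile
arrives, the region is assembled and written exactly once — the
`cuboidify_calls` counter makes this testable. Staged tiles are marked
deletable and swept by `vox_gc()` rather than deleted at assembly time,
which aids crash recovery. Volumetric chunks must be cuboid-grid aligned
(misalignment is a validation error, not a silent re-chunk): unaligned
sources would require cross-chunk write merging that a parallel ingest
cannot order, and such data can always take the tile path. Tile sizes need
not match the cuboid footprint; coverage arithmetic handles tiles that
span cuboid columns.

Built-in plug-ins read PNG/TIFF tiles and Zarr chunks, with `{x}`, `{y}`,
`{z:04d}`-style path templating; other layouts are user plug-ins
registered with `vox_register_plugin()`. JPEG is not offered (lossy, and
excluded from round-trip guarantees); HDF5 and N5 chunk containers are not
built in — Zarr covers the chunked-file path, and its R implementation
here interoperates with the Python `zarr`/`numcodecs` stack, which the
test suite checks directly.

## Phantoms: what the tests show

The fixture generator rasterizes labelled spheres and boxes over a
background with optional gradient and speckle noise, deterministically
given a seed, and tabulates per-label ground truth (voxel counts, tight
bounding boxes) from the dense array itself — never from the store indices
under test, so index tests are non-circular. Phantom volumes exercise
geometry, chunking, and label bookkeeping exactly; they do not emulate EM
texture, imaging noise statistics, alignment artefacts, or realistic
segmentation morphology. Passing tests therefore demonstrate storage and
index correctness — bit-exact round-trips, exact query semantics — not
anything about analysis quality on real micrographs.

## Problem sizes and numerical choices

The randomized suites run at desk scale chosen to cross many chunk
boundaries while staying quick: cutout/dense-array equivalence uses a 256³
domain with 64 × 64 × 16 cuboids and 200 mixed operations per dtype;
Morton bijectivity samples 10⁴ coordinates and tiles 10³ random ranges;
downsample identity uses a 256 × 192 × 64 frame over four levels. Cuboid
shape is a per-channel parameter, and smaller-than-default chunks are the
intended configuration at these extents.

Degenerate inputs are rejected rather than coerced: empty ranges,
out-of-frame requests, dtype/shape mismatches, label 0 in annotation
queries, and misaligned chunks all raise typed conditions
(`vox_error_validation`, `vox_error_not_found`, ...). Ties and rounding are
fixed (half-up means, smallest-id modes) so that every derived artefact —
blobs, levels, indices — is reproducible byte-for-byte across runs.

## Known limitations

No deletion or versioning of resources and voxels (metadata keys are the
exception); no authentication — permissions are a pluggable hook defaulting
to allow-all; single-process access with no file locking; one time index
per request; Morton coordinates bounded at 2^17 per axis by double
precision; annotation reduction memory scales with distinct labels per
region. These bounds are deliberate: the package targets embedded,
desk-scale use with the same semantics as its cloud-scale counterparts,
not their concurrency or throughput envelope.
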