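Package: voxstore
Title: Embedded Chunked Datastore for Volumetric Neuroimaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An embedded, single-machine datastore for large multi-channel 3D
    (+time) image and annotation volumes, modelled on cloud-native volumetric
    databases used in connectomics. Volumes are stored as fixed-shape cuboid
    chunks addressed by a Morton-order (z-order) space-filling curve, behind a
    two-tier storage hierarchy (an in-memory LRU cache over a compressed
    on-disk object store). Services include arbitrary-volume cutout reads and
    writes, orthogonal-plane image slices, voxel-annotation spatial indices
    with bounding-box and region-membership queries, an anisotropy-aware
    multi-resolution downsample hierarchy with partial rebuilds, and tile and
    volumetric-chunk ingest pipelines with at-least-once task queues and
    plug-in file readers. A phantom generator produces synthetic volumes with
    known geometry and ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
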