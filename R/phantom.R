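# Synthetic phantom volumes with known geometry: labelled spheres and boxes
# over a background (optionally with an intensity gradient and speckle
# noise), plus writers that lay a volume out as a tile stack or a chunk file
# for exercising the ingest pipelines. The ground-truth table (per-label
# voxel count and tight bounding box) is computed from the rasterized dense
# array itself, independently of any store index.

#' Describe a phantom volume
#'
#' @param extent Integer triple, voxel extent `(x, y, z)`.
#' @param dtype Image dtype (`uint8`/`uint16`); annotations are always
#'   uint64.
#' @param seed Integer seed making generation fully deterministic.
#' @param objects List of primitives from [phantom_sphere()] /
#'   [phantom_box()]. Later objects overwrite earlier ones where they
#'   overlap; the ground truth reflects the final volume.
#' @param background Background image intensity (default 0).
#' @param gradient Optional axis name (`"x"`, `"y"`, `"z"`): adds a ramp of
#'   0..extent-1 (clipped to the dtype) to the image volume.
#' @param noise Standard deviation of rounded Gaussian speckle added to the
#'   image volume (0 disables).
#' @return A `vox_phantom_spec`.
#' @export
phantom_spec <- function(extent, dtype = "uint8", seed = 1L, objects = list(),
                         background = 0, gradient = NULL, noise = 0) {
  extent <- as.double(extent)
  if (length(extent) != 3 || any(extent < 1)) {
    vox_abort("extent must be three positive integers", "validation")
  }
  labels <- vapply(objects, function(o) o$label, numeric(1))
  if (anyDuplicated(labels)) {
    vox_abort("object labels must be distinct", "validation")
  }
  if (any(labels <= 0)) vox_abort("labels must be positive", "validation")
  structure(list(extent = extent, dtype = dtype, seed = as.integer(seed),
                 objects = objects, background = as.double(background),
                 gradient = gradient, noise = as.double(noise)),
            class = "vox_phantom_spec")
}

#' Phantom primitives
#'
#' @param center,radius Sphere center (voxel coords) and radius; a voxel
#'   belongs to the sphere when its center lies within `radius` of `center`.
#' @param from,to Box bounds, half-open per axis.
#' @param label Nonzero annotation label.
#' @param intensity Image intensity painted over the object (defaults to the
#'   label value clipped to the image dtype).
#' @return A primitive description for [phantom_spec()].
#' @export
phantom_sphere <- function(center, radius, label, intensity = NULL) {
  if (label <= 0) vox_abort("labels must be positive", "validation")
  list(kind = "sphere", center = as.double(center), radius = as.double(radius),
       label = as.double(label), intensity = intensity)
}

#' @rdname phantom_sphere
#' @export
phantom_box <- function(from, to, label, intensity = NULL) {
  if (label <= 0) vox_abort("labels must be positive", "validation")
  if (any(to <= from)) vox_abort("box needs from < to per axis", "validation")
  list(kind = "box", from = as.double(from), to = as.double(to),
       label = as.double(label), intensity = intensity)
}

#' Generate a phantom volume pair with ground truth
#'
#' Rasterizes the spec into an image volume and a coregistered uint64
#' annotation volume, and tabulates per-label ground truth (exact voxel count
#' and tight half-open bounding box) from the dense annotation array.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (array, image dtype), `annotation` (array,
#'   uint64 labels), and `truth` (data.frame: `label`, `count`, `x0`..`z1`).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   c(64, 64, 16),
#'   objects = list(phantom_box(c(10, 5, 0), c(20, 6, 2), label = 7))
#' ))
#' ph$truth
generate_phantom <- function(spec) {
  if (!inherits(spec, "vox_phantom_spec")) {
    vox_abort("spec must come from phantom_spec()", "validation")
  }
  ext <- spec$extent
  info <- dtype_info(spec$dtype)
  set.seed(spec$seed)
  img <- array(spec$background, ext)
  ann <- array(0, ext)
  if (!is.null(spec$gradient)) {
    axis <- match(spec$gradient, c("x", "y", "z"))
    ramp <- pmin(seq_len(ext[axis]) - 1, info$max)
    img <- img + array(switch(axis,
      rep(ramp, times = ext[2] * ext[3]),
      rep(rep(ramp, each = ext[1]), times = ext[3]),
      rep(ramp, each = ext[1] * ext[2])
    ), ext)
  }
  if (spec$noise > 0) {
    img <- img + round(abs(stats::rnorm(prod(ext), 0, spec$noise)))
  }
  img <- pmin(pmax(img, 0), info$max)
  xs <- seq_len(ext[1]) - 1; ys <- seq_len(ext[2]) - 1; zs <- seq_len(ext[3]) - 1
  for (ob in spec$objects) {
    inten <- min(ob$intensity %||% ob$label, info$max)
    if (ob$kind == "box") {
      if (any(ob$from < 0) || any(ob$to > ext)) {
        vox_abort("box outside phantom extent", "validation")
      }
      ix <- seq.int(ob$from[1] + 1, ob$to[1]); iy <- seq.int(ob$from[2] + 1, ob$to[2])
      iz <- seq.int(ob$from[3] + 1, ob$to[3])
      ann[ix, iy, iz] <- ob$label
      img[ix, iy, iz] <- inten
    } else {
      # voxel-center distance rasterization
      dx2 <- (xs - ob$center[1])^2; dy2 <- (ys - ob$center[2])^2
      dz2 <- (zs - ob$center[3])^2
      mask <- outer(outer(dx2, dy2, "+"), dz2, "+") <= ob$radius^2
      ann[mask] <- ob$label
      img[mask] <- inten
    }
  }
  labels <- sort(unique(as.vector(ann)))
  labels <- labels[labels != 0]
  truth <- do.call(rbind, lapply(labels, function(lb) {
    w <- which(ann == lb)
    pos <- arrayInd(w, ext)
    data.frame(label = lb, count = length(w),
               x0 = min(pos[, 1]) - 1, x1 = max(pos[, 1]),
               y0 = min(pos[, 2]) - 1, y1 = max(pos[, 2]),
               z0 = min(pos[, 3]) - 1, z1 = max(pos[, 3]))
  })) %||% data.frame(label = numeric(), count = numeric(),
                      x0 = numeric(), x1 = numeric(), y0 = numeric(),
                      y1 = numeric(), z0 = numeric(), z1 = numeric())
  list(image = img, annotation = ann, truth = truth)
}

#' Write a volume as a 2D tile stack
#'
#' Lays the volume out as one image file per (tile-column, z-slice) following
#' an ingest path pattern, and returns a manifest describing every file.
#' PNG supports uint8 tiles; TIFF supports uint8 and uint16 (both lossless).
#' uint64 annotation volumes have no image-tile encoding — ingest them as
#' chunks.
#'
#' @param volume Dense 3D array.
#' @param dir Output directory.
#' @param dtype Voxel dtype of the volume.
#' @param format `"png"` or `"tiff"`.
#' @param tile_size Integer pair (default `c(512, 512)`).
#' @param pattern Path pattern with `{x}`, `{y}`, `{z}` fields.
#' @return The manifest (list with `files` data.frame, `tile_size`,
#'   `pattern`, `extent`, `dtype`); also written as `manifest.json` in `dir`.
#' @export
write_tiles <- function(volume, dir, dtype = "uint8", format = c("png", "tiff"),
                        tile_size = c(512, 512),
                        pattern = NULL) {
  format <- match.arg(format)
  if (dtype == "uint64") {
    vox_abort("uint64 volumes have no image-tile encoding; use write_chunks",
              "validation")
  }
  if (format == "png" && dtype != "uint8") {
    vox_abort("PNG tiles support uint8 only; use TIFF for uint16", "validation")
  }
  ext <- tolower(if (format == "png") "png" else "tif")
  pattern <- pattern %||% paste0("z{z:04d}/y{y}_x{x}.", ext)
  d <- dim(volume)
  tile_size <- as.double(tile_size)
  ntx <- ceiling(d[1] / tile_size[1]); nty <- ceiling(d[2] / tile_size[2])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (z in seq_len(d[3]) - 1) for (ty in seq_len(nty) - 1) for (tx in seq_len(ntx) - 1) {
    x0 <- tx * tile_size[1]; x1 <- min(x0 + tile_size[1], d[1])
    y0 <- ty * tile_size[2]; y1 <- min(y0 + tile_size[2], d[2])
    tile <- volume[seq.int(x0 + 1, x1), seq.int(y0 + 1, y1), z + 1, drop = FALSE]
    tile <- matrix(tile, x1 - x0, y1 - y0)
    rel <- format_path(pattern, list(x = tx, y = ty, z = z))
    p <- file.path(dir, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    vox_save_slice(tile, p, dtype)
    files[[length(files) + 1L]] <- data.frame(file = rel, x = tx, y = ty, z = z)
  }
  manifest <- list(kind = "tiles", format = format, dtype = dtype,
                   extent = d, tile_size = tile_size, pattern = pattern,
                   files = do.call(rbind, files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Write a volume as a chunked Zarr array
#'
#' @param volume Dense 3D array.
#' @param path Output Zarr directory.
#' @param dtype Voxel dtype.
#' @param chunk_size Integer triple (default the whole volume).
#' @return The manifest list; also written as `manifest.json` next to the
#'   array.
#' @export
write_chunks <- function(volume, path, dtype, chunk_size = dim(volume)) {
  write_zarr(volume, path, dtype, chunks = chunk_size)
  manifest <- list(kind = "zarr", dtype = dtype, extent = dim(volume),
                   chunk_size = as.double(chunk_size), path = path)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
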