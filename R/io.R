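# Image and mask I/O: float TIFF with a JSON range sidecar, and JSON mask
# manifests.

#' Write / read a floating-point image as TIFF
#'
#' TIFF samples are stored in \[0, 1\]; arbitrary-range float images are
#' therefore min-max scaled before writing, with the affine range recorded
#' in a JSON sidecar (`<path>.json`) and undone on reading. Round-trip is
#' lossless to 32-bit float precision. Binary masks round-trip exactly.
#'
#' @param img numeric matrix.
#' @param path TIFF path.
#' @return `write_image()` returns the path; `read_image()` the matrix.
#' @export
write_image <- function(img, path) {
  check_image(img)
  lo <- min(img); hi <- max(img)
  scaled <- if (hi > lo) (img - lo) / (hi - lo) else img * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  jsonlite::write_json(list(lo = lo, hi = hi), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    rng <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- img * (rng$hi - rng$lo) + rng$lo
  }
  img
}

#' Write / read a bone mask set via a JSON manifest
#'
#' Each mask is stored as a TIFF next to a `manifest.json` mapping structure
#' names (`ribs`, `clavicle`, `lung`) to file names.
#'
#' @param masks a [bone_mask_set()].
#' @param dir output directory (created if needed).
#' @param manifest path to a `manifest.json`.
#' @return `write_mask_manifest()` returns the manifest path;
#'   `read_mask_manifest()` a `bone_mask_set`.
#' @export
write_mask_manifest <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rib_files <- character(0)
  for (nm in names(masks$rib_masks)) {
    f <- sprintf("rib_%s.tif", nm)
    tiff::writeTIFF(masks$rib_masks[[nm]] + 0, file.path(dir, f), bits.per.sample = 8L)
    rib_files[nm] <- f
  }
  manifest <- list(ribs = as.list(rib_files))
  if (!is.null(masks$clavicle_mask)) {
    tiff::writeTIFF(masks$clavicle_mask + 0, file.path(dir, "clavicle.tif"), bits.per.sample = 8L)
    manifest$clavicle <- "clavicle.tif"
  }
  if (!is.null(masks$lung_mask)) {
    tiff::writeTIFF(masks$lung_mask + 0, file.path(dir, "lung.tif"), bits.per.sample = 8L)
    manifest$lung <- "lung.tif"
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask_manifest
#' @export
read_mask_manifest <- function(manifest) {
  dir <- dirname(manifest)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  read_mask <- function(f) round(tiff::readTIFF(file.path(dir, f)))
  ribs <- lapply(man$ribs, read_mask)
  clav <- if (!is.null(man$clavicle)) read_mask(man$clavicle) else NULL
  lung <- if (!is.null(man$lung)) read_mask(man$lung) else NULL
  bone_mask_set(ribs, clavicle_mask = clav, lung_mask = lung)
}
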