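# Rib/clavicle mask handling: ingestion, anterior/posterior splitting,
# segmentation scoring, and the pluggable segmenter interface.

#' Set of bone masks on one pixel grid
#'
#' @param rib_masks named list of binary rib masks (one per rib; up to 20,
#'   the first ten ribs bilaterally).
#' @param clavicle_mask binary clavicle mask (may be empty).
#' @param lung_mask optional binary lung mask (needed for the
#'   anterior/posterior split).
#' @return object of class `bone_mask_set`.
#' @export
bone_mask_set <- function(rib_masks = list(), clavicle_mask = NULL, lung_mask = NULL) {
  rib_masks <- lapply(rib_masks, as_binary_mask, name = "rib mask")
  shp <- NULL
  for (m in rib_masks) { if (is.null(shp)) shp <- dim(m) else check_same_shape(rib_masks[[1]], m, "rib masks") }
  if (!is.null(clavicle_mask)) {
    clavicle_mask <- as_binary_mask(clavicle_mask, "clavicle mask")
    if (is.null(shp)) shp <- dim(clavicle_mask) else check_same_shape(rib_masks[[1]], clavicle_mask, "masks")
  }
  if (!is.null(lung_mask)) {
    lung_mask <- as_binary_mask(lung_mask, "lung mask")
    if (is.null(shp)) shp <- dim(lung_mask)
    else if (!identical(shp, dim(lung_mask))) df_stop("shape_mismatch", "lung mask shape differs")
  }
  structure(list(rib_masks = rib_masks, clavicle_mask = clavicle_mask,
                 lung_mask = lung_mask, shape = shp),
            class = "bone_mask_set")
}

#' Drop caudal ribs from a mask set
#'
#' The two most caudal ribs mostly overlay abdominal structures and are
#' excluded from lung-directed correction by default. Ribs are matched by
#' their numeric suffix in the mask name (e.g. `L11`, `R12`).
#'
#' @param masks a `bone_mask_set`.
#' @param keep_n highest rib number retained (default 10).
#' @return filtered `bone_mask_set`.
#' @export
exclude_caudal_ribs <- function(masks, keep_n = 10) {
  nums <- suppressWarnings(as.integer(gsub("\\D", "", names(masks$rib_masks))))
  keep <- is.na(nums) | nums <= keep_n
  bone_mask_set(masks$rib_masks[keep], masks$clavicle_mask, masks$lung_mask)
}

# inner boundary band of a binary mask (mask minus its erosion)
lung_boundary_band <- function(lung_mask, width = 1) {
  k <- EBImage::makeBrush(2 * width + 1, shape = "box")
  er <- EBImage::erode(lung_mask, k)
  band <- lung_mask * (1 - er)
  band
}

#' Split a rib mask into posterior and anterior components
#'
#' In a posterior-anterior radiograph each rib projects twice per image
#' column: the posterior segment superiorly and the anterior segment
#' inferiorly, crossing the lung outline near the lateral turn. The split
#' locates, per column, the overlap of the rib with the inner lung-boundary
#' band and takes the median row of those pixels as the boundary; columns
#' without overlap inherit the nearest computed boundary. Rib pixels with a
#' smaller row index than the boundary (superior; row 1 is the image top)
#' are posterior, the rest anterior.
#'
#' @param rib_mask,lung_mask binary masks of identical shape; rib non-empty.
#' @param band_width half-width (pixels) of the lung boundary band.
#' @param fallback assignment when the rib never meets the lung boundary:
#'   `"auto"` (default) assigns the whole rib by comparing its centroid row
#'   with the lung centroid row (above = posterior), `"posterior"` /
#'   `"anterior"` force the label; the event is messaged.
#' @return object of class `labeled_rib`: list with binary `posterior` and
#'   `anterior` masks (disjoint, union = input).
#' @export
split_anterior_posterior <- function(rib_mask, lung_mask, band_width = 1,
                                     fallback = c("auto", "posterior", "anterior")) {
  fallback <- match.arg(fallback)
  rib_mask <- as_binary_mask(rib_mask, "rib mask")
  lung_mask <- as_binary_mask(lung_mask, "lung mask")
  check_same_shape(rib_mask, lung_mask, "rib and lung masks")
  if (sum(rib_mask) == 0) df_stop("validation", "rib mask is empty")

  band <- lung_boundary_band(lung_mask, band_width)
  ov <- rib_mask * band
  rows <- row(rib_mask)
  if (sum(ov) == 0) {
    if (fallback == "auto") {
      rib_row <- mean(rows[rib_mask == 1])
      lung_row <- if (sum(lung_mask) > 0) mean(rows[lung_mask == 1]) else nrow(rib_mask) / 2
      fallback <- if (rib_row < lung_row) "posterior" else "anterior"
    }
    message("split_anterior_posterior: rib has no lung-boundary overlap; fallback = ", fallback)
    post <- if (fallback == "posterior") rib_mask else rib_mask * 0
    ant <- rib_mask - post
    return(structure(list(posterior = post, anterior = ant), class = "labeled_rib"))
  }
  ov_cols <- which(colSums(ov) > 0)
  b_at <- vapply(ov_cols, function(j) stats::median(which(ov[, j] > 0)), numeric(1))
  rib_cols <- which(colSums(rib_mask) > 0)
  # nearest computed boundary for every rib column
  nearest <- vapply(rib_cols, function(j) b_at[which.min(abs(ov_cols - j))], numeric(1))
  boundary <- rep(NA_real_, ncol(rib_mask))
  boundary[rib_cols] <- nearest
  bmat <- matrix(boundary, nrow(rib_mask), ncol(rib_mask), byrow = TRUE)
  post <- rib_mask * (rows < bmat)
  post[is.na(post)] <- 0
  ant <- rib_mask - post
  structure(list(posterior = post, anterior = ant), class = "labeled_rib")
}

#' Overlap scores for a binary segmentation
#'
#' Dice coefficient `2|P&T| / (|P|+|T|)`, sensitivity `|P&T|/|T|` and
#' specificity `|!P & !T| / |!T|`. Two empty masks agree perfectly
#' (Dice 1); sensitivity with empty truth (and specificity with full truth)
#' are undefined and reported as `NA`.
#'
#' @param predicted,truth binary masks of identical shape.
#' @return object of class `segmentation_score`: list with `dice`,
#'   `sensitivity`, `specificity`.
#' @export
score_segmentation <- function(predicted, truth) {
  p <- as_binary_mask(predicted, "predicted")
  t <- as_binary_mask(truth, "truth")
  check_same_shape(p, t, "predicted and truth masks")
  inter <- sum(p * t)
  np <- sum(p); nt <- sum(t); n <- length(p)
  dice <- if (np + nt == 0) 1 else 2 * inter / (np + nt)
  sens <- if (nt == 0) NA_real_ else inter / nt
  spec <- if (n - nt == 0) NA_real_ else sum((1 - p) * (1 - t)) / (n - nt)
  structure(list(dice = dice, sensitivity = sens, specificity = spec),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("dice %.3f  sensitivity %.3f  specificity %.3f\n",
              x$dice, x$sensitivity, x$specificity))
  invisible(x)
}

#' Pluggable bone segmenter interface
#'
#' `segment_bones()` dispatches on a segmenter object and must return a
#' valid [bone_mask_set()] matching the input image shape. Two
#' implementations ship with the package: [file_segmenter()] loads
#' previously written masks from a manifest (e.g. manual annotations or an
#' external network's output), and [tophat_segmenter()] is a classical
#' morphological detector for noiseless synthetic phantoms: a white top-hat
#' on the attenuation image removes the smooth torso background so bone
#' plateaus can be thresholded, and connected components become individual
#' masks. Deep-learning segmenters can be plugged in by providing a class
#' with a `segment_bones` method; implementation failures are surfaced
#' uniformly as segmentation errors.
#'
#' @param segmenter a segmenter object.
#' @param image single-channel floating-point attenuation image.
#' @param ... implementation-specific arguments.
#' @return a `bone_mask_set`.
#' @export
segment_bones <- function(segmenter, image, ...) UseMethod("segment_bones")

#' @export
segment_bones.default <- function(segmenter, image, ...) {
  df_stop("segmentation_failure", "no segment_bones method for class '%s'",
          paste(class(segmenter), collapse = "/"))
}

#' @rdname segment_bones
#' @param manifest path to a JSON mask manifest (see [write_mask_manifest()]).
#' @export
file_segmenter <- function(manifest) {
  structure(list(manifest = manifest), class = "file_segmenter")
}

#' @export
segment_bones.file_segmenter <- function(segmenter, image, ...) {
  masks <- tryCatch(read_mask_manifest(segmenter$manifest),
                    error = function(e) df_stop("segmentation_failure",
                                                "mask manifest could not be read: %s",
                                                conditionMessage(e)))
  if (!is.null(image) && !is.null(masks$shape) && !identical(dim(image), masks$shape))
    df_stop("segmentation_failure", "manifest masks do not match the image shape")
  masks
}

#' @rdname segment_bones
#' @param line_length vertical extent (pixels) of the opening's structuring
#'   element; must exceed the projected bone band height but stay below the
#'   band-to-band separation — on a densely interleaved rib cage (bands
#'   closer than the band height) no single element satisfies both and a
#'   learned segmenter is required instead.
#' @param rel_threshold bone decision threshold on the top-hat response
#'   relative to the local attenuation (a bone of aluminum contribution
#'   fraction f adds a relative attenuation contrast of about f/(1-f)).
#' @export
tophat_segmenter <- function(line_length = 21, rel_threshold = 0.05) {
  structure(list(line_length = line_length, rel_threshold = rel_threshold),
            class = "tophat_segmenter")
}

#' @export
segment_bones.tophat_segmenter <- function(segmenter, image, ...) {
  check_image(image)
  mx <- max(image)
  if (mx <= 0) df_stop("segmentation_failure", "attenuation image has no signal")
  # grayscale morphology operates on [0, 1]: normalize, open with a vertical
  # line (ribs project as near-horizontal bands), rescale the top-hat
  vk <- matrix(1, segmenter$line_length, 1)
  u <- image / mx
  opened <- EBImage::dilate(EBImage::erode(u, vk), vk)
  th <- (u - opened) * mx
  # the body outline itself is a huge top-hat response; only the interior counts
  body <- (image > 0.02 * mx) * 1
  interior <- EBImage::erode(body, EBImage::makeBrush(11, "disc"))
  bone <- (th / pmax(image, 0.05 * mx) > segmenter$rel_threshold) * interior
  if (sum(bone) == 0)
    return(bone_mask_set(list(), clavicle_mask = bone, lung_mask = NULL))
  lab <- EBImage::bwlabel(bone)
  ids <- sort(unique(as.vector(lab))); ids <- ids[ids > 0]
  comps <- lapply(ids, function(i) (lab == i) * 1)
  # order components superior-to-inferior by centroid row
  cr <- vapply(comps, function(m) mean(row(m)[m == 1]), numeric(1))
  comps <- comps[order(cr)]
  names(comps) <- sprintf("C%02d", seq_along(comps))
  bone_mask_set(comps, clavicle_mask = image * 0, lung_mask = NULL)
}
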