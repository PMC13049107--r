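# Attenuation-contribution maps: rasterized regional aluminum weights,
# Sobel edge incorporation, Gaussian smoothing, and the water complement.

#' Regional aluminum weight configuration
#'
#' Aluminum attenuation-contribution fractions assigned to bone regions and
#' the background, as measured from decomposed spectral CT maps of one male
#' and one female patient. Unspecified fields take the sex defaults:
#' male 0.15/0.1/0.2/0.05/0.05 and female 0.1/0.05/0.2/0.05/0.05 for
#' posterior ribs / anterior ribs / clavicle / bone edge / background.
#'
#' @param sex `"male"` or `"female"`.
#' @param posterior,anterior,clavicle,edge,background fractions in \[0, 1\].
#' @return object of class `weight_config`.
#' @export
weight_config <- function(sex = c("male", "female"), posterior = NULL,
                          anterior = NULL, clavicle = NULL, edge = NULL,
                          background = NULL) {
  sex <- match.arg(sex)
  def <- if (sex == "male")
    list(posterior = 0.15, anterior = 0.10, clavicle = 0.20, edge = 0.05, background = 0.05)
  else
    list(posterior = 0.10, anterior = 0.05, clavicle = 0.20, edge = 0.05, background = 0.05)
  w <- list(sex = sex,
            posterior = posterior %||% def$posterior,
            anterior = anterior %||% def$anterior,
            clavicle = clavicle %||% def$clavicle,
            edge = edge %||% def$edge,
            background = background %||% def$background)
  for (f in c("posterior", "anterior", "clavicle", "edge", "background"))
    if (w[[f]] < 0 || w[[f]] > 1)
      df_stop("validation", "weight '%s' must be in [0, 1]", f)
  structure(w, class = "weight_config")
}

#' Rasterize regional weights onto the pixel grid
#'
#' Paints the configured aluminum fraction onto each labeled region
#' (posterior rib, anterior rib, clavicle); every remaining pixel receives
#' the background weight. Overlapping regions resolve to the maximum weight.
#'
#' @param labeled_ribs list of `labeled_rib` objects (see
#'   [split_anterior_posterior()]).
#' @param clavicle_mask binary mask or `NULL`.
#' @param config a [weight_config()].
#' @param shape image dimensions `c(rows, cols)` (required if no masks given).
#' @return raw aluminum weight image (matrix in \[0, 1\]).
#' @export
rasterize_weights <- function(labeled_ribs, clavicle_mask, config, shape = NULL) {
  if (is.null(shape)) {
    if (length(labeled_ribs)) shape <- dim(labeled_ribs[[1]]$posterior)
    else if (!is.null(clavicle_mask)) shape <- dim(clavicle_mask)
    else df_stop("validation", "shape required when no masks are supplied")
  }
  w <- matrix(config$background, shape[1], shape[2])
  for (lr in labeled_ribs) {
    check_same_shape(w, lr$posterior, "weight image and rib masks")
    w <- pmax(w, lr$posterior * config$posterior)
    w <- pmax(w, lr$anterior * config$anterior)
  }
  if (!is.null(clavicle_mask)) {
    cm <- as_binary_mask(clavicle_mask, "clavicle mask")
    check_same_shape(w, cm, "weight image and clavicle mask")
    w <- pmax(w, cm * config$clavicle)
  }
  w
}

# Sobel gradient magnitude > 0 marks the edge band of a binary mask.
sobel_edges <- function(mask) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(mask, kx, boundary = "replicate")
  gy <- EBImage::filter2(mask, t(kx), boundary = "replicate")
  (sqrt(gx^2 + gy^2) > 1e-6) * 1
}

#' Incorporate dilated bone-edge bands into a weight map
#'
#' Spectral CT shows increased attenuation contribution at cortical bone
#' edges. Edges are extracted from each binary bone mask with a Sobel
#' filter, dilated, and composed into the map. Composition is by maximum
#' (default), which leaves interior regional weights untouched; `"add-clip"`
#' adds the edge weight and clips to 1.
#'
#' @param map raw weight image in \[0, 1\].
#' @param bone_masks list of binary masks (ribs and clavicle).
#' @param edge_weight fraction in \[0, 1\] (default 0.05).
#' @param dilation_radius pixels (default 2).
#' @param mode `"max"` or `"add-clip"`.
#' @return edge-enhanced weight image.
#' @export
add_bone_edges <- function(map, bone_masks, edge_weight = 0.05,
                           dilation_radius = 2, mode = c("max", "add-clip")) {
  mode <- match.arg(mode)
  check_image(map)
  if (edge_weight < 0 || edge_weight > 1)
    df_stop("validation", "edge_weight must be in [0, 1]")
  if (length(bone_masks) == 0) return(map)
  edge <- matrix(0, nrow(map), ncol(map))
  for (m in bone_masks) {
    bm <- as_binary_mask(m, "bone mask")
    check_same_shape(map, bm, "weight map and bone mask")
    edge <- pmax(edge, sobel_edges(bm))
  }
  if (dilation_radius > 0)
    edge <- EBImage::dilate(edge, EBImage::makeBrush(2 * dilation_radius + 1, "disc"))
  if (mode == "max") pmax(map, edge * edge_weight)
  else pmin(1, map + edge * edge_weight)
}

gaussian_kernel <- function(sigma, truncate = 3) {
  r <- ceiling(truncate * sigma)
  g <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- outer(g, g)
  k / sum(k)
}

#' Gaussian smoothing of a weight map
#'
#' Convolution with a normalized Gaussian kernel (default sigma 2.2 px,
#' truncated at 3 sigma; replicated borders), ensuring gradual spatial
#' transitions in the correction instead of sharp mask discontinuities.
#' Being a convex combination it creates no new extrema.
#'
#' @param map weight image in \[0, 1\].
#' @param sigma kernel width in pixels (> 0).
#' @param truncate kernel support radius in units of sigma.
#' @return smoothed image, same shape.
#' @export
smooth_map <- function(map, sigma = 2.2, truncate = 3) {
  check_image(map)
  if (sigma <= 0) df_stop("validation", "sigma must be > 0")
  EBImage::filter2(map, gaussian_kernel(sigma, truncate), boundary = "replicate")
}

#' Water complement of an aluminum weight image
#'
#' @param omega_al aluminum weight image in \[0, 1\].
#' @return object of class `contribution_map`: list with `omega_al` and
#'   `omega_water = 1 - omega_al` (exact per pixel).
#' @export
complement_map <- function(omega_al) {
  check_image(omega_al)
  if (any(omega_al < 0) || any(omega_al > 1))
    df_stop("validation", "omega_al must lie in [0, 1]")
  structure(list(omega_al = omega_al, omega_water = 1 - omega_al),
            class = "contribution_map")
}

#' Full contribution-map pipeline
#'
#' Composes the four stages: anterior/posterior splitting of each rib mask,
#' weight rasterization, bone-edge incorporation, Gaussian smoothing, and
#' the water complement (taken after smoothing so the complement identity
#' holds exactly on the output).
#'
#' @param masks a [bone_mask_set()] (lung mask required unless pre-labeled
#'   ribs are supplied).
#' @param config a [weight_config()].
#' @param labeled_ribs optional list of pre-labeled ribs (`labeled_rib`),
#'   bypassing the split (e.g. phantom ground-truth labels).
#' @param edge_weight,dilation_radius,edge_mode see [add_bone_edges()].
#' @param sigma,truncate see [smooth_map()]; `sigma = 0` skips smoothing.
#' @param exclude_caudal drop ribs numbered above 10 first (default TRUE).
#' @return a `contribution_map`.
#' @export
make_contribution_map <- function(masks, config = weight_config(),
                                  labeled_ribs = NULL,
                                  edge_weight = config$edge, dilation_radius = 2,
                                  edge_mode = "max", sigma = 2.2, truncate = 3,
                                  exclude_caudal = TRUE) {
  if (!inherits(masks, "bone_mask_set")) df_stop("validation", "masks must be a bone_mask_set")
  if (exclude_caudal) masks <- exclude_caudal_ribs(masks)
  if (is.null(labeled_ribs)) {
    if (length(masks$rib_masks) && is.null(masks$lung_mask))
      df_stop("validation", "lung mask required to split ribs (or supply labeled_ribs)")
    labeled_ribs <- lapply(masks$rib_masks, split_anterior_posterior,
                           lung_mask = masks$lung_mask)
  }
  shape <- masks$shape %||% dim(labeled_ribs[[1]]$posterior)
  raw <- rasterize_weights(labeled_ribs, masks$clavicle_mask, config, shape)
  bone <- c(masks$rib_masks, if (!is.null(masks$clavicle_mask)) list(masks$clavicle_mask))
  raw <- add_bone_edges(raw, bone, edge_weight, dilation_radius, edge_mode)
  sm <- if (sigma > 0) smooth_map(raw, sigma, truncate) else raw
  sm <- pmin(pmax(sm, 0), 1)  # guard fp round-off at the range ends
  out <- complement_map(sm)
  attr(out, "raw_omega_al") <- raw
  out
}
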