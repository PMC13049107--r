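# Synthetic 2D thorax phantom: water/aluminum thickness maps with labeled
# rib, clavicle and lung masks plus a ground-truth dark-field map, and the
# spectral forward projector producing registered radiograph pairs.

#' Generate a synthetic thorax phantom
#'
#' Builds an elliptical water torso with two lung ellipses (reduced water
#' path, positive true dark-field), per-side rib cages of 8--10 ribs, each a
#' "V" of a near-horizontal posterior band and an oblique anterior band
#' meeting at the lateral lung boundary, and clavicles above the apices.
#' Aluminum-equivalent thicknesses are chosen so that the *true* aluminum
#' attenuation-contribution fraction of each region (at the reference
#' energy) equals the configured regional weight — posterior/anterior ribs
#' and clavicle per the weight configuration, and a uniform soft-tissue
#' background fraction mirroring the contribution measured between ribs in
#' decomposed spectral CT. The generator is fully deterministic per seed;
#' the seed drives the rib count, band slopes and row jitter.
#'
#' @param shape image dimensions `c(rows, cols)`, at least 128 each.
#' @param seed integer seed (reproducibility).
#' @param sex `"male"` or `"female"` (selects default regional weights).
#' @param weights a [weight_config()]; defaults to the sex defaults.
#' @param torso_thickness_cm peak water-equivalent torso thickness.
#' @param lung_water_reduction maximal fractional water-path reduction at
#'   the lung center.
#' @param d_true true (microstructural) lung dark-field level
#'   (dimensionless; constant over the lung mask, zero outside).
#' @param al_background_fraction aluminum contribution fraction of plain
#'   soft tissue (0 disables, giving pure water outside bones).
#' @param n_rib_pairs number of rib pairs per side, or `NULL` to sample
#'   8--10 from the seed.
#' @param rib_halfwidth_px half-width of rib bands in pixels.
#' @param include_clavicles logical.
#' @param al_scale global multiplier on all aluminum thicknesses
#'   (0 gives a bone-free, aluminum-free phantom).
#' @param reference_energy keV at which contribution fractions are defined;
#'   default the mean energy of the default 70 kVp / 2.5 mm Al spectrum.
#' @param pixel_size_mm metadata only.
#' @return object of class `thorax_phantom`: list with `t_water`, `t_al`
#'   (cm), `lung_mask`, `bone_masks` (a [bone_mask_set()]), `labeled_ribs`
#'   (ground-truth posterior/anterior labels), `region_masks` (posterior,
#'   anterior, clavicle, edge, background), `d_true` map, `sex`, `seed`,
#'   `weights`, `reference_energy`.
#' @export
generate_phantom <- function(shape = c(256, 256), seed = 1,
                             sex = c("male", "female"),
                             weights = NULL,
                             torso_thickness_cm = 22,
                             lung_water_reduction = 0.65,
                             d_true = 0.6,
                             al_background_fraction = 0.05,
                             n_rib_pairs = NULL,
                             rib_halfwidth_px = 4,
                             include_clavicles = TRUE,
                             al_scale = 1,
                             reference_energy = NULL,
                             pixel_size_mm = 0.4) {
  sex <- match.arg(sex)
  if (any(shape < 128)) df_stop("validation", "phantom shape must be at least 128x128")
  if (d_true < 0 || lung_water_reduction < 0 || lung_water_reduction >= 1 ||
      al_background_fraction < 0 || al_background_fraction >= 1 || al_scale < 0)
    df_stop("validation", "inconsistent phantom parameters")
  weights <- weights %||% weight_config(sex)
  if (is.null(reference_energy))
    reference_energy <- mean_energy(sample_tube_spectrum(70, 2.5, energy_grid()))
  mu_ratio <- material_mu("water", reference_energy)$mu /
    material_mu("aluminum", reference_energy)$mu
  # t_al giving aluminum contribution fraction f at local water path tw
  al_for_fraction <- function(f, tw) if (f <= 0) 0 * tw else f / (1 - f) * mu_ratio * tw

  rng <- local({ set.seed(seed); list(
    n_ribs = if (is.null(n_rib_pairs)) sample(8:10, 1) else n_rib_pairs,
    slope_p = 0.18 * stats::runif(1, 0.9, 1.1),
    slope_a = 0.45 * stats::runif(1, 0.9, 1.1),
    jitter = stats::runif(24, -1.5, 1.5)
  )})

  n1 <- shape[1]; n2 <- shape[2]
  rr <- row(matrix(0, n1, n2)); cc <- col(matrix(0, n1, n2))
  r0 <- 0.54 * n1; c0 <- (n2 + 1) / 2
  A <- 0.44 * n2; B <- 0.50 * n1
  e_t <- ((cc - c0) / A)^2 + ((rr - r0) / B)^2
  torso <- e_t < 1
  t_w <- torso_thickness_cm * sqrt(pmax(0, 1 - e_t))

  # lungs
  al_ <- 0.16 * n2; bl_ <- 0.28 * n1; rl <- 0.42 * n1
  lung_mask <- matrix(0, n1, n2)
  lung_factor <- matrix(0, n1, n2)
  lung_centers <- c0 + c(-1, 1) * 0.215 * n2
  for (cl in lung_centers) {
    e_l <- ((cc - cl) / al_)^2 + ((rr - rl) / bl_)^2
    inside <- e_l < 1
    lung_mask[inside] <- 1
    lung_factor[inside] <- pmax(lung_factor[inside], sqrt(pmax(0, 1 - e_l[inside])))
  }
  t_w <- t_w * (1 - lung_water_reduction * lung_factor)

  # ribs: V-shaped bands with vertex on the lateral lung boundary
  rib_masks <- list(); labeled <- list()
  jit_i <- 1
  for (side in 1:2) {
    cl <- lung_centers[side]; s <- if (side == 1) -1 else 1  # lateral direction
    for (i in seq_len(rng$n_ribs)) {
      frac <- if (rng$n_ribs > 1) (i - 1) / (rng$n_ribs - 1) else 0.5
      r_turn <- rl + bl_ * (-0.80 + 1.62 * frac) + rng$jitter[((jit_i - 1) %% 24) + 1]
      jit_i <- jit_i + 1
      dx <- al_ * sqrt(pmax(0, 1 - ((r_turn - rl) / bl_)^2))
      c_turn <- cl + s * dx
      u_max_p <- dx + 0.75 * al_   # posterior reaches past the medial lung edge
      u_max_a <- 0.75 * u_max_p
      u <- s * (c_turn - cc)       # medial distance from the vertex, in columns
      w <- rib_halfwidth_px
      post_band <- (u >= 0 & u <= u_max_p &
                      abs(rr - (r_turn - rng$slope_p * u)) <= w)
      ant_band <- (u >= 0 & u <= u_max_a &
                     abs(rr - (r_turn + rng$slope_a * u)) <= w)
      rib <- ((post_band | ant_band) & torso) * 1
      if (sum(rib) == 0) next
      post_gt <- rib * (rr < r_turn)
      nm <- sprintf("%s%02d", if (side == 1) "L" else "R", i)
      rib_masks[[nm]] <- rib
      labeled[[nm]] <- structure(list(posterior = post_gt, anterior = rib - post_gt),
                                 class = "labeled_rib")
    }
  }

  clav <- matrix(0, n1, n2)
  if (include_clavicles) {
    rcl <- rl - bl_ - 0.05 * n1
    for (side in 1:2) {
      cl <- lung_centers[side]
      band <- (abs(cc - cl) <= 0.8 * al_) &
        (abs(rr - (rcl - 0.10 * abs(cc - cl))) <= rib_halfwidth_px) & torso
      clav[band] <- 1
    }
  }

  # aluminum thicknesses from regional contribution fractions
  t_al <- matrix(0, n1, n2)
  for (nm in names(labeled)) {
    lr <- labeled[[nm]]
    t_al <- pmax(t_al, lr$posterior * al_for_fraction(weights$posterior, t_w))
    t_al <- pmax(t_al, lr$anterior * al_for_fraction(weights$anterior, t_w))
  }
  t_al <- pmax(t_al, clav * al_for_fraction(weights$clavicle, t_w))
  if (al_background_fraction > 0)
    t_al <- pmax(t_al, torso * al_for_fraction(al_background_fraction, t_w))
  t_al <- t_al * al_scale

  bone <- Reduce(pmax, rib_masks, clav)
  edge_band <- if (sum(bone) > 0) {
    eb <- EBImage::dilate(sobel_edges(bone), EBImage::makeBrush(5, "disc"))
    eb * (1 - bone)
  } else matrix(0, n1, n2)
  # exclusive ground-truth regions, precedence by descending aluminum weight
  # (overlap pixels carry the larger fraction via pmax above)
  post_all <- Reduce(pmax, lapply(labeled, `[[`, "posterior"), matrix(0, n1, n2))
  ant_all <- Reduce(pmax, lapply(labeled, `[[`, "anterior"), matrix(0, n1, n2))
  post_all <- post_all * (1 - clav)
  ant_all <- ant_all * (1 - clav) * (1 - post_all)
  background <- torso * (1 - pmax(bone, edge_band)) * 1

  structure(list(
    t_water = t_w, t_al = t_al, lung_mask = lung_mask,
    bone_masks = bone_mask_set(rib_masks, clavicle_mask = clav, lung_mask = lung_mask),
    labeled_ribs = labeled,
    region_masks = list(posterior = post_all, anterior = ant_all, clavicle = clav,
                        edge = edge_band, background = background),
    d_true = lung_mask * d_true,
    sex = sex, seed = seed, weights = weights,
    reference_energy = reference_energy, pixel_size_mm = pixel_size_mm
  ), class = "thorax_phantom")
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat(sprintf("thorax phantom %dx%d (seed %d, %s): %d ribs, lung %d px, d_true max %.3g\n",
              nrow(x$t_water), ncol(x$t_water), x$seed, x$sex,
              length(x$bone_masks$rib_masks), sum(x$lung_mask), max(x$d_true)))
  invisible(x)
}

#' Additive Gaussian noise model for simulated radiograph pairs
#'
#' @param ap_sigma,dp_sigma standard deviations of additive Gaussian noise
#'   on the attenuation and dark-field images (>= 0).
#' @param seed integer seed for reproducible noise.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(ap_sigma = 0, dp_sigma = 0, seed = 1) {
  if (ap_sigma < 0 || dp_sigma < 0) df_stop("validation", "noise sigmas must be >= 0")
  structure(list(ap_sigma = ap_sigma, dp_sigma = dp_sigma, seed = seed),
            class = "noise_model")
}

#' Spectrally project a phantom into a radiograph pair
#'
#' Per pixel, the polychromatic attenuation Ap and the beam-hardening
#' induced dark-field DpBH follow from the water/aluminum thickness maps;
#' the measured dark-field is `Dp = DpBH + d_true` (the true microstructural
#' signal composes multiplicatively with the hardened visibility, hence
#' additively in the log domain). The noiseless projection is deterministic;
#' noise is reproducible from the noise model's seed.
#'
#' @param phantom a [generate_phantom()] result.
#' @param setup a [setup_config()].
#' @param noise a [noise_model()] or `NULL`.
#' @return a [radiograph_pair()]; the beam-hardening map is attached as
#'   attribute `"dpbh"`.
#' @export
forward_project <- function(phantom, setup = setup_config(), noise = NULL) {
  comp <- setup_components(setup)
  sig <- poly_signals(as.vector(phantom$t_water), as.vector(phantom$t_al),
                      comp$spectrum, comp$v0, comp$mu_w, comp$mu_al)
  shp <- dim(phantom$t_water)
  ap <- matrix(sig$ap, shp[1], shp[2])
  dpbh <- matrix(sig$dpbh, shp[1], shp[2])
  dp <- dpbh + phantom$d_true
  if (!is.null(noise)) {
    set.seed(noise$seed)
    if (noise$ap_sigma > 0) ap <- pmax(ap + stats::rnorm(length(ap), 0, noise$ap_sigma), 0)
    if (noise$dp_sigma > 0) dp <- dp + stats::rnorm(length(dp), 0, noise$dp_sigma)
  }
  pair <- radiograph_pair(ap, dp, pixel_size_mm = phantom$pixel_size_mm)
  attr(pair, "dpbh") <- dpbh
  pair
}
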