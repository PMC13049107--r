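# Two-material (water/aluminum) decomposition of a mono-energetic image pair
# and region-wise attenuation-contribution profiling.

#' Pair of mono-energetic attenuation images
#'
#' Holds two co-registered linear-attenuation maps (per-pixel line integrals,
#' dimensionless, or per-cm values — the decomposition is linear either way)
#' reconstructed at two distinct energies, e.g. virtual mono-energetic images
#' at 50 and 200 keV from a spectral CT.
#'
#' @param low_image,high_image numeric matrices of identical shape.
#' @param e_low,e_high energies in keV, `e_low < e_high`.
#' @return object of class `vmi_pair`.
#' @export
vmi_pair <- function(low_image, high_image, e_low = 50, e_high = 200) {
  check_image(low_image); check_image(high_image)
  check_same_shape(low_image, high_image, "mono-energetic images")
  if (!(e_low < e_high)) df_stop("validation", "e_low must be < e_high")
  structure(list(low = low_image, high = high_image,
                 e_low = e_low, e_high = e_high), class = "vmi_pair")
}

#' Two-material basis decomposition
#'
#' Solves, per pixel, the 2x2 linear system expressing the measured
#' attenuation at the two energies as a water/aluminum mixture:
#' `A(E) = mu_w(E) t_w + mu_al(E) t_al`. Negative thicknesses (noise) are
#' clipped to zero by default, with the clipped count recorded.
#'
#' @param pair a [vmi_pair()].
#' @param mu_w,mu_al `df_mu` tables evaluated at `c(e_low, e_high)`;
#'   defaults use the embedded reference tables.
#' @param negativity `"clip"` (default) or `"keep"`.
#' @return object of class `thickness_maps`: list with `t_water`, `t_al`
#'   (cm, matrices) and `n_clipped`.
#' @export
decompose_two_materials <- function(pair,
                                    mu_w = material_mu("water", c(pair$e_low, pair$e_high)),
                                    mu_al = material_mu("aluminum", c(pair$e_low, pair$e_high)),
                                    negativity = c("clip", "keep")) {
  negativity <- match.arg(negativity)
  B <- matrix(c(mu_w$mu[1], mu_w$mu[2], mu_al$mu[1], mu_al$mu[2]), 2, 2)
  if (abs(det(B)) < 1e-10 * prod(sqrt(colSums(B^2))))
    df_stop("decomposition_conditioning",
            "basis matrix is (near-)singular; energies too close")
  Binv <- solve(B)
  tw <- Binv[1, 1] * pair$low + Binv[1, 2] * pair$high
  ta <- Binv[2, 1] * pair$low + Binv[2, 2] * pair$high
  n_clipped <- 0L
  if (negativity == "clip") {
    n_clipped <- sum(tw < 0) + sum(ta < 0)
    if (n_clipped > 0)
      message(sprintf("decompose_two_materials: clipped %d negative thickness value(s)",
                      n_clipped))
    tw <- pmax(tw, 0); ta <- pmax(ta, 0)
  }
  structure(list(t_water = tw, t_al = ta, n_clipped = n_clipped),
            class = "thickness_maps")
}

#' Aluminum attenuation-contribution fraction
#'
#' Per pixel, the fraction of total linear attenuation at a reference energy
#' carried by the aluminum component:
#' `mu_al t_al / (mu_w t_w + mu_al t_al)`; zero where total attenuation is
#' zero. The reference energy defaults to the mean energy of the default
#' effective spectrum, since contributions are (mildly) energy dependent.
#'
#' @param maps a `thickness_maps` (non-negative).
#' @param reference_energy keV.
#' @return matrix in \[0, 1\].
#' @export
contribution_fraction <- function(maps, reference_energy = NULL) {
  if (any(maps$t_water < 0) || any(maps$t_al < 0))
    df_stop("domain", "thickness maps must be non-negative (use negativity = 'clip')")
  if (is.null(reference_energy))
    reference_energy <- mean_energy(sample_tube_spectrum(70, 2.5, energy_grid()))
  mw <- material_mu("water", reference_energy)$mu
  ma <- material_mu("aluminum", reference_energy)$mu
  num <- ma * maps$t_al
  den <- mw * maps$t_water + num
  out <- ifelse(den > 0, num / den, 0)
  if (is.matrix(maps$t_al)) matrix(out, nrow(maps$t_al), ncol(maps$t_al)) else out
}

#' Region-wise mean contribution profile
#'
#' Means of a contribution image over named binary region masks (posterior
#' ribs, anterior ribs, clavicle, edge band, background, ...). Empty regions
#' are reported as absent (`NA`), not zero.
#'
#' @param contribution contribution image in \[0, 1\].
#' @param region_masks named list of binary masks, same shape.
#' @param sex optional tag carried through to the profile.
#' @return object of class `contribution_profile`: named numeric vector of
#'   region means (attribute `sex`).
#' @export
profile_regions <- function(contribution, region_masks, sex = NULL) {
  check_image(contribution)
  vals <- vapply(names(region_masks), function(nm) {
    m <- as_binary_mask(region_masks[[nm]], nm)
    check_same_shape(contribution, m, sprintf("contribution image and mask '%s'", nm))
    if (sum(m) == 0) return(NA_real_)
    mean(contribution[m == 1])
  }, numeric(1))
  structure(vals, sex = sex, class = c("contribution_profile", "numeric"))
}
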