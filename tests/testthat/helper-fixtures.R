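# Shared fixtures: cached default setup components, delta spectra, an
# independent brute-force quadrature oracle, and a single-rib slab phantom.

.fixture_cache <- new.env(parent = emptyenv())

default_comp <- function() {
  if (is.null(.fixture_cache$comp))
    .fixture_cache$comp <- dfbhc:::setup_components(setup_config())
  .fixture_cache$comp
}

default_luts <- function() {
  if (is.null(.fixture_cache$luts)) .fixture_cache$luts <- calibrate_luts()
  .fixture_cache$luts
}

# spectrum with all weight in a single bin (monochromatic limit)
delta_spectrum <- function(grid = energy_grid(), bin = 41) {
  w <- rep(0, length(grid))
  w[bin] <- 1
  spectrum(as.numeric(grid), w)
}

# Independent quadrature oracle: trapezoid integration via pracma::trapz,
# coded without the package's integration path.
oracle_poly <- function(t_w, t_al, spec, v0) {
  e <- spec$energies
  mw <- material_mu("water", e)$mu
  ma <- material_mu("aluminum", e)$mu
  s <- spec$weights * exp(-mw * t_w - ma * t_al)
  i0 <- pracma::trapz(e, spec$weights)
  is <- pracma::trapz(e, s)
  vp <- pracma::trapz(e, v0$v0 * s) / is
  vp0 <- pracma::trapz(e, v0$v0 * spec$weights) / i0
  list(ap = -log(is / i0), vp = vp, dpbh = -log(vp / vp0))
}

# Flat water plate with one horizontal rib band; soft tissue carries the
# background aluminum fraction so the default weights are matched.
slab_fixture <- function(n = 128, rib_rows = 60:76, plate_cm = 15,
                         rib_fraction = 0.15, bg_fraction = 0.05,
                         d_true = 0.5) {
  tw <- matrix(plate_cm, n, n)
  rib <- matrix(0, n, n); rib[rib_rows, ] <- 1
  eref <- mean_energy(sample_tube_spectrum(70, 2.5, energy_grid()))
  mur <- material_mu("water", eref)$mu / material_mu("aluminum", eref)$mu
  frac <- rib * rib_fraction + (1 - rib) * bg_fraction
  ta <- ifelse(frac > 0, frac / (1 - frac) * mur * tw, 0)
  comp <- default_comp()
  sig <- dfbhc:::poly_signals(as.vector(tw), as.vector(ta), comp$spectrum, comp$v0)
  list(rib = rib, t_water = tw, t_al = ta,
       ap = matrix(sig$ap, n, n),
       dpbh = matrix(sig$dpbh, n, n),
       dp = matrix(sig$dpbh, n, n) + d_true,
       d_true = d_true)
}

# small phantom for unit tests (thin ribs so the 128 grid stays uncrowded)
small_phantom <- function(seed = 1, ...) {
  generate_phantom(shape = c(128, 128), seed = seed, rib_halfwidth_px = 2, ...)
}
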