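# Polychromatic signal formation: spectra, attenuation, visibility, and the
# beam-hardening-induced dark-field signal.

test_that("tube spectrum respects filtration identity, cutoff, and hardening", {
  grid <- energy_grid()
  e <- as.numeric(grid)
  unfiltered <- sample_tube_spectrum(70, 0, grid)
  # filtration identity: 0 mm Al leaves the bremsstrahlung form untouched
  expect_equal(unfiltered$weights, pmax(0, (70 - e) / e))
  # tube cutoff: no weight at or above kvp
  expect_true(all(unfiltered$weights[e >= 70] == 0))
  filtered <- sample_tube_spectrum(70, 2.5, grid)
  expect_true(all(filtered$weights[e >= 70] == 0))
  # filtration preferentially removes low energies
  i15 <- which(e == 15); i40 <- which(e == 40)
  expect_lt(filtered$weights[i15] / filtered$weights[i40],
            unfiltered$weights[i15] / unfiltered$weights[i40])
  expect_gt(mean_energy(filtered), mean_energy(unfiltered))
  expect_error(sample_tube_spectrum(5, 0, grid), class = "dfbhc_invalid_configuration")
  expect_error(energy_grid(10, 10, 1), class = "dfbhc_invalid_configuration")
})

test_that("embedded attenuation tables decrease over the diagnostic range", {
  for (mat in c("water", "aluminum")) {
    mu <- material_mu(mat, seq(10, 70, 0.5))
    expect_true(all(mu$mu > 0))
    expect_true(all(diff(mu$mu) < 0))
  }
  expect_error(material_mu("water", 5), class = "dfbhc_domain")
})

test_that("polychromatic attenuation matches closed forms and the quadrature oracle", {
  comp <- default_comp()
  expect_equal(transmission_poly(0, 0, comp$spectrum)$ap, 0)
  # monochromatic closed form: Ap = mu_w(E0) * t
  ds <- delta_spectrum(bin = 41)
  e0 <- ds$energies[41]
  expect_equal(transmission_poly(1, 0, ds)$ap, material_mu("water", e0)$mu,
               tolerance = 1e-12)
  # independent trapezoid oracle at 20 cm water
  got <- transmission_poly(20, 0, comp$spectrum)$ap
  expect_equal(got, oracle_poly(20, 0, comp$spectrum, comp$v0)$ap, tolerance = 1e-12)
  expect_error(transmission_poly(-1, 0, comp$spectrum), class = "dfbhc_domain")
  bad_mu <- material_mu("water", seq(10, 69, 0.5))
  expect_error(transmission_poly(1, 0, comp$spectrum, mu_w = bad_mu),
               class = "dfbhc_grid_mismatch")
})

test_that("polychromatic visibility is the spectrum-weighted mean of V0", {
  comp <- default_comp()
  grid <- energy_grid()
  const_v0 <- structure(list(energies = as.numeric(grid), v0 = rep(0.3, length(grid))),
                        class = "df_visibility")
  expect_equal(visibility_poly(comp$spectrum, const_v0), 0.3)
  ds <- delta_spectrum(bin = 17)
  expect_equal(visibility_poly(ds, comp$v0), comp$v0$v0[17])
  set.seed(42)
  for (i in 1:5) {
    w <- runif(length(grid)); v <- runif(length(grid))
    sp <- spectrum(as.numeric(grid), w)
    vv <- structure(list(energies = as.numeric(grid), v0 = v), class = "df_visibility")
    ct <- dfbhc:::trapz_weights(as.numeric(grid))
    expect_equal(visibility_poly(sp, vv), sum(ct * w * v) / sum(ct * w), tolerance = 1e-14)
  }
  zero_trans <- structure(list(energies = as.numeric(grid), weights = rep(0, length(grid))),
                          class = "df_spectrum")
  expect_error(visibility_poly(zero_trans, comp$v0), class = "dfbhc_degenerate_beam")
})

test_that("a monochromatic beam cannot harden: DpBH identically zero", {
  comp <- default_comp()
  ds <- delta_spectrum(bin = 61)
  tsweep <- seq(0, 25, length.out = 50)
  d <- bh_darkfield(tsweep, tsweep / 10, ds, comp$v0)
  expect_true(all(abs(d) < 1e-12))
})

test_that("beam-hardening dark-field is zero at zero thickness, non-negative, monotone, and matches the oracle", {
  comp <- default_comp()
  expect_equal(bh_darkfield(0, 0, comp$spectrum, comp$v0), 0)
  ta <- seq(0, 3, length.out = 50)
  d <- bh_darkfield(rep(0, 50), ta, comp$spectrum, comp$v0)
  expect_true(all(d >= 0))
  expect_true(all(diff(d) >= 0))
  for (i in c(2, 25, 50))
    expect_equal(d[i], oracle_poly(0, ta[i], comp$spectrum, comp$v0)$dpbh,
                 tolerance = 1e-12)
  tw <- seq(0, 30, length.out = 50)
  ap <- dfbhc:::poly_signals(tw, rep(0, 50), comp$spectrum, comp$v0)$ap
  expect_true(all(diff(ap) > 0))
  dw <- bh_darkfield(tw, rep(0, 50), comp$spectrum, comp$v0)
  expect_true(all(diff(dw) >= 0))
})

test_that("attenuation is additive for delta spectra and sub-additive for polychromatic beams", {
  comp <- default_comp()
  ds <- delta_spectrum(bin = 31)
  a1 <- transmission_poly(3, 0, ds)$ap
  a2 <- transmission_poly(5, 0, ds)$ap
  a12 <- transmission_poly(8, 0, ds)$ap
  expect_equal(a12, a1 + a2, tolerance = 1e-12)
  for (t in c(2, 5, 10, 15)) {
    ap1 <- transmission_poly(t, 0, comp$spectrum)$ap
    ap2 <- transmission_poly(2 * t, 0, comp$spectrum)$ap
    expect_lt(ap2, 2 * ap1)
  }
})

test_that("random spectra and visibilities agree with the brute-force oracle", {
  grid <- energy_grid()
  set.seed(7)
  for (i in 1:100) {
    w <- runif(length(grid), 0, 2)
    v <- runif(length(grid), 0.05, 0.9)
    sp <- spectrum(as.numeric(grid), w)
    vv <- structure(list(energies = as.numeric(grid), v0 = v), class = "df_visibility")
    tw <- runif(1, 0, 10); ta <- runif(1, 0, 2)
    got <- dfbhc:::poly_signals(tw, ta, sp, vv)
    want <- oracle_poly(tw, ta, sp, vv)
    expect_equal(got$ap, want$ap, tolerance = 1e-10)
    expect_equal(got$vp, want$vp, tolerance = 1e-10)
    # dpbh of a random (non-monotone) v0 can sit near 0: mixed abs/rel bound
    expect_lt(abs(got$dpbh - want$dpbh), 1e-10 * (1 + abs(want$dpbh)))
  }
})

test_that("true dark-field scales linearly with the scatter line integral", {
  expect_equal(true_darkfield_line(0, 1), 0)
  expect_equal(true_darkfield_line(0.7, 1), 0.7)
  expect_equal(true_darkfield_line(2 * 0.31, setup_config(c_d = 1)),
               2 * true_darkfield_line(0.31, setup_config(c_d = 1)))
  expect_error(true_darkfield_line(-1, 1), class = "dfbhc_domain")
})
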