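# Polychromatic signal formation for a Talbot-Lau interferometer:
# spectra, energy-dependent transmission, fringe visibility, and the
# beam-hardening-induced dark-field signal.

#' Energy grid for polychromatic integrals
#'
#' Strictly increasing energy samples (keV) over the diagnostic range on
#' which all spectral integrals are evaluated by the trapezoid rule.
#'
#' @param e_min,e_max grid span in keV (default 10--70).
#' @param step grid resolution in keV (default 0.5).
#' @return numeric vector of energies with class `energy_grid`.
#' @export
energy_grid <- function(e_min = 10, e_max = 70, step = 0.5) {
  if (!(e_min > 0 && e_max > e_min && step > 0))
    df_stop("invalid_configuration", "energy grid requires 0 < e_min < e_max and step > 0")
  g <- seq(e_min, e_max, by = step)
  check_grid(g)
  structure(g, class = c("energy_grid", "numeric"))
}

check_grid <- function(g) {
  if (length(g) < 16 || any(g <= 0) || any(diff(g) <= 0))
    df_stop("invalid_configuration",
            "energy grid must be strictly increasing, positive, with >= 16 bins")
  invisible(g)
}

same_grid <- function(a, b) {
  if (length(a) != length(b) || any(abs(a - b) > 1e-9))
    df_stop("grid_mismatch", "inputs are defined on different energy grids")
  invisible(TRUE)
}

#' Interferometer and acquisition configuration
#'
#' Bundles the tube/spectral parameters, the reference-visibility model and
#' the dark-field setup constant. Defaults mirror a clinical dark-field chest
#' scanner: 70 kVp tube voltage with 2.5 mm aluminum-equivalent prefiltration
#' and an effective pixel size of 0.4 mm.
#'
#' @param kvp tube voltage in kV (spectrum endpoint).
#' @param prefiltration_mm_al aluminum-equivalent prefiltration in mm.
#' @param energy_min,energy_max,energy_step energy grid parameters in keV.
#' @param v0_model list with `v_max` (peak reference visibility),
#'   `design_energy_kev` (interferometer design energy) and `slope_per_kev`
#'   (exponential visibility decay above the design energy). See
#'   [visibility_spectrum()].
#' @param c_d dimensionless dark-field setup constant linking the scatter
#'   line integral to the dark-field signal (grating geometry factor).
#' @param pixel_size_mm effective detector pixel size in mm (metadata only).
#' @param detector detector response model: `list(type = "flat")` or
#'   `list(type = "table", energies = ..., response = ...)` with a tabulated
#'   relative response folded into the effective source spectrum.
#' @return object of class `df_setup`.
#' @export
setup_config <- function(kvp = 70, prefiltration_mm_al = 2.5,
                         energy_min = 10, energy_max = 70, energy_step = 0.5,
                         v0_model = list(v_max = 0.35, design_energy_kev = 27,
                                         slope_per_kev = 0.02),
                         c_d = 1, pixel_size_mm = 0.4,
                         detector = list(type = "flat")) {
  if (kvp <= 0 || prefiltration_mm_al < 0)
    df_stop("invalid_configuration", "kvp must be > 0 and prefiltration >= 0")
  grid <- energy_grid(energy_min, energy_max, energy_step)
  if (v0_model$design_energy_kev < energy_min || v0_model$design_energy_kev > energy_max)
    df_stop("invalid_configuration", "design energy must lie within the grid span")
  structure(list(kvp = kvp, prefiltration_mm_al = prefiltration_mm_al,
                 grid = grid, v0_model = v0_model, c_d = c_d,
                 pixel_size_mm = pixel_size_mm, detector = detector),
            class = "df_setup")
}

#' @export
print.df_setup <- function(x, ...) {
  cat(sprintf("dark-field setup: %g kVp, %.1f mm Al prefiltration, grid %g-%g keV (%d bins)\n",
              x$kvp, x$prefiltration_mm_al, min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  V0 model: v_max %.2f, design energy %g keV, slope %.3f /keV; c_d %g\n",
              x$v0_model$v_max, x$v0_model$design_energy_kev,
              x$v0_model$slope_per_kev, x$c_d))
  invisible(x)
}

#' Effective tube spectrum
#'
#' Bremsstrahlung model of Kramers form, `(kvp - E)/E` up to the tube
#' voltage, shaped by Beer-Lambert transmission through the aluminum-equivalent
#' prefiltration and (optionally) a tabulated detector response. Characteristic
#' lines are omitted. The result is the effective source intensity S0(E):
#' photon spectrum times detector response, the only combination the
#' downstream signal model uses.
#'
#' @param kvp tube voltage in kV; weights are zero for E >= kvp.
#' @param prefiltration_mm_al aluminum-equivalent filtration in mm.
#' @param grid [energy_grid()] (or any strictly increasing keV vector).
#' @param detector detector response model, see [setup_config()].
#' @return object of class `df_spectrum`: list with `energies` and
#'   non-negative `weights` (arbitrary units).
#' @export
sample_tube_spectrum <- function(kvp, prefiltration_mm_al = 0, grid = energy_grid(),
                                 detector = list(type = "flat")) {
  check_grid(grid)
  if (kvp <= min(grid))
    df_stop("invalid_configuration", "kvp (%g) must exceed the grid minimum (%g)",
            kvp, min(grid))
  e <- as.numeric(grid)
  w <- pmax(0, (kvp - e) / e)
  if (prefiltration_mm_al < 0)
    df_stop("invalid_configuration", "prefiltration must be >= 0")
  if (prefiltration_mm_al > 0) {
    mu_al <- material_mu("aluminum", e)$mu
    w <- w * exp(-mu_al * prefiltration_mm_al / 10)
  }
  w <- w * detector_response(detector, e)
  spectrum(e, w)
}

detector_response <- function(detector, energies) {
  type <- detector$type %||% "flat"
  if (type == "flat") return(rep(1, length(energies)))
  if (type == "table") {
    if (is.null(detector$energies) || is.null(detector$response))
      df_stop("invalid_configuration", "tabulated detector response needs 'energies' and 'response'")
    r <- stats::approx(detector$energies, detector$response, xout = energies, rule = 2)$y
    if (any(r < 0)) df_stop("invalid_configuration", "detector response must be >= 0")
    return(r)
  }
  df_stop("invalid_configuration", "unknown detector response type '%s'", type)
}

#' Construct a spectrum object
#'
#' @param energies strictly increasing keV grid.
#' @param weights non-negative spectral weights with positive total.
#' @return object of class `df_spectrum`.
#' @export
spectrum <- function(energies, weights) {
  check_grid(energies)
  if (length(weights) != length(energies) || any(weights < 0) || sum(weights) <= 0)
    df_stop("validation", "spectrum weights must be >= 0 with positive total")
  structure(list(energies = as.numeric(energies), weights = as.numeric(weights)),
            class = "df_spectrum")
}

#' Mean energy of a spectrum (trapezoid-weighted)
#' @param spec a `df_spectrum`.
#' @export
mean_energy <- function(spec) {
  ct <- trapz_weights(spec$energies)
  sum(ct * spec$weights * spec$energies) / sum(ct * spec$weights)
}

#' Reference visibility spectrum V0(E)
#'
#' Parametric stand-in for the interferometer's reference visibility:
#' constant at `v_max` below the design energy, exponentially decreasing
#' above it, clipped to \[0, 1\]. A monotone non-increasing V0(E) makes the
#' beam-hardening-induced dark-field signal non-negative and monotone in
#' material thickness, matching the positive rib artifact seen clinically.
#'
#' @param grid energy grid (keV).
#' @param v_max peak visibility in (0, 1].
#' @param design_energy_kev design energy below which V0 is flat.
#' @param slope_per_kev exponential decay rate above the design energy.
#' @return object of class `df_visibility`: list with `energies`, `v0`.
#' @export
visibility_spectrum <- function(grid = energy_grid(), v_max = 0.35,
                                design_energy_kev = 27, slope_per_kev = 0.02) {
  check_grid(grid)
  if (v_max <= 0 || v_max > 1)
    df_stop("invalid_configuration", "v_max must be in (0, 1]")
  e <- as.numeric(grid)
  v <- ifelse(e < design_energy_kev, v_max,
              v_max * exp(-(e - design_energy_kev) * slope_per_kev))
  v <- pmin(1, pmax(0, v))
  structure(list(energies = e, v0 = v), class = "df_visibility")
}

#' Polychromatic transmission and attenuation signal
#'
#' Attenuates the effective spectrum by homogeneous water and aluminum slabs
#' and integrates it: the transmitted spectrum is
#' `S(E) = S0(E) exp(-mu_w(E) t_w - mu_al(E) t_al)` and the measured
#' polychromatic attenuation is `Ap = -ln(int S / int S0)` (trapezoid rule).
#'
#' @param t_water,t_al slab thicknesses in cm (scalars, >= 0).
#' @param spec effective source spectrum (`df_spectrum`).
#' @param mu_w,mu_al `df_mu` tables on the same grid; defaults are the
#'   embedded reference tables evaluated on the spectrum grid.
#' @return list with `spectrum` (transmitted `df_spectrum`) and `ap`.
#' @export
transmission_poly <- function(t_water, t_al, spec,
                              mu_w = material_mu("water", spec$energies),
                              mu_al = material_mu("aluminum", spec$energies)) {
  if (t_water < 0 || t_al < 0)
    df_stop("domain", "thicknesses must be >= 0")
  same_grid(spec$energies, mu_w$energies)
  same_grid(spec$energies, mu_al$energies)
  s <- spec$weights * exp(-mu_w$mu * t_water - mu_al$mu * t_al)
  ct <- trapz_weights(spec$energies)
  ap <- -log(sum(ct * s) / sum(ct * spec$weights))
  list(spectrum = spectrum(spec$energies, s), ap = ap)
}

#' Polychromatic fringe visibility
#'
#' Spectrum-weighted mean of the reference visibility over the transmitted
#' spectrum: `Vp = int V0(E) S(E) dE / int S(E) dE`.
#'
#' @param transmitted transmitted spectrum (`df_spectrum`).
#' @param v0 reference visibility (`df_visibility`) on the same grid.
#' @return scalar Vp, bounded by the range of V0.
#' @export
visibility_poly <- function(transmitted, v0) {
  same_grid(transmitted$energies, v0$energies)
  ct <- trapz_weights(transmitted$energies)
  denom <- sum(ct * transmitted$weights)
  if (denom <= 0) df_stop("degenerate_beam", "transmitted spectrum has zero total weight")
  sum(ct * transmitted$weights * v0$v0) / denom
}

# Vectorized core: Ap, Vp and DpBH for thickness vectors (shared by the
# scalar wrappers, the calibration module and the phantom projector).
poly_signals <- function(t_water, t_al, spec, v0,
                         mu_w = material_mu("water", spec$energies),
                         mu_al = material_mu("aluminum", spec$energies)) {
  if (any(t_water < 0) || any(t_al < 0)) df_stop("domain", "thicknesses must be >= 0")
  if (length(t_water) != length(t_al))
    df_stop("validation", "thickness vectors must have equal length")
  same_grid(spec$energies, v0$energies)
  same_grid(spec$energies, mu_w$energies)
  same_grid(spec$energies, mu_al$energies)
  ct <- trapz_weights(spec$energies)
  s0w <- ct * spec$weights
  # attenuation factors: n_pixels x n_energies
  ex <- exp(-outer(t_water, mu_w$mu) - outer(t_al, mu_al$mu))
  i0 <- sum(s0w)
  i_s <- as.vector(ex %*% s0w)
  i_sv <- as.vector(ex %*% (s0w * v0$v0))
  vp0 <- sum(s0w * v0$v0) / i0
  ap <- -log(i_s / i0)
  vp <- i_sv / i_s
  list(ap = ap, vp = vp, vp0 = vp0, dpbh = -log(vp / vp0))
}

#' Beam-hardening-induced dark-field signal
#'
#' The artificial dark-field signal generated by spectral hardening alone:
#' `DpBH = -ln(Vp(t) / Vp(0))`, where Vp is the polychromatic visibility of
#' the hardened spectrum and Vp(0) the reference-scan visibility. For a
#' monochromatic (delta) spectrum this is identically zero; with the default
#' monotone-decreasing V0(E) it is non-negative and non-decreasing in each
#' material thickness.
#'
#' @param t_water,t_al thicknesses in cm (vectors of equal length, >= 0).
#' @param spec effective source spectrum.
#' @param v0 reference visibility spectrum.
#' @param mu_w,mu_al attenuation tables (defaults: embedded reference tables).
#' @return numeric vector of DpBH values.
#' @export
bh_darkfield <- function(t_water, t_al, spec, v0,
                         mu_w = material_mu("water", spec$energies),
                         mu_al = material_mu("aluminum", spec$energies)) {
  poly_signals(t_water, t_al, spec, v0, mu_w, mu_al)$dpbh
}

#' True (microstructural) dark-field signal from a scatter line integral
#'
#' Energy-independent effective model: the dark-field signal is the setup
#' constant times the line integral of the linear diffusion (scatter)
#' coefficient along the beam, `D = c_d * integral(epsilon)`.
#'
#' @param epsilon_line_integral per-pixel scatter line integral (>= 0).
#' @param setup a `df_setup` (uses `c_d`), or a bare numeric `c_d`.
#' @return dark-field signal, same shape as the input.
#' @export
true_darkfield_line <- function(epsilon_line_integral, setup = setup_config()) {
  if (any(epsilon_line_integral < 0))
    df_stop("domain", "scatter line integral must be >= 0")
  c_d <- if (inherits(setup, "df_setup")) setup$c_d else setup
  c_d * epsilon_line_integral
}

# Convenience: grid, spectrum, visibility and mu tables implied by a setup.
setup_components <- function(setup) {
  grid <- setup$grid
  spec <- sample_tube_spectrum(setup$kvp, setup$prefiltration_mm_al, grid,
                               detector = setup$detector)
  v0 <- visibility_spectrum(grid, setup$v0_model$v_max,
                            setup$v0_model$design_energy_kev,
                            setup$v0_model$slope_per_kev)
  list(grid = grid, spectrum = spec, v0 = v0,
       mu_w = material_mu("water", as.numeric(grid)),
       mu_al = material_mu("aluminum", as.numeric(grid)))
}

# Spectrum/visibility export helpers (two-column CSV).
#' Export a spectrum or visibility curve as a two-column CSV
#' @param x a `df_spectrum` or `df_visibility`.
#' @param path output CSV path.
#' @export
write_spectrum_csv <- function(x, path) {
  if (inherits(x, "df_spectrum")) {
    utils::write.csv(data.frame(energy_keV = x$energies, value = x$weights),
                     path, row.names = FALSE)
  } else if (inherits(x, "df_visibility")) {
    utils::write.csv(data.frame(energy_keV = x$energies, value = x$v0),
                     path, row.names = FALSE)
  } else df_stop("validation", "x must be a df_spectrum or df_visibility")
  invisible(path)
}
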