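# Per-material look-up tables mapping measured polychromatic attenuation Ap
# to the beam-hardening-induced dark-field signal DpBH.

#' Simulate a per-material calibration curve
#'
#' Sweeps a homogeneous slab of one material through a thickness grid and
#' records the (Ap, DpBH) pair at each step using the polychromatic forward
#' model — the in-silico analogue of the physical calibration measurements
#' performed with water and aluminum stacks.
#'
#' @param material `"water"` or `"aluminum"`.
#' @param thickness_grid cm; must start at 0 and be strictly increasing.
#'   Defaults: water 0--40 cm step 0.5; aluminum 0--8 cm step 0.1 (spanning
#'   thoracic attenuation at 70 kVp).
#' @param setup a [setup_config()]; or pass `spec`, `v0` explicitly.
#' @param spec,v0 optional explicit spectrum / reference visibility.
#' @return object of class `bhc_calibration`: list with `material`,
#'   `thicknesses`, `ap`, `dpbh`, `setup_hash`.
#' @export
build_calibration_curve <- function(material = c("water", "aluminum"),
                                    thickness_grid = NULL,
                                    setup = setup_config(),
                                    spec = NULL, v0 = NULL) {
  material <- match.arg(material)
  if (is.null(thickness_grid))
    thickness_grid <- if (material == "water") seq(0, 40, 0.5) else seq(0, 8, 0.1)
  if (thickness_grid[1] != 0 || any(diff(thickness_grid) <= 0))
    df_stop("validation", "thickness grid must start at 0 and be strictly increasing")
  if (is.null(spec) || is.null(v0)) {
    comp <- setup_components(setup)
    spec <- spec %||% comp$spectrum
    v0 <- v0 %||% comp$v0
  }
  tw <- if (material == "water") thickness_grid else rep(0, length(thickness_grid))
  ta <- if (material == "aluminum") thickness_grid else rep(0, length(thickness_grid))
  sig <- poly_signals(tw, ta, spec, v0)
  if (any(diff(sig$ap) <= 0))
    df_stop("calibration_failure",
            "calibration produced non-monotone Ap for %s (pathological spectrum)", material)
  structure(list(material = material, thicknesses = thickness_grid,
                 ap = sig$ap, dpbh = sig$dpbh,
                 setup_hash = object_hash(list(spec$weights, v0$v0))),
            class = "bhc_calibration")
}

#' Turn a calibration curve into an evaluable look-up table
#'
#' Knots are interpolated with a monotone shape-preserving piecewise-cubic
#' (Fritsch-Carlson) scheme, so interpolated DpBH values never overshoot the
#' bracketing knots — important in the steep low-Ap region. Outside the
#' calibrated Ap range the table either clamps to the end values (default;
#' out-of-range attenuation such as metal or collimator edges must not
#' produce runaway corrections) or extends linearly with the end slope.
#'
#' @param curve a `bhc_calibration`.
#' @param policy `"clamp"` (default) or `"linear"` extrapolation.
#' @return object of class `bhc_lut` with fields `material`, `ap`, `dpbh`,
#'   `policy`, `setup_hash`.
#' @export
curve_to_lut <- function(curve, policy = c("clamp", "linear")) {
  policy <- match.arg(policy)
  if (!inherits(curve, "bhc_calibration"))
    df_stop("validation", "curve must be a bhc_calibration")
  if (length(curve$ap) < 2)
    df_stop("insufficient_calibration", "need at least 2 calibration knots")
  structure(list(material = curve$material, ap = curve$ap, dpbh = curve$dpbh,
                 policy = policy, setup_hash = curve$setup_hash),
            class = "bhc_lut")
}

#' @export
print.bhc_lut <- function(x, ...) {
  cat(sprintf("BHC LUT (%s): %d knots, Ap in [%.3g, %.3g], policy %s\n",
              x$material, length(x$ap), min(x$ap), max(x$ap), x$policy))
  invisible(x)
}

lut_interpolant <- function(lut) {
  stats::splinefun(lut$ap, lut$dpbh, method = "monoH.FC")
}

#' Evaluate a look-up table on an attenuation image
#'
#' Element-wise monotone interpolation of the calibrated DpBH(Ap) relation.
#' Non-finite pixels are refused with an error listing their coordinates;
#' upstream code is expected to flag or mask them explicitly.
#'
#' @param lut a `bhc_lut`.
#' @param ap_image attenuation image (matrix or numeric vector), finite, >= 0.
#' @return DpBH image with the shape of `ap_image`.
#' @export
lut_eval <- function(lut, ap_image) {
  if (!inherits(lut, "bhc_lut")) df_stop("validation", "lut must be a bhc_lut")
  bad <- which(!is.finite(ap_image))
  if (length(bad)) {
    coords <- if (is.matrix(ap_image)) {
      rc <- arrayInd(utils::head(bad, 10), dim(ap_image))
      paste(sprintf("(%d,%d)", rc[, 1], rc[, 2]), collapse = " ")
    } else paste(utils::head(bad, 10), collapse = " ")
    df_stop("flagged_pixel", "%d non-finite pixel(s) in attenuation image, first at %s",
            length(bad), coords)
  }
  f <- lut_interpolant(lut)
  x <- as.numeric(ap_image)
  lo <- lut$ap[1]; hi <- lut$ap[length(lut$ap)]
  y <- numeric(length(x))
  inside <- x >= lo & x <= hi
  y[inside] <- f(x[inside])
  if (any(!inside)) {
    if (lut$policy == "clamp") {
      y[x < lo] <- lut$dpbh[1]
      y[x > hi] <- lut$dpbh[length(lut$dpbh)]
      df_warn("extrapolation", "%d pixel(s) outside the calibrated Ap range were clamped",
              sum(!inside))
    } else {
      eps <- (hi - lo) * 1e-6
      slo <- (f(lo + eps) - f(lo)) / eps
      shi <- (f(hi) - f(hi - eps)) / eps
      y[x < lo] <- lut$dpbh[1] + slo * (x[x < lo] - lo)
      y[x > hi] <- lut$dpbh[length(lut$dpbh)] + shi * (x[x > hi] - hi)
    }
  }
  if (is.matrix(ap_image)) matrix(y, nrow(ap_image), ncol(ap_image)) else y
}

#' Calibrate the default water and aluminum tables for a setup
#'
#' @param setup a [setup_config()].
#' @param policy extrapolation policy passed to [curve_to_lut()].
#' @return list with elements `water` and `aluminum` (`bhc_lut` objects).
#' @export
calibrate_luts <- function(setup = setup_config(), policy = "clamp") {
  comp <- setup_components(setup)
  list(
    water = curve_to_lut(build_calibration_curve("water", spec = comp$spectrum,
                                                 v0 = comp$v0), policy),
    aluminum = curve_to_lut(build_calibration_curve("aluminum", spec = comp$spectrum,
                                                    v0 = comp$v0), policy)
  )
}

#' Serialize / read a look-up table (CSV knots + JSON sidecar)
#'
#' The knot table goes to `<path>` as CSV (columns `ap`, `dpbh`); material,
#' extrapolation policy and the calibration setup hash go to `<path>.json`.
#'
#' @param lut a `bhc_lut`.
#' @param path CSV path.
#' @export
write_lut <- function(lut, path) {
  utils::write.csv(data.frame(ap = lut$ap, dpbh = lut$dpbh), path, row.names = FALSE)
  jsonlite::write_json(list(material = lut$material, policy = lut$policy,
                            setup_hash = lut$setup_hash),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(material = meta$material, ap = tab$ap, dpbh = tab$dpbh,
                 policy = meta$policy, setup_hash = meta$setup_hash),
            class = "bhc_lut")
}
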