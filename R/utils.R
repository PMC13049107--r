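# Internal helpers: classed conditions, mask/image validation, trapezoid weights.

df_stop <- function(subclass, msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c(paste0("dfbhc_", subclass), "dfbhc_error", "error", "condition")
  ))
}

df_warn <- function(subclass, msg, ...) {
  warning(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c(paste0("dfbhc_", subclass), "dfbhc_warning", "warning", "condition")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_image <- function(img, name = deparse(substitute(img)), allow_nonfinite = FALSE) {
  if (!is.matrix(img) || !is.numeric(img))
    df_stop("validation", "'%s' must be a numeric matrix", name)
  if (!allow_nonfinite && !all(is.finite(img)))
    df_stop("validation", "'%s' contains non-finite values", name)
  invisible(img)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    df_stop("shape_mismatch", "%s have mismatched shapes (%s vs %s)",
            what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

# Coerce a mask to a 0/1 numeric matrix, erroring on anything non-binary.
as_binary_mask <- function(mask, name = "mask") {
  if (is.logical(mask)) {
    m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
    return(m)
  }
  check_image(mask, name)
  if (!all(mask %in% c(0, 1)))
    df_stop("validation", "'%s' must be binary (0/1)", name)
  mask
}

# Trapezoid quadrature weights for a strictly increasing grid: integral(y) = sum(y * w).
trapz_weights <- function(x) {
  n <- length(x)
  d <- diff(x)
  c(d / 2, 0) + c(0, d / 2)
}

# Deterministic md5 of an R object (for provenance / setup hashes).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

# round half away from zero at `digits` decimals (printed-table convention)
round_half_away <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
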