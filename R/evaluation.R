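# Homogeneity and separability statistics: coefficient of variation,
# quartiles / IQR / IQR overlap, an exact Wilcoxon signed-rank test, the
# volume-normalized dark-field sum, and cohort summaries.

#' Coefficient of variation
#'
#' Standard deviation over mean. The population convention (divide the sum
#' of squares by n) is the default; `variance = "sample"` divides by n - 1.
#'
#' @param values non-empty numeric vector with non-zero mean.
#' @param variance `"population"` or `"sample"`.
#' @return scalar CV.
#' @export
coefficient_of_variation <- function(values, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  values <- values[is.finite(values)]
  if (length(values) == 0) df_stop("validation", "no finite values")
  m <- mean(values)
  if (m == 0) df_stop("undefined_cv", "CV undefined: mean is zero")
  v <- if (variance == "population") mean((values - m)^2) else stats::var(values)
  sqrt(v) / m
}

#' Quartiles and interquartile range
#'
#' Quartiles use linear interpolation of the empirical CDF
#' (`stats::quantile` type 7, the common default); the convention is
#' exposed because separability statistics inherit it.
#'
#' @param values numeric vector with at least 4 values.
#' @param type quantile type passed to [stats::quantile()].
#' @return `quartiles()`: named vector `c(q1, q3)`; `iqr()`: `q3 - q1`.
#' @export
quartiles <- function(values, type = 7) {
  values <- values[is.finite(values)]
  if (length(values) < 4) df_stop("validation", "need at least 4 values for quartiles")
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  c(q1 = q[1], q3 = q[2])
}

#' @rdname quartiles
#' @export
iqr <- function(values, type = 7) {
  q <- quartiles(values, type)
  unname(q["q3"] - q["q1"])
}

#' Overlap of two interquartile ranges
#'
#' `max(0, min(Q3A, Q3B) - max(Q1A, Q1B))`: the length of the intersection
#' of the two IQR intervals, a distribution-separability measure (smaller
#' overlap = better separated cohorts). Symmetric in its arguments.
#'
#' @param a_values,b_values numeric samples (>= 4 values each).
#' @param type quantile convention, see [quartiles()].
#' @return scalar overlap length.
#' @export
iqr_overlap <- function(a_values, b_values, type = 7) {
  qa <- quartiles(a_values, type); qb <- quartiles(b_values, type)
  max(0, min(qa["q3"], qb["q3"]) - max(qa["q1"], qb["q1"]))
}

# Exact distribution of the positive-rank sum W+ via the rank generating
# function: product over (1 + x^(2 r_i)) with ranks doubled so midranks
# become integers. Returns P(W+ = k/2) for k = 0..sum(2 r_i).
signed_rank_exact_pmf <- function(ranks2) {
  tot <- sum(ranks2)
  f <- numeric(tot + 1); f[1] <- 1
  for (v in ranks2) {
    g <- f
    idx <- (v + 1):(tot + 1)
    g[idx] <- g[idx] + f[idx - v]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests whether paired differences `post - pre` are symmetric about zero.
#' Zero differences are dropped (the original convention; `zeros = "pratt"`
#' keeps them in the ranking and removes their contribution from the
#' statistic). Midranks are used for ties. The null distribution is exact
#' (computed by a generating-function convolution over the, possibly tied,
#' ranks) for up to 25 informative pairs, and a normal approximation with
#' tie correction and continuity correction above that. The two-sided exact
#' p-value is twice the smaller tail probability, capped at 1.
#'
#' @param pre,post paired numeric vectors, equal length.
#' @param n_min minimal number of informative (non-zero-difference) pairs
#'   required to report a p-value (default 6).
#' @param exact_max largest n for which the exact distribution is used.
#' @param zeros `"drop"` or `"pratt"`.
#' @return object of class `signed_rank_test`: list with `statistic` (W+,
#'   the positive-rank sum), `p_value`, `n` (informative pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(pre, post, n_min = 6, exact_max = 25,
                                 zeros = c("drop", "pratt")) {
  zeros <- match.arg(zeros)
  if (length(pre) != length(post)) df_stop("validation", "pre and post must be paired")
  d <- post - pre
  d <- d[is.finite(d)]
  nz <- d != 0
  if (!any(nz)) df_stop("degenerate_test", "all paired differences are zero")
  if (zeros == "drop") d <- d[nz]
  r <- rank(abs(d))
  if (zeros == "pratt") { w_plus <- sum(r[d > 0]); r <- r[d != 0]; d <- d[d != 0] }
  else w_plus <- sum(r[d > 0])
  n <- length(d)
  if (n < n_min)
    df_stop("validation", "need at least %d informative pairs (have %d)", n_min, n)
  if (n <= exact_max) {
    pmf <- signed_rank_exact_pmf(as.integer(round(2 * r)))
    k <- as.integer(round(2 * w_plus))
    p_le <- sum(pmf[seq_len(k + 1)])
    p_ge <- sum(pmf[(k + 1):length(pmf)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie and continuity correction"
  }
  structure(list(statistic = w_plus, p_value = p, n = n, method = method),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W+ = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n, x$p_value, x$method))
  invisible(x)
}

#' Volume-normalized dark-field sum
#'
#' Sum of the dark-field signal over the lung mask divided by a supplied
#' normalizer (typically an estimate of lung volume, or the mask area).
#' Non-finite pixels inside the mask are excluded.
#'
#' @param darkfield dark-field image.
#' @param lung_mask non-empty binary mask.
#' @param normalizer positive scalar.
#' @return scalar.
#' @export
normalized_df_sum <- function(darkfield, lung_mask, normalizer) {
  m <- as_binary_mask(lung_mask, "lung mask")
  check_image(darkfield, allow_nonfinite = TRUE)
  check_same_shape(darkfield, m, "dark-field image and lung mask")
  if (sum(m) == 0) df_stop("validation", "lung mask is empty")
  if (!is.finite(normalizer) || normalizer <= 0)
    df_stop("validation", "normalizer must be > 0")
  sum(darkfield[m == 1], na.rm = TRUE) / normalizer
}

#' Relative change in percent
#'
#' `100 (after - before) / before`, reported to one decimal with
#' round-half-away-from-zero (printed-table convention).
#'
#' @param before,after scalars, `before != 0`.
#' @param digits decimals to report.
#' @return rounded percent change.
#' @export
relative_change <- function(before, after, digits = 1) {
  if (before == 0) df_stop("validation", "relative change undefined for zero baseline")
  round_half_away(100 * (after - before) / before, digits)
}

#' Cohort summary of paired pre/post metrics
#'
#' For each (group, metric): median and mean of the pre and post values,
#' their relative changes, and the Wilcoxon signed-rank p-value of the
#' paired change. For the designated overlap metric, the IQR overlap of the
#' reference group against every other group is computed from the pre and
#' the post values, with its relative change. Groups with fewer than 4
#' subjects are flagged and their overlap statistics reported absent.
#'
#' @param records data frame with columns `subject_id`, `group`, `metric`,
#'   `pre`, `post`.
#' @param overlap_metric metric name used for pairwise IQR overlaps.
#' @param reference_group group compared against the others (default: first
#'   group in order of appearance).
#' @return object of class `cohort_summary`: list with data frames
#'   `metrics` and `overlaps`.
#' @export
summarize_cohorts <- function(records, overlap_metric = NULL, reference_group = NULL) {
  need <- c("subject_id", "group", "metric", "pre", "post")
  if (!all(need %in% names(records)))
    df_stop("validation", "records must have columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(records$pre)) || any(!is.finite(records$post)))
    df_stop("validation", "pre/post values must be finite")
  groups <- unique(records$group)
  metrics <- unique(records$metric)
  reference_group <- reference_group %||% groups[1]
  overlap_metric <- overlap_metric %||% metrics[1]

  rows <- list()
  for (g in groups) for (m in metrics) {
    sub <- records[records$group == g & records$metric == m, ]
    if (nrow(sub) == 0) next
    p <- tryCatch(wilcoxon_signed_rank(sub$pre, sub$post)$p_value,
                  dfbhc_error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(
      group = g, metric = m, n = nrow(sub),
      median_pre = stats::median(sub$pre), median_post = stats::median(sub$post),
      mean_pre = mean(sub$pre), mean_post = mean(sub$post),
      rel_change_median = relative_change(stats::median(sub$pre), stats::median(sub$post)),
      rel_change_mean = relative_change(mean(sub$pre), mean(sub$post)),
      wilcoxon_p = p, undersized = nrow(sub) < 4)
  }
  met <- do.call(rbind, rows)

  orows <- list()
  ref <- records[records$group == reference_group & records$metric == overlap_metric, ]
  for (g in setdiff(groups, reference_group)) {
    sub <- records[records$group == g & records$metric == overlap_metric, ]
    ok <- nrow(ref) >= 4 && nrow(sub) >= 4
    d_pre <- if (ok) iqr_overlap(ref$pre, sub$pre) else NA_real_
    d_post <- if (ok) iqr_overlap(ref$post, sub$post) else NA_real_
    orows[[length(orows) + 1]] <- data.frame(
      reference = reference_group, group = g, metric = overlap_metric,
      overlap_pre = d_pre, overlap_post = d_post,
      rel_change = if (ok && d_pre != 0) relative_change(d_pre, d_post) else NA_real_,
      undersized = !ok)
  }
  structure(list(metrics = met, overlaps = do.call(rbind, orows)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Per-group metrics:\n"); print(x$metrics)
  if (!is.null(x$overlaps) && nrow(x$overlaps)) {
    cat("\nIQR overlaps vs reference:\n"); print(x$overlaps)
  }
  invisible(x)
}

#' Export a cohort summary as CSV (+ JSON)
#' @param summary a `cohort_summary`.
#' @param path_prefix files `<prefix>_metrics.csv`, `<prefix>_overlaps.csv`
#'   and `<prefix>.json` are written.
#' @export
write_cohort_summary <- function(summary, path_prefix) {
  utils::write.csv(summary$metrics, paste0(path_prefix, "_metrics.csv"), row.names = FALSE)
  if (!is.null(summary$overlaps))
    utils::write.csv(summary$overlaps, paste0(path_prefix, "_overlaps.csv"), row.names = FALSE)
  jsonlite::write_json(summary, paste0(path_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path_prefix)
}
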