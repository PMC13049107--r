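# Homogeneity / separability statistics and cohort summaries.

test_that("coefficient of variation follows the population convention", {
  expect_equal(coefficient_of_variation(rep(3.2, 10)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), 1 / 3)  # sigma=1 (pop), mu=3
  x <- rexp(20) + 0.1
  expect_equal(coefficient_of_variation(5 * x), coefficient_of_variation(x))
  expect_equal(coefficient_of_variation(c(2, 4), variance = "sample"),
               stats::sd(c(2, 4)) / 3)
  expect_error(coefficient_of_variation(c(-1, 1)), class = "dfbhc_undefined_cv")
})

# brute-force type-7 quantile: linear interpolation of the order statistics
oracle_q <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

test_that("quartiles and IQR match the linear-interpolation convention", {
  q <- quartiles(1:8)
  expect_equal(unname(q), c(2.75, 6.25))
  expect_equal(iqr(1:8), 3.5)
  expect_equal(iqr(rep(2, 6)), 0)
  set.seed(14)
  for (i in 1:25) {
    x <- rnorm(sample(4:40, 1))
    expect_equal(unname(quartiles(x)), c(oracle_q(x, 0.25), oracle_q(x, 0.75)))
    expect_equal(iqr(x + 17.3), iqr(x), tolerance = 1e-12)
  }
  expect_error(quartiles(1:3), class = "dfbhc_validation")
})

test_that("IQR overlap: self-overlap, disjoint samples, constructed quartiles, symmetry", {
  x <- rnorm(30)
  expect_equal(iqr_overlap(x, x), iqr(x))
  expect_equal(iqr_overlap(1:10, 101:110), 0)
  # samples engineered to have (Q1,Q3) = (1,5) and (2,7) under type 7
  a <- seq(-1, 7, by = 2)
  b <- seq(-0.5, 9.5, by = 2.5)
  expect_equal(unname(quartiles(a)), c(1, 5))
  expect_equal(unname(quartiles(b)), c(2, 7))
  expect_equal(iqr_overlap(a, b), 3)
  set.seed(15)
  for (i in 1:20) {
    p <- rnorm(12); q <- rnorm(9, 0.5)
    expect_equal(iqr_overlap(p, q), iqr_overlap(q, p))
  }
})

# exhaustive sign-flip null: enumerate all 2^n assignments of |d| signs
oracle_signrank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  list(statistic = w_obs, p = min(1, 2 * min(p_le, p_ge)))
}

test_that("exact signed-rank test matches exhaustive enumeration (with and without ties)", {
  # the worked difference set {1,-2,3,-4,5,6}
  pre <- rep(0, 6); post <- c(1, -2, 3, -4, 5, 6)
  got <- wilcoxon_signed_rank(pre, post)
  want <- oracle_signrank(post)
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$p_value, want$p)
  # a uniform shift is maximal evidence: W+ = 0 and the smallest attainable p
  shifted <- wilcoxon_signed_rank(post, post - 2)
  expect_equal(shifted$statistic, 0)
  expect_equal(shifted$p_value, 2 / 2^6)
  set.seed(16)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    d <- round(rnorm(n, 0.3), sample(c(0, 1), 1))  # rounding induces ties/zeros
    if (all(d == 0)) d[1] <- 1
    got <- tryCatch(wilcoxon_signed_rank(rep(0, n), d), dfbhc_error = function(e) NULL)
    if (is.null(got)) next  # fewer than 6 informative pairs after zero-drop
    want <- oracle_signrank(d)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p)
  }
})

test_that("exact signed-rank p agrees with the reference implementation when untied", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    d <- rnorm(n)
    got <- wilcoxon_signed_rank(rep(0, n), d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate and undersized signed-rank inputs are refused", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), class = "dfbhc_degenerate_test")
  expect_error(wilcoxon_signed_rank(rep(0, 4), rep(1, 4)), class = "dfbhc_validation")
})

test_that("normalized dark-field sum scales as a mask mean", {
  img <- matrix(0.7, 10, 10)
  m <- matrix(0, 10, 10); m[2:5, 2:5] <- 1
  expect_equal(normalized_df_sum(img, m, sum(m)), 0.7)
  expect_equal(normalized_df_sum(img, m, 2 * sum(m)), 0.35)
  ph <- small_phantom(seed = 5)
  expect_equal(normalized_df_sum(ph$d_true, ph$lung_mask, 100),
               sum(ph$d_true[ph$lung_mask == 1]) / 100)
  expect_error(normalized_df_sum(img, m * 0, 1), class = "dfbhc_validation")
  expect_error(normalized_df_sum(img, m, 0), class = "dfbhc_validation")
})

test_that("relative changes reproduce printed-table arithmetic", {
  expect_equal(relative_change(5, 5), 0)
  expect_equal(relative_change(3.76, 3.14), -16.5)
  expect_equal(relative_change(2.48, 2.17), -12.5)
  expect_error(relative_change(0, 1), class = "dfbhc_validation")
})

test_that("cohort summaries aggregate metrics, overlaps, and flag degeneracies", {
  set.seed(18)
  mk <- function(group, n, mu) data.frame(
    subject_id = paste0(group, seq_len(n)), group = group,
    metric = "normalized_signal", pre = rnorm(n, mu, 0.3),
    post = rnorm(n, mu * 0.85, 0.3))
  rec <- rbind(mk("healthy", 12, 3.7), mk("copd", 10, 3.0), mk("covid", 14, 3.5))
  s <- summarize_cohorts(rec, reference_group = "healthy")
  expect_equal(nrow(s$metrics), 3)
  expect_equal(nrow(s$overlaps), 2)
  h <- rec[rec$group == "healthy", ]
  expect_equal(s$metrics$median_pre[s$metrics$group == "healthy"], median(h$pre))
  expect_equal(s$overlaps$overlap_pre[s$overlaps$group == "copd"],
               iqr_overlap(h$pre, rec$pre[rec$group == "copd"]))
  # identical pre/post: zero relative change, degenerate Wilcoxon flagged NA
  rec2 <- rec; rec2$post <- rec2$pre
  s2 <- summarize_cohorts(rec2)
  expect_true(all(s2$metrics$rel_change_median == 0))
  expect_true(all(is.na(s2$metrics$wilcoxon_p)))
  # two identical groups: overlap equals the common IQR
  twin <- mk("a", 10, 3)
  twin2 <- twin; twin2$group <- "b"; twin2$subject_id <- paste0("b", 1:10)
  twin2$pre <- twin$pre; twin2$post <- twin$post
  s3 <- summarize_cohorts(rbind(twin, twin2), reference_group = "a")
  expect_equal(s3$overlaps$overlap_pre, iqr(twin$pre))
  # undersized group flagged, overlap absent
  s4 <- summarize_cohorts(rbind(mk("a", 10, 3), mk("b", 3, 3)), reference_group = "a")
  expect_true(s4$overlaps$undersized)
  expect_true(is.na(s4$overlaps$overlap_pre))
})
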