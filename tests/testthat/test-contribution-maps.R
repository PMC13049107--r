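# Regional weights, edge incorporation, smoothing, and the water complement.

lab_rib <- function(post, ant) structure(list(posterior = post, anterior = ant),
                                         class = "labeled_rib")

test_that("default weight configurations carry the measured regional fractions", {
  m <- weight_config("male")
  expect_equal(c(m$posterior, m$anterior, m$clavicle, m$edge, m$background),
               c(0.15, 0.10, 0.20, 0.05, 0.05))
  f <- weight_config("female")
  expect_equal(c(f$posterior, f$anterior, f$clavicle, f$edge, f$background),
               c(0.10, 0.05, 0.20, 0.05, 0.05))
  expect_error(weight_config("male", posterior = 1.2), class = "dfbhc_validation")
})

test_that("rasterization paints regional weights with max-overlap and background fill", {
  z <- matrix(0, 20, 20)
  post <- z; post[5:8, 5:15] <- 1
  ant <- z; ant[12:14, 5:15] <- 1
  clav <- z; clav[2:3, 8:12] <- 1
  w <- rasterize_weights(list(lab_rib(post, ant)), clav, weight_config("male"))
  expect_equal(w[6, 10], 0.15)   # posterior interior
  expect_equal(w[13, 10], 0.10)  # anterior interior
  expect_equal(w[2, 10], 0.20)   # clavicle
  expect_equal(w[18, 18], 0.05)  # outside all masks: background
  # empty mask set: uniform background
  expect_equal(rasterize_weights(list(), NULL, weight_config("male"), shape = c(6, 6)),
               matrix(0.05, 6, 6))
  # overlap resolves to the maximum
  w2 <- rasterize_weights(list(lab_rib(post, post)), NULL, weight_config("male"))
  expect_equal(w2[6, 10], 0.15)
})

test_that("edge bands compose by maximum and match a brute-force morphology oracle", {
  z <- matrix(0, 24, 24)
  sq <- z; sq[8:15, 8:15] <- 1
  base <- matrix(0.05, 24, 24)
  # equal weight: max composition leaves the map unchanged
  expect_equal(add_bone_edges(base, list(sq), edge_weight = 0.05), base)
  # interior of a painted rib stays at its regional weight
  w <- rasterize_weights(list(lab_rib(sq, z)), NULL, weight_config("male"))
  w2 <- add_bone_edges(w, list(sq), edge_weight = 0.08, dilation_radius = 2)
  expect_equal(w2[11, 11], 0.15)
  # brute-force oracle: Sobel support = pixels whose 3x3 neighborhood is mixed,
  # then chebyshev-disc dilation
  sob <- matrix(0, 24, 24)
  for (i in 2:23) for (j in 2:23) {
    nb <- sq[(i - 1):(i + 1), (j - 1):(j + 1)]
    gx <- sum(nb * matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
    gy <- sum(nb * t(matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)))
    if (abs(gx) + abs(gy) > 0) sob[i, j] <- 1
  }
  got_band <- dfbhc:::sobel_edges(sq)
  expect_equal(got_band, sob)
  # band before dilation: two-pixel perimeter shell (inner ring 28 + outer ring 36)
  expect_equal(sum(sob), 64)
  r <- 2
  dil <- matrix(0, 24, 24)
  for (i in 1:24) for (j in 1:24) {
    if (sob[i, j] == 1) {
      for (di in -r:r) for (dj in -r:r) {
        if (di^2 + dj^2 <= r^2 + 1) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= 24 && jj >= 1 && jj <= 24) dil[ii, jj] <- 1
        }
      }
    }
  }
  w3 <- add_bone_edges(matrix(0, 24, 24), list(sq), edge_weight = 0.05,
                       dilation_radius = 2)
  got_dil <- (w3 > 0) * 1
  # package and oracle dilation discs agree up to the disc-shape convention
  expect_gte(sum(got_dil * dil) / sum(pmax(got_dil, dil)), 0.9)
  expect_true(all(got_dil[sob == 1] == 1))
})

test_that("Gaussian smoothing preserves constants, kernel mass, and step monotonicity", {
  cst <- matrix(0.3, 30, 30)
  expect_equal(smooth_map(cst), cst, tolerance = 1e-12)
  # spike response: center equals the kernel central coefficient
  spike <- matrix(0, 31, 31); spike[16, 16] <- 1
  sm <- smooth_map(spike, sigma = 2.2, truncate = 3)
  r <- ceiling(3 * 2.2)
  g <- exp(-0.5 * ((-r:r) / 2.2)^2)
  k2 <- outer(g, g) / sum(outer(g, g))
  expect_equal(sm[16, 16], k2[r + 1, r + 1], tolerance = 1e-12)
  # step edge: monotone transition strictly between the two levels
  step <- matrix(0.05, 40, 40); step[, 21:40] <- 0.2
  ss <- smooth_map(step)
  prof <- ss[20, ]
  expect_true(all(diff(prof) >= -1e-12))
  expect_true(all(prof >= 0.05 - 1e-12 & prof <= 0.2 + 1e-12))
  expect_true(prof[20] > 0.05 && prof[21] < 0.2)
  # mass preservation away from borders
  blob <- matrix(0, 60, 60); blob[25:35, 25:35] <- 0.2
  sb <- smooth_map(blob)
  expect_lt(abs(sum(sb) - sum(blob)) / sum(blob), 0.001)
  expect_error(smooth_map(cst, sigma = 0), class = "dfbhc_validation")
})

test_that("the water complement is exact and range-checked", {
  z <- matrix(0, 8, 8)
  cm <- complement_map(z)
  expect_equal(cm$omega_water, matrix(1, 8, 8))
  cm2 <- complement_map(matrix(0.15, 4, 4))
  expect_equal(cm2$omega_water, matrix(0.85, 4, 4))
  set.seed(9)
  rnd <- matrix(runif(100), 10, 10)
  cm3 <- complement_map(rnd)
  expect_equal(max(abs(cm3$omega_al + cm3$omega_water - 1)), 0)
  expect_error(complement_map(matrix(1.5, 2, 2)), class = "dfbhc_validation")
})

test_that("full contribution-map pipeline: exact interiors pre-smoothing, conserved complement", {
  ph <- small_phantom(seed = 6)
  cmap <- make_contribution_map(ph$bone_masks, weight_config("male"),
                                labeled_ribs = ph$labeled_ribs)
  raw <- attr(cmap, "raw_omega_al")
  # pre-smoothing interior values equal the configured table entries exactly
  post <- ph$labeled_ribs[[3]]$posterior
  interior <- EBImage::erode(post, EBImage::makeBrush(7, "box"))
  if (sum(interior) > 0) expect_true(all(raw[interior == 1] == 0.15))
  clav_int <- EBImage::erode(ph$bone_masks$clavicle_mask, EBImage::makeBrush(7, "box"))
  if (sum(clav_int) > 0) expect_true(all(raw[clav_int == 1] == 0.20))
  expect_true(all(cmap$omega_al >= 0 & cmap$omega_al <= 1))
  expect_equal(max(abs(cmap$omega_al + cmap$omega_water - 1)), 0)
  # empty mask set: uniform background map, complement uniform
  empty <- bone_mask_set(list(), clavicle_mask = matrix(0, 130, 130))
  cm0 <- make_contribution_map(empty, weight_config("male"))
  expect_equal(cm0$omega_al, matrix(0.05, 130, 130), tolerance = 1e-12)
})
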