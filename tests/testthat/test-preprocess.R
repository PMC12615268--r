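# Intensity conditioning, probability normalization, Otsu thresholds,
# contrast scores and diameter scanning.

test_that("percentile normalization maps the stated percentiles to 0 and 1", {
  ramp <- as_volume(array(seq(0, 100, length.out = 16^3), c(16, 16, 16)))
  out <- normalize_percentile(ramp, 0, 100)
  expect_equal(range(unclass(out)), c(0, 1))
  expect_equal(as.vector(unclass(out)), seq(0, 1, length.out = 16^3))
  set.seed(4)
  v <- array(rnorm(20^3), c(20, 20, 20))
  out <- normalize_percentile(v, 2, 99.8)
  q <- quantile(v, c(0.02, 0.998), names = FALSE)
  expect_true(all(out >= 0 & out <= 1))
  expect_true(all(out[v <= q[1]] == 0))
  expect_true(all(out[v >= q[2]] == 1))
  # idempotent on already-normalised input with full-range percentiles
  expect_equal(normalize_percentile(out, 0, 100), out)
  expect_error(normalize_percentile(array(1, c(4, 4, 4))), "constant")
})

test_that("illumination correction preserves constants and flattens shading", {
  const <- array(3, c(16, 16, 16))
  out <- correct_illumination(const, sigma_bg = 2, ds = 2)
  expect_lt(max(abs(out - 3)), 1e-6)
  # multiplicative shading on a flat background becomes more uniform
  z <- seq(0.5, 1.5, length.out = 32)
  shade <- array(rep(z, each = 1), c(32, 32, 32))
  for (k in 1:32) shade[, , k] <- z[k]
  img <- shade * 2
  out <- correct_illumination(img, sigma_bg = 2, ds = 2)
  core <- 7:26   # interior, away from boundary-padding effects
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(out[core, core, core]), cv(img[core, core, core]) / 2)
  # ds = 1 smooths at full resolution (no resampling round trip)
  direct <- mean(img) * img / (orthoseg3d:::gaussian_smooth(img, 4) + 1e-8)
  expect_equal(correct_illumination(img, sigma_bg = 4, ds = 1), direct)
})

test_that("gamma correction follows the rescale-then-power contract", {
  v <- array(seq(0, 4, length.out = 4^3), c(4, 4, 4))
  expect_equal(gamma_correct(v, 1), (v - min(v)) / diff(range(v)))
  x <- array(c(0, 0.25, 0.5, 1), c(1, 2, 2))
  expect_equal(as.vector(gamma_correct(x, 0.5)), c(0, 0.5, sqrt(0.5), 1))
  # monotone: ordering preserved
  set.seed(5)
  v <- array(runif(6^3), c(6, 6, 6))
  expect_identical(order(as.vector(gamma_correct(v, 0.4))), order(as.vector(v)))
})

test_that("ridge enhancement favours thin tubes over blobs and ignores offsets", {
  expect_true(all(enhance_ridges(matrix(0, 32, 32), 2) == 0))
  tube <- matrix(0, 41, 41); tube[19:21, 6:36] <- 1
  blob <- matrix(0, 41, 41)
  ij <- expand.grid(i = 1:41, j = 1:41)
  blob[(ij$i - 21)^2 + (ij$j - 21)^2 <= 100] <- 1
  rt <- enhance_ridges(tube, sigmas = c(1, 2))
  rb <- enhance_ridges(blob, sigmas = c(1, 2))
  expect_gt(rt[20, 21], rb[21, 21])       # centreline beats blob centre
  r_off <- enhance_ridges(tube + 5, sigmas = c(1, 2))
  expect_equal(r_off, rt, tolerance = 1e-10)  # additive offset invariance
})

test_that("probability normalization clips at the float32 guard and is monotone", {
  expect_equal(normalize_probability(0), 0.5)
  expect_equal(normalize_probability(1000), 1 / (1 + exp(-88.72)))
  expect_equal(normalize_probability(-1000), 1 / (1 + exp(88.72)))
  x <- seq(-100, 100, by = 0.5)
  expect_true(all(diff(normalize_probability(x)) >= 0))
  expect_true(all(normalize_probability(x) >= 0 & normalize_probability(x) <= 1))
  x2 <- seq(-10, 10, by = 0.25)   # strictly increasing away from saturation
  expect_true(all(diff(normalize_probability(x2)) > 0))
})

test_that("Otsu thresholds separate bimodal maps and honour floor/rounding", {
  set.seed(6)
  p <- c(rnorm(4000, 0.1, 0.03), rnorm(4000, 0.9, 0.03))
  p <- pmin(pmax(p, 0), 1)
  th <- auto_threshold_probability(p, classes = 2, floor = 0)
  expect_gt(th, 0.2); expect_lt(th, 0.8)
  # agreement with the independent 2-class implementation in EBImage
  th_eb <- EBImage::otsu(EBImage::Image(matrix(p, 80, 100)), range = c(0, 1))
  expect_lt(abs(th - th_eb), 2 / 256)
  # 3-class on a trimodal map: lower < higher, both between the modes
  p3 <- pmin(pmax(c(rnorm(3000, 0.1, 0.03), rnorm(3000, 0.5, 0.03),
                    rnorm(3000, 0.9, 0.03)), 0), 1)
  lo <- auto_threshold_probability(p3, classes = 3, pick = "lower", floor = 0)
  hi <- auto_threshold_probability(p3, classes = 3, pick = "higher", floor = 0)
  expect_lt(lo, hi)
  expect_gt(lo, 0.1); expect_lt(hi, 0.9)
  # minimum threshold rule and rounding down
  low_map <- pmin(pmax(c(rnorm(5000, 0.02, 0.01), rnorm(200, 0.2, 0.02)), 0), 1)
  expect_equal(auto_threshold_probability(low_map, 2, floor = 0.25), 0.25)
  expect_equal(floor(0.3799 * 10) / 10, 0.3)
  expect_error(auto_threshold_probability(rep(0.5, 100)), "constant")
})

test_that("contrast score matches a sliding-window oracle and scales with w", {
  expect_equal(contrast_score(matrix(0.7, 12, 12), matrix(-0.2, 12, 12), P = 3),
               0)
  # alternating checkerboard: compare to brute-force local SD with
  # symmetric padding
  gx <- outer(1:12, 1:12, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
  gy <- matrix(0, 12, 12)
  sd_oracle <- function(img, P) {
    r <- (P - 1) %/% 2
    refl <- function(i, n) { j <- (i - 1) %% (2 * n); j <- ifelse(j < 0, j + 2 * n, j)
      ifelse(j < n, j + 1, 2 * n - j) }
    out <- img
    for (i in 1:nrow(img)) for (j in 1:ncol(img)) {
      w <- img[refl((i - r):(i + r), nrow(img)), refl((j - r):(j + r), ncol(img))]
      out[i, j] <- sqrt(mean(w^2) - mean(w)^2)
    }
    out
  }
  expect_equal(contrast_score(gx, gy, P = 3),
               mean(sd_oracle(gx, 3) + sd_oracle(gy, 3)))
  # linearity in the weight
  set.seed(7)
  gx <- matrix(rnorm(100), 10, 10); gy <- matrix(rnorm(100), 10, 10)
  w <- matrix(runif(100), 10, 10)
  expect_equal(contrast_score(gx, gy, p = 2 * w, P = 3, use_p = TRUE),
               2 * contrast_score(gx, gy, p = w, P = 3, use_p = TRUE))
})

test_that("diameter scanning finds the peak of a unimodal predictor", {
  # synthetic predictor whose gradient sharpness peaks at d = 30
  predictor <- function(img, d) {
    amp <- exp(-(d - 30)^2 / 200)
    gx <- amp * outer(1:16, 1:16, function(i, j) ifelse((i + j) %% 2 == 0, 1, -1))
    list(gx = gx, gy = gx * 0, p_raw = gx * 0 + 5)
  }
  img <- matrix(0, 16, 16)
  sc <- scan_diameter(predictor, img, d_low = 10, d_high = 60, step = 2.5,
                      window = 5)
  expect_equal(attr(sc, "d_opt"), 30)
  # window = 1 keeps the raw scores
  sc1 <- scan_diameter(predictor, img, d_low = 10, d_high = 60, step = 5,
                       window = 1)
  expect_equal(sc1$smoothed, sc1$score)
  expect_identical(glance(sc)$d_opt, 30)
  # determinism for a deterministic predictor
  sc2 <- scan_diameter(predictor, img, d_low = 10, d_high = 60, step = 2.5,
                       window = 5)
  expect_identical(tidy(sc), tidy(sc2))
})

test_that("reference slice selection follows each strategy", {
  set.seed(8)
  sharp <- matrix(rep(c(0, 1), 128), 16, 16)
  vol <- array(0, c(7, 16, 16))
  for (z in 1:7) vol[z, , ] <- orthoseg3d:::gaussian_smooth(sharp, 2)
  vol[4, , ] <- sharp
  expect_identical(select_reference_slice(as_volume(vol), "focus"), 4L)
  expect_identical(select_reference_slice(as_volume(array(0, c(11, 4, 4))), "mid"), 6L)
  bright <- array(0.1, c(5, 8, 8)); bright[2, , ] <- 0.9
  expect_identical(select_reference_slice(as_volume(bright), "intensity"), 2L)
  expect_identical(select_reference_slice(as_volume(bright), "index", index = 3), 3L)
  expect_error(select_reference_slice(as_volume(bright), "index", index = 9),
               "out of range")
})
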