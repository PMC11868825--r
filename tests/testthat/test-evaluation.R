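test_that("icc: identity, null, offset penalty vs ANOVA mean squares", {
  x <- c(1, 3, 5, 9, 2, 7)
  expect_equal(icc(x, x), 1, tolerance = 1e-12)
  set.seed(5)
  a <- stats::rnorm(1e4); b <- stats::rnorm(1e4)
  expect_lt(abs(icc(a, b)), 0.05)
  # absolute agreement penalizes a constant shift; Pearson does not
  y <- x + stats::sd(x)
  expect_lt(icc(x, y), stats::cor(x, y))
  # longhand variance-components check via stats::aov mean squares
  set.seed(31)
  xx <- stats::rnorm(40); yy <- xx + 0.3 * stats::rnorm(40) + 0.2
  df <- data.frame(v = c(xx, yy),
                   subj = factor(rep(1:40, 2)),
                   rater = factor(rep(1:2, each = 40)))
  ms <- summary(stats::aov(v ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 40; k <- 2
  want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc(xx, yy), want, tolerance = 1e-10)
  expect_error(icc(1:3, 1:4), "equal length")
  expect_error(icc(1, 2), ">= 2")
})

test_that("compare_protocols: trivial identities and symmetry", {
  dims <- c(4, 4, 2)
  set.seed(2)
  mk <- function(d12) {
    parameter_maps(d12 = d12,
                   alpha = array(stats::runif(32, 0.6, 0.95), dims),
                   ip = array(stats::runif(32, 3e3, 9e3), dims),
                   mse = array(0, dims), mask = array(TRUE, dims))
  }
  m <- mk(array(stats::runif(32, 5e-4, 1e-3), dims))
  self <- compare_protocols(m, m)
  expect_equal(self$bias, rep(0, 3))
  expect_equal(self$uncertainty, rep(0, 3))
  expect_equal(self$icc, rep(1, 3), tolerance = 1e-12)
  shifted <- m
  shifted$d12 <- m$d12 + 1e-4
  cmp <- compare_protocols(m, shifted)
  expect_equal(cmp$bias[cmp$parameter == "d12"], 1e-4, tolerance = 1e-12)
  expect_equal(cmp$uncertainty[cmp$parameter == "d12"], 0, tolerance = 1e-12)
  # antisymmetric bias, symmetric uncertainty and icc under swapping
  m2 <- mk(array(stats::runif(32, 5e-4, 1e-3), dims))
  ab <- compare_protocols(m, m2)
  ba <- compare_protocols(m2, m)
  expect_equal(ab$bias, -ba$bias, tolerance = 1e-12)
  expect_equal(ab$uncertainty, ba$uncertainty, tolerance = 1e-12)
  expect_equal(ab$icc, ba$icc, tolerance = 1e-12)
  expect_error(compare_protocols(m, parameter_maps(
    array(1, c(2, 2, 2)), array(1, c(2, 2, 2)), array(1, c(2, 2, 2)),
    array(1, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))), "geometry")
})

test_that("compare_protocols excludes sentinel voxels pairwise", {
  dims <- c(3, 3, 1)
  base <- array(stats::runif(9, 0.5, 1), dims)
  mk <- function(ip) parameter_maps(base, base, ip, base,
                                    array(TRUE, dims))
  ip1 <- base * 1e4; ip2 <- base * 1e4
  ip1[1, 1, 1] <- NA  # undefined IP in one map only
  cmp <- compare_protocols(mk(ip1), mk(ip2))
  expect_identical(cmp$n_voxels[cmp$parameter == "ip"], 8L)
  expect_identical(cmp$n_voxels[cmp$parameter == "d12"], 9L)
})

test_that("roi_stats: constants, order statistics, sentinel exclusion", {
  dims <- c(3, 3, 1)
  m <- array(7, dims)
  roi <- array(TRUE, dims)
  st <- roi_stats(m, roi)
  expect_identical(st$median, 7)
  expect_identical(st$q75 - st$q25, 0)
  m2 <- array(as.numeric(1:9), dims)
  expect_identical(roi_stats(m2, roi)$median, 5)
  m2[2, 2, 1] <- NA
  st2 <- roi_stats(m2, roi)
  expect_identical(st2$n, 8L)
  expect_identical(st2$n_excluded, 1L)
  expect_error(roi_stats(m2, array(FALSE, dims)), "empty ROI")
  expect_error(roi_stats(m2, array(TRUE, c(2, 2, 2))), "shapes differ")
})

test_that("bmax_sweep: subsumption, nested least squares, skip warning", {
  sch <- make_scheme("dataset1")
  b <- sort(unique(sch$bvals))
  gm <- qdi_params(0.8e-3, 0.88)
  noiseless <- decay_curve(b, qdi_attenuation(b, gm))
  sweep <- bmax_sweep(noiseless, c(2000, 4000, 8000, 15000))
  # exact model: every bmax with >= 3 points recovers the truth
  expect_true(all(abs(sweep$alpha - 0.88) < 1e-5))
  expect_true(all(abs(sweep$d12 / 0.8e-3 - 1) < 1e-5))
  # full-range mse is non-increasing in bmax on noiseless data
  expect_true(all(diff(sweep$mse_full) <= 1e-12))
  expect_warning(bmax_sweep(noiseless, c(500, 15000)), "skipped")
  expect_error(bmax_sweep(noiseless, c(4000, 1200)), "ascending")
})

test_that("bmax truncation biases alpha toward the Gaussian exponent", {
  # uncorrected magnitude data (the bmax-sweep protocol): the residual noise
  # floor flattens the tail, so low-bmax fits drift toward alpha = 1
  curves <- simulate_curves(40, make_scheme("dataset1"), seed = 19,
                            correct = FALSE)
  sweep <- bmax_sweep(curves, c(1200, 15000))
  a_low <- stats::median(sweep$alpha[sweep$bmax == 1200])
  a_full <- stats::median(sweep$alpha[sweep$bmax == 15000])
  expect_gt(a_low, a_full)
  # uncorrected tails bias the full-range alpha below truth; sanity bound only
  expect_lt(abs(a_full - 0.88), 0.08)
})
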