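gm <- qdi_params(0.8e-3, 0.88)

test_that("powder_average: shell means, normalization, pass-through", {
  # 1x1x1 voxel, 2 b0 + one shell with two directions (values 2 and 4)
  sch <- acquisition_scheme(c(0, 0, 1000, 1000),
                            cbind(0, 0, c(1, 0, 0), c(0, 1, 0)))
  dwi <- array(c(8, 8, 2, 4), c(1, 1, 1, 4))
  set <- powder_average(dwi, sch)
  expect_identical(set$b, c(0, 1000))
  expect_identical(as.numeric(set$s_norm[1, 1, 1, ]), c(1, 3 / 8))
  # constant signal across directions
  dwi2 <- array(c(8, 8, 5, 5), c(1, 1, 1, 4))
  expect_identical(as.numeric(
    powder_average(dwi2, sch)$s_norm[1, 1, 1, 2]), 5 / 8)
  # single-direction shells pass through
  sch3 <- acquisition_scheme(c(0, 2000), cbind(0, c(0, 0, 1)))
  dwi3 <- array(c(10, 7), c(1, 1, 1, 2))
  expect_identical(as.numeric(
    powder_average(dwi3, sch3)$s_norm[1, 1, 1, 2]), 0.7)
  expect_error(powder_average(array(1, c(1, 1, 1, 3)), sch), "count")
  sch_no_b0 <- acquisition_scheme(c(500, 1000),
                                  cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_error(powder_average(array(1, c(1, 1, 1, 2)), sch_no_b0), "b = 0")
})

test_that("powder_average groups shells within the 50 s/mm^2 tolerance", {
  sch <- acquisition_scheme(c(0, 990, 1010), cbind(0, c(1, 0, 0), c(0, 1, 0)))
  set <- powder_average(array(c(10, 4, 6), c(1, 1, 1, 3)), sch)
  expect_identical(length(set$b), 2L)
  expect_equal(set$b[2], 1000)
  expect_identical(as.numeric(set$s_norm[1, 1, 1, 2]), 0.5)
})

test_that("fit_decay recovers noiseless parameters", {
  b <- sort(unique(make_scheme("dataset1")$bvals))
  f <- fit_decay(decay_curve(b, qdi_attenuation(b, gm)))
  expect_rel(f$params$d12, gm$d12, 1e-6)
  expect_rel(f$params$alpha, gm$alpha, 1e-6)
  expect_lt(f$mse_log, 1e-12)
  expect_true(f$converged)
  expect_identical(f$n_points, 11L)
  # pure exponential is subsumed exactly
  fe <- fit_decay(decay_curve(b, exp(-1e-3 * b)))
  expect_gte(fe$params$alpha, 0.9999)
  expect_error(fit_decay(decay_curve(c(0, 1000), c(1, 0.5))), "insufficient")
})

test_that("fit_decay solution is locally optimal", {
  b <- sort(unique(make_scheme("dataset1")$bvals))
  curve <- simulate_curves(1, make_scheme("dataset1"), seed = 3)[[1]]
  f <- fit_decay(curve)
  base <- mse_log(f$params, curve)
  set.seed(8)
  for (i in 1:100) {
    p <- qdi_params(f$params$d12 * exp(stats::rnorm(1, 0, 0.1)),
                    min(1, max(0.06, f$params$alpha +
                                 stats::rnorm(1, 0, 0.05))))
    expect_gte(mse_log(p, curve), base - 1e-12)
  }
})

test_that("mse_log: zero at truth, constant offset, truncation ordering", {
  b <- sort(unique(make_scheme("dataset1")$bvals))
  curve <- decay_curve(b, qdi_attenuation(b, gm))
  expect_equal(mse_log(gm, curve), 0, tolerance = 1e-20)
  delta <- 0.07
  off <- decay_curve(b, qdi_attenuation(b, gm) * exp(delta))
  expect_equal(mse_log(gm, off), delta^2, tolerance = 1e-10)
  # params fitted on a truncated range score worse on the full range than the
  # full-range fit (on a curve the model cannot represent exactly)
  s_noisy <- simulate_curves(1, make_scheme("dataset1"), seed = 12)[[1]]
  f_full <- fit_decay(s_noisy)
  keep <- s_noisy$b <= 1200
  f_trunc <- fit_decay(decay_curve(s_noisy$b[keep], s_noisy$s_norm[keep],
                                   s_noisy$valid[keep]))
  expect_gt(mse_log(f_trunc$params, s_noisy), mse_log(f_full$params, s_noisy))
})

test_that("fit_volume: phantom round trip, sentinels, determinism", {
  sch <- make_scheme("dataset1_short")
  ph <- make_phantom(default_phantom_spec(shape = c(6, 3, 1), snr_b0 = Inf),
                     sch)
  maps <- fit_volume(ph$dwi, sch)
  expect_lt(mean(abs(maps$alpha - ph$truth$alpha)), 1e-6)
  expect_rel(maps$d12, ph$truth$d12, 1e-5)
  # IP: defined where truth defined, NA for the Gaussian region
  expect_identical(is.na(maps$ip), is.na(ph$truth$ip))
  # determinism
  maps2 <- fit_volume(ph$dwi, sch)
  expect_identical(maps$d12, maps2$d12)
  expect_identical(maps$alpha, maps2$alpha)
  # a voxel with invalid data gets the sentinel and the run continues
  dwi_bad <- ph$dwi
  dwi_bad[1, 1, 1, ] <- 0
  maps3 <- fit_volume(dwi_bad, sch)
  expect_true(is.na(maps3$d12[1, 1, 1]))
  expect_false(maps3$mask[1, 1, 1])
  expect_false(is.na(maps3$d12[2, 1, 1]))
  expect_error(fit_volume(ph$dwi, sch, mask = array(FALSE, c(6, 3, 1))),
               "empty mask")
  expect_error(fit_volume(ph$dwi, sch, mask = array(TRUE, c(2, 2, 2))),
               "mask shape")
})

test_that("zero-noise identifiability across schemes with IP-spanning b", {
  set.seed(21)
  for (preset in c("dataset1", "dataset2", "dataset3")) {
    b <- sort(unique(make_scheme(preset)$bvals))
    for (i in 1:3) {
      p <- qdi_params(stats::runif(1, 3e-4, 2e-3), stats::runif(1, 0.55, 0.95))
      f <- fit_decay(decay_curve(b, qdi_attenuation(b, p)))
      expect_rel(f$params$d12, p$d12, 1e-5, info = preset)
      expect_rel(f$params$alpha, p$alpha, 1e-5, info = preset)
    }
  }
})
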