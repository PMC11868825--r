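gm <- qdi_params(0.8e-3, 0.88)

test_that("qdi_attenuation: anchors, exemplar, monotonicity", {
  expect_identical(qdi_attenuation(0, gm), 1)
  expect_equal(qdi_attenuation(1000, qdi_params(1e-3, 1)), exp(-1),
               tolerance = 1e-14)
  # grey-matter exemplar, frozen from the extended-precision series oracle
  expect_rel(qdi_attenuation(5000, gm), 0.0737632694386511, 1e-10)
  b <- exp(seq(log(10), log(1e6), length.out = 200))
  s <- qdi_attenuation(b, gm)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
  expect_error(qdi_attenuation(-5, gm), ">= 0")
})

test_that("qdi_attenuation: scale invariance and alpha = 1/2 identity", {
  b <- c(100, 1000, 7000)
  for (cc in c(10, 0.1)) {
    expect_equal(qdi_attenuation(b, qdi_params(1e-3, 0.7)),
                 qdi_attenuation(cc * b, qdi_params(1e-3 / cc, 0.7)),
                 tolerance = 1e-12)
  }
  p <- qdi_params(0.4e-3, 0.5)
  u <- p$d12 * b
  expect_rel(qdi_attenuation(b, p), exp(u) * qdimri:::.erfc(sqrt(u)), 1e-10)
})

test_that("alpha ordering of the tail matches the power-law family", {
  # in the power-law regime S ~ b^(-alpha): lower alpha decays shallower and
  # sits higher at fixed large D12*b (the family-of-curves behaviour)
  b <- 1e5  # D12*b = 100, well past the inflection for these alphas
  vals <- vapply(c(0.5, 0.7, 0.9), function(a)
    qdi_attenuation(b, qdi_params(1e-3, a)), numeric(1))
  expect_true(all(diff(vals) < 0))
  # below D12*b = 1 the ordering reverses (stretched exponential regime)
  vals_lo <- vapply(c(0.5, 0.7, 0.9), function(a)
    qdi_attenuation(500, qdi_params(1e-3, a)), numeric(1))
  expect_true(all(diff(vals_lo) > 0))
})

test_that("asymptotic regimes bracket and match the full model", {
  # alpha = 1 low-b limit is exact
  expect_equal(qdi_asymptote(c(100, 5000), qdi_params(1e-3, 1), "low_b"),
               exp(-1e-3 * c(100, 5000)), tolerance = 1e-14)
  # sin(pi/2) Gamma(1/2) / pi = 1/sqrt(pi) at (D b)^alpha = 1
  expect_rel(qdi_asymptote(1 / 0.5e-3, qdi_params(0.5e-3, 0.5), "high_b"),
             1 / sqrt(pi), 1e-12)
  expect_error(qdi_asymptote(1000, qdi_params(1e-3, 1), "high_b"), "alpha")
  # regime sandwich: low-b within 1% when (Db)^a <= 0.1, high-b within 1e-3
  # when (Db)^a >= 1e3 (alpha = 0.7 example sweep)
  p <- qdi_params(1e-3, 0.7)
  b_lo <- (0.1)^(1 / 0.7) / p$d12 * c(0.05, 0.2, 1)
  full <- qdi_attenuation(b_lo, p)
  expect_true(all(abs(qdi_asymptote(b_lo, p, "low_b") - full) / full <= 0.01))
  b_hi <- (1e3)^(1 / 0.7) / p$d12 * c(1, 5, 100)
  full <- qdi_attenuation(b_hi, p)
  expect_true(all(abs(qdi_asymptote(b_hi, p, "high_b") - full) / full <= 1e-3))
})

test_that("log_slope: Gaussian case, -alpha limit, finite differences", {
  expect_equal(log_slope(1000, qdi_params(1e-3, 1)), -1, tolerance = 1e-12)
  # Fig-2 behaviour: gradient tends to -alpha
  p6 <- qdi_params(1e-3, 0.6)
  b <- (1e6)^(1 / 0.6) / p6$d12
  expect_true(abs(log_slope(b, p6) - (-0.6)) < 0.01)
  expect_equal(log_slope(2000, gm), fd_log_slope(2000, gm),
               tolerance = 1e-5)
  bg <- c(50, 500, 5000, 5e4)
  expect_true(all(log_slope(bg, gm) < 0))
  expect_error(log_slope(0, gm), "> 0")
})

test_that("log_curvature: Gaussian reduction, IP zero, single sign change", {
  expect_equal(log_curvature(1000, qdi_params(1e-3, 1)), -1,
               tolerance = 1e-12)
  ip <- find_ip(gm)
  expect_lt(abs(log_curvature(ip, gm)), 1e-6)
  expect_lt(log_curvature(100, qdi_params(1e-3, 0.7)), 0)
  # finite-difference agreement
  for (b in c(300, 3000, 30000)) {
    expect_equal(log_curvature(b, gm), fd_log_curvature(b, gm),
                 tolerance = 1e-4)
  }
  # exactly one sign change over a dense grid
  b <- exp(seq(log(10), log(1e7), length.out = 400))
  sgn <- sign(log_curvature(b, qdi_params(0.7e-3, 0.75)))
  flips <- sum(diff(sgn[sgn != 0]) != 0)
  expect_identical(flips, 1L)
  # Gaussian curvature strictly negative: no inflection
  expect_true(all(log_curvature(b, qdi_params(1e-3, 1)) < 0))
})

test_that("stick model: limit, closed form, high-b exponent", {
  expect_identical(stick_attenuation(0, 2e-3), 1)
  # b * d_par = 4 -> (sqrt(pi)/2) erf(2) / 2
  expect_rel(stick_attenuation(4 / 2e-3, 2e-3), 0.441040695381211, 1e-12)
  # high-b log-log slope -> -1/2 when d_perp = 0
  b0 <- 1e4 / 2e-3
  h <- 1e-3
  sl <- (log(stick_attenuation(b0 * exp(h), 2e-3)) -
           log(stick_attenuation(b0 * exp(-h), 2e-3))) / (2 * h)
  expect_true(abs(sl - (-0.5)) < 0.01)
  expect_error(stick_attenuation(100, 1e-3, 2e-3), "d_par")
})

test_that("effective coefficient and round trip", {
  expect_identical(effective_coefficient(qdi_params(1e-3, 1)), 1e-3)
  expect_equal(effective_coefficient(qdi_params(4e-4, 0.5)), 0.02)
  set.seed(11)
  for (i in 1:20) {
    p <- qdi_params(10^stats::runif(1, -4, -2.3), stats::runif(1, 0.1, 1))
    expect_equal(effective_coefficient(p)^(1 / p$alpha), p$d12,
                 tolerance = 1e-12)
  }
})

test_that("qdi_params validation", {
  expect_error(qdi_params(-1e-3, 0.9), "d12")
  expect_error(qdi_params(1e-3, 0), "alpha")
  expect_error(qdi_params(1e-3, 1.1), "alpha")
})
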