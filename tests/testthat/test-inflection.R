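gm <- qdi_params(0.8e-3, 0.88)

test_that("find_ip: sentinel, exemplar, scale invariance", {
  expect_identical(find_ip(qdi_params(1e-3, 1)), NA_real_)
  expect_identical(find_ip(qdi_params(2e-3, 1 - 1e-8)), NA_real_)
  ip <- find_ip(gm)
  expect_true(ip > 1000 && ip < 10000)  # low-thousands s/mm^2
  expect_equal(ip, brute_force_ip(gm, step = 1e-4,
                                  lo = log(ip) - 0.05, hi = log(ip) + 0.05),
               tolerance = 1e-3)
  # halving D12 exactly doubles the IP
  expect_equal(find_ip(qdi_params(0.4e-3, 0.88)), 2 * ip, tolerance = 1e-12)
  # root validity
  expect_lt(abs(log_curvature(ip, gm)), 1e-6)
})

test_that("IP outside the scan window or below alpha = 1/2 is a sentinel", {
  # ln b beyond 50 (extremely low D12): sentinel, not a value
  expect_identical(find_ip(qdi_params(1e-30, 0.55)), NA_real_)
  # no inflection exists at or below alpha = 1/2 (curvature approaches zero
  # from below without crossing)
  expect_identical(find_ip(qdi_params(1e-3, 0.5)), NA_real_)
  expect_identical(find_ip(qdi_params(1e-3, 0.45)), NA_real_)
})

test_that("scale invariance: D12 * IP constant over two decades", {
  for (a in c(0.55, 0.75, 0.9)) {
    d <- 10^seq(-4.3, -2.3, length.out = 9)
    ips <- vapply(d, function(di) find_ip(qdi_params(di, a)), numeric(1))
    prod <- d * ips
    expect_lt(stats::sd(prod) / mean(prod), 1e-3)
  }
})

test_that("find_ip agrees with brute-force curvature zero crossings", {
  set.seed(101)
  for (i in 1:25) {
    p <- qdi_params(stats::runif(1, 2e-4, 3e-3), stats::runif(1, 0.52, 0.97))
    ip <- find_ip(p)
    bf <- brute_force_ip(p)
    expect_false(is.na(ip))
    expect_lt(abs(log(ip) - log(bf)), 0.001 + 1e-9)
    # direction of crossing: concave below, convex above
    expect_lt(log_curvature(ip * exp(-0.1), p), 0)
    expect_gt(log_curvature(ip * exp(0.1), p), 0)
  }
})

test_that("build_ip_table: shape, node consistency, monotonicity, sentinel", {
  tab <- build_ip_table(d12_range = c(2e-4, 2e-3), alpha_range = c(0.6, 0.9),
                        alpha_step = 0.05, n_d12 = 7L)
  expect_s3_class(tab, "ip_table")
  expect_identical(dim(tab$ip), c(7L, 7L))
  for (j in seq_along(tab$alpha)) {
    expect_equal(tab$ip[, j],
                 vapply(tab$d12, function(d)
                   find_ip(qdi_params(d, tab$alpha[j])), numeric(1)))
    expect_true(all(diff(tab$ip[, j]) < 0))  # decreasing in D12 (Fig 2d)
  }
  # alpha columns at/above the Gaussian limit are sentinel-filled
  tab2 <- build_ip_table(d12_range = c(5e-4, 2e-3),
                         alpha_range = c(0.9999990, 0.9999999),
                         alpha_step = 4e-7, n_d12 = 3L)
  expect_true(all(is.na(tab2$ip)))
  expect_error(build_ip_table(d12_range = c(2e-3, 1e-3)), "increasing")
  expect_error(build_ip_table(alpha_step = -1), "positive")
})

test_that("lookup_ip: node-exact, 1% off-grid, sentinel and range errors", {
  tab <- build_ip_table()
  # grid node: exact
  i <- 20L; j <- 60L
  expect_equal(lookup_ip(tab, qdi_params(tab$d12[i], tab$alpha[j])),
               tab$ip[i, j], tolerance = 1e-12)
  # off-grid queries within 1% of the direct solve
  set.seed(7)
  for (k in 1:20) {
    p <- qdi_params(stats::runif(1, 2e-5, 2.9e-3), stats::runif(1, 0.4, 0.95))
    got <- lookup_ip(tab, p)
    want <- find_ip(p)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else if (is.na(got)) {
      # sentinel propagation from an undefined cell corner (alpha just
      # above 1/2 next to the no-inflection region)
      expect_lt(p$alpha, 0.501)
    } else {
      expect_rel(got, want, 0.01)
    }
  }
  # alpha above the table's range (built to < 1): sentinel, per the
  # near-Gaussian convention; D12 outside the range is an error
  expect_identical(lookup_ip(tab, qdi_params(1e-3, 0.999)), NA_real_)
  expect_error(lookup_ip(tab, qdi_params(5e-3, 0.8)), "range")
  expect_error(lookup_ip(tab, qdi_params(1e-3, 0.1)), "range")
})

test_that("ip_table serialization round-trips", {
  tab <- build_ip_table(d12_range = c(5e-4, 2e-3), alpha_range = c(0.7, 0.95),
                        alpha_step = 0.05, n_d12 = 5L)
  f <- tempfile(fileext = ".tsv")
  write_ip_table(tab, f)
  back <- read_ip_table(f)
  expect_equal(back$d12, tab$d12, tolerance = 1e-9)
  expect_equal(back$alpha, tab$alpha, tolerance = 1e-9)
  expect_equal(back$ip, tab$ip, tolerance = 1e-9)
  unlink(f)
})
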