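# Shared numerical oracles and small utilities for the suite.

expect_rel <- function(got, want, tol, info = NULL) {
  rel <- abs(got - want) / pmax(abs(want), .Machine$double.xmin)
  expect_true(all(rel <= tol),
              info = paste0(info, " (max rel err ", signif(max(rel), 3), ")"))
}

# central finite differences of ln S in ln b
fd_log_slope <- function(b, params, h = 1e-4) {
  (log(qdi_attenuation(b * exp(h), params)) -
     log(qdi_attenuation(b * exp(-h), params))) / (2 * h)
}

fd_log_curvature <- function(b, params, h = 1e-4) {
  (log(qdi_attenuation(b * exp(h), params)) -
     2 * log(qdi_attenuation(b, params)) +
     log(qdi_attenuation(b * exp(-h), params))) / h^2
}

# brute-force inflection point: zero crossing (- to +) of second central
# differences of ln S on a uniform ln b grid of the given step
brute_force_ip <- function(params, step = 0.001, lo = step, hi = 50 - step) {
  lnb <- seq(lo, hi, by = step)
  y <- log(qdi_attenuation(exp(lnb), params))
  d2 <- diff(y, differences = 2) / step^2
  idx <- which(d2[-length(d2)] < 0 & d2[-1] >= 0)
  if (length(idx) == 0) return(NA_real_)
  exp(lnb[idx[1] + 1L])  # d2[i] corresponds to lnb[i+1]
}

# noisy GM-like decay curves on a given scheme, with the Rician
# correction path applied (known sigma)
simulate_curves <- function(n, scheme, d12 = 0.8e-3, alpha = 0.88,
                            snr = 50, seed = 1, s0 = 100, correct = TRUE) {
  spec <- phantom_spec(c(n, 1L, 1L),
                       list(list(label = "GM", d12 = d12, alpha = alpha,
                                 mask = array(TRUE, c(n, 1L, 1L)))),
                       snr_b0 = snr, seed = seed, s0 = s0)
  ph <- make_phantom(spec, scheme)
  mu_r <- if (correct && ph$sigma > 0) ph$sigma * sqrt(pi / 2) else NULL
  set <- powder_average(ph$dwi, scheme, mu_r = mu_r)
  lapply(seq_len(n), function(i) get_curve(set, i, 1, 1))
}
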