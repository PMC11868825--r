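#' Estimate the Gaussian noise level from a signal-free ROI
#'
#' Estimates the standard deviation `sigma` of the underlying Gaussian channel
#' noise from magnitude signal in a region with no tissue signal: the signal
#' in each gradient direction is subtracted from every other direction
#' voxelwise, and the standard deviation of all pooled differences is taken.
#' A difference of two i.i.d. draws has standard deviation
#' \eqn{\sigma\sqrt{2}}, so the pooled value is divided by \eqn{\sqrt{2}} by
#' default (`sqrt2_correction = FALSE` reproduces the raw pooled standard
#' deviation; note the choice changes the noise floor by 41%).  The mean
#' Rician floor is \eqn{\mu_R = \sigma\sqrt{\pi/2}}.
#'
#' The pairwise-subtraction design cancels any per-voxel offset that is common
#' across directions, so slow spatial structure in the ROI does not bias the
#' estimate.
#'
#' @param roi_signals numeric matrix, voxels x directions (>= 2 columns,
#'   >= 2 rows), magnitude signal.
#' @param sqrt2_correction divide the pooled difference SD by sqrt(2)
#'   (default `TRUE`).
#' @return an object of class `noise_estimate`: list with `sigma`, `mu_r`,
#'   `n_voxels`, `n_directions`.
#' @export
estimate_sigma <- function(roi_signals, sqrt2_correction = TRUE) {
  roi_signals <- as.matrix(roi_signals)
  if (ncol(roi_signals) < 2L)
    stop("need >= 2 gradient directions to form differences", call. = FALSE)
  if (nrow(roi_signals) < 2L)
    stop("need >= 2 voxels in the noise ROI", call. = FALSE)
  if (any(!is.finite(roi_signals)))
    stop("non-finite values in noise ROI", call. = FALSE)
  nd <- ncol(roi_signals)
  diffs <- vector("list", nd * (nd - 1L) / 2L)
  k <- 1L
  for (i in 1:(nd - 1L)) for (j in (i + 1L):nd) {
    diffs[[k]] <- roi_signals[, i] - roi_signals[, j]
    k <- k + 1L
  }
  pooled <- unlist(diffs, use.names = FALSE)
  sigma <- stats::sd(pooled)
  if (sqrt2_correction) sigma <- sigma / sqrt(2)
  structure(list(sigma = sigma, mu_r = sigma * sqrt(pi / 2),
                 n_voxels = nrow(roi_signals), n_directions = nd),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "Noise estimate: sigma = %g, mu_R = %g (%d voxels, %d directions)\n",
    x$sigma, x$mu_r, x$n_voxels, x$n_directions))
  invisible(x)
}

#' Rician noise-floor correction
#'
#' Removes the Rician floor from magnitude signal by quadrature subtraction,
#' \eqn{S_C = \sqrt{S^2 - \mu_R^2}}.  Entries with \eqn{S < \mu_R} (where the
#' subtraction would be imaginary) are clamped to 0 and counted; downstream
#' log-space fitting must exclude clamped points.
#'
#' @param s magnitude signal array (any shape), >= 0.
#' @param mu_r mean Rician floor (>= 0), either a scalar or a
#'   `noise_estimate`.
#' @return corrected array with attributes `n_clamped` (count) and `clamped`
#'   (logical array flagging clamped entries).
#' @export
correct_rician <- function(s, mu_r) {
  if (inherits(mu_r, "noise_estimate")) mu_r <- mu_r$mu_r
  if (!is.finite(mu_r) || mu_r < 0)
    stop("`mu_r` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(s)) || any(s < 0))
    stop("magnitude signal must be finite and >= 0", call. = FALSE)
  clamped <- s < mu_r
  out <- sqrt(pmax(s^2 - mu_r^2, 0))
  attributes(out) <- attributes(s)
  attr(out, "clamped") <- clamped
  attr(out, "n_clamped") <- sum(clamped)
  out
}

# run `expr` with a private RNG stream, leaving the caller's RNG untouched
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate Rician magnitude noise
#'
#' Applies the two-channel magnitude noise model
#' \eqn{S' = \sqrt{(S + g_1)^2 + g_2^2}} with independent zero-mean Gaussian
#' streams \eqn{g_1, g_2} of standard deviation `sigma`, reproducibly derived
#' from `seed`.  The caller's RNG state is preserved.
#'
#' @param signal noiseless signal array (>= 0).
#' @param sigma Gaussian channel noise SD (>= 0).
#' @param seed integer seed; identical seeds give identical output.
#' @return noisy magnitude array of the same shape.
#' @export
add_rician_noise <- function(signal, sigma, seed) {
  if (!is.finite(sigma) || sigma < 0)
    stop("`sigma` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("`signal` must be finite and >= 0", call. = FALSE)
  if (sigma == 0) return(signal)
  n <- length(signal)
  .with_seed(seed, {
    g1 <- stats::rnorm(n, 0, sigma)
    g2 <- stats::rnorm(n, 0, sigma)
    out <- sqrt((signal + g1)^2 + g2^2)
    attributes(out) <- attributes(signal)
    out
  })
}
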