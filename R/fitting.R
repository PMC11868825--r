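#' Per-voxel decay curve
#'
#' Orientationally averaged normalized signal versus b-value for one voxel.
#' Points are stored in ascending b order; `valid` flags points usable by the
#' log-space fit (positive signal, not Rician-clamped).
#'
#' @param b b-values, s/mm^2.
#' @param s_norm normalized signal (S/S0).
#' @param valid logical usability flags (default: finite and positive signal).
#' @return an object of class `decay_curve`.
#' @export
decay_curve <- function(b, s_norm, valid = NULL) {
  if (length(b) != length(s_norm))
    stop("`b` and `s_norm` must have equal length", call. = FALSE)
  if (any(!is.finite(b)) || any(b < 0))
    stop("b-values must be finite and >= 0", call. = FALSE)
  if (is.null(valid)) valid <- is.finite(s_norm) & s_norm > 0
  ord <- order(b)
  structure(list(b = b[ord], s_norm = s_norm[ord], valid = valid[ord]),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("Decay curve: %d points (b in [%g, %g] s/mm^2), %d valid\n",
              length(x$b), min(x$b), max(x$b), sum(x$valid)))
  invisible(x)
}

# group b-values into shells: values within `tol` s/mm^2 are one shell
.group_shells <- function(bvals, tol = 50) {
  ub <- sort(unique(bvals))
  grp_of_ub <- cumsum(c(1L, as.integer(diff(ub) > tol)))
  centers <- as.numeric(tapply(ub, grp_of_ub, mean))
  idx <- grp_of_ub[match(bvals, ub)]
  list(centers = centers, shell = idx)
}

#' Orientationally average a 4-D dataset into per-voxel decay curves
#'
#' Groups volumes into b-shells (b-values within `shell_tol` s/mm^2 are one
#' shell), optionally applies the Rician floor correction per volume first,
#' then averages signal over each shell's directions per voxel.  S0 is the
#' mean over all b = 0 volumes; normalized curves are shell mean / S0.
#' Rician-clamped direction samples are excluded from shell means; shells with
#' no usable directions, non-positive means, or a non-positive S0 are flagged
#' invalid.
#'
#' @param dwi 4-D array (x, y, z, volume) of magnitude signal.
#' @param scheme an [acquisition_scheme] matching the 4th dimension.
#' @param mu_r Rician floor to subtract (scalar or `noise_estimate`); `NULL`
#'   (default) disables correction.
#' @param shell_tol shell grouping tolerance, s/mm^2 (default 50).
#' @return an object of class `decay_set`: `b` (shell centers, ascending,
#'   including 0), `s_norm` (4-D array x, y, z, shell), `valid` (same shape),
#'   `n_clamped` (count of clamped direction samples).
#' @export
powder_average <- function(dwi, scheme, mu_r = NULL, shell_tol = 50) {
  if (length(dim(dwi)) != 4L)
    stop("`dwi` must be a 4-D array", call. = FALSE)
  if (!inherits(scheme, "acquisition_scheme"))
    stop("`scheme` must be an acquisition_scheme", call. = FALSE)
  if (dim(dwi)[4] != length(scheme$bvals))
    stop("volume count does not match scheme length", call. = FALSE)
  sh <- .group_shells(scheme$bvals, shell_tol)
  b0_shell <- which(sh$centers <= shell_tol)[1]
  if (is.na(b0_shell) || sh$centers[b0_shell] > shell_tol)
    stop("no b = 0 volume: cannot normalize", call. = FALSE)
  spatial <- dim(dwi)[1:3]
  nvox <- prod(spatial)
  nvol <- dim(dwi)[4]
  flat <- matrix(dwi, nvox, nvol)
  n_clamped <- 0L
  raw <- flat
  if (!is.null(mu_r)) {
    if (inherits(mu_r, "noise_estimate")) mu_r <- mu_r$mu_r
    flat <- correct_rician(flat, mu_r)
    n_clamped <- attr(flat, "n_clamped")
  }
  # clamped direction samples enter the shell mean as 0 (dropping them would
  # bias low-SNR shell means upward)
  ns <- length(sh$centers)
  smean <- matrix(NA_real_, nvox, ns)
  rawmean <- matrix(NA_real_, nvox, ns)
  ndir <- integer(ns)
  for (s in seq_len(ns)) {
    cols <- which(sh$shell == s)
    ndir[s] <- length(cols)
    smean[, s] <- rowMeans(flat[, cols, drop = FALSE])
    rawmean[, s] <- rowMeans(raw[, cols, drop = FALSE])
  }
  s0 <- smean[, b0_shell]
  s_norm <- smean / s0
  valid <- is.finite(s_norm) & s_norm > 0 & s0 > 0
  # noise-floor-clamped points are excluded from log-space fitting: a shell
  # whose uncorrected mean is not significantly above the Rician floor mu_R
  # (one-sided 5%: 1.65 standard errors; the sd of a floor-level magnitude
  # sample is sigma sqrt(2 - pi/2) ~ 0.655 sigma) carries no signal
  # information, and a single floor-level point can dominate the log-space
  # alpha estimate
  if (!is.null(mu_r) && mu_r > 0) {
    sigma <- mu_r / sqrt(pi / 2)
    thresh <- mu_r + 1.65 * sqrt(2 - pi / 2) * sigma / sqrt(ndir)
    valid <- valid & rawmean > rep(thresh, each = nvox)
  }
  # replace the b0 shell center by exactly 0 for the anchor point
  b <- sh$centers
  b[b0_shell] <- 0
  structure(list(b = b, s_norm = array(s_norm, c(spatial, ns)),
                 valid = array(valid, c(spatial, ns)),
                 n_clamped = n_clamped), class = "decay_set")
}

#' Extract one voxel's decay curve from a decay set
#'
#' @param set a `decay_set` from [powder_average()].
#' @param i,j,k voxel indices.
#' @return a [decay_curve].
#' @export
get_curve <- function(set, i, j, k) {
  if (!inherits(set, "decay_set")) stop("`set` must be a decay_set",
                                        call. = FALSE)
  decay_curve(set$b, set$s_norm[i, j, k, ], set$valid[i, j, k, ])
}

.default_bounds <- function() {
  list(d12 = c(1e-5, 1e-2), alpha = c(0.05, 1))
}

#' Fit the QDI parameters to a decay curve
#'
#' Bounded nonlinear least squares in log-signal space: minimizes
#' \deqn{\sum_i \big[\ln s_i - \ln E_\alpha(-(D_{1,2} b_i)^\alpha)\big]^2}
#' over valid points by projected quasi-Newton (L-BFGS-B) on
#' \eqn{(\ln D_{1,2}, \alpha)} within the bound box.  Unweighted log-space
#' residuals balance the fit across several orders of magnitude of signal
#' decay.  D12 is initialized from the monoexponential slope of the lowest
#' non-zero b point, alpha at 0.9, with a second start at alpha = 0.5 as
#' insurance against the optimizer stalling on low-alpha (white-matter-like)
#' curves; the better minimum is kept.
#'
#' @param curve a [decay_curve] with >= 3 valid points at b > 0.
#' @param bounds list with `d12` and `alpha` ranges (defaults
#'   D12 in \[1e-5, 1e-2\] mm^2/s, alpha in \[0.05, 1\]).
#' @param init optional [qdi_params] starting point (replaces the automatic
#'   initialization).
#' @param ip_table optional [build_ip_table()] table for fast inflection-point
#'   lookup; `NULL` solves directly.
#' @param maxit maximum optimizer iterations.
#' @return an object of class `qdi_fit`: `params`, `mse_log`, `ip`,
#'   `converged`, `n_points`.
#' @export
fit_decay <- function(curve, bounds = .default_bounds(), init = NULL,
                      ip_table = NULL, maxit = 500L) {
  if (!inherits(curve, "decay_curve")) stop("`curve` must be a decay_curve",
                                            call. = FALSE)
  use <- curve$valid & curve$b > 0
  if (sum(use) < 3L)
    stop("insufficient data: need >= 3 valid points with b > 0",
         call. = FALSE)
  b <- curve$b[use]
  ls <- log(curve$s_norm[use])
  lo <- c(log(bounds$d12[1]), bounds$alpha[1])
  hi <- c(log(bounds$d12[2]), bounds$alpha[2])
  obj <- function(theta) {
    # clamp: numerical gradients may probe just outside the box
    d <- exp(min(max(theta[1], lo[1]), hi[1]))
    a <- min(max(theta[2], lo[2]), hi[2])
    model <- log(mlf(-(d * b)^a, a, 1))
    sum((ls - model)^2)
  }
  starts <- if (!is.null(init)) {
    init <- .as_qdi_params(init)
    list(c(log(init$d12), init$alpha))
  } else {
    d0 <- -ls[1] / b[1]
    d0 <- min(max(d0, bounds$d12[1] * 1.01), bounds$d12[2] * 0.99)
    # three starts: generic, low-alpha (white-matter-like) and the exact
    # Gaussian boundary (the MLF develops a boundary layer as alpha -> 1,
    # so alpha = 1 data is only reachable from the bound itself)
    list(c(log(d0), min(0.9, bounds$alpha[2])),
         c(log(d0), max(0.5, bounds$alpha[1])),
         c(log(d0), bounds$alpha[2]))
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lo), hi)
    res <- stats::optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = maxit, factr = 1e7,
                                       pgtol = 1e-10, ndeps = rep(1e-7, 2)))
    if (is.null(best) || res$value < best$value) best <- res
    if (best$value < 1e-20) break
  }
  # derivative-free polish: robust near the alpha -> 1 boundary layer and
  # refines the projected-gradient solution to full precision
  pol <- stats::optim(pmin(pmax(best$par, lo), hi), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 400L, reltol = 1e-14))
  conv <- best$convergence == 0 || pol$convergence == 0
  if (pol$value <= best$value)
    best <- list(par = pmin(pmax(pol$par, lo), hi), value = pol$value)
  best$convergence <- if (conv) 0L else 1L
  params <- qdi_params(exp(best$par[1]), best$par[2])
  ip <- if (!is.null(ip_table)) {
    tryCatch(lookup_ip(ip_table, params), error = function(e) find_ip(params))
  } else {
    find_ip(params)
  }
  structure(list(params = params, mse_log = best$value / sum(use), ip = ip,
                 converged = best$convergence == 0, n_points = sum(use)),
            class = "qdi_fit")
}

#' @export
print.qdi_fit <- function(x, ...) {
  cat(sprintf(paste0("QDI fit: D1,2 = %.4g mm^2/s, alpha = %.4g, ",
                     "IP = %s s/mm^2, MSE(ln) = %.3g (%d points%s)\n"),
              x$params$d12, x$params$alpha,
              if (is.na(x$ip)) "undefined" else sprintf("%.4g", x$ip),
              x$mse_log, x$n_points,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Log-space mean squared error of a parameter pair against a curve
#'
#' Mean over valid b > 0 points of the squared difference between the log of
#' the observed normalized signal and the log of the model attenuation.
#' Evaluating parameters fitted on a truncated b-range against the full-range
#' curve quantifies extrapolation quality.
#'
#' @inheritParams qdi_attenuation
#' @param curve a [decay_curve] with at least one valid b > 0 point.
#' @return mean squared log-residual (unitless).
#' @export
mse_log <- function(params, curve) {
  params <- .as_qdi_params(params)
  if (!inherits(curve, "decay_curve")) stop("`curve` must be a decay_curve",
                                            call. = FALSE)
  use <- curve$valid & curve$b > 0
  if (!any(use)) stop("no valid b > 0 points", call. = FALSE)
  b <- curve$b[use]
  mean((log(curve$s_norm[use]) - log(qdi_attenuation(b, params)))^2)
}

#' Parameter map container
#'
#' Co-registered 3-D maps of D12, alpha, inflection point and log-space fit
#' MSE, plus the mask of fitted voxels.  Values are defined only inside the
#' mask; `NA` is the sentinel elsewhere and for undefined inflection points.
#'
#' @param d12,alpha,ip,mse 3-D numeric arrays of identical shape.
#' @param mask 3-D logical array of the same shape.
#' @return an object of class `parameter_maps`.
#' @export
parameter_maps <- function(d12, alpha, ip, mse, mask) {
  dm <- dim(d12)
  if (length(dm) != 3L)
    stop("maps must be 3-D arrays", call. = FALSE)
  for (m in list(alpha, ip, mse, mask))
    if (!identical(dim(m), dm)) stop("map shape mismatch", call. = FALSE)
  structure(list(d12 = d12, alpha = alpha, ip = ip, mse = mse,
                 mask = mask), class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("Parameter maps %s: %d voxels in mask\n",
              paste(dim(x$d12), collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Fit QDI parameter maps over a masked volume
#'
#' Applies [powder_average()] then [fit_decay()] per masked voxel and
#' assembles [parameter_maps].  Inflection points come from a precomputed
#' lookup table (built once and cached per session) with a direct
#' [find_ip()] fall-back outside the table range.  The procedure is
#' deterministic: identical inputs give identical maps.
#'
#' @param dwi 4-D magnitude array.
#' @param scheme an [acquisition_scheme].
#' @param mask 3-D logical array (default: all voxels).
#' @param mu_r optional Rician floor for correction (see [powder_average()]).
#' @param bounds,maxit passed to [fit_decay()].
#' @param use_ip_table use the cached lookup table for IPs (default `TRUE`).
#' @return a [parameter_maps] object.
#' @export
fit_volume <- function(dwi, scheme, mask = NULL, mu_r = NULL,
                       bounds = .default_bounds(), maxit = 500L,
                       use_ip_table = TRUE) {
  set <- powder_average(dwi, scheme, mu_r = mu_r)
  spatial <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, spatial)
  if (!identical(dim(mask), spatial))
    stop("mask shape does not match image", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  tab <- if (use_ip_table) .default_ip_table() else NULL
  d12 <- alpha <- ip <- mse <- array(NA_real_, spatial)
  fitted <- array(FALSE, spatial)
  for (idx in which(mask)) {
    ijk <- arrayInd(idx, spatial)
    curve <- get_curve(set, ijk[1], ijk[2], ijk[3])
    fit <- tryCatch(fit_decay(curve, bounds = bounds, ip_table = tab,
                              maxit = maxit),
                    error = function(e) NULL)
    if (is.null(fit)) next   # voxel left at the sentinel, run continues
    d12[idx] <- fit$params$d12
    alpha[idx] <- fit$params$alpha
    ip[idx] <- fit$ip
    mse[idx] <- fit$mse_log
    fitted[idx] <- TRUE
  }
  parameter_maps(d12, alpha, ip, mse, fitted)
}

# session-cached default lookup table (covers the default fit bounds in alpha;
# d12 above 3e-3 falls back to find_ip inside fit_decay)
.default_ip_table <- function() {
  tab <- .qdimri_cache[["default_ip_table"]]
  if (is.null(tab)) {
    tab <- build_ip_table()
    .qdimri_cache[["default_ip_table"]] <- tab
  }
  tab
}
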