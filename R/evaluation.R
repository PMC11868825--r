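#' Truncated-range (b_max) fitting sweep
#'
#' For each maximum b-value in `bmax_list`, refits the curve(s) using only
#' points with b <= bmax and scores the fitted parameters on the full b-value
#' range with [mse_log()].  This quantifies how parameter estimates stabilize
#' as the fitting range approaches and crosses the signal inflection point
#' (alpha estimates are biased toward the Gaussian exponent 1 when bmax is
#' too low).
#'
#' @param curves a [decay_curve] or list of them.
#' @param bmax_list ascending maximum b-values, s/mm^2.
#' @param ... passed to [fit_decay()].
#' @return a data.frame with columns `bmax`, `curve`, `d12`, `alpha`, `ip`,
#'   `mse_full` (full-range score), `mse_fit` (truncated-range MSE) and
#'   `converged`.  bmax values retaining fewer than 3 non-zero points are
#'   skipped with a warning.
#' @export
bmax_sweep <- function(curves, bmax_list, ...) {
  if (inherits(curves, "decay_curve")) curves <- list(curves)
  if (is.unsorted(bmax_list)) stop("`bmax_list` must be ascending",
                                   call. = FALSE)
  rows <- list()
  for (bm in bmax_list) {
    for (ci in seq_along(curves)) {
      cv <- curves[[ci]]
      keep <- cv$b <= bm
      sub <- decay_curve(cv$b[keep], cv$s_norm[keep], cv$valid[keep])
      if (sum(sub$valid & sub$b > 0) < 3L) {
        warning(sprintf("bmax = %g retains < 3 non-zero points; skipped", bm),
                call. = FALSE)
        next
      }
      fit <- fit_decay(sub, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        bmax = bm, curve = ci, d12 = fit$params$d12,
        alpha = fit$params$alpha, ip = fit$ip,
        mse_full = mse_log(fit$params, cv), mse_fit = fit$mse_log,
        converged = fit$converged)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC for a
#' paired table (two raters/protocols per subject).  With mean squares from
#' the two-way ANOVA decomposition (MSR between subjects, MSC between raters,
#' MSE residual; n subjects, k = 2 raters):
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}.}
#' Bounded above by 1; equals 1 for identical non-constant vectors.
#'
#' @param x,y paired measurement vectors of equal length >= 2.
#' @return the ICC estimate.
#' @export
icc <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("need >= 2 complete pairs", call. = FALSE)
  k <- 2
  dat <- cbind(x, y)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  grand <- mean(dat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Compare parameter maps from two acquisition protocols
#'
#' Voxelwise agreement between maps fitted from a subset protocol and from
#' the full protocol: bias (mean of subset minus full), uncertainty (standard
#' deviation of the voxelwise difference), ICC(2,1) and Pearson correlation,
#' per parameter (D12, alpha, IP).  Voxels carrying the `NA` sentinel in
#' either map are excluded pairwise per parameter, so undefined inflection
#' points do not void the D12/alpha comparisons.
#'
#' @param maps_full,maps_subset [parameter_maps] of identical geometry.
#' @param mask optional 3-D logical restriction (default: both masks).
#' @return a data.frame with one row per parameter: `parameter`, `bias`,
#'   `uncertainty`, `icc`, `pearson`, `n_voxels`.
#' @export
compare_protocols <- function(maps_full, maps_subset, mask = NULL) {
  for (m in list(maps_full, maps_subset))
    if (!inherits(m, "parameter_maps"))
      stop("inputs must be parameter_maps", call. = FALSE)
  if (!identical(dim(maps_full$d12), dim(maps_subset$d12)))
    stop("geometry mismatch between map sets", call. = FALSE)
  if (is.null(mask)) mask <- maps_full$mask & maps_subset$mask
  if (!identical(dim(mask), dim(maps_full$d12)))
    stop("geometry mismatch for mask", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  rows <- lapply(c("d12", "alpha", "ip"), function(par) {
    xf <- maps_full[[par]][mask]
    xs <- maps_subset[[par]][mask]
    ok <- is.finite(xf) & is.finite(xs)
    if (sum(ok) < 2L)
      return(data.frame(parameter = par, bias = NA_real_,
                        uncertainty = NA_real_, icc = NA_real_,
                        pearson = NA_real_, n_voxels = sum(ok)))
    d <- xs[ok] - xf[ok]
    data.frame(parameter = par, bias = mean(d), uncertainty = stats::sd(d),
               icc = icc(xf[ok], xs[ok]),
               pearson = stats::cor(xf[ok], xs[ok]),
               n_voxels = sum(ok))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' ROI summary statistics
#'
#' Median and quartiles (linear interpolation between order statistics,
#' `stats::quantile` type 7) of a parameter map over the defined
#' (non-sentinel) voxels of a region of interest.
#'
#' @param map 3-D numeric array.
#' @param roi 3-D logical array of the same shape.
#' @return list with `median`, `q25`, `q75`, `n` (defined voxels used) and
#'   `n_excluded` (sentinel voxels inside the ROI).
#' @export
roi_stats <- function(map, roi) {
  if (!identical(dim(map), dim(roi)))
    stop("`map` and `roi` shapes differ", call. = FALSE)
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  v <- map[roi]
  ok <- is.finite(v)
  if (!any(ok)) stop("ROI contains no defined voxels", call. = FALSE)
  q <- stats::quantile(v[ok], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3], n = sum(ok),
       n_excluded = sum(!ok))
}
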