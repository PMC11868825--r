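#' Acquisition scheme
#'
#' Container for a multi-shell diffusion acquisition: per-volume b-values
#' (s/mm^2), unit gradient directions (3 x n matrix, zero columns for b = 0
#' volumes) and the gradient timing metadata delta (duration) and Delta
#' (separation), both in ms.  Timings are metadata only; they do not enter any
#' computation.
#'
#' @param bvals numeric vector of b-values, s/mm^2 (>= 0).
#' @param bvecs 3 x n matrix of gradient directions; non-zero-b columns must
#'   have unit norm (tolerance 1e-6).
#' @param delta_small gradient duration delta, ms.
#' @param delta_big gradient separation Delta, ms.
#' @return an object of class `acquisition_scheme`.
#' @export
acquisition_scheme <- function(bvals, bvecs, delta_small = NA_real_,
                               delta_big = NA_real_) {
  bvals <- as.numeric(bvals)
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and >= 0", call. = FALSE)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals))
    stop("`bvecs` must be a 3 x length(bvals) matrix", call. = FALSE)
  nrm <- sqrt(colSums(bvecs^2))
  nz <- bvals > 0
  if (any(abs(nrm[nz] - 1) > 1e-6))
    stop("non-zero-b gradient directions must have unit norm", call. = FALSE)
  structure(list(bvals = bvals, bvecs = bvecs, delta_small = delta_small,
                 delta_big = delta_big), class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  sh <- .group_shells(x$bvals)
  nz <- sh$centers > 0
  cat(sprintf(
    "Acquisition scheme: %d volumes, %d b=0, %d shells (max b = %g s/mm^2)\n",
    length(x$bvals), sum(x$bvals == 0), sum(nz), max(sh$centers)))
  if (is.finite(x$delta_small))
    cat(sprintf("  delta/Delta = %g/%g ms\n", x$delta_small, x$delta_big))
  invisible(x)
}

# Near-uniform points on the sphere: golden-angle spiral followed by a
# seed-derived random rotation (deterministic given seed).
.sphere_dirs <- function(n, seed) {
  k <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * k
  cost <- 1 - 2 * k / n
  sint <- sqrt(pmax(1 - cost^2, 0))
  pts <- rbind(sint * cos(phi), sint * sin(phi), cost)
  rot <- .with_seed(seed, qr.Q(qr(matrix(stats::rnorm(9), 3))))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  rot %*% pts
}

#' Acquisition scheme presets
#'
#' Returns the b-value tables of the three reference protocols (plus a
#' 4-b-value short subset of the first):
#' \describe{
#'   \item{dataset1}{in vivo human, 6 x b=0 plus 11 shells at b = 400, 800,
#'     1200, 2000, 3000, 4000, 6000, 8000, 10000, 12000, 15000 s/mm^2 with
#'     16, 16, 21, 31, 21, 21, 31, 31, 31, 31, 46 directions;
#'     delta/Delta = 12/23 ms.}
#'   \item{dataset1_short}{the clinically feasible subset
#'     b = 0, 1200, 4000, 15000 s/mm^2 (same per-shell direction counts).}
#'   \item{dataset2}{in vivo human, 50 x b=0 plus shells at b = 200, 950,
#'     2300, 4250, 6750, 9850, 13500, 17800 s/mm^2; 32 directions below
#'     b = 2400, 64 at or above; delta/Delta = 8/49 ms.}
#'   \item{dataset3}{ex vivo rat, single direction at b = 0, 1000, 2000,
#'     3000, 6000, 9000, 12000, 15000, 18000, 21000, 25000 s/mm^2;
#'     delta/Delta = 3.5/17.5 ms.}
#' }
#' Gradient direction tables are not part of the published protocols, so
#' directions are synthesized near-uniformly on the sphere from `seed`.
#'
#' @param preset one of `"dataset1"`, `"dataset1_short"`, `"dataset2"`,
#'   `"dataset3"`.
#' @param seed integer seed for direction synthesis.
#' @return an [acquisition_scheme].
#' @export
make_scheme <- function(preset = c("dataset1", "dataset1_short", "dataset2",
                                   "dataset3"), seed = 1L) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    dataset1 = list(
      n_b0 = 6L,
      b = c(400, 800, 1200, 2000, 3000, 4000, 6000, 8000, 10000, 12000,
            15000),
      ndir = c(16L, 16L, 21L, 31L, 21L, 21L, 31L, 31L, 31L, 31L, 46L),
      delta = 12, Delta = 23),
    dataset1_short = list(
      n_b0 = 6L,
      b = c(1200, 4000, 15000),
      ndir = c(21L, 21L, 46L),
      delta = 12, Delta = 23),
    dataset2 = list(
      n_b0 = 50L,
      b = c(200, 950, 2300, 4250, 6750, 9850, 13500, 17800),
      ndir = ifelse(c(200, 950, 2300, 4250, 6750, 9850, 13500,
                      17800) < 2400, 32L, 64L),
      delta = 8, Delta = 49),
    dataset3 = list(
      n_b0 = 1L,
      b = c(1000, 2000, 3000, 6000, 9000, 12000, 15000, 18000, 21000, 25000),
      ndir = rep(1L, 10L),
      delta = 3.5, Delta = 17.5))
  bvals <- c(rep(0, spec$n_b0), rep(spec$b, spec$ndir))
  vecs <- matrix(0, 3, spec$n_b0)
  for (i in seq_along(spec$b)) {
    d <- if (spec$ndir[i] == 1L) matrix(c(0, 1, 0), 3) else
      .sphere_dirs(spec$ndir[i], seed + i)
    vecs <- cbind(vecs, d)
  }
  acquisition_scheme(bvals, vecs, spec$delta, spec$Delta)
}

#' Phantom specification
#'
#' Describes a piecewise-constant synthetic parameter image: image shape,
#' disjoint labelled regions with ground-truth (D12, alpha), the b=0
#' signal-to-noise ratio defining the Rician noise level, and a seed.
#'
#' @param shape integer 3-vector of image dimensions.
#' @param regions list of regions, each a list with fields `label`,
#'   `d12`, `alpha` and `mask` (logical array of dimension `shape`).
#' @param snr_b0 SNR at b = 0 (sets sigma = s0 / snr_b0); `Inf` for
#'   noise-free.
#' @param seed integer noise seed.
#' @param s0 b = 0 signal amplitude (arbitrary units).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, regions, snr_b0 = 50, seed = 42L, s0 = 100) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("`shape` must be 3 positive dimensions", call. = FALSE)
  taken <- array(FALSE, shape)
  for (r in regions) {
    stopifnot(is.list(r), !is.null(r$label), !is.null(r$d12),
              !is.null(r$alpha), !is.null(r$mask))
    qdi_params(r$d12, r$alpha)  # validates truth values
    if (!identical(dim(r$mask), dim(taken)))
      stop("region mask shape mismatch", call. = FALSE)
    if (any(taken & r$mask))
      stop("regions must be disjoint", call. = FALSE)
    taken <- taken | r$mask
  }
  if (!is.finite(snr_b0) && !is.infinite(snr_b0))
    stop("`snr_b0` must be positive or Inf", call. = FALSE)
  if (snr_b0 <= 0) stop("`snr_b0` must be positive", call. = FALSE)
  structure(list(shape = shape, regions = regions, snr_b0 = snr_b0,
                 seed = as.integer(seed), s0 = s0), class = "phantom_spec")
}

#' Default three-tissue phantom
#'
#' Three equal slabs along the first axis with ground truth near reported
#' in vivo tissue medians: grey-matter-like (D12 = 0.8e-3 mm^2/s,
#' alpha = 0.88), white-matter-like (0.7e-3, 0.75) and CSF-like (3.0e-3,
#' alpha = 1, Gaussian).
#'
#' @inheritParams phantom_spec
#' @return a [phantom_spec].
#' @export
default_phantom_spec <- function(shape = c(12L, 12L, 3L), snr_b0 = 50,
                                 seed = 42L, s0 = 100) {
  shape <- as.integer(shape)
  slab <- function(lo, hi) {
    m <- array(FALSE, shape)
    m[lo:hi, , ] <- TRUE
    m
  }
  cut1 <- max(1L, floor(shape[1] / 3))
  cut2 <- max(cut1 + 1L, floor(2 * shape[1] / 3))
  regions <- list(
    list(label = "GM",  d12 = 0.8e-3, alpha = 0.88,
         mask = slab(1L, cut1)),
    list(label = "WM",  d12 = 0.7e-3, alpha = 0.75,
         mask = slab(cut1 + 1L, cut2)),
    list(label = "CSF", d12 = 3.0e-3, alpha = 1.00,
         mask = slab(cut2 + 1L, shape[1])))
  phantom_spec(shape, regions, snr_b0 = snr_b0, seed = seed, s0 = s0)
}

#' Generate a synthetic multi-shell dataset with known ground truth
#'
#' Simulates a 4-D magnitude dataset: per voxel the QDI forward model
#' evaluated at the scheme's b-values (identical in every direction - the
#' phantom is isotropic, matching the orientational averaging used in
#' fitting), scaled by `s0`, with Rician noise at sigma = s0 / snr_b0.
#' Ground-truth parameter maps, including the analytic inflection point per
#' region, are returned alongside.
#'
#' @param spec a [phantom_spec].
#' @param scheme an [acquisition_scheme].
#' @return list with `dwi` (4-D array), `scheme`, `truth` (a
#'   [parameter_maps] object), `sigma` (noise SD) and `spec`.
#' @examples
#' ph <- make_phantom(default_phantom_spec(snr_b0 = Inf),
#'                    make_scheme("dataset1_short"))
#' dim(ph$dwi)
#' @export
make_phantom <- function(spec, scheme) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec",
                                            call. = FALSE)
  if (!inherits(scheme, "acquisition_scheme"))
    stop("`scheme` must be an acquisition_scheme", call. = FALSE)
  nvol <- length(scheme$bvals)
  dwi <- array(0, c(spec$shape, nvol))
  d12_map <- array(NA_real_, spec$shape)
  alpha_map <- array(NA_real_, spec$shape)
  ip_map <- array(NA_real_, spec$shape)
  mask <- array(FALSE, spec$shape)
  nxyz <- prod(spec$shape)
  dwi_flat <- matrix(0, nxyz, nvol)
  for (r in spec$regions) {
    p <- qdi_params(r$d12, r$alpha)
    sig <- spec$s0 * qdi_attenuation(scheme$bvals, p)
    idx <- which(r$mask)
    dwi_flat[idx, ] <- matrix(sig, length(idx), nvol, byrow = TRUE)
    d12_map[idx] <- r$d12
    alpha_map[idx] <- r$alpha
    ip_map[idx] <- find_ip(p)
    mask[idx] <- TRUE
  }
  sigma <- if (is.infinite(spec$snr_b0)) 0 else spec$s0 / spec$snr_b0
  if (sigma > 0)
    dwi_flat <- add_rician_noise(dwi_flat, sigma, spec$seed)
  dwi <- array(dwi_flat, c(spec$shape, nvol))
  truth <- parameter_maps(d12 = d12_map, alpha = alpha_map, ip = ip_map,
                          mse = array(NA_real_, spec$shape), mask = mask)
  list(dwi = dwi, scheme = scheme, truth = truth, sigma = sigma, spec = spec)
}
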