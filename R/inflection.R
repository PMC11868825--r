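#  Inflection point of the log-log QDI decay.
#
#  The curvature d^2 ln S / d(ln b)^2 depends on (b, d12) only through
#  u = d12 * b (equivalently through the MLF argument z = -u^alpha), so the
#  zero crossing is solved once per alpha in ln(-z) and rescaled to b.  This
#  is mathematically identical to the direct scan over ln b in (0, 50) in
#  steps of 0.001 and guarantees exact scale invariance d12 * IP = f(alpha).
#  Roots are cached per alpha within a session.

.qdimri_cache <- new.env(parent = emptyenv())

# ln(-z) at the curvature zero crossing for a given alpha, or NA if alpha is
# at/above the Gaussian limit.  fine_step is the ln b scan step (0.001 per the
# scan convention) mapped into ln(-z) units (multiplied by alpha).
.ip_zroot <- function(alpha, fine_step = 0.001) {
  if (alpha >= 1 - 1e-6) return(NA_real_)
  key <- sprintf("%.15g|%.6g", alpha, fine_step)
  hit <- .qdimri_cache[[key]]
  if (!is.null(hit)) return(hit)
  coarse <- seq(-15, 60, by = 0.25)
  nv <- .curvature_numerator(-exp(coarse), alpha)
  idx <- which(nv[-length(nv)] < 0 & nv[-1] >= 0)
  if (length(idx) == 0) {
    .qdimri_cache[[key]] <- NA_real_
    return(NA_real_)
  }
  i <- idx[1]
  # one extra step past the coarse bracket end: seq() stops short of the
  # upper bound when the step does not divide the interval
  fine <- seq(coarse[i], coarse[i + 1] + fine_step * alpha,
              by = fine_step * alpha)
  nf <- .curvature_numerator(-exp(fine), alpha)
  j <- which(nf[-length(nf)] < 0 & nf[-1] >= 0)[1]
  if (is.na(j)) {
    .qdimri_cache[[key]] <- NA_real_
    return(NA_real_)
  }
  # linear interpolation of the sign change between bracketing grid points
  root <- fine[j] - nf[j] * (fine[j + 1] - fine[j]) / (nf[j + 1] - nf[j])
  # guard against spurious crossings: for alpha <= 0.5 the log-log curvature
  # tends to 0 from below without a zero, and round-off in the tail fakes
  # sign changes at noise level (~1e-16).  A genuine root has normalized
  # curvature of at least ~1e-7 one ln-unit to either side (alpha = 0.5005);
  # require comfortably more than noise.
  curv <- function(lnx) {
    z <- -exp(lnx)
    .curvature_numerator(z, alpha) / mlf(z, alpha, 1)^2
  }
  if (!(curv(root - 1) < -1e-10 && curv(root + 1) > 1e-10)) {
    .qdimri_cache[[key]] <- NA_real_
    return(NA_real_)
  }
  .qdimri_cache[[key]] <- root
  root
}

#' b-value of the QDI signal inflection point
#'
#' Locates the b-value at which the second derivative of \eqn{\ln S} with
#' respect to \eqn{\ln b} crosses zero: the transition from the
#' stretched-exponential regime (concave in log-log space) to the negative
#' power-law regime (convex).  The zero crossing is scanned on a grid of step
#' `scan_step` in \eqn{\ln b} restricted to \eqn{0 < \ln b < 50} and refined
#' by linear interpolation between the bracketing grid points.
#'
#' Gaussian decay (`alpha = 1`, curvature strictly negative) has no inflection
#' point; `NA` is returned as the undefined sentinel, likewise whenever the
#' crossing falls outside the scan window (the representation should not be
#' extrapolated beyond acquired b-value ranges).
#'
#' @inheritParams qdi_attenuation
#' @param scan_step scan step in \eqn{\ln b} (default 0.001).
#' @return the inflection-point b-value in s/mm^2, or `NA_real_`.
#' @examples
#' find_ip(qdi_params(0.8e-3, 0.88))  # low-thousands s/mm^2 (grey matter)
#' find_ip(qdi_params(1e-3, 1))       # NA: Gaussian decay
#' @export
find_ip <- function(params, scan_step = 0.001) {
  params <- .as_qdi_params(params)
  lnz <- .ip_zroot(params$alpha, scan_step)
  if (is.na(lnz)) return(NA_real_)
  lnb <- lnz / params$alpha - log(params$d12)
  if (lnb <= 0 || lnb >= 50) return(NA_real_)
  exp(lnb)
}

#' Precomputed inflection-point lookup table
#'
#' Builds a grid of inflection-point b-values over (D12, alpha) for fast map
#' generation.  The default grid is log-spaced in D12 from 1e-5 to 3e-3 mm^2/s
#' (60 nodes) and linear in alpha from 0.30 to 0.995 (step 0.005, 140 nodes),
#' wide enough to cover fitted white-matter/corpus-callosum voxels (alpha down
#' to ~0.5) and low ex vivo diffusivities.  Entries equal [find_ip()] at the
#' grid nodes; undefined entries hold `NA`.
#'
#' @param d12_range range of D12 values, mm^2/s.
#' @param alpha_range range of alpha values (within (0, 1)).
#' @param d12_step step for an arithmetic D12 grid; if `NULL` (default) a
#'   log-spaced grid of `n_d12` nodes is used.
#' @param alpha_step alpha grid step (default 0.005).
#' @param n_d12 number of log-spaced D12 nodes when `d12_step` is `NULL`.
#' @param scan_step passed to [find_ip()].
#' @param refine_low add geometrically spaced alpha nodes just above 0.5,
#'   where the inflection point diverges (default `TRUE`).
#' @return an object of class `ip_table` with fields `d12`, `alpha`
#'   (ascending grids) and `ip` (matrix, D12 rows x alpha columns).
#' @export
build_ip_table <- function(d12_range = c(1e-5, 3e-3),
                           alpha_range = c(0.30, 0.995),
                           d12_step = NULL, alpha_step = 0.005,
                           n_d12 = 60L, scan_step = 0.001,
                           refine_low = TRUE) {
  if (length(d12_range) != 2L || any(d12_range <= 0) || diff(d12_range) <= 0)
    stop("`d12_range` must be an increasing positive interval", call. = FALSE)
  if (length(alpha_range) != 2L || any(alpha_range <= 0) ||
      any(alpha_range >= 1) || diff(alpha_range) <= 0)
    stop("`alpha_range` must be an increasing interval within (0, 1)",
         call. = FALSE)
  d12 <- if (is.null(d12_step)) {
    exp(seq(log(d12_range[1]), log(d12_range[2]), length.out = n_d12))
  } else {
    if (d12_step <= 0) stop("`d12_step` must be positive", call. = FALSE)
    seq(d12_range[1], d12_range[2], by = d12_step)
  }
  if (alpha_step <= 0) stop("`alpha_step` must be positive", call. = FALSE)
  alpha <- seq(alpha_range[1], alpha_range[2], by = alpha_step)
  if (refine_low && alpha_range[1] < 0.53 && alpha_range[2] > 0.5) {
    # the IP diverges as alpha -> 0.5+ (ln IP ~ -2 ln(alpha - 1/2) at fixed
    # D12); geometric nodes in (alpha - 1/2) keep the ln-interpolation error
    # of lookup_ip within its 1% contract near the boundary
    extra <- 0.5 + 5e-4 * 1.15^(0:32)
    extra <- extra[extra < min(0.53, alpha_range[2]) &
                     extra > alpha_range[1]]
    alpha <- sort(unique(c(alpha, extra)))
  }
  if (length(d12) < 1L || length(alpha) < 1L)
    stop("empty grid", call. = FALSE)
  ip <- matrix(NA_real_, length(d12), length(alpha))
  for (j in seq_along(alpha)) {
    lnz <- .ip_zroot(alpha[j], scan_step)
    if (is.na(lnz)) next
    lnb <- lnz / alpha[j] - log(d12)
    ok <- lnb > 0 & lnb < 50
    ip[ok, j] <- exp(lnb[ok])
  }
  structure(list(d12 = d12, alpha = alpha, ip = ip,
                 scan_step = scan_step), class = "ip_table")
}

#' @export
print.ip_table <- function(x, ...) {
  cat(sprintf(paste0("IP lookup table: %d D12 nodes [%g, %g] mm^2/s x ",
                     "%d alpha nodes [%g, %g]; %d undefined entries\n"),
              length(x$d12), min(x$d12), max(x$d12),
              length(x$alpha), min(x$alpha), max(x$alpha),
              sum(is.na(x$ip))))
  invisible(x)
}

#' Interpolated inflection-point lookup
#'
#' Bilinear interpolation of \eqn{\ln(IP)} over \eqn{(\ln D_{1,2}, \alpha)}
#' in a precomputed [build_ip_table()] grid.  Queries at grid nodes return the
#' node value exactly; the `NA` sentinel propagates if any corner of the
#' enclosing cell is undefined.  Queries outside the table range are an error
#' (callers fall back to [find_ip()]).
#'
#' @param table an `ip_table`.
#' @inheritParams qdi_attenuation
#' @return interpolated IP b-value (s/mm^2) or `NA_real_`.
#' @export
lookup_ip <- function(table, params) {
  if (!inherits(table, "ip_table")) stop("`table` must be an ip_table",
                                         call. = FALSE)
  params <- .as_qdi_params(params)
  if (params$alpha >= 1 - 1e-6) return(NA_real_)
  d <- params$d12; a <- params$alpha
  # above the table's alpha range the decay is closer to Gaussian than any
  # tabulated column: the undefined sentinel, not an error (the IP moves out
  # of any scanned window as alpha -> 1)
  if (a > max(table$alpha)) return(NA_real_)
  if (d < min(table$d12) || d > max(table$d12) || a < min(table$alpha))
    stop("query outside table range", call. = FALSE)
  i <- findInterval(d, table$d12, rightmost.closed = TRUE)
  j <- findInterval(a, table$alpha, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(table$d12) - 1L)
  j <- min(max(j, 1L), length(table$alpha) - 1L)
  corners <- table$ip[i + 0:1, j + 0:1]
  if (any(is.na(corners))) return(NA_real_)
  tx <- (log(d) - log(table$d12[i])) /
    (log(table$d12[i + 1]) - log(table$d12[i]))
  ty <- (a - table$alpha[j]) / (table$alpha[j + 1] - table$alpha[j])
  lip <- log(corners)
  v <- (1 - tx) * (1 - ty) * lip[1, 1] + tx * (1 - ty) * lip[2, 1] +
    (1 - tx) * ty * lip[1, 2] + tx * ty * lip[2, 2]
  exp(v)
}

#' Write / read an inflection-point table as plain text
#'
#' Serializes an `ip_table` to a tab-separated file with a commented metadata
#' header (axes, units, sentinel convention).  `NA` is the undefined-IP
#' sentinel on disk.
#'
#' @param table an `ip_table`.
#' @param path file path.
#' @return `write_ip_table` returns `path` invisibly; `read_ip_table` returns
#'   the reconstructed `ip_table`.
#' @export
write_ip_table <- function(table, path) {
  if (!inherits(table, "ip_table")) stop("`table` must be an ip_table",
                                         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# qdimri inflection-point lookup table",
    "# rows: D12 (mm^2/s), columns: alpha (unitless); values: IP b (s/mm^2)",
    "# sentinel: NA (inflection point undefined or outside 0 < ln b < 50)",
    sprintf("# scan_step: %g", table$scan_step),
    paste0("# alpha\t", paste(sprintf("%.10g", table$alpha), collapse = "\t"))
  ), con)
  for (i in seq_along(table$d12)) {
    writeLines(paste(c(sprintf("%.10g", table$d12[i]),
                       sprintf("%.10g", table$ip[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' @rdname write_ip_table
#' @export
read_ip_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  aline <- hdr[grepl("^# alpha\t", hdr)]
  if (length(aline) != 1L) stop("malformed ip_table file", call. = FALSE)
  alpha <- as.numeric(strsplit(sub("^# alpha\t", "", aline), "\t")[[1]])
  sline <- hdr[grepl("^# scan_step:", hdr)]
  scan_step <- if (length(sline)) as.numeric(sub("^# scan_step: *", "",
                                                sline[1])) else 0.001
  vals <- do.call(rbind, lapply(strsplit(body, "\t"), function(x) {
    x[x == "NA"] <- NA_character_
    as.numeric(x)
  }))
  structure(list(d12 = vals[, 1], alpha = alpha,
                 ip = vals[, -1, drop = FALSE], scan_step = scan_step),
            class = "ip_table")
}
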