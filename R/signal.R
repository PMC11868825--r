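#' QDI parameter pair
#'
#' Constructs and validates the quasi-diffusion parameter pair: the
#' quasi-diffusion coefficient `d12` (mm^2/s, > 0) and the fractional exponent
#' `alpha` (unitless, in (0, 1]; `alpha = 1` is Gaussian diffusion).  `alpha`
#' equals the negative power-law exponent of the signal at high b-values and
#' decreases with increasing microstructural heterogeneity.
#'
#' @param d12 quasi-diffusion coefficient, mm^2/s.
#' @param alpha fractional exponent in (0, 1].
#' @return an object of class `qdi_params` (named list `d12`, `alpha`).
#' @examples
#' qdi_params(0.8e-3, 0.88)  # typical cortical grey matter
#' @export
qdi_params <- function(d12, alpha) {
  if (!is.finite(d12) || d12 <= 0)
    stop("`d12` must be a finite value > 0 (mm^2/s)", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  structure(list(d12 = d12, alpha = alpha), class = "qdi_params")
}

#' @export
print.qdi_params <- function(x, ...) {
  cat(sprintf("QDI parameters: D1,2 = %g mm^2/s, alpha = %g\n", x$d12,
              x$alpha))
  invisible(x)
}

.as_qdi_params <- function(params) {
  if (inherits(params, "qdi_params")) return(params)
  if (is.numeric(params) && length(params) == 2L)
    return(qdi_params(params[[1]], params[[2]]))
  stop("`params` must be a qdi_params object or a (d12, alpha) pair",
       call. = FALSE)
}

# z = -(d12 * b)^alpha, the MLF argument; b in s/mm^2
.qdi_z <- function(b, params) -(params$d12 * b)^params$alpha

#' QDI signal attenuation (forward model)
#'
#' Normalized orientationally averaged signal
#' \deqn{S(b)/S_0 = E_\alpha\!\left(-(D_{1,2}\, b)^\alpha\right),}
#' the stretched Mittag-Leffler decay that interpolates between a stretched
#' exponential at low b and a negative power law with exponent \eqn{-\alpha}
#' at high b.  Equals 1 at b = 0 and is strictly decreasing in b.
#'
#' @param b b-values, s/mm^2 (>= 0).
#' @param params a [qdi_params] object (or `c(d12, alpha)`).
#' @return normalized signal in (0, 1], same length as `b`.
#' @examples
#' qdi_attenuation(c(0, 1000, 5000), qdi_params(0.8e-3, 0.88))
#' @export
qdi_attenuation <- function(b, params) {
  params <- .as_qdi_params(params)
  if (any(!is.finite(b)) || any(b < 0))
    stop("`b` must be finite and >= 0", call. = FALSE)
  mlf(.qdi_z(b, params), params$alpha, 1)
}

#' Asymptotic QDI signal regimes
#'
#' Low-b stretched-exponential and high-b power-law limits of the QDI decay:
#' \deqn{E_\alpha(-(Db)^\alpha) \sim \exp\!\big(-(Db)^\alpha/\Gamma(\alpha+1)\big)
#'   \quad (b \to 0),}
#' \deqn{E_\alpha(-(Db)^\alpha) \sim \frac{\sin(\alpha\pi)}{\pi}\,
#'   \frac{\Gamma(\alpha)}{(Db)^\alpha} \quad (b \to \infty).}
#' The high-b limit has log-log slope exactly \eqn{-\alpha}; it does not exist
#' for Gaussian decay (`alpha = 1`).
#'
#' @inheritParams qdi_attenuation
#' @param regime `"low_b"` or `"high_b"`.
#' @return normalized signal values of the requested asymptote.
#' @export
qdi_asymptote <- function(b, params, regime = c("low_b", "high_b")) {
  params <- .as_qdi_params(params)
  regime <- match.arg(regime)
  if (any(!is.finite(b)) || any(b <= 0))
    stop("`b` must be finite and > 0", call. = FALSE)
  u <- (params$d12 * b)^params$alpha
  if (regime == "low_b") {
    exp(-u / gamma(params$alpha + 1))
  } else {
    if (params$alpha >= 1)
      stop("high_b power-law asymptote does not exist for alpha = 1 ",
           "(Gaussian decay)", call. = FALSE)
    sinpi(params$alpha) * gamma(params$alpha) / (pi * u)
  }
}

#' Log-log slope of the QDI decay
#'
#' First derivative of \eqn{\ln S} with respect to \eqn{\ln b} (b referenced
#' to 1 s/mm^2):
#' \deqn{\frac{dy}{d\ln b} = \frac{E_{\alpha,0}(z)}{E_{\alpha,1}(z)}, \qquad
#'   z = -(D_{1,2} b)^\alpha.}
#' Negative for all b > 0 and tending to \eqn{-\alpha} as b grows
#' (for alpha < 1).
#'
#' @inheritParams qdi_attenuation
#' @return slope values (dimensionless).
#' @export
log_slope <- function(b, params) {
  params <- .as_qdi_params(params)
  if (any(!is.finite(b)) || any(b <= 0))
    stop("`b` must be finite and > 0", call. = FALSE)
  z <- .qdi_z(b, params)
  if (params$alpha == 1) return(z)
  mlf(z, params$alpha, 0) / mlf(z, params$alpha, 1)
}

#' Log-log curvature of the QDI decay
#'
#' Second derivative of \eqn{\ln S} with respect to \eqn{\ln b}:
#' \deqn{\frac{d^2y}{d\ln b^2} =
#'  \frac{\big(E_{\alpha,-1}(z) + E_{\alpha,0}(z)\big) E_{\alpha,1}(z)
#'        - E_{\alpha,0}(z)^2}{E_{\alpha,1}(z)^2}.}
#' For `alpha < 1` this changes sign exactly once (negative to positive) as b
#' increases; the zero crossing is the signal inflection point.  For
#' `alpha = 1` it reduces to \eqn{z = -D_{1,2} b} and is strictly negative.
#'
#' @inheritParams qdi_attenuation
#' @return curvature values (dimensionless).
#' @export
log_curvature <- function(b, params) {
  params <- .as_qdi_params(params)
  if (any(!is.finite(b)) || any(b <= 0))
    stop("`b` must be finite and > 0", call. = FALSE)
  z <- .qdi_z(b, params)
  if (params$alpha == 1) return(z)
  e1 <- mlf(z, params$alpha, 1)
  e0 <- mlf(z, params$alpha, 0)
  em <- mlf(z, params$alpha, -1)
  ((em + e0) * e1 - e0^2) / e1^2
}

# curvature numerator only (denominator E1^2 > 0); used by the root finder
.curvature_numerator <- function(z, alpha) {
  e1 <- mlf(z, alpha, 1)
  e0 <- mlf(z, alpha, 0)
  em <- mlf(z, alpha, -1)
  (em + e0) * e1 - e0^2
}

#' Directionally averaged stick (intraneurite cylinder) signal
#'
#' Classical powder-averaged signal from impermeable cylinders,
#' \deqn{S(b)/S_0 = e^{-D_\perp b}\,\frac{\sqrt{\pi}}{2}\,
#'   \frac{\mathrm{erf}\!\big(\sqrt{b (D_\parallel - D_\perp)}\big)}
#'        {\sqrt{b (D_\parallel - D_\perp)}},}
#' the reference model whose high-b log-log slope tends to \eqn{-1/2} when
#' \eqn{D_\perp = 0}.  Continuous at b = 0 where the value is 1.
#'
#' @param b b-values, s/mm^2 (>= 0).
#' @param d_par diffusion coefficient along the cylinder, mm^2/s.
#' @param d_perp diffusion coefficient across the cylinder, mm^2/s
#'   (`d_par > d_perp >= 0`).
#' @return normalized signal values.
#' @export
stick_attenuation <- function(b, d_par, d_perp = 0) {
  if (!is.finite(d_par) || !is.finite(d_perp) || d_perp < 0 ||
      d_par <= d_perp)
    stop("require d_par > d_perp >= 0", call. = FALSE)
  if (any(!is.finite(b)) || any(b < 0))
    stop("`b` must be finite and >= 0", call. = FALSE)
  x <- sqrt(b * (d_par - d_perp))
  out <- exp(-d_perp * b) * sqrt(pi) / 2 * .erf(x) / x
  out[b == 0] <- 1
  out
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
.erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Effective diffusion coefficient
#'
#' Converts the quasi-diffusion coefficient to the normal effective
#' coefficient of the fractional diffusion formulation,
#' \eqn{D_{\alpha,2\alpha} = D_{1,2}^{\alpha}} (units mm^(2 alpha) s^(-alpha)).
#' Given `alpha`, the inverse mapping `d_eff^(1/alpha)` recovers `d12`.
#'
#' @inheritParams qdi_attenuation
#' @return the effective coefficient \eqn{D_{1,2}^\alpha}.
#' @export
effective_coefficient <- function(params) {
  params <- .as_qdi_params(params)
  params$d12^params$alpha
}
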