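#' Multivariate-t and logistic-approximation utilities
#'
#' The latent variables behind ordinal outcomes are modelled as (multivariate)
#' Student-t with a fixed low degrees of freedom \eqn{\nu_0}, because a t
#' distribution with \eqn{\nu_0 = 7.3} and a variance-matched scale is nearly
#' indistinguishable from the standard logistic. This keeps the Gibbs sampler
#' conjugate (a t is a scale mixture of normals) while letting identified
#' coefficients be read as log odds ratios. These helpers compute the
#' variance-matching scale, re-derive the optimal df numerically, draw the
#' auxiliary mixture precisions, and map t-distributed latents to exactly
#' logistic ones.
#'
#' @name mvt-utils
NULL

#' Constants of the t approximation to the logistic
#'
#' Bundles the fixed degrees of freedom \eqn{\nu_0} of the latent ordinal
#' block with the scale variance \eqn{\sigma_0^2} that matches the t variance
#' to the standard-logistic variance \eqn{\pi^2/3}.
#'
#' @param nu0 Degrees of freedom of the approximating t; must exceed 2.
#'   Default 7.3, the minimizer of the integrated squared distance between
#'   the variance-matched t density and the logistic density.
#' @return An object of class `"t_approx"`: list with elements `nu0` and
#'   `sigma0_sq`.
#' @examples
#' t_approx()$sigma0_sq            # 2.3885...
#' @export
t_approx <- function(nu0 = 7.3) {
  stopifnot(is.numeric(nu0), length(nu0) == 1L, nu0 > 2)
  structure(list(nu0 = nu0, sigma0_sq = logistic_matching_scale(nu0)),
            class = "t_approx")
}

#' Variance-matching scale for a t approximation to the logistic
#'
#' Returns the scale variance \eqn{\sigma^2} such that a Student-t with
#' `nu` degrees of freedom and that scale has variance \eqn{\pi^2/3}, the
#' variance of the standard logistic: \eqn{\sigma^2 \nu/(\nu-2) = \pi^2/3}.
#'
#' @param nu Degrees of freedom, must exceed 2 (else the t variance is
#'   undefined).
#' @return The matching scale variance (positive scalar).
#' @examples
#' logistic_matching_scale(7.3)
#' @export
logistic_matching_scale <- function(nu) {
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu))
  if (nu <= 2) stop("nu must exceed 2: the t variance is undefined otherwise")
  pi^2 / 3 * (nu - 2) / nu
}

#' Optimal degrees of freedom for the logistic approximation
#'
#' Finds the df \eqn{\nu} minimizing the integrated squared distance between
#' the variance-matched t density and the standard-logistic density,
#' \deqn{\int (f_t(x;\nu,\sigma(\nu)) - f_L(x))^2 dx,}
#' by bounded 1-D minimization with adaptive quadrature on (-40, 40) (both
#' densities are numerically zero beyond). The minimizer is approximately
#' 7.3, the constant fixed for the latent ordinal block.
#'
#' @param search_lo,search_hi Search interval for \eqn{\nu}; must satisfy
#'   `2 < search_lo < search_hi`.
#' @param tol Optimizer tolerance on \eqn{\nu}.
#' @return The minimizing degrees of freedom.
#' @export
optimal_logistic_df <- function(search_lo = 2.5, search_hi = 50, tol = 1e-4) {
  stopifnot(2 < search_lo, search_lo < search_hi)
  objective <- function(nu) {
    s <- sqrt(logistic_matching_scale(nu))
    val <- stats::integrate(
      function(x) (stats::dt(x / s, df = nu) / s - stats::dlogis(x))^2,
      lower = -40, upper = 40, rel.tol = 1e-10)$value
    if (!is.finite(val)) stop("non-finite integrand in density distance")
    val
  }
  stats::optimize(objective, c(search_lo, search_hi), tol = tol)$minimum
}

#' Auxiliary mixture precisions of the t scale mixture
#'
#' A t likelihood with df \eqn{\nu} is a scale mixture of normals: drawing a
#' per-observation precision \eqn{\phi \sim} Gamma(\eqn{\nu/2}, rate
#' \eqn{\nu/2}) and then \eqn{N(\mu, \Sigma/\phi)} marginalizes to the t.
#' This data augmentation is what keeps the Gibbs updates conjugate.
#'
#' @param nu Degrees of freedom (positive).
#' @param n Number of draws.
#' @return Vector of `n` positive precisions with mean 1.
#' @export
sample_mixture_precision <- function(nu, n) {
  stopifnot(is.numeric(nu), length(nu) == 1L, nu > 0, n >= 1)
  stats::rgamma(n, shape = nu / 2, rate = nu / 2)
}

#' Map t-distributed latents to exactly logistic ones
#'
#' The quantile transform \eqn{F_L^{-1}(T_\nu(z/s))} where \eqn{T_\nu} is the
#' Student-t CDF and \eqn{F_L} the standard-logistic CDF. Applied marginally
#' to a latent with a t(\eqn{\nu}) marginal of scale sd `scale_sd`, the
#' result is exactly standard logistic; the data generator uses it so that
#' ordinal categories are discretized on the logistic scale.
#'
#' CDF values are clamped to `[1e-12, 1 - 1e-12]` (with a warning) before
#' quantile inversion to avoid infinite latents in floating point.
#'
#' @param z Numeric vector of latent values.
#' @param nu Degrees of freedom of the t marginal.
#' @param scale_sd Scale (standard deviation parameter) of the t marginal;
#'   positive.
#' @return Numeric vector, strictly increasing in `z`.
#' @export
t_to_logistic <- function(z, nu, scale_sd) {
  stopifnot(is.numeric(z), nu > 0, scale_sd > 0)
  p <- stats::pt(z / scale_sd, df = nu)
  if (any(p <= 0 | p >= 1)) {
    warning("t CDF saturated in floating point; clamping before inversion")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }
  stats::qlogis(p)
}

#' Degrees-of-freedom parameter with a uniform prior on its reciprocal
#'
#' Unknown t dfs (for mediators and for the continuous-outcome block) carry a
#' uniform prior on \eqn{1/\nu}. The default support `(0, 1]` spans the
#' normal limit (\eqn{1/\nu \to 0}) through the Cauchy (\eqn{1/\nu = 1}) and
#' favors longer-tailed models.
#'
#' @param nu Current df value.
#' @param prior_lo_inv,prior_hi_inv Bounds of the uniform prior on
#'   \eqn{1/\nu}; `0 <= prior_lo_inv < prior_hi_inv <= 1`.
#' @return Object of class `"df_param"`.
#' @export
df_param <- function(nu, prior_lo_inv = 0, prior_hi_inv = 1) {
  stopifnot(prior_lo_inv >= 0, prior_hi_inv <= 1,
            prior_lo_inv < prior_hi_inv)
  inv <- 1 / nu
  if (inv < prior_lo_inv || inv > prior_hi_inv)
    stop("1/nu must lie within the prior support")
  structure(list(nu = nu, prior_lo_inv = prior_lo_inv,
                 prior_hi_inv = prior_hi_inv),
            class = "df_param")
}
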