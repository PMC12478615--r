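#' Convergence diagnostics
#'
#' Minimal chain diagnostics on the retained (post burn-in, thinned) draw
#' series: parameter traces by systematic name, effective sample size via
#' the initial-positive-sequence autocorrelation estimator, and the Geweke
#' z statistic comparing the means of the first 10% and last 50% of the
#' series. Diagnostics are computed on the identified scale.
#'
#' @name era-diagnostics
NULL

# Extract one named parameter series from era_draws. Names follow the
# storage convention: "W[p]", "a0[q]", "a1[r]", "A2[k,r]", "A3[k,q]",
# "A4[r,q]", "SigmaM[i,j]", "SigmaY[i,j]", "gamma[q,j]", "nu_M", "nu_C".
param_series <- function(draws, name) {
  d <- if (inherits(draws, "era_fit")) draws$draws else draws
  if (name == "nu_M") return(d$nu_M)
  if (name == "nu_C") return(d$nu_C)
  m <- regmatches(name, regexec("^([A-Za-z0-9]+)\\[([0-9]+)(,([0-9]+))?\\]$",
                                name))[[1L]]
  if (!length(m)) stop(sprintf("unknown parameter name '%s'", name))
  base <- m[2L]
  i <- as.integer(m[3L])
  j <- if (nzchar(m[5L])) as.integer(m[5L]) else NA_integer_
  out <- switch(base,
    W = d$w[, i],
    a0 = d$a0[, i],
    a1 = d$a1[, i],
    A2 = d$A2[, i, j],
    A3 = d$A3[, i, j],
    A4 = d$A4[, i, j],
    SigmaM = d$SigmaM[, i, j],
    SigmaY = d$SigmaY[, i, j],
    gamma = d$cut[[i]][, j],
    stop(sprintf("unknown parameter name '%s'", name)))
  if (is.null(out)) stop(sprintf("parameter '%s' not stored", name))
  out
}

#' Retained-draw trace of a parameter
#'
#' Returns the post-burn-in, thinned series in iteration order together
#' with the MCMC iteration numbers it came from; plotting is a thin
#' consumer of this.
#'
#' @param fit An `"era_fit"` (or `"era_draws"`; then iteration metadata
#'   requires the fit).
#' @param name Systematic parameter name, e.g. `"A2[1,2]"`, `"W[3]"`,
#'   `"nu_M"`, `"gamma[1,2]"`.
#' @param identified Compute on the identified scale (default `TRUE`).
#' @return `data.frame` with columns `iteration` and `value`.
#' @export
era_trace <- function(fit, name, identified = TRUE) {
  d <- if (inherits(fit, "era_fit")) fit$draws else fit
  if (identified) d <- identified_rescale(d)
  v <- param_series(d, name)
  iter <- if (inherits(fit, "era_fit"))
    fit$control$burn_in + fit$control$thin * seq_along(v)
  else seq_along(v)
  data.frame(iteration = iter, value = v)
}

#' Effective sample size and Geweke diagnostic
#'
#' ESS uses `n / (1 + 2 sum rho_k)` with the autocorrelation sum truncated
#' by Geyer's initial positive sequence (pairs of consecutive
#' autocorrelations are summed while the pair sums stay positive). The
#' Geweke statistic is the z score of the difference between the means of
#' the first 10% and the last 50% of the series, each variance scaled by
#' its own segment ESS.
#'
#' @param fit An `"era_fit"` or `"era_draws"`.
#' @param name Parameter name as in [era_trace()].
#' @param identified Compute on the identified scale (default `TRUE`).
#' @return List with `ess` and `geweke_z` (both `NA` for a zero-variance
#'   series).
#' @export
ess_geweke <- function(fit, name, identified = TRUE) {
  v <- era_trace(fit, name, identified = identified)$value
  if (length(v) < 100L) stop("need at least 100 draws for diagnostics")
  if (stats::sd(v) < 1e-14) return(list(ess = NA_real_,
                                        geweke_z = NA_real_))
  n1 <- max(2L, floor(0.1 * length(v)))
  s1 <- v[seq_len(n1)]
  s2 <- v[seq.int(floor(0.5 * length(v)) + 1L, length(v))]
  zden <- stats::var(s1) / ess_ips(s1) + stats::var(s2) / ess_ips(s2)
  list(ess = ess_ips(v),
       geweke_z = (mean(s1) - mean(s2)) / sqrt(zden))
}

# Initial-positive-sequence ESS (Geyer 1992 truncation).
ess_ips <- function(v) {
  n <- length(v)
  if (stats::sd(v) < 1e-14) return(NA_real_)
  rho <- stats::acf(v, lag.max = min(n - 2L, 500L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  acsum <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair <= 0) break
    acsum <- acsum + pair
    k <- k + 2L
  }
  max(1, min(n, n / (1 + 2 * acsum)))
}
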