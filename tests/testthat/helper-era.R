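# Shared fixtures, all generated in code. The small reference fit is
# memoized so several test files can reuse it without refitting.

.era_cache <- new.env(parent = emptyenv())

# Small default-scenario fit with latent storage, reused by invariant,
# effects, diagnostics and io tests.
shared_small_fit <- function() {
  if (is.null(.era_cache$fit)) {
    sc <- default_scenario(120, seed = 424)
    fit <- era_fit(sc$data, sc$spec,
                   control = era_control(n_iter = 900, burn_in = 300,
                                         thin = 3, seed = 99))
    .era_cache$fit <- fit
    .era_cache$scenario <- sc
  }
  list(fit = .era_cache$fit, sc = .era_cache$scenario)
}

# One-continuous-outcome toy with known conjugate posterior: K=1 component
# of two predictors, no mediators, everything but (a0, a3) pinned.
conjugate_toy <- function(n = 150, seed = 5) {
  set.seed(seed)
  spec <- era_spec(blocks = c(1L, 1L), n_mediators = 0L, n_continuous = 1L)
  X <- matrix(rnorm(n * 2L), n, 2L)
  W0 <- matrix(c(1, 1), 2L, 1L)
  mc <- make_components(X, W0, spec)
  a0 <- 0.5; a3 <- 0.8
  y <- a0 + a3 * mc$F[, 1L] + rnorm(n)
  list(spec = spec, data = era_data(X, Ycont = cbind(y)), W = mc$W,
       Fc = mc$F, y = y)
}

# Truth object for a zero-slope binary-outcome toy (no mediators).
binary_toy_truth <- function(a0 = 0.4) {
  era_truth(W = matrix(c(1, 1), 2L, 1L),
            a1 = numeric(0), A2 = matrix(0, 1L, 0L),
            SigmaM = matrix(0, 0L, 0L), nu_M = 5,
            a0 = a0, A3 = matrix(0, 1L, 1L),
            A4 = matrix(0, 0L, 1L), SigmaY = matrix(1, 1L, 1L),
            nu_C = 5, cutoffs = list(0), sigmaX = diag(2L))
}

# Generate a binary-outcome dataset from the toy truth.
binary_toy_data <- function(n, a0 = 0.4, seed = 1) {
  set.seed(seed)
  truth <- binary_toy_truth(a0)
  spec <- era_spec(blocks = c(1L, 1L), n_mediators = 0L,
                   n_continuous = 0L, n_categories = 2L)
  X <- generate_predictors(n, truth$sigmaX)
  mc <- make_components(X, truth$W, spec)
  truth$W <- mc$W
  out <- simulate_outcomes(mc$F, matrix(0, n, 0L), matrix(0, n, 0L), truth)
  list(spec = spec, data = era_data(X, Yord = out$Yord), truth = truth,
       Zlat = out$Zlat)
}

# Independent quadrature oracle for the t-vs-logistic density distance.
density_distance <- function(nu) {
  s <- sqrt(pi^2 / 3 * (nu - 2) / nu)
  stats::integrate(function(x) (stats::dt(x / s, df = nu) / s -
                                  stats::dlogis(x))^2,
                   -40, 40, rel.tol = 1e-10)$value
}
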