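#' Synthetic-data generation
#'
#' The generator mirrors the model's own generative process: multivariate
#' normal predictor blocks are reduced to unit-variance components; the
#' mediators follow a multivariate t (normal scale mixture) around a linear
#' function of covariates and components; the joint outcome error is drawn
#' from correlated normal blocks with per-subject gamma mixture precisions
#' (so each block is marginally multivariate t), the ordinal-block latents
#' are pushed through the t-to-logistic quantile transform, and categories
#' are read off fixed cutoff sets.
#'
#' Randomness uses R's global stream: call `set.seed()` (or use the `seed`
#' arguments of the high-level wrappers) for reproducibility.
#'
#' @name era-simulate
NULL

#' Draw multivariate-normal predictors
#'
#' @param n Number of subjects.
#' @param sigmaX Positive-definite `P x P` covariance matrix.
#' @return `n x P` matrix of i.i.d. `N(0, sigmaX)` rows.
#' @export
generate_predictors <- function(n, sigmaX) {
  sigmaX <- as.matrix(sigmaX)
  ev <- eigen(symm(sigmaX), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sigmaX must be positive definite")
  rmvnorm_chol(n, 0, sigmaX)
}

#' Build standardized components from block-sparse weights
#'
#' Computes `F = X W`, rescales every column of `W` so the corresponding
#' component has sample variance exactly 1 (and fixes the sign so the first
#' weight of each block is nonnegative). Idempotent on already-standardized
#' input.
#'
#' @param X `N x P` predictor matrix.
#' @param W `P x K` block-sparse weight matrix (nonzeros only where
#'   `spec$blocks` allows).
#' @param spec An [era_spec()].
#' @return List with standardized `F` (`N x K`) and the rescaled `W`.
#' @export
make_components <- function(X, W, spec) {
  W <- as.matrix(W)
  stopifnot(nrow(W) == spec$P, ncol(W) == spec$K)
  free <- cbind(seq_len(spec$P), spec$blocks)
  Wz <- W
  Wz[free] <- 0
  if (any(Wz != 0)) stop("W has nonzeros outside its block pattern")
  Fc <- X %*% W
  s <- apply(Fc, 2L, stats::sd)
  if (any(s < 1e-12)) stop("degenerate input: zero-variance component")
  W <- sweep(W, 2L, s, "/")
  for (k in seq_len(spec$K)) {
    p1 <- which(spec$blocks == k)[1L]
    if (W[p1, k] < 0) W[, k] <- -W[, k]
  }
  list(F = X %*% W, W = W)
}

#' Simulate mediators
#'
#' Per subject, a precision `phi ~ Gamma(nu_M/2, nu_M/2)` scales the
#' mediator error covariance, `M_i ~ N(a1 + A2' [cov_i; f_i], SigmaM/phi)`,
#' so marginally the mediator errors are multivariate t with `nu_M` df.
#'
#' @param F `N x K` standardized components.
#' @param Cov `N x C` covariates (may have zero columns).
#' @param truth An [era_truth()] parameter set.
#' @return `N x R` mediator matrix.
#' @export
simulate_mediators <- function(F, Cov, truth) {
  n <- nrow(F)
  G <- cbind(Cov, F)
  mu <- matrix(truth$a1, n, length(truth$a1), byrow = TRUE) +
    G %*% truth$A2
  phi <- sample_mixture_precision(truth$nu_M, n)
  E <- rmvnorm_chol(n, 0, truth$SigmaM) / sqrt(phi)
  mu + E
}

#' Simulate mixed continuous/ordinal outcomes
#'
#' Draws the joint outcome error: a correlated `N(0, SigmaY)` vector scaled
#' per subject by `1/sqrt(phi1)` on the continuous block (with
#' `phi1 ~ Gamma(nu_C/2, nu_C/2)`) and by `sigma0/sqrt(phi2)` on the ordinal
#' block (`phi2 ~ Gamma(nu0/2, nu0/2)`), then transforms each ordinal-block
#' error marginal from t to exactly logistic and discretizes the latent
#' (mean + logistic error) by the cutoff sets.
#'
#' @param F,Cov,M Components, covariates and mediators.
#' @param truth An [era_truth()].
#' @param approx A [t_approx()] (defaults to `t_approx()`).
#' @return List with `Ycont` (`N x T`), `Yord` (`N x (Q-T)` integer) and the
#'   logistic-scale latent matrix `Zlat` (for testing; never an input to the
#'   fitting API).
#' @export
simulate_outcomes <- function(F, Cov, M, truth, approx = t_approx()) {
  n <- nrow(F)
  Q <- length(truth$a0)
  Tc <- Q - length(truth$cutoffs)
  G <- cbind(Cov, F)
  eta <- matrix(truth$a0, n, Q, byrow = TRUE) + G %*% truth$A3
  if (ncol(M) > 0) eta <- eta + M %*% truth$A4
  Eraw <- rmvnorm_chol(n, 0, truth$SigmaY)
  d <- matrix(1, n, Q)
  if (Tc > 0) {
    phi1 <- sample_mixture_precision(truth$nu_C, n)
    d[, seq_len(Tc)] <- 1 / sqrt(phi1)
  }
  n_ord <- Q - Tc
  Zlat <- matrix(numeric(0), n, 0L)
  Yord <- matrix(integer(0), n, 0L)
  if (n_ord > 0) {
    phi2 <- sample_mixture_precision(approx$nu0, n)
    d[, Tc + seq_len(n_ord)] <- sqrt(approx$sigma0_sq) / sqrt(phi2)
    Zlat <- matrix(0, n, n_ord)
    Yord <- matrix(0L, n, n_ord)
    for (j in seq_len(n_ord)) {
      q <- Tc + j
      err_t <- Eraw[, q] * d[, q]           # marginally t(nu0), scale sigma0
      scale_sd <- sqrt(approx$sigma0_sq * truth$SigmaY[q, q])
      err_logis <- t_to_logistic(err_t, approx$nu0, scale_sd)
      Zlat[, j] <- eta[, q] + err_logis
      Yord[, j] <- apply_cutoffs(Zlat[, j], truth$cutoffs[[j]])
    }
  }
  Ycont <- if (Tc > 0) eta[, seq_len(Tc), drop = FALSE] +
    Eraw[, seq_len(Tc), drop = FALSE] * d[, seq_len(Tc), drop = FALSE]
  else matrix(numeric(0), n, 0L)
  list(Ycont = Ycont, Yord = Yord, Zlat = Zlat)
}

#' Discretize a latent value by ordered cutoffs
#'
#' Returns the category `j` with `gamma_{j-1} < z <= gamma_j`, taking
#' `gamma_0 = -Inf` and `gamma_J = +Inf`; a value exactly at a cutpoint goes
#' to the category whose right endpoint it is.
#'
#' @param z Numeric vector of latent values.
#' @param gammas Strictly increasing cutoff vector of length `J - 1`.
#' @return Integer vector of categories in `1..J`.
#' @export
apply_cutoffs <- function(z, gammas) {
  if (is.unsorted(gammas, strictly = TRUE))
    stop("cutoffs must be strictly increasing")
  findInterval(z, gammas, left.open = TRUE) + 1L
}

#' True-parameter container for the generator
#'
#' @param W `P x K` block-sparse weights (standardized or not; the
#'   scenario builder standardizes against the realized predictors).
#' @param a1,A2,SigmaM,nu_M Mediator model: intercepts (length `R`),
#'   `(C+K) x R` coefficients, error covariance, t df.
#' @param a0,A3,A4,SigmaY,nu_C Outcome model: intercepts (length `Q`),
#'   `(C+K) x Q` direct effects, `R x Q` mediator effects, joint error
#'   covariance, t df of the continuous block.
#' @param cutoffs List, one strictly increasing cutoff vector per ordinal
#'   outcome (first cutoff 0 by the identifiability convention).
#' @param sigmaX `P x P` predictor covariance.
#' @return Object of class `"era_truth"`.
#' @export
era_truth <- function(W, a1, A2, SigmaM, nu_M, a0, A3, A4, SigmaY, nu_C,
                      cutoffs, sigmaX) {
  for (g in cutoffs)
    if (is.unsorted(g, strictly = TRUE))
      stop("cutoff sets must be strictly increasing")
  structure(list(W = as.matrix(W), a1 = a1, A2 = as.matrix(A2),
                 SigmaM = as.matrix(SigmaM), nu_M = nu_M, a0 = a0,
                 A3 = as.matrix(A3), A4 = as.matrix(A4),
                 SigmaY = as.matrix(SigmaY), nu_C = nu_C,
                 cutoffs = cutoffs, sigmaX = as.matrix(sigmaX)),
            class = "era_truth")
}

#' Default simulation scenario
#'
#' The package's reference topology: two components formed from blocks of
#' three correlated predictors each (within-block correlation 0.5), no
#' covariates, two mediators, two continuous and two three-category ordinal
#' outcomes with cutoff sets `(0, 1.1)` and `(0, 1.6)`. All path
#' coefficients are nonzero with magnitudes in `[0.2, 1.0]`; mediator and
#' outcome error laws are t with 5 df; `SigmaM` and `SigmaY` have unit
#' diagonals and 0.3 off-diagonals. The returned truth carries `W`
#' standardized against the realized predictor sample, so recovered weights
#' are directly comparable.
#'
#' @param n Number of subjects (`>= 20`).
#' @param seed Optional integer seed (sets the global RNG stream).
#' @param truth Optionally a modified [era_truth()] to generate from (same
#'   topology).
#' @return List with elements `spec`, `data` ([era_data()]), `truth`
#'   (standardized-W [era_truth()]) and `Zlat`.
#' @export
default_scenario <- function(n, seed = NULL, truth = NULL) {
  stopifnot(n >= 20)
  if (!is.null(seed)) set.seed(seed)
  spec <- era_spec(blocks = c(1L, 1L, 1L, 2L, 2L, 2L),
                   n_covariates = 0L, n_mediators = 2L,
                   n_continuous = 2L, n_categories = c(3L, 3L))
  if (is.null(truth)) truth <- default_truth()
  X <- generate_predictors(n, truth$sigmaX)
  mc <- make_components(X, truth$W, spec)
  truth$W <- mc$W
  Cov <- matrix(0, n, 0L)
  M <- simulate_mediators(mc$F, Cov, truth)
  out <- simulate_outcomes(mc$F, Cov, M, truth)
  data <- era_data(X, Cov = NULL, M = M, Ycont = out$Ycont,
                   Yord = out$Yord)
  validate_era(spec, data)
  list(spec = spec, data = data, truth = truth, Zlat = out$Zlat)
}

# Reference true values of the default scenario. Documented choices: the
# blocks use equal raw weights (standardization fixes the scale), every
# path coefficient is nonzero and moderately sized, cutoffs sit near the
# logistic quartile/upper range so all categories are well populated.
default_truth <- function() {
  blocks <- c(1L, 1L, 1L, 2L, 2L, 2L)
  P <- 6L; K <- 2L
  W <- matrix(0, P, K)
  for (k in seq_len(K)) W[blocks == k, k] <- 1
  sigmaX <- diag(P)
  for (k in seq_len(K)) {
    idx <- which(blocks == k)
    sigmaX[idx, idx] <- 0.5 + 0.5 * diag(length(idx))
  }
  era_truth(
    W = W,
    a1 = c(0.3, -0.3),
    A2 = matrix(c(0.6, -0.4,
                  0.5,  0.7), 2L, 2L, byrow = TRUE),
    SigmaM = matrix(c(1, 0.3, 0.3, 1), 2L, 2L),
    nu_M = 5,
    a0 = c(0.2, -0.2, 0.3, -0.3),
    A3 = matrix(c(0.40, 0.60, -0.50, 0.35,
                  -0.45, 0.30, 0.55, -0.60), 2L, 4L, byrow = TRUE),
    A4 = matrix(c(0.50, -0.40, 0.60, 0.30,
                  -0.60, 0.50, 0.40, -0.50), 2L, 4L, byrow = TRUE),
    SigmaY = 0.3 + 0.7 * diag(4L),
    nu_C = 5,
    cutoffs = list(c(0, 1.1), c(0, 1.6)),
    sigmaX = sigmaX)
}
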