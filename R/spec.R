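#' Model specification for ERA with mediators and mixed outcomes
#'
#' An extended-redundancy-analysis model reduces `P` predictors, partitioned
#' into `K` blocks, to `K` unit-variance weighted composites (components).
#' The components (plus optional covariates) predict `R` continuous
#' mediators and `Q` outcomes, of which the first `T` are continuous and the
#' remaining `Q - T` ordinal with `J_q >= 2` categories each (coded
#' `1..J_q`).
#'
#' @param blocks Integer vector of length `P`: `blocks[p]` is the component
#'   (block) index of predictor `p`, in `1..K`. Every component must own at
#'   least one predictor.
#' @param n_covariates Number of covariate columns `C` (default 0).
#' @param n_mediators Number of mediators `R`.
#' @param n_continuous Number of continuous outcomes `T`.
#' @param n_categories Integer vector, one entry per ordinal outcome, each
#'   `>= 2`. `Q = n_continuous + length(n_categories)`.
#' @return Object of class `"era_spec"` with fields `P`, `K`, `C`, `R`, `Q`,
#'   `T`, `blocks`, `categories`.
#' @examples
#' era_spec(blocks = c(1, 1, 1, 2, 2, 2), n_mediators = 2,
#'          n_continuous = 2, n_categories = c(3, 3))
#' @export
era_spec <- function(blocks, n_covariates = 0L, n_mediators = 0L,
                     n_continuous = 0L, n_categories = integer()) {
  blocks <- as.integer(blocks)
  if (length(blocks) < 1L || anyNA(blocks))
    stop("every predictor needs a block assignment")
  K <- max(blocks)
  if (!setequal(unique(blocks), seq_len(K)))
    stop("block indices must cover 1..K; some component has no predictor")
  n_categories <- as.integer(n_categories)
  if (any(n_categories < 2L)) stop("ordinal outcomes need >= 2 categories")
  Q <- as.integer(n_continuous) + length(n_categories)
  if (Q < 1L) stop("at least one outcome is required")
  structure(list(P = length(blocks), K = K, C = as.integer(n_covariates),
                 R = as.integer(n_mediators), Q = Q,
                 T = as.integer(n_continuous), blocks = blocks,
                 categories = n_categories),
            class = "era_spec")
}

#' @export
print.era_spec <- function(x, ...) {
  cat(sprintf(
    "ERA model spec: P=%d predictors in K=%d blocks, C=%d covariates,\n",
    x$P, x$K, x$C))
  cat(sprintf("  R=%d mediators, Q=%d outcomes (%d continuous, %d ordinal",
              x$R, x$Q, x$T, x$Q - x$T))
  if (length(x$categories))
    cat(sprintf(" with %s categories", paste(x$categories, collapse = "/")))
  cat(")\n")
  invisible(x)
}

#' Dataset container
#'
#' Bundles the rectangular inputs: predictors `X` (N x P), covariates `Cov`
#' (N x C), mediators `M` (N x R), continuous outcomes `Ycont` (N x T) and
#' ordinal outcomes `Yord` (N x (Q-T), integer categories `1..J_q`). Any
#' empty dimension may be passed as `NULL`. No missing values are allowed.
#'
#' @param X,Cov,M,Ycont,Yord Numeric matrices sharing the row count; see
#'   above.
#' @return Object of class `"era_data"`.
#' @export
era_data <- function(X, Cov = NULL, M = NULL, Ycont = NULL, Yord = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  fix <- function(A) if (is.null(A)) matrix(0, n, 0L) else as.matrix(A)
  structure(list(X = X, Cov = fix(Cov), M = fix(M), Ycont = fix(Ycont),
                 Yord = fix(Yord)),
            class = "era_data")
}

#' @export
print.era_data <- function(x, ...) {
  cat(sprintf(
    "ERA dataset: N=%d, P=%d predictors, C=%d covariates, R=%d mediators, %d continuous + %d ordinal outcomes\n",
    nrow(x$X), ncol(x$X), ncol(x$Cov), ncol(x$M), ncol(x$Ycont),
    ncol(x$Yord)))
  invisible(x)
}

#' Validate a spec/data pair
#'
#' Checks every structural invariant: matching dimensions, absence of
#' missing or non-finite values, and ordinal categories within `1..J_q`.
#'
#' @param spec An [era_spec()].
#' @param data An [era_data()].
#' @return Invisibly `TRUE` if valid; otherwise a stop with all violations,
#'   or with `error = FALSE` a character vector of violation messages
#'   (length 0 when valid).
#' @param error If `TRUE` (default) violations raise an error.
#' @export
validate_era <- function(spec, data, error = TRUE) {
  stopifnot(inherits(spec, "era_spec"), inherits(data, "era_data"))
  bad <- character()
  n <- nrow(data$X)
  chk_dim <- function(A, d, what) {
    if (ncol(A) != d) bad <<- c(bad, sprintf(
      "%s has %d columns, spec requires %d", what, ncol(A), d))
    if (nrow(A) != n) bad <<- c(bad, sprintf(
      "%s has %d rows, X has %d", what, nrow(A), n))
  }
  chk_dim(data$X, spec$P, "X")
  chk_dim(data$Cov, spec$C, "Cov")
  chk_dim(data$M, spec$R, "M")
  chk_dim(data$Ycont, spec$T, "Ycont")
  chk_dim(data$Yord, spec$Q - spec$T, "Yord")
  for (nm in c("X", "Cov", "M", "Ycont", "Yord"))
    if (length(data[[nm]]) && !all(is.finite(data[[nm]])))
      bad <- c(bad, sprintf("%s contains missing or non-finite values", nm))
  if (ncol(data$Yord) == ncol(data$Yord) && length(data$Yord) &&
      ncol(data$Yord) == length(spec$categories)) {
    for (q in seq_along(spec$categories)) {
      y <- data$Yord[, q]
      if (any(y != round(y))) bad <- c(bad, sprintf(
        "ordinal outcome %d has non-integer codes", q))
      if (any(y < 1)) bad <- c(bad, sprintf(
        "ordinal outcome %d: category below 1", q))
      if (any(y > spec$categories[q])) bad <- c(bad, sprintf(
        "ordinal outcome %d: category above J=%d", q, spec$categories[q]))
    }
  }
  if (error && length(bad))
    stop("invalid ERA data:\n  ", paste(bad, collapse = "\n  "))
  if (error) invisible(TRUE) else bad
}

#' Prior configuration
#'
#' Conjugate, deliberately diffuse priors. All regression-type parameters
#' (weights `W`, intercepts, coefficient matrices `A2`, `A3`, `A4`) get
#' independent normal priors with mean `coef_mean` and large variance
#' `coef_var`; the precision matrices of the mediator and outcome error laws
#' get Wishart priors with `dim + 2` degrees of freedom and scale
#' `I/(dim + 2)` unless overridden; the unknown t degrees of freedom get a
#' uniform prior on `1/nu` over `(nu_inv_lo, nu_inv_hi]`.
#'
#' @param coef_mean,coef_var Normal prior mean/variance for all coefficients
#'   (defaults 0 and 100).
#' @param wishart_df_M,wishart_scale_M Wishart prior df and scale matrix for
#'   the mediator precision `SigmaM^{-1}`; `NULL` means the dimension-based
#'   default.
#' @param wishart_df_Y,wishart_scale_Y Same for the outcome precision
#'   `SigmaY^{-1}`.
#' @param nu_inv_lo,nu_inv_hi Support of the uniform prior on `1/nu`
#'   (normal limit at 0, Cauchy at 1).
#' @param step_phi,step_nu,step_expand Random-walk step sizes of the
#'   Metropolis updates for per-subject precisions (log scale), degrees of
#'   freedom (1/nu scale) and the parameter-expansion scale move (log
#'   scale).
#' @return Object of class `"era_priors"`.
#' @export
era_priors <- function(coef_mean = 0, coef_var = 100,
                       wishart_df_M = NULL, wishart_scale_M = NULL,
                       wishart_df_Y = NULL, wishart_scale_Y = NULL,
                       nu_inv_lo = 0, nu_inv_hi = 1,
                       step_phi = 0.5, step_nu = 0.05, step_expand = 0.3) {
  stopifnot(coef_var > 0, nu_inv_lo >= 0, nu_inv_hi <= 1,
            nu_inv_lo < nu_inv_hi, step_phi > 0, step_nu > 0)
  structure(list(coef_mean = coef_mean, coef_var = coef_var,
                 wishart_df_M = wishart_df_M,
                 wishart_scale_M = wishart_scale_M,
                 wishart_df_Y = wishart_df_Y,
                 wishart_scale_Y = wishart_scale_Y,
                 nu_inv_lo = nu_inv_lo, nu_inv_hi = nu_inv_hi,
                 step_phi = step_phi, step_nu = step_nu,
                 step_expand = step_expand),
            class = "era_priors")
}

# Resolve the dimension-dependent Wishart defaults for a given spec.
resolve_wishart <- function(priors, dim, which = c("M", "Y")) {
  which <- match.arg(which)
  df <- priors[[paste0("wishart_df_", which)]] %||% (dim + 2)
  S  <- priors[[paste0("wishart_scale_", which)]] %||% (diag(dim) / (dim + 2))
  if (df < dim) stop("Wishart prior df must be >= dimension")
  list(df = df, scale = as.matrix(S))
}

#' MCMC settings
#'
#' @param n_iter Total iterations (default 30000).
#' @param burn_in Burn-in iterations discarded (default 2000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 5).
#' @param seed Integer RNG seed; one seeded stream drives the whole run.
#' @param store_latent Keep the latent ordinal matrices of retained draws
#'   (needed by invariant checks; default `TRUE`).
#' @param expand Apply the parameter-expansion scale move for ordinal
#'   outcome coordinates (default `TRUE`).
#' @param init `"prior"` (draw initial values from the priors, the default)
#'   or `"ls"` (data-driven least-squares start).
#' @return Object of class `"era_control"`.
#' @export
era_control <- function(n_iter = 30000L, burn_in = 2000L, thin = 5L,
                        seed = 1L, store_latent = TRUE, expand = TRUE,
                        init = c("prior", "ls")) {
  stopifnot(burn_in < n_iter, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 store_latent = isTRUE(store_latent),
                 expand = isTRUE(expand), init = match.arg(init)),
            class = "era_control")
}
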