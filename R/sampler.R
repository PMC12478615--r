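#' Gibbs-within-Metropolis sampler for Bayesian ERA with mediators
#'
#' One full cycle updates, in order: (1) the shared component weights `W`
#' from their joint normal full conditional over the mediator and response
#' likelihoods, followed by re-standardization of the components (with the
#' compensating rescale of the coefficient rows) and the sign convention;
#' (2) the mediator-model block `(a1, A2, SigmaM, phi_M, nu_M)`; (3) the
#' latent ordinal variables from truncated conditional normals; (4) the
#' response-model block `(a0, A3, A4, cutpoints, SigmaY, phi1, phi2, nu_C)`.
#' Precision vectors and degrees of freedom use Metropolis steps (their
#' conditionals are non-conjugate once the blocks are correlated); the
#' covariance draws use Wishart full conditionals, with a
#' parameter-expansion scale move on the unidentified ordinal coordinates.
#'
#' @name era-sampler
NULL

# ---- exported primitive updates -------------------------------------------

#' Wishart covariance update
#'
#' Draws the inverse covariance from its Wishart full conditional given
#' precision-scaled residuals and returns the covariance. The conditional is
#' Wishart with prior df plus `N` degrees of freedom and scale
#' `(V0^{-1} + sum phi_i e_i e_i')^{-1}`. Draws are symmetrized; a
#' numerically non-PD draw is retried with diagonal jitter.
#'
#' @param residuals `N x d` residual matrix.
#' @param phi Optional per-subject precision multipliers (length `N`);
#'   `NULL` means all 1.
#' @param prior List with `df` and `scale` of the Wishart prior on the
#'   precision matrix.
#' @return List with `Sigma` and `Sigmainv`.
#' @export
update_covariance <- function(residuals, phi = NULL, prior) {
  residuals <- as.matrix(residuals)
  n <- nrow(residuals)
  E <- if (is.null(phi)) residuals else residuals * sqrt(phi)
  S_res <- crossprod(E)
  V0inv <- chol2inv(chol_jitter(prior$scale))
  Sn <- chol2inv(chol_jitter(V0inv + S_res))
  prec <- rwishart1(prior$df + n, Sn)
  Sigma <- chol2inv(chol_jitter(prec))
  list(Sigma = symm(Sigma), Sigmainv = symm(prec))
}

#' Metropolis update of per-subject mixture precisions
#'
#' Random-walk proposal on the log scale targeting the full conditional
#' \deqn{f(\phi) \propto \phi^{d/2 + \nu/2 - 1}
#'   e^{-\nu\phi/2} e^{-(\phi q_a + \sqrt{\phi} q_b)/2},}
#' the product of the Gamma(\eqn{\nu/2,\nu/2}) mixture prior and the
#' multivariate-normal likelihood of a `d`-dimensional residual block whose
#' quadratic form splits into a within-block part `qa` (multiplying
#' \eqn{\phi}) and a cross-block part `qb` (multiplying \eqn{\sqrt\phi},
#' from correlation with the other, fixed-precision block). All subjects are
#' proposed and accepted independently in one vectorized sweep.
#'
#' @param phi Current precision vector (positive).
#' @param nu Degrees of freedom of the gamma mixture prior.
#' @param d Residual block dimension.
#' @param qa,qb Per-subject quadratic-form coefficients (lengths matching
#'   `phi`; `qb` defaults to 0).
#' @param step Log-scale random-walk standard deviation.
#' @return List with updated `phi` and the number `accepted`.
#' @export
metropolis_precision <- function(phi, nu, d, qa, qb = 0, step = 0.5) {
  stopifnot(step > 0, all(phi > 0))
  n <- length(phi)
  qb <- rep_len(qb, n)
  lphi <- log(phi)
  lprop <- lphi + step * stats::rnorm(n)
  phip <- exp(lprop)
  logf <- function(p, lp) (d / 2 + nu / 2) * lp - (nu / 2) * p -
    (p * qa + sqrt(p) * qb) / 2          # includes +log(phi) Jacobian
  lr <- logf(phip, lprop) - logf(phi, lphi)
  acc <- log(stats::runif(n)) < lr
  phi[acc] <- phip[acc]
  list(phi = phi, accepted = sum(acc))
}

#' Metropolis update of a t degrees-of-freedom parameter
#'
#' Random walk on `1/nu` inside the uniform prior support; proposals
#' outside the support are rejected. The target is the product of
#' Gamma(\eqn{\nu/2,\nu/2}) densities of the current mixture precisions.
#'
#' @param nu Current degrees of freedom.
#' @param phi Vector of current mixture precisions for this family.
#' @param lo_inv,hi_inv Support of the uniform prior on `1/nu`.
#' @param step Random-walk sd on the `1/nu` scale.
#' @return List with updated `nu` and `accepted` (0 or 1).
#' @export
metropolis_df <- function(nu, phi, lo_inv = 0, hi_inv = 1, step = 0.05) {
  x <- 1 / nu
  xp <- x + step * stats::rnorm(1L)
  if (xp <= lo_inv || xp > hi_inv || xp <= 0)
    return(list(nu = nu, accepted = 0L))
  nup <- 1 / xp
  # sum of Gamma(a, a) log densities in closed form: n(a log a - lgamma(a))
  # + (a-1) sum(log phi) - a sum(phi)
  n <- length(phi)
  slog <- sum(log(phi)); sphi <- sum(phi)
  ll <- function(v) {
    a <- v / 2
    n * (a * log(a) - lgamma(a)) + (a - 1) * slog - a * sphi
  }
  lr <- ll(nup) - ll(nu)
  if (log(stats::runif(1L)) < lr) list(nu = nup, accepted = 1L)
  else list(nu = nu, accepted = 0L)
}

# ---- conditional coefficient draws (likelihood + prior; prior-only at N=0) -

# Joint draw of the response coefficient matrix B ((1+C+K+R) x Q) from its
# normal full conditional. Per-subject error covariance is
# D_i Sigma_Y D_i with D_i = diag(1/Dinv_i), so the vec(B) precision has
# (q,q') block SYinv[q,q'] * Xt' diag(Dinv_q Dinv_q') Xt.
draw_coef_response <- function(Xt, U, Dinv, SYinv, tau2, pm) {
  pB <- ncol(Xt)
  Q <- ncol(SYinv)
  Pmat <- matrix(0, pB * Q, pB * Q)
  b <- numeric(pB * Q)
  V <- if (nrow(Xt)) (Dinv * U) %*% SYinv else matrix(0, 0L, Q)
  for (q in seq_len(Q)) {
    rows <- (q - 1L) * pB + seq_len(pB)
    for (q2 in q:Q) {
      cols <- (q2 - 1L) * pB + seq_len(pB)
      Mqq <- crossprod(Xt, Xt * (Dinv[, q] * Dinv[, q2]))
      Pmat[rows, cols] <- SYinv[q, q2] * Mqq
      if (q2 > q) Pmat[cols, rows] <- t(Pmat[rows, cols])
    }
    b[rows] <- crossprod(Xt, Dinv[, q] * V[, q])
  }
  Pmat <- Pmat + diag(1 / tau2, pB * Q)
  b <- b + pm / tau2
  matrix(rmvnorm_precision(b, Pmat), pB, Q)
}

# Joint draw of the mediator coefficient matrix BM ((1+C+K) x R): the error
# is N(0, SigmaM/phi_i), so vec(BM) has precision
# SMinv (x) (G' diag(phi) G) + I/tau2.
draw_coef_mediator <- function(G, M, phiM, SMinv, tau2, pm) {
  pG <- ncol(G)
  R <- ncol(SMinv)
  GtG <- crossprod(G, G * phiM)
  Pmat <- kronecker(SMinv, GtG) + diag(1 / tau2, pG * R)
  b <- as.vector(crossprod(G, phiM * M) %*% SMinv) + pm / tau2
  matrix(rmvnorm_precision(b, Pmat), pG, R)
}

# Joint draw of the free weights w (length P) from the normal full
# conditional combining the mediator likelihood (through the component rows
# A2c of A2) and the response likelihood (through A3c). `med` and/or `resp`
# may be NULL (prior-only when both are).
draw_weights <- function(X, blocks, med = NULL, resp = NULL, tau2, pm) {
  P <- ncol(X)
  Pw <- diag(1 / tau2, P)
  b <- rep(pm / tau2, P)
  if (!is.null(med) && nrow(X)) {
    C2 <- med$A2c %*% med$SMinv %*% t(med$A2c)       # K x K
    XphiX <- crossprod(X, X * med$phiM)
    Pw <- Pw + C2[blocks, blocks] * XphiX
    H <- med$Mt %*% med$SMinv %*% t(med$A2c)         # N x K
    b <- b + crossprod(X, med$phiM * H)[cbind(seq_len(P), blocks)]
  }
  if (!is.null(resp) && nrow(X)) {
    Q <- ncol(resp$SYinv)
    Sc <- (resp$Dinv * resp$Ut) %*% resp$SYinv       # N x Q
    Wm <- resp$Dinv * Sc
    T1 <- Wm %*% t(resp$A3c)                         # N x K
    b <- b + crossprod(X, T1)[cbind(seq_len(P), blocks)]
    for (q in seq_len(Q)) {
      uq <- resp$A3c[blocks, q]
      for (q2 in seq_len(Q)) {
        uq2 <- resp$A3c[blocks, q2]
        Mqq <- crossprod(X, X * (resp$Dinv[, q] * resp$Dinv[, q2]))
        Pw <- Pw + resp$SYinv[q, q2] * (outer(uq, uq2) * Mqq)
      }
    }
  }
  rmvnorm_precision(b, Pw)
}

# ---- full sampler ----------------------------------------------------------

#' Fit Bayesian ERA with mediators by MCMC
#'
#' Runs the full Gibbs-within-Metropolis cycle and returns thinned
#' post-burn-in draws of every parameter. With `include_mediators = FALSE`
#' the response model is fitted without the mediator term (the comparison
#' model used by the difference method of mediation).
#'
#' @param data An [era_data()].
#' @param spec An [era_spec()].
#' @param priors An [era_priors()].
#' @param control An [era_control()]; `control$seed` seeds the single RNG
#'   stream, making runs bit-for-bit reproducible.
#' @param include_mediators Include the mediator model and the
#'   mediator-to-outcome coefficients `A4` (default `TRUE`).
#' @param approx A [t_approx()]; its `nu0` and `sigma0_sq` are fixed
#'   constants of the latent ordinal block, never sampled.
#' @param fixed Optional list pinning parameters for oracle checks and
#'   restricted fits: any of `W` (a `P x K` matrix), `phi = TRUE` (all
#'   mixture precisions pinned at 1), `SigmaM`, `SigmaY`, `nu_M`, `nu_C`.
#'   Pinned parameters are not updated.
#' @return Object of class `"era_fit"`: list with `draws` (class
#'   `"era_draws"`), `spec`, `control`, `accept` (Metropolis acceptance
#'   rates), `runtime` seconds, and the `data`.
#' @export
era_fit <- function(data, spec, priors = era_priors(),
                    control = era_control(), include_mediators = TRUE,
                    approx = t_approx(), fixed = list()) {
  validate_era(spec, data)
  set.seed(control$seed)
  t0 <- proc.time()[["elapsed"]]
  ctx <- new_sampler_ctx(data, spec, priors, control, include_mediators,
                         approx, fixed)
  S <- (control$n_iter - control$burn_in) %/% control$thin
  sto <- alloc_draws(ctx, S)
  s <- 0L
  for (it in seq_len(control$n_iter)) {
    step_weights(ctx)
    step_mediator(ctx)
    step_latent(ctx)
    step_response(ctx)
    if (!all(is.finite(ctx$B)) || !all(is.finite(ctx$U)))
      stop(sprintf("sampler diverged at iteration %d (non-finite state)", it))
    if (it > control$burn_in && (it - control$burn_in) %% control$thin == 0L) {
      s <- s + 1L
      record_draw(ctx, sto, s)
    }
  }
  accept <- lapply(ctx$acc, function(a)
    if (a[["prop"]] > 0) a[["acc"]] / a[["prop"]] else NA_real_)
  draws <- build_draws(ctx, sto, S)
  structure(list(draws = draws, spec = spec, control = control,
                 priors = priors, include_mediators = include_mediators,
                 approx = approx, accept = accept,
                 runtime = proc.time()[["elapsed"]] - t0, data = data),
            class = "era_fit")
}

#' @export
print.era_fit <- function(x, ...) {
  d <- x$draws
  cat(sprintf("Bayesian ERA fit: %d retained draws (%d iterations, %d burn-in, thin %d)\n",
              nrow(d$w), x$control$n_iter, x$control$burn_in,
              x$control$thin))
  cat(sprintf("  mediators %s; runtime %.1fs\n",
              if (x$include_mediators) "included" else "excluded",
              x$runtime))
  ar <- vapply(x$accept, function(a) a %||% NA_real_, numeric(1))
  ar <- ar[!is.na(ar)]
  if (length(ar))
    cat("  Metropolis acceptance: ",
        paste(sprintf("%s %.2f", names(ar), ar), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# Build the mutable sampler context (an environment: state + constants).
new_sampler_ctx <- function(data, spec, priors, control, include_mediators,
                            approx, fixed) {
  ctx <- new.env(parent = emptyenv())
  ctx$N <- nrow(data$X); ctx$P <- spec$P; ctx$K <- spec$K
  ctx$C <- spec$C; ctx$Q <- spec$Q; ctx$Tc <- spec$T
  ctx$n_ord <- spec$Q - spec$T
  ctx$R <- if (include_mediators) spec$R else 0L
  ctx$blocks <- spec$blocks
  ctx$cats <- spec$categories
  ctx$X <- data$X; ctx$Covm <- data$Cov
  ctx$M <- if (ctx$R) data$M else matrix(0, ctx$N, 0L)
  ctx$nu0 <- approx$nu0; ctx$sigma0 <- sqrt(approx$sigma0_sq)
  ctx$tau2 <- priors$coef_var; ctx$pm <- priors$coef_mean
  ctx$nu_lo <- priors$nu_inv_lo; ctx$nu_hi <- priors$nu_inv_hi
  ctx$step_phi <- priors$step_phi; ctx$step_nu <- priors$step_nu
  ctx$step_px <- priors$step_expand
  ctx$expand <- control$expand
  ctx$store_latent <- control$store_latent
  if (ctx$R) {
    ctx$wshM <- resolve_wishart(priors, ctx$R, "M")
    ctx$V0Minv <- chol2inv(chol_jitter(ctx$wshM$scale))
  }
  ctx$wshY <- resolve_wishart(priors, ctx$Q, "Y")
  ctx$V0Yinv <- chol2inv(chol_jitter(ctx$wshY$scale))
  ctx$fixed <- fixed
  ctx$acc <- list(phi1 = c(acc = 0, prop = 0), phi2 = c(acc = 0, prop = 0),
                  phiM = c(acc = 0, prop = 0), nu_C = c(acc = 0, prop = 0),
                  nu_M = c(acc = 0, prop = 0), expand = c(acc = 0, prop = 0))
  init_state(ctx, data, control)
  ctx
}

init_state <- function(ctx, data, control) {
  N <- ctx$N; Q <- ctx$Q; Tc <- ctx$Tc
  tau <- sqrt(ctx$tau2)
  fx <- ctx$fixed
  pin_phi <- isTRUE(fx$phi)
  # degrees of freedom: draw 1/nu uniformly on its prior support
  draw_nu <- function() 1 / stats::runif(1L, max(ctx$nu_lo, 1e-3), ctx$nu_hi)
  from_prior <- control$init == "prior"
  ctx$nu_M <- fx$nu_M %||% (if (from_prior) draw_nu() else 10)
  ctx$nu_C <- fx$nu_C %||% (if (from_prior) draw_nu() else 10)
  # weights: prior draw (or equal weights for the LS start), standardized
  W0 <- matrix(0, ctx$P, ctx$K)
  for (k in seq_len(ctx$K)) {
    idx <- ctx$blocks == k
    W0[idx, k] <- if (!is.null(fx$W)) fx$W[idx, k]
    else if (from_prior) stats::rnorm(sum(idx), ctx$pm, tau)
    else 1
  }
  mc <- make_components(ctx$X, W0, list(P = ctx$P, K = ctx$K,
                                        blocks = ctx$blocks))
  ctx$W <- mc$W; ctx$Fc <- mc$F
  ctx$G <- cbind(1, ctx$Covm, ctx$Fc)
  pG <- ncol(ctx$G)
  # cutpoints: first fixed at 0, the rest unit-spaced to start
  ctx$cut <- lapply(ctx$cats, function(J) as.numeric(0:(J - 2L)))
  ctx$Yord <- data$Yord
  # crude latent start on the logistic scale for the LS initialization
  Z0 <- matrix(0, N, ctx$n_ord)
  for (j in seq_len(ctx$n_ord))
    Z0[, j] <- stats::qlogis((ctx$Yord[, j] - 0.5) / ctx$cats[j])
  U0 <- cbind(data$Ycont, Z0)
  if (ctx$R) {
    ctx$BM <- if (from_prior) matrix(stats::rnorm(pG * ctx$R, ctx$pm, tau),
                                     pG, ctx$R)
    else qr.solve(ctx$G, ctx$M)
    if (!is.null(fx$SigmaM)) {
      ctx$SigmaM <- fx$SigmaM
    } else if (from_prior) {
      prec <- rwishart1(ctx$wshM$df, ctx$wshM$scale)
      ctx$SigmaM <- chol2inv(chol_jitter(prec))
    } else ctx$SigmaM <- symm(stats::cov(ctx$M - ctx$G %*% ctx$BM)) +
        diag(1e-6, ctx$R)
    ctx$SMinv <- chol2inv(chol_jitter(ctx$SigmaM))
    ctx$phiM <- if (pin_phi) rep(1, N)
      else sample_mixture_precision(ctx$nu_M, N)
  }
  ctx$Xt <- cbind(ctx$G, ctx$M)
  pB <- pG + ctx$R
  ctx$B <- if (from_prior) matrix(stats::rnorm(pB * Q, ctx$pm, tau), pB, Q)
  else qr.solve(ctx$Xt, U0)
  if (!is.null(fx$SigmaY)) {
    ctx$SigmaY <- fx$SigmaY
  } else if (from_prior) {
    prec <- rwishart1(ctx$wshY$df, ctx$wshY$scale)
    ctx$SigmaY <- chol2inv(chol_jitter(prec))
  } else ctx$SigmaY <- symm(stats::cov(U0 - ctx$Xt %*% ctx$B)) +
      diag(1e-6, Q)
  ctx$SYinv <- chol2inv(chol_jitter(ctx$SigmaY))
  ctx$phi1 <- if (pin_phi || Tc == 0L || !from_prior) rep(1, N)
    else sample_mixture_precision(ctx$nu_C, N)
  ctx$phi2 <- if (pin_phi || ctx$n_ord == 0L || !from_prior) rep(1, N)
    else sample_mixture_precision(ctx$nu0, N)
  refresh_dinv(ctx)
  # latent ordinal start: truncated draws around the initial mean structure
  eta <- ctx$Xt %*% ctx$B
  ctx$U <- matrix(0, N, Q)
  if (Tc) ctx$U[, seq_len(Tc)] <- data$Ycont
  for (j in seq_len(ctx$n_ord)) {
    q <- Tc + j
    ge <- c(-Inf, ctx$cut[[j]], Inf)
    y <- ctx$Yord[, j]
    sdq <- sqrt(ctx$SigmaY[q, q]) / ctx$Dinv[, q]
    ctx$U[, q] <- rtruncnorm_vec(eta[, q], sdq, ge[y], ge[y + 1L])
  }
  invisible(ctx)
}

# Per-subject inverse error scales: sqrt(phi1) on the continuous block,
# sqrt(phi2)/sigma0 on the ordinal block.
refresh_dinv <- function(ctx) {
  Dinv <- matrix(1, ctx$N, ctx$Q)
  if (ctx$Tc) Dinv[, seq_len(ctx$Tc)] <- sqrt(ctx$phi1)
  if (ctx$n_ord)
    Dinv[, ctx$Tc + seq_len(ctx$n_ord)] <- sqrt(ctx$phi2) / ctx$sigma0
  ctx$Dinv <- Dinv
  invisible(ctx)
}

comp_rows <- function(ctx) 1L + ctx$C + seq_len(ctx$K)

# (1) weights: joint normal full conditional, then standardization with the
# compensating rescale of the component coefficient rows + sign convention.
step_weights <- function(ctx) {
  if (!is.null(ctx$fixed$W)) return(invisible(ctx))
  cr <- comp_rows(ctx)
  med <- if (ctx$R) {
    nc_rows <- setdiff(seq_len(ncol(ctx$G)), cr)
    list(A2c = ctx$BM[cr, , drop = FALSE], SMinv = ctx$SMinv,
         phiM = ctx$phiM,
         Mt = ctx$M - ctx$G[, nc_rows, drop = FALSE] %*%
           ctx$BM[nc_rows, , drop = FALSE])
  }
  nc_rows_b <- setdiff(seq_len(nrow(ctx$B)), cr)
  resp <- list(A3c = ctx$B[cr, , drop = FALSE], SYinv = ctx$SYinv,
               Dinv = ctx$Dinv,
               Ut = ctx$U - ctx$Xt[, nc_rows_b, drop = FALSE] %*%
                 ctx$B[nc_rows_b, , drop = FALSE])
  w <- draw_weights(ctx$X, ctx$blocks, med, resp, ctx$tau2, ctx$pm)
  W <- matrix(0, ctx$P, ctx$K)
  W[cbind(seq_len(ctx$P), ctx$blocks)] <- w
  Fraw <- ctx$X %*% W
  sdev <- apply(Fraw, 2L, stats::sd)
  if (any(sdev < 1e-12)) stop("degenerate weight draw: zero-variance component")
  W <- sweep(W, 2L, sdev, "/")
  A2c <- if (ctx$R) ctx$BM[cr, , drop = FALSE] * sdev
  A3c <- ctx$B[cr, , drop = FALSE] * sdev
  for (k in seq_len(ctx$K)) {
    p1 <- which(ctx$blocks == k)[1L]
    if (W[p1, k] < 0) {
      W[, k] <- -W[, k]
      if (ctx$R) A2c[k, ] <- -A2c[k, ]
      A3c[k, ] <- -A3c[k, ]
    }
  }
  ctx$W <- W
  ctx$Fc <- ctx$X %*% W
  ctx$G <- cbind(1, ctx$Covm, ctx$Fc)
  ctx$Xt <- cbind(ctx$G, ctx$M)
  if (ctx$R) ctx$BM[cr, ] <- A2c
  ctx$B[cr, ] <- A3c
  invisible(ctx)
}

# (2) mediator block: conjugate (a1, A2); Wishart SigmaM; Metropolis phi_M
# and nu_M.
step_mediator <- function(ctx) {
  if (!ctx$R) return(invisible(ctx))
  ctx$BM <- draw_coef_mediator(ctx$G, ctx$M, ctx$phiM, ctx$SMinv,
                               ctx$tau2, ctx$pm)
  EM <- ctx$M - ctx$G %*% ctx$BM
  if (is.null(ctx$fixed$SigmaM)) {
    up <- update_covariance(EM, ctx$phiM, ctx$wshM)
    ctx$SigmaM <- up$Sigma; ctx$SMinv <- up$Sigmainv
  }
  if (!isTRUE(ctx$fixed$phi)) {
    qM <- rowSums((EM %*% ctx$SMinv) * EM)
    up <- metropolis_precision(ctx$phiM, ctx$nu_M, ctx$R, qM,
                               step = ctx$step_phi)
    ctx$phiM <- up$phi
    ctx$acc$phiM <- ctx$acc$phiM + c(acc = up$accepted, prop = ctx$N)
    if (is.null(ctx$fixed$nu_M)) {
      upn <- metropolis_df(ctx$nu_M, ctx$phiM, ctx$nu_lo, ctx$nu_hi,
                           ctx$step_nu)
      ctx$nu_M <- upn$nu
      ctx$acc$nu_M <- ctx$acc$nu_M + c(acc = upn$accepted, prop = 1)
    }
  }
  invisible(ctx)
}

# (3) latent ordinal variables: univariate truncated-normal conditionals of
# the joint error law, one ordinal outcome at a time, vectorized over
# subjects.
step_latent <- function(ctx) {
  if (!ctx$n_ord) return(invisible(ctx))
  eta <- ctx$Xt %*% ctx$B
  Rm <- ctx$U - eta
  for (j in seq_len(ctx$n_ord)) {
    q <- ctx$Tc + j
    dq <- ctx$Dinv[, q]
    pvec <- ctx$SYinv[q, q] * dq^2
    Sq <- (ctx$Dinv * Rm) %*% ctx$SYinv[, q]
    adj <- dq * (Sq - dq * Rm[, q] * ctx$SYinv[q, q])
    mu <- eta[, q] - adj / pvec
    sdq <- 1 / sqrt(pvec)
    ge <- c(-Inf, ctx$cut[[j]], Inf)
    y <- ctx$Yord[, j]
    z <- rtruncnorm_vec(mu, sdq, ge[y], ge[y + 1L])
    ctx$U[, q] <- z
    Rm[, q] <- z - eta[, q]
  }
  invisible(ctx)
}

# (4) response block: conjugate (a0, A3, A4); uniform cutpoint conditionals;
# Wishart SigmaY with the parameter-expansion move; Metropolis phi1, phi2,
# nu_C.
step_response <- function(ctx) {
  ctx$B <- draw_coef_response(ctx$Xt, ctx$U, ctx$Dinv, ctx$SYinv,
                              ctx$tau2, ctx$pm)
  step_cutpoints(ctx)
  ctx$Rm <- ctx$U - ctx$Xt %*% ctx$B
  if (is.null(ctx$fixed$SigmaY)) {
    up <- update_covariance(ctx$Rm * ctx$Dinv, NULL, ctx$wshY)
    ctx$SigmaY <- up$Sigma; ctx$SYinv <- up$Sigmainv
    if (ctx$expand && ctx$n_ord) step_expand_scale(ctx)
  }
  step_precisions(ctx, ctx$Rm)
  invisible(ctx)
}

step_cutpoints <- function(ctx) {
  for (j in seq_len(ctx$n_ord)) {
    J <- ctx$cats[j]
    if (J <= 2L) next
    q <- ctx$Tc + j
    z <- ctx$U[, q]
    y <- ctx$Yord[, j]
    g <- ctx$cut[[j]]
    for (l in 2L:(J - 1L)) {
      lo <- max(c(z[y == l], g[l - 1L]))
      hi <- min(c(z[y == l + 1L], if (l < J - 1L) g[l + 1L] else Inf))
      if (is.finite(hi) && hi > lo) g[l] <- stats::runif(1L, lo, hi)
      # unbounded above (top category empty): keep the current value
    }
    ctx$cut[[j]] <- g
  }
  invisible(ctx)
}

# Parameter-expansion move: Metropolis on the unidentified latent scale of
# each ordinal coordinate. The deterministic group action multiplies the
# latent column, its intercept/coefficients/cutpoints and the SigmaY
# row/column by alpha; identified quantities are invariant, so the move only
# improves mixing/stability of the unidentified scale. The acceptance ratio
# collects the normal coefficient-prior terms, the Wishart prior terms and
# the Jacobian of the action.
step_expand_scale <- function(ctx) {
  for (j in seq_len(ctx$n_ord)) {
    q <- ctx$Tc + j
    eps <- stats::rnorm(1L, 0, ctx$step_px)
    alpha <- exp(eps)
    theta <- c(ctx$B[, q])
    dprior <- sum(stats::dnorm(alpha * theta, ctx$pm, sqrt(ctx$tau2),
                               log = TRUE) -
                  stats::dnorm(theta, ctx$pm, sqrt(ctx$tau2), log = TRUE))
    P <- ctx$SYinv
    P2 <- P
    P2[q, ] <- P2[q, ] / alpha
    P2[, q] <- P2[, q] / alpha
    dtr <- -0.5 * sum(ctx$V0Yinv * (P2 - P))
    nscale <- length(theta) + (ctx$cats[j] - 2L) - ctx$wshY$df
    logA <- nscale * eps + dprior + dtr
    ctx$acc$expand <- ctx$acc$expand + c(acc = 0, prop = 1)
    if (log(stats::runif(1L)) < logA) {
      ctx$U[, q] <- alpha * ctx$U[, q]
      ctx$Rm[, q] <- alpha * ctx$Rm[, q]       # residual scales with u, eta
      ctx$B[, q] <- alpha * ctx$B[, q]
      ctx$cut[[j]] <- alpha * ctx$cut[[j]]
      ctx$SigmaY[q, ] <- alpha * ctx$SigmaY[q, ]
      ctx$SigmaY[, q] <- alpha * ctx$SigmaY[, q]
      ctx$SYinv <- P2
      ctx$acc$expand <- ctx$acc$expand + c(acc = 1, prop = 0)
    }
  }
  invisible(ctx)
}

step_precisions <- function(ctx, Rm) {
  if (isTRUE(ctx$fixed$phi)) return(invisible(ctx))
  Tc <- ctx$Tc; n_ord <- ctx$n_ord
  ci <- seq_len(Tc)
  oi <- Tc + seq_len(n_ord)
  if (Tc) {
    Ec <- Rm[, ci, drop = FALSE]
    Acc <- ctx$SYinv[ci, ci, drop = FALSE]
    qa <- rowSums((Ec %*% Acc) * Ec)
    qb <- 0
    if (n_ord) {
      So <- ctx$Dinv[, oi, drop = FALSE] * Rm[, oi, drop = FALSE]
      Aco <- ctx$SYinv[ci, oi, drop = FALSE]
      qb <- 2 * rowSums((Ec %*% Aco) * So)
    }
    up <- metropolis_precision(ctx$phi1, ctx$nu_C, Tc, qa, qb,
                               ctx$step_phi)
    ctx$phi1 <- up$phi
    ctx$acc$phi1 <- ctx$acc$phi1 + c(acc = up$accepted, prop = ctx$N)
    refresh_dinv(ctx)
    if (is.null(ctx$fixed$nu_C)) {
      upn <- metropolis_df(ctx$nu_C, ctx$phi1, ctx$nu_lo, ctx$nu_hi,
                           ctx$step_nu)
      ctx$nu_C <- upn$nu
      ctx$acc$nu_C <- ctx$acc$nu_C + c(acc = upn$accepted, prop = 1)
    }
  }
  if (n_ord) {
    Bo <- Rm[, oi, drop = FALSE] / ctx$sigma0
    Aoo <- ctx$SYinv[oi, oi, drop = FALSE]
    qa <- rowSums((Bo %*% Aoo) * Bo)
    qb <- 0
    if (Tc) {
      Sc <- ctx$Dinv[, ci, drop = FALSE] * Rm[, ci, drop = FALSE]
      Aoc <- ctx$SYinv[oi, ci, drop = FALSE]
      qb <- 2 * rowSums((Bo %*% Aoc) * Sc)
    }
    up <- metropolis_precision(ctx$phi2, ctx$nu0, n_ord, qa, qb,
                               ctx$step_phi)
    ctx$phi2 <- up$phi
    ctx$acc$phi2 <- ctx$acc$phi2 + c(acc = up$accepted, prop = ctx$N)
    refresh_dinv(ctx)
  }
  invisible(ctx)
}

# ---- draw storage ----------------------------------------------------------

alloc_draws <- function(ctx, S) {
  pG <- 1L + ctx$C + ctx$K
  sto <- new.env(parent = emptyenv())
  sto$w <- matrix(NA_real_, S, ctx$P)
  sto$a0 <- matrix(NA_real_, S, ctx$Q)
  sto$A3 <- array(NA_real_, c(S, ctx$C + ctx$K, ctx$Q))
  sto$SigmaY <- array(NA_real_, c(S, ctx$Q, ctx$Q))
  sto$nu_C <- rep(NA_real_, S)
  sto$A4 <- array(NA_real_, c(S, ctx$R, ctx$Q))
  sto$a1 <- matrix(NA_real_, S, ctx$R)
  sto$A2 <- array(NA_real_, c(S, ctx$C + ctx$K, ctx$R))
  sto$SigmaM <- array(NA_real_, c(S, ctx$R, ctx$R))
  sto$nu_M <- rep(NA_real_, S)
  sto$cut <- lapply(ctx$cats, function(J) matrix(NA_real_, S, J - 1L))
  sto$Z <- if (ctx$n_ord && ctx$store_latent)
    array(NA_real_, c(S, ctx$N, ctx$n_ord))
  sto
}

record_draw <- function(ctx, sto, s) {
  cr <- comp_rows(ctx)
  sto$w[s, ] <- ctx$W[cbind(seq_len(ctx$P), ctx$blocks)]
  sto$a0[s, ] <- ctx$B[1L, ]
  sto$A3[s, , ] <- ctx$B[1L + seq_len(ctx$C + ctx$K), , drop = FALSE]
  if (ctx$R) {
    sto$A4[s, , ] <- ctx$B[1L + ctx$C + ctx$K + seq_len(ctx$R), ,
                           drop = FALSE]
    sto$a1[s, ] <- ctx$BM[1L, ]
    sto$A2[s, , ] <- ctx$BM[1L + seq_len(ctx$C + ctx$K), , drop = FALSE]
    sto$SigmaM[s, , ] <- ctx$SigmaM
    sto$nu_M[s] <- ctx$nu_M
  }
  sto$SigmaY[s, , ] <- ctx$SigmaY
  sto$nu_C[s] <- ctx$nu_C
  for (j in seq_len(ctx$n_ord)) sto$cut[[j]][s, ] <- ctx$cut[[j]]
  if (!is.null(sto$Z))
    sto$Z[s, , ] <- ctx$U[, ctx$Tc + seq_len(ctx$n_ord), drop = FALSE]
  invisible(sto)
}

build_draws <- function(ctx, sto, S) {
  structure(list(w = sto$w, blocks = ctx$blocks, a0 = sto$a0, A3 = sto$A3,
                 A4 = sto$A4, a1 = sto$a1, A2 = sto$A2,
                 SigmaM = sto$SigmaM, nu_M = sto$nu_M,
                 SigmaY = sto$SigmaY, nu_C = sto$nu_C, cut = sto$cut,
                 Z = sto$Z, n_continuous = ctx$Tc,
                 categories = ctx$cats, identified = FALSE),
            class = "era_draws")
}

#' Reconstruct the block-sparse weight matrix of one retained draw
#'
#' @param draws An `"era_draws"` object (or an `"era_fit"`).
#' @param s Draw index.
#' @return `P x K` block-sparse weight matrix.
#' @export
draw_W <- function(draws, s) {
  if (inherits(draws, "era_fit")) draws <- draws$draws
  P <- ncol(draws$w)
  K <- max(draws$blocks)
  W <- matrix(0, P, K)
  W[cbind(seq_len(P), draws$blocks)] <- draws$w[s, ]
  W
}

#' Rescale draws to the identified (unit latent variance) scale
#'
#' For each retained draw and each ordinal outcome coordinate, divides the
#' intercept, the coefficient columns of `A3`/`A4` and the cutpoints by the
#' square root of the corresponding `SigmaY` diagonal, and rescales the
#' `SigmaY` rows/columns so those diagonals become 1. Continuous-outcome
#' coordinates are unchanged. On this scale ordinal coefficients are
#' interpretable as log odds ratios (the latent residual is the
#' variance-matched t(7.3), i.e. near-logistic). Idempotent: applying twice
#' is a no-op.
#'
#' @param x An `"era_fit"` or `"era_draws"` object.
#' @return An `"era_draws"` object on the identified scale.
#' @export
identified_rescale <- function(x) {
  d <- if (inherits(x, "era_fit")) x$draws else x
  stopifnot(inherits(d, "era_draws"))
  if (isTRUE(d$identified)) return(d)
  Tc <- d$n_continuous
  n_ord <- length(d$categories)
  if (n_ord) {
    S <- nrow(d$a0)
    # per-draw latent sd of every ordinal coordinate, taken before any
    # rescaling touches SigmaY
    sq <- vapply(seq_len(n_ord),
                 function(j) sqrt(d$SigmaY[, Tc + j, Tc + j]), numeric(S))
    sq <- matrix(sq, S, n_ord)
    for (j in seq_len(n_ord)) {
      q <- Tc + j
      d$a0[, q] <- d$a0[, q] / sq[, j]
      d$A3[, , q] <- d$A3[, , q] / sq[, j]
      if (length(d$A4)) d$A4[, , q] <- d$A4[, , q] / sq[, j]
      d$cut[[j]] <- d$cut[[j]] / sq[, j]
    }
    for (j in seq_len(n_ord)) {
      q <- Tc + j
      d$SigmaY[, q, ] <- d$SigmaY[, q, ] / sq[, j]
      d$SigmaY[, , q] <- d$SigmaY[, , q] / sq[, j]
    }
  }
  d$identified <- TRUE
  d
}
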