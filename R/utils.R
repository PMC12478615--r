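# Internal numerical helpers shared by the simulator and the sampler.

# Draw n rows from N(mean, Sigma) via Cholesky. `mean` is a vector (recycled
# per row) or an n x d matrix of per-row means.
rmvnorm_chol <- function(n, mean, Sigma) {
  d <- ncol(Sigma)
  L <- chol(Sigma)
  Z <- matrix(stats::rnorm(n * d), n, d) %*% L
  if (is.matrix(mean)) Z + mean else sweep(Z, 2, rep_len(mean, d), "+")
}

# Symmetrize a nearly-symmetric matrix (guards accumulated FP asymmetry).
symm <- function(A) (A + t(A)) / 2

# Cholesky with escalating diagonal jitter; used when a conditional
# covariance/precision draw is numerically non-PD.
chol_jitter <- function(A, max_tries = 6L) {
  A <- symm(A)
  eps <- 0
  for (k in seq_len(max_tries)) {
    R <- tryCatch(chol(A + diag(eps, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) return(R)
    eps <- if (eps == 0) 1e-10 * max(1, max(abs(diag(A)))) else eps * 100
  }
  stop("matrix not positive definite even after jitter")
}

# Draw from N(P^{-1} b, P^{-1}) given precision P and linear term b.
rmvnorm_precision <- function(b, P) {
  R <- chol_jitter(P)                 # P = R'R
  mu <- backsolve(R, forwardsolve(t(R), b))
  mu + backsolve(R, stats::rnorm(length(b)))
}

# One draw of a Wishart(df, S) matrix (E = df * S), thin wrapper kept so the
# call site reads as the model does.
rwishart1 <- function(df, S) {
  W <- stats::rWishart(1L, df, symm(S))[, , 1L]
  symm(W)
}

# Vectorized truncated-normal sampler on (lo, hi], robust in far tails.
# Inverse-CDF in the bulk; Robert (1995) exponential rejection when the
# whole interval sits beyond ~6 sd, where pnorm() underflows.
rtruncnorm_vec <- function(mean, sd, lo, hi) {
  n <- length(mean)
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  out <- numeric(n)
  far_r <- a > 6                       # interval deep in the upper tail
  far_l <- b < -6                      # deep in the lower tail
  mid <- !(far_r | far_l)
  if (any(mid)) {
    pa <- stats::pnorm(a[mid])
    pb <- stats::pnorm(b[mid])
    u <- stats::runif(sum(mid), pa, pb)
    u <- pmin(pmax(u, 1e-300), 1 - 1e-16)
    out[mid] <- stats::qnorm(u)
  }
  if (any(far_r)) out[far_r] <- rtail_exp(a[far_r], b[far_r])
  if (any(far_l)) out[far_l] <- -rtail_exp(-b[far_l], -a[far_l])
  out * sd + mean
}

# Rejection sampler for standard normal truncated to (a, b), all a > 0 large.
rtail_exp <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    m <- sum(todo)
    aa <- a[todo]
    x <- aa + stats::rexp(m, aa)       # shifted-exponential proposal
    acc <- stats::runif(m) <= exp(-(x - aa)^2 / 2) & x <= b[todo]
    idx <- which(todo)[acc]
    out[idx] <- x[acc]
    todo[idx] <- FALSE
  }
  out
}

# Named-index label helpers ("A2[1,2]" style) used by draws I/O and trace().
idx_names <- function(base, d1, d2 = NULL) {
  if (is.null(d2)) sprintf("%s[%d]", base, seq_len(d1))
  else as.vector(outer(seq_len(d1), seq_len(d2),
                       function(i, j) sprintf("%s[%d,%d]", base, i, j)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
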