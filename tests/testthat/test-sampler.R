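test_that("update_covariance reproduces its prior and a known posterior", {
  # prior-only (N = 0): draws match the inverse-Wishart prior mean.
  # Use df = d + 10 so the prior mean has finite variance: E[Sigma] =
  # scale^{-1} / (df - d - 1).
  prior <- list(df = 12, scale = diag(2) / 12)
  set.seed(41)
  S <- 4000
  acc <- matrix(0, 2, 2)
  for (s in seq_len(S))
    acc <- acc + update_covariance(matrix(0, 0, 2), NULL, prior)$Sigma
  expect_lt(max(abs(acc / S - 12 * diag(2) / 9)), 0.1)

  # dominant-likelihood regime: residuals from N(0, diag(1, 4)); MC mean of
  # the draws matches the exact inverse-Wishart posterior mean
  set.seed(42)
  E <- cbind(rnorm(1e4), 2 * rnorm(1e4))
  prior2 <- list(df = 4, scale = diag(2) / 4)
  acc <- matrix(0, 2, 2)
  for (s in 1:200) {
    up <- update_covariance(E, rep(1, 1e4), prior2)
    acc <- acc + up$Sigma
    expect_lt(max(abs(up$Sigma - t(up$Sigma))), 1e-12)
    expect_true(all(eigen(up$Sigma, only.values = TRUE)$values > 0))
  }
  post_mean <- (solve(prior2$scale) + crossprod(E)) / (4 + 1e4 - 3)
  expect_lt(max(abs(acc / 200 - post_mean)), 0.05)
  expect_lt(max(abs(post_mean - diag(c(1, 4)))), 0.15)  # sanity vs truth
})

test_that("metropolis_precision targets its full conditional", {
  # step -> 0: everything is accepted
  set.seed(43)
  up <- metropolis_precision(rep(1, 50), nu = 5, d = 2, qa = rep(1, 50),
                             step = 1e-9)
  expect_equal(up$accepted, 50L)
  expect_true(all(up$phi > 0))

  # 1-subject toy vs dense numerical integration of
  # f(phi) ~ phi^{d/2+nu/2-1} exp(-nu phi/2) exp(-(phi qa + sqrt(phi) qb)/2)
  nu <- 4; d <- 2; qa <- 1.5; qb <- 0.8
  grid <- seq(1e-5, 30, length.out = 40000)
  lf <- (d / 2 + nu / 2 - 1) * log(grid) - nu * grid / 2 -
    (grid * qa + sqrt(grid) * qb) / 2
  w <- exp(lf - max(lf)); w <- w / sum(w)
  m_true <- sum(grid * w)
  q_true <- grid[findInterval(c(0.25, 0.5, 0.75), cumsum(w)) + 1L]
  set.seed(44)
  phi <- 1
  draws <- numeric(20000)
  for (s in seq_along(draws)) {
    phi <- metropolis_precision(phi, nu, d, qa, qb, step = 0.8)$phi
    draws[s] <- phi
  }
  expect_lt(abs(mean(draws) - m_true), 0.05 * m_true + 0.02)
  emp_q <- quantile(draws, c(0.25, 0.5, 0.75), names = FALSE)
  expect_lt(max(abs(emp_q - q_true)), 0.08)
})

test_that("metropolis_df respects its support and moves toward the data", {
  set.seed(45)
  # every retained state stays inside the prior support on 1/nu
  phi <- sample_mixture_precision(5, 200)
  for (i in 1:50) {
    up <- metropolis_df(4, phi, lo_inv = 0.2, hi_inv = 0.3, step = 5)
    if (up$accepted) expect_true(1 / up$nu >= 0.2 && 1 / up$nu <= 0.3)
    else expect_identical(up$nu, 4)
  }
  # chain over the gamma likelihood concentrates near the generating nu
  set.seed(46)
  phi <- sample_mixture_precision(5, 2000)
  nu <- 2
  draws <- numeric(3000)
  for (s in seq_along(draws)) {
    nu <- metropolis_df(nu, phi, step = 0.02)$nu
    draws[s] <- nu
  }
  kept <- draws[-(1:500)]
  q <- quantile(kept, c(0.05, 0.95))
  expect_lt(q[[1]], 5); expect_gt(q[[2]], 4)   # mass brackets nu = 5
  expect_true(abs(mean(kept) - 5) < 1.5)
  expect_true(all(1 / draws <= 1 & 1 / draws > 0))
})

test_that("coefficient and weight conditionals reduce to the prior at N=0", {
  set.seed(47)
  S <- 4000
  tau2 <- 4; pm <- 0.5
  # response coefficients, 2 outcomes x 2 columns
  draws <- replicate(S, bera:::draw_coef_response(
    matrix(0, 0, 2), matrix(0, 0, 2), matrix(0, 0, 2), diag(2), tau2, pm))
  expect_lt(max(abs(apply(draws, c(1, 2), mean) - pm)), 4 * sqrt(tau2 / S))
  expect_lt(abs(var(draws[1, 1, ]) - tau2), 4 * tau2 * sqrt(2 / S))
  # mediator coefficients
  draws2 <- replicate(S, bera:::draw_coef_mediator(
    matrix(0, 0, 2), matrix(0, 0, 1), numeric(0), diag(1), tau2, pm))
  expect_lt(max(abs(apply(draws2, c(1, 2), mean) - pm)), 4 * sqrt(tau2 / S))
  # free weights (prior-only: med and resp absent)
  draws3 <- replicate(S, bera:::draw_weights(
    matrix(0, 0, 3), c(1L, 1L, 2L), NULL, NULL, tau2, pm))
  expect_lt(max(abs(rowMeans(draws3) - pm)), 4 * sqrt(tau2 / S))
  expect_lt(abs(var(draws3[2, ]) - tau2), 4 * tau2 * sqrt(2 / S))
})

test_that("truncated-normal sampler matches the half-normal and is robust", {
  set.seed(48)
  n <- 1e4
  z <- bera:::rtruncnorm_vec(rep(0, n), rep(1, n), rep(0, n), rep(Inf, n))
  expect_true(all(z > 0))
  ks <- suppressWarnings(
    ks.test(z, function(x) 2 * pnorm(x) - 1))
  expect_gt(ks$p.value, 0.01)
  # far-tail truncation stays finite and inside the interval
  zt <- bera:::rtruncnorm_vec(rep(-50, 100), rep(1, 100), rep(0, 100),
                              rep(Inf, 100))
  expect_true(all(is.finite(zt) & zt > 0))
  zb <- bera:::rtruncnorm_vec(rep(30, 100), rep(1, 100), rep(-Inf, 100),
                              rep(0, 100))
  expect_true(all(is.finite(zb) & zb <= 0))
})

test_that("negating the predictors gives the same identified posterior", {
  # the sign convention (first weight per block nonnegative) makes the
  # weight posterior identical for X and -X, with component coefficients
  # negated; checked on posterior means up to Monte-Carlo error
  sc <- default_scenario(200, seed = 49)
  ctrl <- era_control(n_iter = 900, burn_in = 300, thin = 2, seed = 3,
                      store_latent = FALSE, init = "ls")
  f1 <- era_fit(sc$data, sc$spec, control = ctrl)
  data_neg <- sc$data
  data_neg$X <- -data_neg$X
  f2 <- era_fit(data_neg, sc$spec, control = ctrl)
  expect_lt(max(abs(colMeans(f1$draws$w) - colMeans(f2$draws$w))), 0.12)
  expect_lt(max(abs(apply(f1$draws$A2, c(2, 3), mean) +
                      apply(f2$draws$A2, c(2, 3), mean))), 0.2)
})

test_that("every stored draw satisfies the structural invariants", {
  sh <- shared_small_fit()
  fit <- sh$fit; sc <- sh$sc
  d <- fit$draws
  S <- nrow(d$w)
  expect_equal(S, (900 - 300) %/% 3)
  for (s in seq(1L, S, by = 7L)) {
    W <- draw_W(d, s)
    # block sparsity and unit component variance
    expect_true(all(W[cbind(seq_len(sc$spec$P), sc$spec$blocks)] != 0))
    expect_equal(sum(W != 0), sc$spec$P)
    expect_lt(max(abs(apply(sc$data$X %*% W, 2, var) - 1)), 1e-10)
    # first weight per block nonnegative
    for (k in 1:sc$spec$K)
      expect_gte(W[which(sc$spec$blocks == k)[1], k], 0)
    # PD covariances
    expect_true(all(eigen(d$SigmaM[s, , ], only.values = TRUE)$values > 0))
    expect_true(all(eigen(d$SigmaY[s, , ], only.values = TRUE)$values > 0))
    # cutpoint ordering with the first fixed at zero
    for (j in 1:2) {
      g <- d$cut[[j]][s, ]
      expect_identical(g[1], 0)
      expect_true(all(diff(g) > 0))
    }
    # latent ordinal variables inside their category intervals
    for (j in 1:2) {
      ge <- c(-Inf, d$cut[[j]][s, ], Inf)
      y <- sc$data$Yord[, j]
      z <- d$Z[s, , j]
      expect_true(all(z > ge[y] & z <= ge[y + 1]))
    }
  }
})

test_that("fits are bit-for-bit reproducible under a fixed seed", {
  sc <- default_scenario(50, seed = 50)
  ctrl <- era_control(n_iter = 120, burn_in = 40, thin = 2, seed = 8)
  f1 <- era_fit(sc$data, sc$spec, control = ctrl)
  f2 <- era_fit(sc$data, sc$spec, control = ctrl)
  expect_identical(f1$draws$w, f2$draws$w)
  expect_identical(f1$draws$SigmaY, f2$draws$SigmaY)
  expect_identical(f1$draws$cut, f2$draws$cut)
})

test_that("identified_rescale is idempotent and scale-invariant", {
  sh <- shared_small_fit()
  d1 <- identified_rescale(sh$fit)
  expect_true(d1$identified)
  d2 <- identified_rescale(d1)
  expect_identical(d1, d2)
  # ordinal diagonals are exactly 1 after rescaling
  for (q in 3:4) expect_equal(d1$SigmaY[, q, q], rep(1, nrow(d1$a0)),
                              tolerance = 1e-12)
  # doubling an ordinal coordinate's scale leaves identified draws unchanged
  raw <- sh$fit$draws
  q <- 3L
  raw$a0[, q] <- 2 * raw$a0[, q]
  raw$A3[, , q] <- 2 * raw$A3[, , q]
  raw$A4[, , q] <- 2 * raw$A4[, , q]
  raw$cut[[1]] <- 2 * raw$cut[[1]]
  raw$SigmaY[, q, ] <- 2 * raw$SigmaY[, q, ]
  raw$SigmaY[, , q] <- 2 * raw$SigmaY[, , q]
  d3 <- identified_rescale(raw)
  expect_equal(d3$a0, d1$a0, tolerance = 1e-10)
  expect_equal(d3$A4, d1$A4, tolerance = 1e-10)
  expect_equal(d3$cut[[1]], d1$cut[[1]], tolerance = 1e-10)
})

test_that("the t df of the mediator errors is recovered", {
  sc <- default_scenario(400, seed = 51)       # generated with nu_M = 5
  fit <- era_fit(sc$data, sc$spec,
                 control = era_control(n_iter = 2500, burn_in = 500,
                                       thin = 5, seed = 9,
                                       store_latent = FALSE))
  ci <- quantile(fit$draws$nu_M, c(0.025, 0.975))
  expect_lt(ci[[1]], 5)
  expect_gt(ci[[2]], 5)
})
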