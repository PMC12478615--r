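test_that("generate_predictors draws the requested Gaussian law", {
  set.seed(31)
  n <- 1e4
  S <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  X <- generate_predictors(n, S)
  # 3 s.e. Monte-Carlo bands (se of a variance ~ sqrt(2/n), of r ~ 1/sqrt(n))
  expect_lt(max(abs(apply(X, 2, var) - 1)), 3 * sqrt(2 / n))
  expect_lt(abs(cor(X)[1, 2] - 0.5), 3 / sqrt(n))
  set.seed(7); A <- generate_predictors(5, diag(2))
  set.seed(7); B <- generate_predictors(5, diag(2))
  expect_identical(A, B)
  expect_error(generate_predictors(10, matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("make_components standardizes, compensates, and is idempotent", {
  spec <- era_spec(blocks = c(1L, 2L), n_continuous = 1L)
  set.seed(32)
  x1 <- scale(rnorm(400))[, 1]           # exactly unit variance
  x2 <- 2 * scale(rnorm(400))[, 1]       # variance 4
  X <- cbind(x1, x2)
  mc <- make_components(X, diag(2), spec)
  expect_equal(apply(mc$F, 2, var), c(1, 1), tolerance = 1e-12)
  # single unit-variance predictor with weight 1: component IS the predictor
  expect_equal(mc$F[, 1], x1, tolerance = 1e-12)
  # raw variance 4 block: weight divided by 2
  expect_equal(mc$W[2, 2], 0.5, tolerance = 1e-12)
  # idempotence on already-standardized weights
  mc2 <- make_components(X, mc$W, spec)
  expect_equal(mc2$W, mc$W, tolerance = 1e-12)
  # sign convention: first weight per block nonnegative
  mc3 <- make_components(X, -diag(2), spec)
  expect_true(all(mc3$W[cbind(1:2, 1:2)] >= 0))
  expect_error(make_components(X, matrix(1, 2, 2), spec), "block pattern")
  expect_error(make_components(X * 0, diag(2), spec), "degenerate")
})

test_that("simulate_mediators has t margins around the linear predictor", {
  tr <- bera:::default_truth()
  n <- 2e4
  set.seed(33)
  Fc <- matrix(rnorm(n * 2), n, 2)
  Cov <- matrix(0, n, 0)
  # zero mean structure: column means near 0
  tr0 <- tr; tr0$A2 <- matrix(0, 2, 2); tr0$a1 <- c(0, 0)
  M <- simulate_mediators(Fc, Cov, tr0)
  expect_lt(max(abs(colMeans(M))), 3 * sqrt(5 / 1 / n) * 2)
  # nu_M = 5: excess kurtosis 6/(nu-4) = 6 > 0
  k <- mean((M[, 1] - mean(M[, 1]))^4) / var(M[, 1])^2
  expect_gt(k, 3.5)
  # large df limit: empirical covariance approaches SigmaM = I
  tr0$nu_M <- 1e6; tr0$SigmaM <- diag(2)
  M2 <- simulate_mediators(Fc, Cov, tr0)
  expect_lt(max(abs(cov(M2) - diag(2))), 0.06)
})

test_that("simulate_outcomes matches logistic category probabilities", {
  tr <- bera:::default_truth()
  tr$A3 <- matrix(0, 2, 4); tr$A4 <- matrix(0, 2, 4)
  tr$a0 <- rep(0, 4)
  tr$cutoffs <- list(0, c(0, 1.5))
  n <- 4e4
  set.seed(34)
  Fc <- matrix(rnorm(n * 2), n, 2)
  M <- matrix(rnorm(n * 2), n, 2)
  out <- simulate_outcomes(Fc, matrix(0, n, 0), M, tr)
  # binary outcome with cutoff 0 and zero mean: half in category 2
  expect_lt(abs(mean(out$Yord[, 1] == 2) - 0.5), 3 * 0.5 / sqrt(n))
  # P(cat 3) = 1 - F_L(1.5) = 0.1824 (logistic CDF oracle)
  p3 <- 1 - plogis(1.5)
  expect_lt(abs(mean(out$Yord[, 2] == 3) - p3),
            3 * sqrt(p3 * (1 - p3) / n))
  # continuous outcomes with zero coefficients: mean 0 (t(5) errors)
  expect_lt(max(abs(colMeans(out$Ycont))), 3 * sqrt(5 / 3 / n) * 2)
})

test_that("zero-mean ordinal latents are exactly standard logistic", {
  tr <- bera:::default_truth()
  tr$A3 <- matrix(0, 2, 4); tr$A4 <- matrix(0, 2, 4); tr$a0 <- rep(0, 4)
  n <- 1e5
  set.seed(35)
  out <- simulate_outcomes(matrix(rnorm(n * 2), n, 2), matrix(0, n, 0),
                           matrix(rnorm(n * 2), n, 2), tr)
  for (j in 1:2) {
    ks <- suppressWarnings(ks.test(out$Zlat[, j], plogis))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("SigmaY correlation propagates to mixed-outcome association", {
  # zero mean structure isolates the residual law: the 0.3 off-diagonal of
  # SigmaY must induce positive rank correlation between a continuous and
  # an ordinal outcome
  tr <- bera:::default_truth()
  tr$A3 <- matrix(0, 2, 4); tr$A4 <- matrix(0, 2, 4); tr$a0 <- rep(0, 4)
  n <- 1e4
  set.seed(36)
  out <- simulate_outcomes(matrix(rnorm(n * 2), n, 2), matrix(0, n, 0),
                           matrix(rnorm(n * 2), n, 2), tr)
  tau <- cor(out$Ycont[, 1], as.numeric(out$Yord[, 1]), method = "kendall")
  expect_gt(tau, 0)
})

test_that("apply_cutoffs uses half-open intervals with left ties", {
  expect_equal(apply_cutoffs(0.5, c(0, 1.5)), 2L)
  expect_equal(apply_cutoffs(-3, 0), 1L)
  expect_equal(apply_cutoffs(0, c(0, 1.5)), 1L)    # tie: right endpoint
  expect_equal(apply_cutoffs(1.5, c(0, 1.5)), 2L)
  expect_equal(apply_cutoffs(c(-1, 0.2, 9), c(0, 1.5)), c(1L, 2L, 3L))
  expect_error(apply_cutoffs(1, c(1, 0)), "increasing")
})

test_that("default_scenario is valid, seeded, and matches its implied law", {
  sc1 <- default_scenario(100, seed = 37)
  sc2 <- default_scenario(100, seed = 37)
  expect_true(validate_era(sc1$spec, sc1$data))
  expect_identical(sc1$data, sc2$data)
  expect_error(default_scenario(10), "n >= 20")
  # component variance of truth weights is exactly 1 on the realized sample
  Fc <- sc1$data$X %*% sc1$truth$W
  expect_equal(apply(Fc, 2, var), c(1, 1), tolerance = 1e-12)

  # large n: ordinal category frequencies match the analytic logistic
  # probabilities conditional on the realized mean structure within 0.01
  n <- 1e5
  sc <- default_scenario(n, seed = 38)
  Fc <- sc$data$X %*% sc$truth$W
  eta <- matrix(sc$truth$a0, n, 4, byrow = TRUE) + Fc %*% sc$truth$A3 +
    sc$data$M %*% sc$truth$A4
  for (j in 1:2) {
    q <- 2 + j
    g <- c(-Inf, sc$truth$cutoffs[[j]], Inf)
    for (cat in 1:3) {
      p_analytic <- mean(plogis(g[cat + 1] - eta[, q]) -
                           plogis(g[cat] - eta[, q]))
      expect_lt(abs(mean(sc$data$Yord[, j] == cat) - p_analytic), 0.01)
    }
  }
})
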