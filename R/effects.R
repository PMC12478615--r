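#' Mediation effects and posterior summaries
#'
#' Indirect effects use the product-of-coefficients method: per retained
#' draw, the effect of source `s` on outcome `q` through mediator `m` is
#' `A2[s,m] * A4[m,q]`, so the posterior of the product (not the product of
#' posterior means) is summarized. The difference method contrasts the
#' component-to-outcome coefficients of a fit without mediators against the
#' fit with them. Ordinal-outcome effects can be reported on the odds-ratio
#' scale by exponentiating each draw before summarizing.
#'
#' @name era-effects
NULL

#' Per-draw indirect effects (product of coefficients)
#'
#' @param x An `"era_fit"` or `"era_draws"` object containing mediator
#'   (`A2`) and mediator-to-outcome (`A4`) draws. Draws are moved to the
#'   identified scale first if they are not already.
#' @return 4-d array `[draw, source, mediator, outcome]` with dimnames;
#'   sources are the covariate rows followed by the component rows of `A2`.
#' @export
indirect_effects <- function(x) {
  d <- identified_rescale(x)
  if (!length(d$A4))
    stop("no mediator coefficients in these draws (mediators excluded?)")
  S <- dim(d$A2)[1L]; nsrc <- dim(d$A2)[2L]
  R <- dim(d$A2)[3L]; Q <- dim(d$A4)[3L]
  if (dim(d$A4)[2L] != R) stop("mediator dimensions of A2 and A4 disagree")
  out <- array(NA_real_, c(S, nsrc, R, Q),
               dimnames = list(NULL, sprintf("src%d", seq_len(nsrc)),
                               sprintf("m%d", seq_len(R)),
                               sprintf("y%d", seq_len(Q))))
  for (m in seq_len(R))
    for (q in seq_len(Q))
      out[, , m, q] <- d$A2[, , m] * d$A4[, m, q]
  out
}

#' Per-draw difference-method mediation effects
#'
#' Pairs draws of the no-mediator fit with draws of the full fit by draw
#' index (an approximation across independent chains, flagged in the
#' result's attributes) and differences the component-to-outcome
#' coefficients `A3` on the identified scale.
#'
#' @param fit_full Fit with mediators.
#' @param fit_nomed Fit of the same spec/data without mediators.
#' @return 3-d array `[draw, source, outcome]` of
#'   `A3_nomediator - A3_full`, attribute `pairing = "by-index"`.
#' @export
difference_method <- function(fit_full, fit_nomed) {
  df_ <- identified_rescale(fit_full)
  dn <- identified_rescale(fit_nomed)
  if (!identical(dim(df_$A3)[-1L], dim(dn$A3)[-1L]))
    stop("fits have different coefficient dimensions; same spec required")
  S <- min(dim(df_$A3)[1L], dim(dn$A3)[1L])
  out <- dn$A3[seq_len(S), , , drop = FALSE] -
    df_$A3[seq_len(S), , , drop = FALSE]
  dimnames(out) <- list(NULL, sprintf("src%d", seq_len(dim(out)[2L])),
                        sprintf("y%d", seq_len(dim(out)[3L])))
  attr(out, "pairing") <- "by-index"
  out
}

#' Summarize per-draw effect samples
#'
#' Posterior mean and equal-tailed credible interval for every effect path
#' in a draws-first array. With `as_odds_ratio = TRUE` each draw is
#' exponentiated before summarizing (the convention for ordinal outcomes,
#' whose identified coefficients are log odds ratios). An effect is flagged
#' significant when its interval excludes the null (0 on the raw scale, 1
#' on the odds-ratio scale).
#'
#' @param samples Array (or vector) whose first dimension indexes draws.
#' @param level Credible level in (0, 1); default 0.95.
#' @param as_odds_ratio Exponentiate draws before summarizing.
#' @return `data.frame` with columns `path`, `mean`, `lo`, `hi`, `scale`,
#'   `significant`.
#' @export
summarize_effects <- function(samples, level = 0.95,
                              as_odds_ratio = FALSE) {
  stopifnot(level > 0, level < 1)
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  S <- dim(samples)[1L]
  if (S < 2L) stop("need at least 2 draws to summarize")
  flat <- matrix(samples, nrow = S)
  dn <- dimnames(samples)
  labs <- if (!is.null(dn) && all(lengths(dn[-1L]) > 0)) {
    grid <- expand.grid(dn[-1L], stringsAsFactors = FALSE)
    apply(grid, 1L, paste, collapse = " -> ")
  } else sprintf("effect%d", seq_len(ncol(flat)))
  if (as_odds_ratio) flat <- exp(flat)
  a <- (1 - level) / 2
  qs <- apply(flat, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  null_val <- if (as_odds_ratio) 1 else 0
  data.frame(path = labs,
             mean = colMeans(flat),
             lo = qs[1L, ], hi = qs[2L, ],
             scale = if (as_odds_ratio) "odds-ratio" else "raw",
             significant = qs[1L, ] > null_val | qs[2L, ] < null_val,
             row.names = NULL, stringsAsFactors = FALSE)
}
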