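#' Central multivariate t rectangle probability
#'
#' Computes `P(max_k |T_k| <= bound)` for a central K-variate t vector with
#' correlation matrix `R` and `df` degrees of freedom — the quantity the
#' single-step max-t adjustment inverts. Evaluation uses the Genz-Bretz
#' quasi-Monte-Carlo algorithm (via \pkg{mvtnorm}) under a locally seeded
#' RNG, so results are reproducible and the caller's random stream is left
#' untouched. Contrast-induced correlation matrices are often singular
#' (rank `J - 1`); these are handled.
#'
#' @param bound Positive scalar threshold.
#' @param R Correlation matrix (symmetric, unit diagonal, positive
#'   semidefinite).
#' @param df Degrees of freedom (positive integer).
#' @param seed Integer seed for the quasi-Monte-Carlo integration.
#' @param abseps Absolute error tolerance of the integration.
#' @param lower_tail_only If `TRUE` compute the one-sided orthant
#'   `P(max_k T_k <= bound)` instead of the symmetric rectangle.
#' @return Probability in `[0, 1]` (attribute `error` carries the
#'   integration error estimate).
#' @examples
#' R <- contrast_correlation(ave_contrasts(3), c(10, 20, 10))
#' mvt_rectangle_prob(2.5, R, df = 37)
#' @export
mvt_rectangle_prob <- function(bound, R, df, seed = 1L, abseps = 1e-4,
                               lower_tail_only = FALSE) {
  if (!is.numeric(bound) || length(bound) != 1L || !is.finite(bound) || bound < 0)
    stop_invalid("'bound' must be a single non-negative number")
  R <- as.matrix(R)
  K <- nrow(R)
  if (ncol(R) != K || any(abs(R - t(R)) > 1e-8) || any(abs(diag(R) - 1) > 1e-8))
    stop_invalid("'R' must be a symmetric correlation matrix with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop_invalid("'R' is not positive semidefinite (min eigenvalue %g)", min(ev))
  df <- as.integer(df)
  if (is.na(df) || df < 1L)
    stop_invalid("'df' must be a positive integer")
  lower <- if (lower_tail_only) rep(-Inf, K) else rep(-bound, K)
  if (K == 1L) {
    p <- stats::pt(bound, df) - if (lower_tail_only) 0 else stats::pt(-bound, df)
    return(structure(min(max(p, 0), 1), error = 0))
  }
  p <- with_local_seed(seed, mvtnorm::pmvt(
    lower = lower, upper = rep(bound, K), df = df, corr = R,
    algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = 1e6)))
  structure(min(max(as.numeric(p), 0), 1), error = attr(p, "error"))
}

#' Two-sided max-t critical value
#'
#' Solves `P(max_k |T_k| <= q) = 1 - alpha` for `q` under the central
#' multivariate t with correlation `R` and `df` degrees of freedom. Used by
#' the simulation engine: with fixed group sizes the rejection decision
#' `global p < alpha` is equivalent to `max_k |T_k| > q`.
#'
#' @inheritParams mvt_rectangle_prob
#' @param alpha Familywise level in (0, 1).
#' @return The critical value (scalar).
#' @export
mct_critical_value <- function(R, df, alpha = 0.05, seed = 1L, abseps = 1e-5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_invalid("'alpha' must be in (0, 1)")
  K <- nrow(as.matrix(R))
  lo <- stats::qt(1 - alpha / 2, df)            # K = 1 bound
  hi <- stats::qt(1 - alpha / (2 * K), df) + .1 # Bonferroni bound
  if (K == 1L) return(lo)
  f <- function(q) mvt_rectangle_prob(q, R, df, seed = seed, abseps = abseps) -
    (1 - alpha)
  stats::uniroot(f, c(lo, hi), tol = 1e-5, extendInt = "upX")$root
}

# Run `expr` under a fixed RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
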