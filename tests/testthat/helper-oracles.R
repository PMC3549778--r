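# Independent oracles used to cross-check the package's statistics.

# Direct transcription of the median-centred Brown-Forsythe F statistic,
# deliberately routed through lm()/anova() rather than the package's sums.
oracle_brown_forsythe <- function(y, g) {
  g <- factor(g)
  med <- tapply(y, g, median)
  z <- abs(y - med[g])
  fit <- anova(lm(z ~ g))
  list(statistic = fit[["F value"]][1],
       df1 = fit$Df[1], df2 = fit$Df[2],
       p_value = fit[["Pr(>F)"]][1])
}

# Monte-Carlo estimate of P(max_k |T_k| <= b) under the central K-variate t
# with correlation R (possibly singular, hence eigen rather than Cholesky).
oracle_mvt_rect <- function(bound, R, df, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  A <- e$vectors %*% diag(sqrt(lam), length(lam))
  Z <- matrix(rnorm(n_draws * ncol(R)), n_draws) %*% t(A)
  Tm <- Z / sqrt(rchisq(n_draws, df) / df)
  hits <- rowSums(abs(Tm) > bound) == 0
  p <- mean(hits)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Simple seeded 3-group dataset generator for property loops.
make_groups <- function(seed, sizes = c(10, 20, 15), sds = c(1, 1, 1),
                        means = c(0, 0, 0)) {
  set.seed(seed)
  g <- rep(0:2, sizes)
  y <- rnorm(sum(sizes), mean = means[g + 1], sd = sds[g + 1])
  list(y = y, g = g)
}
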