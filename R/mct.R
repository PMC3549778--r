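#' Levene-type multiple contrast test for variance heterogeneity
#'
#' The workhorse of the package. Observations are transformed to
#' median-based Levene residuals `Z_ji`; for each contrast row `c_k` of `C`
#' the t-type statistic
#' \deqn{T_k = \frac{\sum_j c_{kj} \bar Z_{j.}}{S\sqrt{\sum_j c_{kj}^2/n_j}}}
#' is computed, where `S` is the root mean square error of the one-way
#' model on the residuals (denominator `N - J`). Because the `T_k` are
#' jointly multivariate t with `nu = N - J` degrees of freedom and the
#' correlation matrix from [contrast_correlation()], single-step adjusted
#' p-values are obtained from the max-|t| distribution:
#' `adj_p_k = 1 - P(max_m |T_m| <= |t_k|)`. The smallest adjusted p-value
#' doubles as the global test, and each contrast keeps its own adjusted
#' p-value for an allele-level interpretation (which genotype group drives
#' the heterogeneity).
#'
#' @param data A [grouped_trait] object.
#' @param C A `contrast_matrix` with one column per group; defaults to the
#'   grand-mean contrasts [ave_contrasts()] for the groups in `data`.
#' @param seed Integer seed for the multivariate-t integration, making
#'   adjusted p-values reproducible.
#' @param alternative `"two.sided"` (default) uses `max_k |T_k|`;
#'   `"greater"` uses the one-sided `max_k T_k`, sensitive only to groups
#'   whose variance exceeds the reference.
#' @param abseps Absolute tolerance of the multivariate-t integration.
#' @return An object of class `mct_test`: list with `statistics`,
#'   `estimates` (the contrast values `sum_j c_kj Zbar_j`), `raw_p`,
#'   `adj_p`, `global_p`, `df`, `s`, `correlation`, `contrast_labels`,
#'   `kind`, `group_sizes`.
#' @examples
#' set.seed(1)
#' g <- rep(0:2, c(25, 50, 25))
#' y <- rnorm(100, sd = c(1, 2, 2)[g + 1])
#' mct_test(grouped_trait(y, g))
#' @export
mct_test <- function(data, C = NULL, seed = 1L,
                     alternative = c("two.sided", "greater"),
                     abseps = 1e-4) {
  if (!inherits(data, "grouped_trait"))
    stop_invalid("'data' must be a grouped_trait object")
  alternative <- match.arg(alternative)
  N <- data$total_n; J <- data$n_groups
  if (N - J < 1L)
    stop_invalid("need N - J >= 1 residual degrees of freedom (N = %d, J = %d)", N, J)
  if (is.null(C))
    C <- ave_contrasts(J, group_names = as.character(data$group_keys))
  if (ncol(C) != J)
    stop_invalid("contrast matrix has %d columns but the data have %d groups",
                 ncol(C), J)
  lr <- levene_residuals(data)
  core <- levene_core(lr$z, data$group_labels, data$group_sizes)
  nu <- N - J
  s2 <- core$sse / nu
  if (s2 <= 0)
    stop_degenerate("pooled variance of the Levene residuals is zero")
  Cm <- unclass(C)
  est <- as.vector(Cm %*% core$zbar)
  se <- sqrt(s2 * as.vector(Cm^2 %*% (1 / data$group_sizes)))
  Tk <- est / se
  R <- contrast_correlation(C, data$group_sizes)
  two_sided <- alternative == "two.sided"
  raw_p <- if (two_sided) 2 * stats::pt(-abs(Tk), nu) else
    stats::pt(Tk, nu, lower.tail = FALSE)
  adj_p <- vapply(Tk, function(t) {
    b <- if (two_sided) abs(t) else t
    if (!two_sided && b < 0) return(1)  # one-sided: negative stat cannot reject
    1 - mvt_rectangle_prob(b, R, nu, seed = seed, abseps = abseps,
                           lower_tail_only = !two_sided)
  }, numeric(1))
  adj_p <- pmin(pmax(adj_p, raw_p), 1)   # single-step adj p can never undercut raw
  structure(list(statistics = stats::setNames(Tk, rownames(Cm)),
                 estimates = stats::setNames(est, rownames(Cm)),
                 raw_p = raw_p,
                 adj_p = adj_p,
                 global_p = min(adj_p),
                 df = nu,
                 s = sqrt(s2),
                 correlation = R,
                 contrast_labels = rownames(Cm),
                 kind = attr(C, "kind"),
                 group_sizes = data$group_sizes,
                 alternative = alternative),
            class = "mct_test")
}

#' @export
print.mct_test <- function(x, digits = 4, ...) {
  cat(sprintf("Levene-type multiple contrast test (%s contrasts, %s)\n",
              x$kind %||% "custom",
              if (x$alternative == "two.sided") "two-sided" else "one-sided"))
  tab <- data.frame(estimate = x$estimates,
                    t = x$statistics,
                    `adj p` = x$adj_p,
                    check.names = FALSE,
                    row.names = x$contrast_labels)
  print(format(tab, digits = digits))
  cat(sprintf("Global p = %s (df = %d, S = %s)\n",
              format(x$global_p, digits = digits), x$df,
              format(x$s, digits = digits)))
  invisible(x)
}
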