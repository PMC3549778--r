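#' Group a quantitative trait by genotype
#'
#' Bundles a trait vector with per-sample genotype codes into the grouped
#' one-way layout used by all tests in this package. Samples with a missing
#' trait value or a missing genotype are dropped pairwise and counted;
#' genotype groups that end up empty are dropped, so the number of groups
#' `J` reflects the groups actually observed. Internally groups are recoded
#' to consecutive integers `0, ..., J-1`; the original labels (e.g. allele
#' pairs, or the 0/1/2 dosage codes) are kept as `group_keys`.
#'
#' @param values Numeric trait vector.
#' @param groups Genotype code per observation (integer, character or
#'   factor), same length as `values`. `NA` marks a missing genotype.
#' @return An object of class `grouped_trait`: a list with `values`,
#'   `group_labels` (0-based consecutive codes), `group_keys` (original
#'   labels, ordered), `group_sizes`, `total_n`, `n_groups`, `n_missing`.
#' @examples
#' g <- rep(0:2, c(5, 10, 5))
#' y <- rnorm(20)
#' gt <- grouped_trait(y, g)
#' gt$group_sizes
#' @export
grouped_trait <- function(values, groups) {
  if (length(values) != length(groups))
    stop_invalid("'values' (length %d) and 'groups' (length %d) differ in length",
                 length(values), length(groups))
  values <- as.numeric(values)
  keep <- !is.na(values) & !is.na(groups)
  n_missing <- sum(!keep)
  values <- values[keep]
  groups <- groups[keep]
  if (any(!is.finite(values)))
    stop_invalid("trait values must be finite")
  keys <- sort(unique(groups))
  if (length(keys) < 2L)
    stop_invalid("need at least 2 non-empty genotype groups, got %d", length(keys))
  labels <- match(groups, keys) - 1L
  sizes <- tabulate(labels + 1L, nbins = length(keys))
  structure(list(
    values       = values,
    group_labels = labels,
    group_keys   = keys,
    group_sizes  = sizes,
    total_n      = length(values),
    n_groups     = length(keys),
    n_missing    = n_missing
  ), class = "grouped_trait")
}

#' @export
print.grouped_trait <- function(x, ...) {
  cat("Grouped quantitative trait: N =", x$total_n, "in", x$n_groups, "groups\n")
  tab <- x$group_sizes
  names(tab) <- as.character(x$group_keys)
  print(tab)
  if (x$n_missing > 0)
    cat(x$n_missing, "observation(s) dropped for missing trait or genotype\n")
  invisible(x)
}

#' Median-based Levene residuals
#'
#' Transforms each observation to its absolute deviation from the median of
#' its genotype group, `Z_ji = |Y_ji - median(Y_j.)|` (the Brown-Forsythe
#' variant of the Levene transformation). Variance heterogeneity among the
#' original groups becomes mean heterogeneity among the residuals, which is
#' what the global F test and the contrast tests act on.
#'
#' @param data A [grouped_trait] object.
#' @return An object of class `levene_residuals`: list with `z` (residuals,
#'   aligned one-to-one with `data$values`), `group_labels` and
#'   `group_medians`.
#' @examples
#' gt <- grouped_trait(c(1, 2, 3, 5, 5, 5), rep(0:1, each = 3))
#' levene_residuals(gt)$z
#' @export
levene_residuals <- function(data) {
  if (!inherits(data, "grouped_trait"))
    stop_invalid("'data' must be a grouped_trait object")
  if (any(data$group_sizes < 1L))
    stop_invalid("group '%s' is empty",
                 data$group_keys[which(data$group_sizes < 1L)[1L]])
  med <- vapply(split(data$values, data$group_labels), stats::median, numeric(1))
  z <- unname(abs(data$values - med[data$group_labels + 1L]))
  structure(list(z = z,
                 group_labels = data$group_labels,
                 group_medians = unname(med)),
            class = "levene_residuals")
}

#' Global Levene (Brown-Forsythe) test for variance heterogeneity
#'
#' Tests the null hypothesis that all genotype-group variances are equal by
#' a one-way ANOVA F statistic on the median-based Levene residuals:
#' \deqn{T^2 = \frac{(N-J)\sum_j n_j(\bar Z_{j.}-\bar Z_{..})^2}
#'                  {(J-1)\sum_j\sum_i (Z_{ji}-\bar Z_{j.})^2}}
#' referred to the F distribution with `J-1` and `N-J` degrees of freedom.
#'
#' @param data A [grouped_trait] object.
#' @return An object of class `levene_test`: list with `statistic`, `df1`,
#'   `df2`, `p_value`, plus the residual object under `residuals`.
#' @examples
#' set.seed(1)
#' gt <- grouped_trait(rnorm(90, sd = rep(c(1, 1, 2), each = 30)),
#'                     rep(0:2, each = 30))
#' levene_test(gt)
#' @export
levene_test <- function(data) {
  if (!inherits(data, "grouped_trait"))
    stop_invalid("'data' must be a grouped_trait object")
  N <- data$total_n; J <- data$n_groups
  if (N - J < 1L)
    stop_invalid("need N - J >= 1 residual degrees of freedom (N = %d, J = %d)", N, J)
  lr <- levene_residuals(data)
  core <- levene_core(lr$z, data$group_labels, data$group_sizes)
  if (core$sse <= 0)
    stop_degenerate("all Levene residuals are identical within groups; variance of the residuals is zero")
  stat <- (N - J) * core$ssb / ((J - 1) * core$sse)
  structure(list(statistic = stat,
                 df1 = J - 1L,
                 df2 = N - J,
                 p_value = stats::pf(stat, J - 1L, N - J, lower.tail = FALSE),
                 residuals = lr),
            class = "levene_test")
}

# Between/within sums of squares of residuals z across groups;
# shared by levene_test, mct_test and the simulation fast path.
levene_core <- function(z, labels, sizes) {
  zbar <- vapply(split(z, labels), mean, numeric(1))
  grand <- mean(z)
  ssb <- sum(sizes * (zbar - grand)^2)
  sse <- sum((z - zbar[labels + 1L])^2)
  list(zbar = unname(zbar), ssb = ssb, sse = sse)
}

#' @export
print.levene_test <- function(x, digits = 4, ...) {
  cat("Median-based Levene (Brown-Forsythe) test\n")
  cat(sprintf("F = %s on df (%d, %d), p = %s\n",
              format(x$statistic, digits = digits), x$df1, x$df2,
              format(x$p_value, digits = digits)))
  invisible(x)
}
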