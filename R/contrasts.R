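#' Grand-mean ("Ave") contrast matrix
#'
#' One row per group, comparing that group against the average of the
#' remaining groups. By default the average is unweighted: coefficient `-1`
#' for the group itself and `1/(J-1)` elsewhere, so for `J = 3` genotype
#' groups the rows are `(-1, 0.5, 0.5)`, `(0.5, -1, 0.5)`,
#' `(0.5, 0.5, -1)` — each genotype's variance signal versus the pooled
#' signal of the other two. With `weights` (typically the group sizes) row
#' `k` becomes `w/sum(w) - e_k`, the comparison of group `k` against the
#' weighted grand mean; for equal weights this is proportional to the
#' default rows (hence gives identical t statistics), and for unbalanced
#' designs it matches the grand-mean contrasts of the \pkg{multcomp}
#' tradition, which down-weight sparsely observed groups.
#'
#' @param J Number of groups (>= 2).
#' @param group_names Optional character labels for the groups, used in the
#'   row labels; defaults to `g0, g1, ...`.
#' @param weights Optional positive weights of length `J` (usually group
#'   sizes) for a weighted grand-mean comparison; `NULL` (default) gives
#'   the equal-weight rows above.
#' @return A `contrast_matrix`: numeric `J x J` matrix with attribute
#'   `kind = "ave"` and descriptive row names. Every row sums to zero.
#' @examples
#' ave_contrasts(3)
#' ave_contrasts(3, weights = c(50, 30, 20))
#' @export
ave_contrasts <- function(J, group_names = NULL, weights = NULL) {
  J <- as.integer(J)
  if (is.na(J) || J < 2L)
    stop_invalid("'J' must be an integer >= 2")
  nm <- group_names %||% paste0("g", seq_len(J) - 1L)
  if (length(nm) != J)
    stop_invalid("'group_names' must have length J = %d", J)
  if (is.null(weights)) {
    C <- matrix(1 / (J - 1), J, J)
    diag(C) <- -1
  } else {
    if (length(weights) != J || any(weights <= 0))
      stop_invalid("'weights' must be %d positive numbers", J)
    C <- matrix(weights / sum(weights), J, J, byrow = TRUE) - diag(J)
  }
  rownames(C) <- vapply(seq_len(J), function(k)
    sprintf("var(%s) vs avg var(%s)", nm[k], paste(nm[-k], collapse = ",")),
    character(1))
  colnames(C) <- nm
  new_contrast_matrix(C, "ave")
}

#' All-pairs contrast matrix
#'
#' One row per unordered pair of groups `(j, j')`, `j < j'`, with
#' coefficient `-1` at `j`, `+1` at `j'` and zero elsewhere
#' (`J(J-1)/2` rows). For `J = 3` this is the Tukey-type set of all
#' pairwise variance comparisons.
#'
#' @inheritParams ave_contrasts
#' @return A `contrast_matrix` with attribute `kind = "pairs"`.
#' @examples
#' pairwise_contrasts(3)
#' @export
pairwise_contrasts <- function(J, group_names = NULL) {
  J <- as.integer(J)
  if (is.na(J) || J < 2L)
    stop_invalid("'J' must be an integer >= 2")
  nm <- group_names %||% paste0("g", seq_len(J) - 1L)
  if (length(nm) != J)
    stop_invalid("'group_names' must have length J = %d", J)
  pairs <- utils::combn(J, 2)
  C <- matrix(0, ncol(pairs), J)
  for (k in seq_len(ncol(pairs))) {
    C[k, pairs[1, k]] <- -1
    C[k, pairs[2, k]] <- 1
  }
  rownames(C) <- sprintf("var(%s) vs var(%s)", nm[pairs[1, ]], nm[pairs[2, ]])
  colnames(C) <- nm
  new_contrast_matrix(C, "pairs")
}

#' Construct a custom contrast matrix
#'
#' Validates a user-supplied coefficient matrix: every row must sum to zero
#' (within 1e-12) and no row may be all zero.
#'
#' @param coefficients Numeric `K x J` matrix of contrast coefficients.
#' @param kind Label stored with the matrix; `"custom"` by default.
#' @return A `contrast_matrix`.
#' @export
contrast_matrix <- function(coefficients, kind = "custom") {
  coefficients <- as.matrix(coefficients)
  if (!is.numeric(coefficients) || nrow(coefficients) < 1L)
    stop_invalid("'coefficients' must be a numeric matrix with at least one row")
  new_contrast_matrix(coefficients, kind)
}

new_contrast_matrix <- function(C, kind) {
  if (any(abs(rowSums(C)) > 1e-12))
    stop_invalid("contrast row(s) %s do not sum to zero",
                 paste(which(abs(rowSums(C)) > 1e-12), collapse = ", "))
  if (any(apply(C, 1, function(r) all(r == 0))))
    stop_invalid("contrast matrix contains an all-zero row")
  if (is.null(rownames(C)))
    rownames(C) <- paste0("c", seq_len(nrow(C)))
  structure(C, kind = kind, class = c("contrast_matrix", class(C)))
}

#' Correlation matrix of contrast test statistics
#'
#' Under a homoscedastic one-way model the vector of contrast t statistics
#' is jointly multivariate t with correlation
#' \deqn{\rho_{kk'} = \frac{\sum_j c_{kj} c_{k'j} / n_j}
#'   {\sqrt{(\sum_j c_{kj}^2/n_j)(\sum_j c_{k'j}^2/n_j)}}}
#' which depends only on the contrast coefficients and the group sizes.
#'
#' @param C A `contrast_matrix` (or plain `K x J` matrix).
#' @param group_sizes Integer vector of the `J` group sizes, all >= 1.
#' @return Symmetric `K x K` correlation matrix with unit diagonal.
#' @examples
#' contrast_correlation(ave_contrasts(3), c(10, 10, 10))
#' @export
contrast_correlation <- function(C, group_sizes) {
  C <- unclass(C)
  if (ncol(C) != length(group_sizes))
    stop_invalid("contrast matrix has %d columns but %d group sizes were given",
                 ncol(C), length(group_sizes))
  if (any(group_sizes < 1L))
    stop_invalid("all group sizes must be >= 1")
  V <- C %*% diag(1 / group_sizes, length(group_sizes)) %*% t(C)
  R <- stats::cov2cor(V)
  dimnames(R) <- list(rownames(C), rownames(C))
  (R + t(R)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
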