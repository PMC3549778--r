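#' Hardy-Weinberg genotype group sizes
#'
#' Deterministically allocates `N` samples to three genotype groups indexed
#' by the number of copies (0, 1, 2) of the variance-increasing (dominant)
#' allele, whose frequency is `1 - p` when `p` is the frequency of the
#' recessive allele. The Hardy-Weinberg group proportions are therefore
#' `(p^2, 2p(1-p), (1-p)^2)`; note group 0 — the baseline variance group —
#' is the recessive homozygote. Allocation uses largest-remainder rounding
#' with fractional-count ties broken towards the lower genotype code.
#' Every group is guaranteed at least `min_group` observations (deficits
#' are taken from the largest group) so that within-group variances remain
#' estimable.
#'
#' @param p Recessive-allele frequency in (0, 1).
#' @param N Total sample size.
#' @param min_group Minimum size per group (default 2).
#' @return Integer vector `(n0, n1, n2)` summing to `N`.
#' @examples
#' hwe_group_sizes(0.5, 100)   # (25, 50, 25)
#' hwe_group_sizes(0.75, 100)  # (56, 38, 6)
#' @export
hwe_group_sizes <- function(p, N, min_group = 2L) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop_invalid("'p' must be in (0, 1)")
  N <- as.integer(N)
  if (is.na(N) || N < 3L * min_group)
    stop_invalid("N = %d is too small to give all 3 groups >= %d observations",
                 N, min_group)
  prob <- hwe_probs(p)
  exact <- prob * N
  n <- floor(exact)
  rem <- exact - n
  short <- N - sum(n)
  if (short > 0) {
    # largest remainder first; ties towards the lower genotype code
    ord <- order(-rem, seq_along(rem))
    n[ord[seq_len(short)]] <- n[ord[seq_len(short)]] + 1
  }
  while (any(n < min_group)) {
    i <- which.min(n); j <- which.max(n)
    n[i] <- n[i] + 1L; n[j] <- n[j] - 1L
    if (n[j] < min_group)
      stop_invalid("N = %d cannot give all 3 groups >= %d observations", N, min_group)
  }
  as.integer(n)
}

# HWE genotype probabilities, group j = copies of the dominant
# (variance-increasing) allele; p = recessive-allele frequency.
hwe_probs <- function(p) c(p^2, 2 * p * (1 - p), (1 - p)^2)

#' Genotype-dependent standard deviations under a mode of inheritance
#'
#' Maps an inheritance mode and a variance increment `delta` to the group
#' standard deviations `(sigma0, sigma1, sigma2)`: the trait spread grows
#' with the number of variance-increasing alleles. Additive:
#' `(1, 1+delta, 1+2*delta)`; dominant: `(1, 1+2*delta, 1+2*delta)` (one
#' allele suffices); recessive: `(1, 1, 1+2*delta)` (both alleles needed).
#' `delta = 0` is the homoscedastic null in every mode.
#'
#' @param mode One of `"additive"`, `"dominant"`, `"recessive"`.
#' @param delta Non-negative increment.
#' @return Numeric vector of 3 standard deviations.
#' @examples
#' variance_profile("additive", 1)    # (1, 2, 3)
#' variance_profile("recessive", 0.5) # (1, 1, 2)
#' @export
variance_profile <- function(mode, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop_invalid("'delta' must be a single non-negative number")
  switch(match.arg(mode, c("additive", "dominant", "recessive")),
         additive  = c(1, 1 + delta, 1 + 2 * delta),
         dominant  = c(1, 1 + 2 * delta, 1 + 2 * delta),
         recessive = c(1, 1, 1 + 2 * delta))
}

#' Configuration of a size/power simulation
#'
#' @param allele_freq Recessive-allele frequency `p` in (0, 1).
#' @param total_n Total sample size `N`.
#' @param delta Variance increment (standard-deviation scale).
#' @param mode Inheritance mode, see [variance_profile()].
#' @param n_reps Number of simulation replicates.
#' @param alpha Nominal level (default 0.05).
#' @param seed Master seed.
#' @param tests Subset of `c("levene", "mct_pairs", "mct_ave")`.
#' @param group_sizes Optional explicit `(n0, n1, n2)` overriding the
#'   Hardy-Weinberg allocation (e.g. for balanced designs).
#' @param allocation `"multinomial"` (default) redraws the genotype of
#'   every sample independently from the Hardy-Weinberg frequencies in each
#'   replicate, so group sizes vary; replicates in which any genotype group
#'   has fewer than 2 observations (so that its variance is not estimable)
#'   are counted as non-rejections and reported in `n_excluded`.
#'   `"fixed"` uses the deterministic largest-remainder group sizes of
#'   [hwe_group_sizes()] for every replicate — a variance-reduced design
#'   with no exclusions.
#' @param ave_weighted Use group-size-weighted grand-mean contrasts for the
#'   `mct_ave` test (default `TRUE`, the behaviour of the reference size
#'   and power study); `FALSE` uses the equal-weight rows of
#'   [ave_contrasts()]. Identical for balanced group sizes.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(allele_freq = 0.5, total_n = 100, delta = 0,
                              mode = "dominant", n_reps = 10000,
                              alpha = 0.05, seed = 1L,
                              tests = c("levene", "mct_pairs", "mct_ave"),
                              group_sizes = NULL,
                              allocation = c("multinomial", "fixed"),
                              ave_weighted = TRUE) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop_invalid("'alpha' must be in (0, 1]")
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L)
    stop_invalid("'n_reps' must be >= 1")
  allocation <- match.arg(allocation)
  if (!is.null(group_sizes)) allocation <- "fixed"
  sizes <- if (is.null(group_sizes)) hwe_group_sizes(allele_freq, total_n)
           else {
             gs <- as.integer(group_sizes)
             if (length(gs) != 3L || any(gs < 2L))
               stop_invalid("'group_sizes' must be 3 integers, all >= 2")
             gs
           }
  structure(list(allele_freq = allele_freq,
                 total_n = sum(sizes),
                 delta = delta,
                 mode = match.arg(mode, c("additive", "dominant", "recessive")),
                 n_reps = n_reps,
                 alpha = alpha,
                 seed = as.integer(seed),
                 tests = tests,
                 group_sizes = sizes,
                 allocation = allocation,
                 ave_weighted = isTRUE(ave_weighted)),
            class = "simulation_config")
}

#' Run a size/power simulation
#'
#' Draws `n_reps` replicate datasets of independent normal observations with
#' group standard deviations from [variance_profile()], applies the
#' requested tests, and returns the proportion of replicates whose global
#' p-value falls below `alpha`. Under the default multinomial allocation
#' every sample's genotype is redrawn from the Hardy-Weinberg frequencies
#' each replicate; replicates in which any genotype group ends up with
#' fewer than 2 observations are counted as non-rejections (their group
#' variance is not estimable) and reported in `n_excluded` — at p = 0.75,
#' N = 25 this affects half the replicates and is what drives rejection
#' rates at small N well below the nominal level. Under `"fixed"`
#' allocation the group sizes are identical in every replicate and the data
#' are drawn vectorised from one seeded stream before any test is applied,
#' so rejection counts do not depend on which tests are requested. In both
#' cases the multiple-contrast decision compares `max_k |T_k|` against the
#' critical value from [mct_critical_value()] for the replicate's group
#' sizes (memoised across replicates), which is equivalent to
#' `global p < alpha` by monotonicity of the adjusted p-value. Degenerate
#' replicates (zero residual variance; a probability-zero event for
#' continuous traits) are likewise counted as non-rejections.
#'
#' @param config A [simulation_config()].
#' @param keep_details If `TRUE` (fixed allocation only), attach
#'   per-replicate Levene p-values and max-|t| statistics (`details`
#'   element) for diagnostic use.
#' @return A `simulation_result`: list with `rejection_rate` (named, per
#'   test), `mc_se`, `n_effective`, `n_excluded`, `n_degenerate`,
#'   `group_sizes` (fixed allocation), and the `config`.
#' @examples
#' cfg <- simulation_config(0.5, 100, delta = 1, mode = "dominant",
#'                          n_reps = 200, seed = 7)
#' run_simulation(cfg)
#' @export
run_simulation <- function(config, keep_details = FALSE) {
  if (!inherits(config, "simulation_config"))
    stop_invalid("'config' must be a simulation_config object")
  if (identical(config$allocation, "multinomial"))
    return(run_simulation_multinomial(config))
  n <- config$group_sizes
  N <- sum(n); J <- 3L; nu <- N - J
  sigma <- variance_profile(config$mode, config$delta)
  gidx <- rep.int(1:3, n)
  reps <- config$n_reps

  crit <- list()
  for (fam in intersect(c("mct_pairs", "mct_ave"), config$tests))
    crit[[fam]] <- sim_critical_value(fam, n, config$alpha, config$seed,
                                      config$ave_weighted)

  set.seed(config$seed)
  Y <- matrix(stats::rnorm(N * reps), N, reps) * sigma[gidx]

  # Levene residuals per replicate: per-group column medians
  Z <- Y
  for (j in 1:3) {
    rows <- which(gidx == j)
    med <- apply(Y[rows, , drop = FALSE], 2, stats::median)
    Z[rows, ] <- abs(Y[rows, , drop = FALSE] - rep(med, each = n[j]))
  }
  zbar <- rowsum(Z, gidx) / n                   # 3 x reps group means
  grand <- colMeans(Z)
  ssb <- colSums(n * (zbar - rep(grand, each = 3))^2)
  sse <- colSums(Z^2) - colSums(n * zbar^2)
  degenerate <- sse <= 0
  sse[degenerate] <- NA_real_

  out <- list(); details <- list()
  if ("levene" %in% config$tests) {
    Fstat <- nu * ssb / ((J - 1) * sse)
    p <- stats::pf(Fstat, J - 1, nu, lower.tail = FALSE)
    out$levene <- sum(p < config$alpha, na.rm = TRUE) / reps
    if (keep_details) details$levene_p <- p
  }
  s <- sqrt(sse / nu)
  for (fam in intersect(c("mct_pairs", "mct_ave"), config$tests)) {
    Cm <- sim_contrasts(fam, n, config$ave_weighted)
    Tk <- (Cm %*% zbar) / outer(sqrt(as.vector(Cm^2 %*% (1 / n))), s)
    maxT <- apply(abs(Tk), 2, max)
    out[[fam]] <- sum(maxT > crit[[fam]], na.rm = TRUE) / reps
    if (keep_details) details[[paste0(fam, "_max_t")]] <- maxT
  }

  rate <- unlist(out)[config$tests[config$tests %in% names(out)]]
  res <- structure(list(
    rejection_rate = rate,
    mc_se = sqrt(rate * (1 - rate) / reps),
    n_effective = reps,
    n_excluded = 0L,
    n_degenerate = sum(degenerate),
    group_sizes = n,
    critical_values = unlist(crit),
    config = config), class = "simulation_result")
  if (keep_details) res$details <- details
  res
}

# Bare contrast coefficients for the simulation hot path (J = 3); identical
# to pairwise_contrasts() / ave_contrasts() up to labels, asserted in tests.
.sim_C_pairs <- rbind(c(-1, 1, 0), c(0, -1, 1), c(-1, 0, 1))
.sim_C_ave_equal <- matrix(0.5, 3, 3) - diag(1.5, 3)

sim_contrasts <- function(fam, n, ave_weighted) {
  if (fam == "mct_pairs") return(.sim_C_pairs)
  if (!ave_weighted) return(.sim_C_ave_equal)
  matrix(n / sum(n), 3, 3, byrow = TRUE) - diag(3)
}

# Memoised max-|t| critical values: group-size configurations recur heavily
# across replicates and grid cells, and the value depends only on
# (contrast family, sizes, alpha, integration seed).
.sim_crit_cache <- new.env(parent = emptyenv())

sim_critical_value <- function(fam, n, alpha, seed, ave_weighted) {
  key <- paste(fam, if (fam == "mct_ave") ave_weighted else "", alpha, seed,
               paste(n, collapse = "."))
  val <- .sim_crit_cache[[key]]
  if (is.null(val)) {
    Cm <- sim_contrasts(fam, n, ave_weighted)
    R <- contrast_correlation(Cm, n)
    val <- if (alpha >= 1) 0 else
      mct_critical_value(R, sum(n) - length(n), alpha, seed = seed,
                         abseps = 1e-4)
    .sim_crit_cache[[key]] <- val
  }
  val
}

# Multinomial-allocation path: genotypes redrawn per replicate, group sizes
# vary, so critical values are memoised per observed size configuration.
run_simulation_multinomial <- function(config) {
  prob <- hwe_probs(config$allele_freq)
  sigma <- variance_profile(config$mode, config$delta)
  N <- config$total_n; reps <- config$n_reps
  rej <- stats::setNames(numeric(length(config$tests)), config$tests)
  n_excluded <- 0L; n_degenerate <- 0L
  do_lev <- "levene" %in% config$tests
  fams <- intersect(c("mct_pairs", "mct_ave"), config$tests)
  set.seed(config$seed)
  for (i in seq_len(reps)) {
    n <- as.vector(stats::rmultinom(1L, N, prob))
    if (min(n) < 2L) {
      # group variance not estimable: replicate yields no rejection
      n_excluded <- n_excluded + 1L
      next
    }
    zbar <- numeric(3L); ssw <- numeric(3L)
    for (j in 1:3) {
      yj <- stats::rnorm(n[j]) * sigma[j]
      zj <- abs(yj - stats::median(yj))
      zbar[j] <- mean(zj); ssw[j] <- sum((zj - zbar[j])^2)
    }
    sse <- sum(ssw)
    if (sse <= 0) { n_degenerate <- n_degenerate + 1L; next }
    nu <- N - 3L
    if (do_lev) {
      grand <- sum(n * zbar) / N
      Fst <- nu * sum(n * (zbar - grand)^2) / (2 * sse)
      if (stats::pf(Fst, 2L, nu, lower.tail = FALSE) < config$alpha)
        rej[["levene"]] <- rej[["levene"]] + 1
    }
    s <- sqrt(sse / nu)
    for (fam in fams) {
      Cm <- sim_contrasts(fam, n, config$ave_weighted)
      Tk <- (Cm %*% zbar) / (s * sqrt(as.vector(Cm^2 %*% (1 / n))))
      crit <- sim_critical_value(fam, n, config$alpha, config$seed,
                                 config$ave_weighted)
      if (max(abs(Tk)) > crit) rej[[fam]] <- rej[[fam]] + 1
    }
  }
  rate <- rej / reps
  structure(list(rejection_rate = rate,
                 mc_se = sqrt(rate * (1 - rate) / reps),
                 n_effective = reps,
                 n_excluded = n_excluded,
                 n_degenerate = n_degenerate,
                 group_sizes = NULL,
                 critical_values = NULL,
                 config = config), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat(sprintf("Rejection rates (%s mode, p = %g, N = %d, delta = %g, %d reps, alpha = %g)\n",
              cfg$mode, cfg$allele_freq, cfg$total_n, cfg$delta,
              x$n_effective, cfg$alpha))
  tab <- rbind(rate = x$rejection_rate, mc_se = x$mc_se)
  print(round(tab, digits))
  if ((x$n_excluded %||% 0L) > 0)
    cat(x$n_excluded,
        "replicate(s) with a genotype group smaller than 2 counted as non-rejections\n")
  if (x$n_degenerate > 0)
    cat(x$n_degenerate, "degenerate replicate(s) counted as non-rejections\n")
  invisible(x)
}

#' Size/power table over the standard simulation grid
#'
#' Runs [run_simulation()] over the grid `p` in `{0.5, 0.75}` times `N` in
#' `{25, 50, 75, 100}` times `delta` in `{0, 0.5, 1}` for one inheritance
#' mode and all three tests, the layout of the package's reference size and
#' power study. Per-configuration seeds are derived deterministically from
#' the master seed.
#'
#' @param mode Inheritance mode.
#' @param n_reps Replicates per cell (>= 100).
#' @param seed Master seed.
#' @param p_values,n_values,deltas Grid axes (defaults as above).
#' @param alpha Nominal level.
#' @return A data frame with columns `p, N, delta, test, rejection_rate,
#'   mc_se, n_reps`.
#' @export
replicate_table <- function(mode, n_reps = 10000, seed = 1L,
                            p_values = c(0.5, 0.75),
                            n_values = c(25, 50, 75, 100),
                            deltas = c(0, 0.5, 1),
                            alpha = 0.05) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 100L)
    stop_invalid("'n_reps' must be >= 100")
  grid <- expand.grid(p = p_values, N = n_values, delta = deltas,
                      KEEP.OUT.ATTRS = FALSE)
  cfg_seeds <- with_local_seed(seed,
    sample.int(.Machine$integer.max - 1L, nrow(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- simulation_config(grid$p[i], grid$N[i], grid$delta[i], mode,
                             n_reps = n_reps, alpha = alpha,
                             seed = cfg_seeds[i])
    res <- run_simulation(cfg)
    data.frame(p = grid$p[i], N = grid$N[i], delta = grid$delta[i],
               test = names(res$rejection_rate),
               rejection_rate = unname(res$rejection_rate),
               mc_se = unname(res$mc_se),
               n_reps = n_reps, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, out$N, out$delta, out$test), , drop = FALSE]
}

#' Synthetic genotype/phenotype fixture with an optional planted vQTL
#'
#' Draws per-SNP genotypes under Hardy-Weinberg equilibrium at a
#' uniform-random minor-allele frequency within `maf_range`, and a standard
#' normal phenotype — except when `vqtl` designates one SNP as a variance
#' QTL, in which case the phenotype's standard deviation follows
#' [variance_profile()] of that SNP's genotype. Used for end-to-end scan
#' tests and demonstrations.
#'
#' @param n_snps,n_samples Dimensions of the fixture.
#' @param maf_range Interval within (0, 0.5] for minor-allele frequencies.
#' @param vqtl Optional list `list(snp =, mode =, delta =)` planting a
#'   variance QTL at SNP index `snp`.
#' @param seed Integer seed.
#' @return A list with `genotypes` (integer `n_snps x n_samples` matrix,
#'   rows named `snp1, ...`), `snp_info` (data frame `snp_id, chrom, pos`),
#'   `phenotype` (named numeric vector), `maf`, and `vqtl`.
#' @examples
#' fx <- generate_fixture(5, 100, seed = 3)
#' dim(fx$genotypes)
#' @export
generate_fixture <- function(n_snps, n_samples, maf_range = c(0.05, 0.5),
                             vqtl = NULL, seed = 1L) {
  if (n_snps < 1L || n_samples < 1L)
    stop_invalid("'n_snps' and 'n_samples' must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_invalid("'maf_range' must be a non-empty interval within (0, 0.5]")
  if (!is.null(vqtl)) {
    if (is.null(vqtl$snp) || vqtl$snp < 1L || vqtl$snp > n_snps)
      stop_invalid("'vqtl$snp' must index one of the %d SNPs", n_snps)
    sigma <- variance_profile(vqtl$mode, vqtl$delta)
  }
  set.seed(seed)
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  G <- t(vapply(maf, function(q) stats::rbinom(n_samples, 2L, q),
                integer(n_samples)))
  snp_ids <- paste0("snp", seq_len(n_snps))
  rownames(G) <- snp_ids
  sample_ids <- paste0("s", seq_len(n_samples))
  colnames(G) <- sample_ids
  y <- stats::rnorm(n_samples)
  if (!is.null(vqtl))
    y <- y * sigma[G[vqtl$snp, ] + 1L]
  names(y) <- sample_ids
  list(genotypes = G,
       snp_info = data.frame(snp_id = snp_ids,
                             chrom = rep_len(as.character(1:22), n_snps),
                             pos = seq_len(n_snps) * 1000L,
                             stringsAsFactors = FALSE),
       phenotype = y,
       maf = maf,
       vqtl = vqtl)
}
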