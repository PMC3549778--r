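#' Genome-wide variance-heterogeneity scan
#'
#' Applies the global Levene test and both multiple contrast tests
#' ([mct_test()] with grand-mean and with pairwise contrasts) SNP-by-SNP.
#' For each SNP, samples with a missing genotype or missing phenotype are
#' dropped pairwise; genotype groups observed for that SNP determine `J`
#' (a SNP with no minor-allele homozygotes is tested with `J = 2` and
#' flagged `reduced`). A SNP is reported `untestable` — never an error —
#' when fewer than two genotype groups remain, when any remaining group is a
#' singleton, or when the Levene residuals carry no variance (e.g. a
#' constant phenotype). The per-SNP integration seed is derived
#' deterministically from the master `seed` and the SNP identifier, so
#' results do not depend on SNP order.
#'
#' @param genotypes Integer matrix of genotype codes in `{0, 1, 2, NA}`
#'   (0 = major homozygote, 2 = minor homozygote), one row per SNP, one
#'   column per sample; `dimnames` give SNP and sample identifiers. A list
#'   as returned by [read_genotype_tsv()] / [generate_fixture()] is also
#'   accepted.
#' @param phenotype Named numeric trait vector. Names must match the
#'   genotype sample identifiers (order-free); unnamed vectors are accepted
#'   when lengths match and are taken to be aligned.
#' @param snp_info Optional data frame with columns `snp_id`, `chrom`,
#'   `pos` (taken from the input list when available).
#' @param seed Master integer seed for the multivariate-t integrations.
#' @return A data frame of class `vqtl_scan` with one row per SNP:
#'   genotype counts (`n0`, `n1`, `n2`, `n_missing`), `levene_p`,
#'   `mct_ave_global_p`, `mct_ave_p_0`, `mct_ave_p_1`, `mct_ave_p_2`
#'   (per-genotype grand-mean contrasts; `NA` for absent groups),
#'   `mct_pairs_global_p`, `mct_pairs_p_01`, `mct_pairs_p_02`,
#'   `mct_pairs_p_12`, and the logical flags `untestable` and `reduced`.
#' @examples
#' fx <- generate_fixture(3, 200, vqtl = list(snp = 1, mode = "dominant",
#'                                            delta = 1), seed = 5)
#' vqtl_scan(fx$genotypes, fx$phenotype)
#' @export
vqtl_scan <- function(genotypes, phenotype = NULL, snp_info = NULL, seed = 1L) {
  if (is.list(genotypes) && !is.null(genotypes$genotypes)) {
    if (is.null(snp_info)) snp_info <- genotypes$snp_info
    if (is.null(phenotype)) phenotype <- genotypes$phenotype
    genotypes <- genotypes$genotypes
  }
  if (is.null(phenotype))
    stop_invalid("'phenotype' is required (supply a vector or a fixture list containing one)")
  G <- as.matrix(genotypes)
  if (is.null(rownames(G))) rownames(G) <- paste0("snp", seq_len(nrow(G)))
  if (!is.null(names(phenotype)) && !is.null(colnames(G))) {
    missing_in_g <- setdiff(names(phenotype), colnames(G))
    missing_in_p <- setdiff(colnames(G), names(phenotype))
    if (length(missing_in_g) || length(missing_in_p))
      stop_invalid("sample identifiers do not match; missing from genotypes: %s; missing from phenotype: %s",
                   paste(utils::head(missing_in_g, 5), collapse = ","),
                   paste(utils::head(missing_in_p, 5), collapse = ","))
    phenotype <- phenotype[colnames(G)]
  } else if (length(phenotype) != ncol(G)) {
    stop_invalid("phenotype length (%d) does not match sample count (%d)",
                 length(phenotype), ncol(G))
  }
  if (nrow(G) < 1L) stop_invalid("need at least one SNP")

  rows <- lapply(seq_len(nrow(G)), function(i) {
    scan_one(G[i, ], phenotype, rownames(G)[i], seed)
  })
  out <- do.call(rbind, rows)
  if (!is.null(snp_info)) {
    idx <- match(out$snp_id, snp_info$snp_id)
    out$chrom <- snp_info$chrom[idx]
    out$pos <- snp_info$pos[idx]
  } else {
    out$chrom <- NA_character_
    out$pos <- NA_integer_
  }
  out <- out[, c("snp_id", "chrom", "pos",
                 setdiff(names(out), c("snp_id", "chrom", "pos")))]
  class(out) <- c("vqtl_scan", "data.frame")
  out
}

# Test a single SNP; returns a one-row data frame.
scan_one <- function(g, y, snp_id, seed) {
  ok <- !is.na(g) & !is.na(y)
  counts <- tabulate(g[ok] + 1L, nbins = 3L)
  row <- data.frame(snp_id = snp_id,
                    n0 = counts[1], n1 = counts[2], n2 = counts[3],
                    n_missing = sum(!ok),
                    levene_p = NA_real_,
                    mct_ave_global_p = NA_real_,
                    mct_ave_p_0 = NA_real_, mct_ave_p_1 = NA_real_,
                    mct_ave_p_2 = NA_real_,
                    mct_pairs_global_p = NA_real_,
                    mct_pairs_p_01 = NA_real_, mct_pairs_p_02 = NA_real_,
                    mct_pairs_p_12 = NA_real_,
                    untestable = TRUE, reduced = FALSE,
                    stringsAsFactors = FALSE)
  present <- which(counts > 0L) - 1L
  if (length(present) < 2L || any(counts[present + 1L] < 2L))
    return(row)
  snp_seed <- derive_seed(seed, snp_id)
  res <- tryCatch({
    gt <- grouped_trait(y[ok], g[ok])
    codes <- as.integer(gt$group_keys)
    lt <- levene_test(gt)
    ave <- mct_test(gt, ave_contrasts(gt$n_groups, as.character(codes)),
                    seed = snp_seed)
    prs <- mct_test(gt, pairwise_contrasts(gt$n_groups, as.character(codes)),
                    seed = snp_seed)
    list(codes = codes, lt = lt, ave = ave, prs = prs)
  }, levenemct_error = function(e) NULL)
  if (is.null(res)) return(row)

  row$untestable <- FALSE
  row$reduced <- length(res$codes) < 3L
  row$levene_p <- res$lt$p_value
  row$mct_ave_global_p <- res$ave$global_p
  for (k in seq_along(res$codes))
    row[[paste0("mct_ave_p_", res$codes[k])]] <- res$ave$adj_p[k]
  row$mct_pairs_global_p <- res$prs$global_p
  pair_idx <- utils::combn(res$codes, 2)
  for (k in seq_len(ncol(pair_idx)))
    row[[sprintf("mct_pairs_p_%d%d", pair_idx[1, k], pair_idx[2, k])]] <-
      res$prs$adj_p[k]
  row
}

# Deterministic 31-bit seed from (master seed, snp id): order-independent.
derive_seed <- function(seed, snp_id) {
  h <- sum(utf8ToInt(as.character(snp_id)) *
             (31 ^ (seq_along(utf8ToInt(as.character(snp_id))) %% 7)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483646) + 1L
}

#' Flag SNPs failing the group-size reporting filters
#'
#' Variance estimates from near-empty genotype groups are unstable, so
#' screens of this kind report only SNPs where every genotype group holds at
#' least a fixed fraction of the samples and where enough minor-allele
#' homozygotes were observed. Rows failing a rule are flagged — never
#' removed — so the denominator of any downstream multiplicity correction
#' stays explicit; use [filter_pass()] for the filtered view.
#'
#' @param rows A [vqtl_scan] result.
#' @param min_group_fraction Minimum fraction of the SNP's non-missing
#'   samples required in each of the three genotype categories (default
#'   0.01, i.e. one percent; an absent category counts as size 0 and
#'   fails). Set to 0 to disable.
#' @param min_minor_homozygotes Minimum count of minor-allele homozygotes
#'   (default 5). Set to 0 to disable.
#' @return `rows` with logical columns `min_group_fraction_fail` and
#'   `min_homozygote_fail` added/updated.
#' @export
apply_group_filters <- function(rows, min_group_fraction = 0.01,
                                min_minor_homozygotes = 5L) {
  counts <- cbind(rows$n0, rows$n1, rows$n2)
  N <- rowSums(counts)
  rows$min_group_fraction_fail <-
    apply(counts < min_group_fraction * N, 1, any)
  rows$min_homozygote_fail <- rows$n2 < min_minor_homozygotes
  rows
}

#' Filtered view of a scan
#'
#' @param rows A [vqtl_scan] result, after [apply_group_filters()].
#' @return The subset of rows that are testable and pass all filters.
#' @export
filter_pass <- function(rows) {
  keep <- !rows$untestable
  for (fl in c("min_group_fraction_fail", "min_homozygote_fail"))
    if (fl %in% names(rows)) keep <- keep & !rows[[fl]]
  rows[keep, , drop = FALSE]
}

#' Bonferroni significance flags for a scan
#'
#' Flags SNPs whose selected p-value falls below `alpha / m`, with `m` the
#' number of SNPs entering the comparison: by default the testable rows
#' passing the group filters (when filter columns are present), mirroring
#' the usual practice of correcting over the reported subset.
#'
#' @param rows A [vqtl_scan] result.
#' @param alpha Familywise level (default 0.05).
#' @param which_p Which p-value column drives the flag: `"mct_ave"`,
#'   `"levene"` or `"mct_pairs"` (global p-values).
#' @param use_filtered Count only filter-passing rows in `m` (default
#'   `TRUE`); filtered-out rows are never flagged significant.
#' @return `rows` with a logical `bonferroni_significant` column;
#'   attributes `bonferroni_m` and `bonferroni_threshold` record the
#'   correction.
#' @export
bonferroni_flag <- function(rows, alpha = 0.05,
                            which_p = c("mct_ave", "levene", "mct_pairs"),
                            use_filtered = TRUE) {
  which_p <- match.arg(which_p)
  col <- switch(which_p, mct_ave = "mct_ave_global_p",
                levene = "levene_p", mct_pairs = "mct_pairs_global_p")
  eligible <- !rows$untestable
  if (use_filtered)
    for (fl in c("min_group_fraction_fail", "min_homozygote_fail"))
      if (fl %in% names(rows)) eligible <- eligible & !rows[[fl]]
  m <- sum(eligible)
  if (m < 1L) stop_invalid("no testable rows to correct over")
  thr <- alpha / m
  rows$bonferroni_significant <- eligible & !is.na(rows[[col]]) &
    rows[[col]] < thr
  attr(rows, "bonferroni_m") <- m
  attr(rows, "bonferroni_threshold") <- thr
  rows
}

#' QQ- and Manhattan-plot tables
#'
#' Prepares the two standard genome-scan summaries from the tested rows of a
#' scan: a QQ table pairing the sorted observed `-log10` p-values with the
#' expected `-log10` uniform order statistics `(i - 0.5)/m`, and a
#' Manhattan table of `(chrom, pos, -log10 p)`.
#'
#' @param rows A [vqtl_scan] result (pass a [filter_pass()] view to restrict
#'   to filter-passing SNPs).
#' @param which_p p-value selector as in [bonferroni_flag()].
#' @return List with data frames `qq` (`expected`, `observed`, `snp_id`)
#'   and `manhattan` (`snp_id`, `chrom`, `pos`, `neg_log10_p`).
#' @export
qq_manhattan_tables <- function(rows, which_p = c("mct_ave", "levene",
                                                  "mct_pairs")) {
  which_p <- match.arg(which_p)
  col <- switch(which_p, mct_ave = "mct_ave_global_p",
                levene = "levene_p", mct_pairs = "mct_pairs_global_p")
  tested <- rows[!rows$untestable & !is.na(rows[[col]]), , drop = FALSE]
  m <- nrow(tested)
  if (m < 1L) stop_invalid("no tested rows")
  ord <- order(tested[[col]])
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(tested[[col]][ord]),
                   snp_id = tested$snp_id[ord],
                   stringsAsFactors = FALSE)
  manhattan <- data.frame(snp_id = tested$snp_id,
                          chrom = tested$chrom,
                          pos = tested$pos,
                          neg_log10_p = -log10(tested[[col]]),
                          stringsAsFactors = FALSE)
  list(qq = qq, manhattan = manhattan)
}
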