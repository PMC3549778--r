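#' Read a genotype matrix from TSV
#'
#' Expects a tab-separated file whose header row is
#' `snp_id  chrom  pos  <sample ids...>` followed by one row per SNP with
#' genotype codes in `{0, 1, 2, NA}` (0 = major homozygote, 1 =
#' heterozygote, 2 = minor homozygote; `NA` literal, case-sensitive, for
#' missing). The reader is strict: any other cell value is a parse error
#' naming the offending file line, and duplicated SNP identifiers are
#' rejected.
#'
#' @param path Path to the TSV file.
#' @return List with `genotypes` (integer matrix, SNPs x samples, dimnames
#'   set) and `snp_info` (data frame `snp_id, chrom, pos, n0, n1, n2,
#'   n_missing`).
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  fixed <- c("snp_id", "chrom", "pos")
  if (ncol(raw) < 4L || !identical(names(raw)[1:3], fixed))
    stop_parse("%s: header must start with 'snp_id\tchrom\tpos' followed by sample ids", path)
  sample_ids <- names(raw)[-(1:3)]
  if (anyDuplicated(sample_ids))
    stop_parse("%s: duplicated sample id(s): %s", path,
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(raw$snp_id))
    stop_parse("%s: duplicated snp_id(s): %s", path,
               paste(unique(raw$snp_id[duplicated(raw$snp_id)]), collapse = ", "))
  cells <- as.matrix(raw[, -(1:3), drop = FALSE])
  bad <- matrix(!(cells %in% c("0", "1", "2", "NA")), nrow(cells))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop_parse("%s line %d: invalid genotype code '%s' for sample '%s' (allowed: 0, 1, 2, NA)",
               path, ij[1] + 1L, cells[ij[1], ij[2]], sample_ids[ij[2]])
  }
  G <- matrix(suppressWarnings(as.integer(cells)), nrow(cells), ncol(cells),
              dimnames = list(raw$snp_id, sample_ids))
  list(genotypes = G, snp_info = snp_info_from_matrix(G, raw$chrom,
                                                      as.integer(raw$pos)))
}

snp_info_from_matrix <- function(G, chrom, pos) {
  counts <- t(apply(G, 1, function(g) tabulate(g + 1L, nbins = 3L)))
  data.frame(snp_id = rownames(G), chrom = chrom, pos = pos,
             n0 = counts[, 1], n1 = counts[, 2], n2 = counts[, 3],
             n_missing = rowSums(is.na(G)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read genotypes from a minimal VCF
#'
#' Reads the GT field of a VCF 4.x file (via \pkg{vcfR}) and converts to
#' dosage codes: `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./.` ->
#' missing; phased separators (`|`) are accepted. Records with more than
#' one ALT allele are skipped with a warning and counted.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @return As [read_genotype_tsv()], with an additional `n_skipped`
#'   element counting skipped multiallelic records and `allele_labels`
#'   (REF/ALT) columns in `snp_info`.
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0L || !("FORMAT" %in% colnames(v@gt)))
    stop_parse("%s: no genotype (FORMAT/GT) section", path)
  if (!all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop_parse("%s: GT missing from FORMAT field", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_skipped <- sum(multi)
  if (n_skipped > 0)
    warning(sprintf("%s: skipped %d multiallelic record(s)", path, n_skipped))
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out
  }
  G <- matrix(code(gt), nrow(gt), ncol(gt),
              dimnames = list(ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                     paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                     fix[, "ID"]),
                              colnames(gt)))
  info <- snp_info_from_matrix(G, fix[, "CHROM"], as.integer(fix[, "POS"]))
  info$ref <- fix[, "REF"]
  info$alt <- fix[, "ALT"]
  list(genotypes = G, snp_info = info, n_skipped = n_skipped)
}

#' Read one trait from a phenotype TSV
#'
#' Expects a tab-separated file with a `sample_id` column and one or more
#' named numeric trait columns; `NA` (case-sensitive) marks missing values.
#' Non-numeric cells are parse errors naming the file line.
#'
#' @param path Path to the TSV file.
#' @param trait Name of the trait column to extract.
#' @return Named numeric vector (names = sample ids, `NA` for missing).
#' @export
read_phenotype_tsv <- function(path, trait) {
  if (!file.exists(path)) stop_parse("file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  if (!("sample_id" %in% names(raw)))
    stop_parse("%s: no 'sample_id' column", path)
  traits <- setdiff(names(raw), "sample_id")
  if (length(traits) < 1L) stop_parse("%s: no trait columns", path)
  if (!(trait %in% traits))
    stop_parse("%s: trait '%s' not found; available: %s", path, trait,
               paste(traits, collapse = ", "))
  if (anyDuplicated(raw$sample_id))
    stop_parse("%s: duplicated sample id(s): %s", path,
               paste(unique(raw$sample_id[duplicated(raw$sample_id)]),
                     collapse = ", "))
  x <- raw[[trait]]
  val <- suppressWarnings(as.numeric(x))
  bad <- is.na(val) & x != "NA"
  if (any(bad))
    stop_parse("%s line %d: non-numeric value '%s' in trait '%s'",
               path, which(bad)[1] + 1L, x[which(bad)[1]], trait)
  stats::setNames(val, raw$sample_id)
}

#' Write scan results to TSV
#'
#' Writes one row per SNP with a stable column order (`snp_id, chrom, pos,
#' n0, n1, n2, n_missing, levene_p, mct_ave_global_p, mct_ave_p_0,
#' mct_ave_p_1, mct_ave_p_2, mct_pairs_global_p, mct_pairs_p_01,
#' mct_pairs_p_02, mct_pairs_p_12, flags`). P-values are printed in
#' scientific notation with 6 significant digits; `flags` is a
#' semicolon-separated list of raised flags or `.`.
#'
#' @param rows A [vqtl_scan] result (optionally after
#'   [apply_group_filters()] / [bonferroni_flag()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(rows, path) {
  pcols <- c("levene_p", "mct_ave_global_p", "mct_ave_p_0", "mct_ave_p_1",
             "mct_ave_p_2", "mct_pairs_global_p", "mct_pairs_p_01",
             "mct_pairs_p_02", "mct_pairs_p_12")
  out <- data.frame(snp_id = rows$snp_id, chrom = rows$chrom, pos = rows$pos,
                    n0 = rows$n0, n1 = rows$n1, n2 = rows$n2,
                    n_missing = rows$n_missing, stringsAsFactors = FALSE)
  for (pc in pcols)
    out[[pc]] <- ifelse(is.na(rows[[pc]]), "NA", sprintf("%.6e", rows[[pc]]))
  flag_cols <- intersect(c("untestable", "reduced", "min_group_fraction_fail",
                           "min_homozygote_fail", "bonferroni_significant"),
                         names(rows))
  out$flags <- apply(as.matrix(rows[, flag_cols, drop = FALSE]), 1, function(fl) {
    raised <- flag_cols[which(as.logical(fl))]
    if (length(raised)) paste(raised, collapse = ";") else "."
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    stop(errorCondition(sprintf("cannot write to '%s'", path),
                        class = c("levenemct_io_error", "levenemct_error")))
  invisible(path)
}
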