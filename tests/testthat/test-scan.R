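test_that("single-SNP scan reproduces the direct test results exactly", {
  fx <- generate_fixture(3, 300, maf_range = c(0.3, 0.5),
                         vqtl = list(snp = 2, mode = "recessive", delta = 1),
                         seed = 17)
  rows <- vqtl_scan(fx, seed = 5)
  expect_equal(nrow(rows), 3L)
  for (i in 1:3) {
    gt <- grouped_trait(fx$phenotype, fx$genotypes[i, ])
    snp_seed <- levenemct:::derive_seed(5, rows$snp_id[i])
    expect_equal(rows$levene_p[i], levene_test(gt)$p_value, tolerance = 1e-12)
    ave <- mct_test(gt, ave_contrasts(3, as.character(0:2)), seed = snp_seed)
    expect_equal(rows$mct_ave_global_p[i], ave$global_p, tolerance = 1e-12)
    expect_equal(c(rows$mct_ave_p_0[i], rows$mct_ave_p_1[i],
                   rows$mct_ave_p_2[i]),
                 unname(ave$adj_p), tolerance = 1e-12)
    prs <- mct_test(gt, pairwise_contrasts(3, as.character(0:2)),
                    seed = snp_seed)
    expect_equal(c(rows$mct_pairs_p_01[i], rows$mct_pairs_p_02[i],
                   rows$mct_pairs_p_12[i]),
                 unname(prs$adj_p), tolerance = 1e-12)
  }
  # per-SNP seeds derive from the SNP id, so row order cannot matter
  rows_rev <- vqtl_scan(fx$genotypes[3:1, ], fx$phenotype,
                        snp_info = fx$snp_info, seed = 5)
  expect_equal(rows_rev[rows_rev$snp_id == "snp2", ]$mct_ave_global_p,
               rows[rows$snp_id == "snp2", ]$mct_ave_global_p)
})

test_that("constant phenotype makes every SNP untestable without crashing", {
  fx <- generate_fixture(4, 80, seed = 3)
  rows <- vqtl_scan(fx$genotypes, rep(1.5, 80))
  expect_true(all(rows$untestable))
  expect_true(all(is.na(rows$levene_p)))
})

test_that("a SNP with no minor-allele homozygotes is tested with J = 2 and flagged", {
  set.seed(8)
  g <- matrix(sample(0:1, 120, replace = TRUE), 1,
              dimnames = list("snpA", NULL))
  y <- rnorm(120) * c(1, 2)[g[1, ] + 1]
  rows <- vqtl_scan(g, y, seed = 2)
  expect_false(rows$untestable)
  expect_true(rows$reduced)
  expect_equal(rows$n2, 0L)
  expect_false(is.na(rows$mct_pairs_p_01))
  expect_true(is.na(rows$mct_pairs_p_02))
  expect_true(is.na(rows$mct_ave_p_2))
})

test_that("missing genotypes and phenotypes are dropped pairwise per SNP", {
  fx <- generate_fixture(2, 100, seed = 21)
  G <- fx$genotypes
  G[1, 1:10] <- NA
  y <- fx$phenotype
  y[11:15] <- NA
  rows <- vqtl_scan(G, y, seed = 1)
  expect_equal(rows$n_missing[1], 15L)
  expect_equal(rows$n_missing[2], 5L)
  expect_equal(rows$n0 + rows$n1 + rows$n2 + rows$n_missing, c(100L, 100L))
})

test_that("sample identifier mismatches are rejected with offenders named", {
  fx <- generate_fixture(2, 20, seed = 4)
  y <- fx$phenotype
  names(y)[1] <- "stranger"
  expect_error(vqtl_scan(fx$genotypes, y), "stranger",
               class = "levenemct_invalid_input")
})

test_that("group filters flag rather than drop and never touch p-values", {
  rows <- data.frame(snp_id = c("a", "b", "c"), chrom = "1", pos = 1:3,
                     n0 = c(400L, 300L, 100L), n1 = c(120L, 200L, 100L),
                     n2 = c(5L, 25L, 100L), n_missing = 0L,
                     levene_p = c(0.01, 0.5, 0.9),
                     mct_ave_global_p = c(0.01, 0.5, 0.9),
                     mct_ave_p_0 = NA_real_, mct_ave_p_1 = NA_real_,
                     mct_ave_p_2 = NA_real_,
                     mct_pairs_global_p = c(0.02, 0.6, 0.9),
                     mct_pairs_p_01 = NA_real_, mct_pairs_p_02 = NA_real_,
                     mct_pairs_p_12 = NA_real_,
                     untestable = FALSE, reduced = FALSE,
                     stringsAsFactors = FALSE)
  out <- apply_group_filters(rows)          # defaults: 1%, >= 5 homozygotes
  expect_equal(nrow(out), 3L)               # row count conserved
  expect_equal(out$levene_p, rows$levene_p) # p-values untouched
  # N = 525, n2 = 5 < 5.25 fails the 1% rule but passes the >= 5 rule
  expect_true(out$min_group_fraction_fail[1])
  expect_false(out$min_homozygote_fail[1])
  expect_false(out$min_group_fraction_fail[2])
  expect_false(out$min_homozygote_fail[2])
  # disabling the fraction rule clears its flags
  off <- apply_group_filters(rows, min_group_fraction = 0)
  expect_false(any(off$min_group_fraction_fail))
  expect_equal(filter_pass(out)$snp_id, c("b", "c"))
})

test_that("Bonferroni flags use alpha over the post-filter count", {
  rows <- data.frame(snp_id = paste0("s", 1:100), chrom = "1", pos = 1:100,
                     n0 = 50L, n1 = 30L, n2 = 20L, n_missing = 0L,
                     levene_p = 1, mct_ave_global_p = 1,
                     mct_ave_p_0 = NA_real_, mct_ave_p_1 = NA_real_,
                     mct_ave_p_2 = NA_real_,
                     mct_pairs_global_p = 1,
                     mct_pairs_p_01 = NA_real_, mct_pairs_p_02 = NA_real_,
                     mct_pairs_p_12 = NA_real_,
                     untestable = FALSE, reduced = FALSE,
                     stringsAsFactors = FALSE)
  rows$mct_ave_global_p[7] <- 4e-4          # just below 0.05 / 100
  out <- bonferroni_flag(rows, alpha = 0.05, which_p = "mct_ave")
  expect_equal(attr(out, "bonferroni_m"), 100L)
  expect_equal(attr(out, "bonferroni_threshold"), 5e-4)
  expect_equal(which(out$bonferroni_significant), 7L)
  rows$mct_ave_global_p[7] <- 1             # all p = 1 -> no flags
  expect_equal(sum(bonferroni_flag(rows)$bonferroni_significant), 0L)
})

test_that("QQ and Manhattan tables pair observed with uniform order statistics", {
  rows <- data.frame(snp_id = "only", chrom = "2", pos = 5L,
                     n0 = 10L, n1 = 10L, n2 = 10L, n_missing = 0L,
                     levene_p = 0.1, mct_ave_global_p = 0.1,
                     mct_ave_p_0 = NA_real_, mct_ave_p_1 = NA_real_,
                     mct_ave_p_2 = NA_real_,
                     mct_pairs_global_p = 0.1,
                     mct_pairs_p_01 = NA_real_, mct_pairs_p_02 = NA_real_,
                     mct_pairs_p_12 = NA_real_,
                     untestable = FALSE, reduced = FALSE,
                     stringsAsFactors = FALSE)
  tabs <- qq_manhattan_tables(rows, which_p = "levene")
  expect_equal(tabs$qq$expected, -log10(0.5))
  expect_equal(tabs$qq$observed, 1)
  expect_equal(tabs$manhattan$neg_log10_p, 1)
  # uniform p-values hug the diagonal
  m <- 2000
  set.seed(99)
  unif <- rows[rep(1, m), ]
  unif$snp_id <- paste0("s", 1:m)
  unif$levene_p <- runif(m)
  qq <- qq_manhattan_tables(unif, which_p = "levene")$qq
  expect_lt(max(abs(10^-qq$observed - 10^-qq$expected)), 0.05)
})

test_that("null scan calibration matches the simulation engine's null rate", {
  fx <- generate_fixture(400, 500, maf_range = c(0.4, 0.5), seed = 2024)
  rows <- vqtl_scan(fx, seed = 11)
  frac <- mean(rows$levene_p[!rows$untestable] < 0.05)
  sim <- run_simulation(simulation_config(0.5, 500, 0, "dominant",
                                          n_reps = 2000, seed = 12,
                                          tests = "levene"))
  rate <- sim$rejection_rate[["levene"]]
  tol <- 3 * sqrt(rate * (1 - rate) / 400) + 3 * sim$mc_se[["levene"]]
  expect_lt(abs(frac - rate), tol)
})
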