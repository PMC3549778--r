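test_that("Hardy-Weinberg allocation follows largest-remainder rounding", {
  expect_equal(hwe_group_sizes(0.5, 100), c(25L, 50L, 25L))
  expect_equal(hwe_group_sizes(0.5, 25), c(6L, 13L, 6L))
  # group index counts the variance-increasing (dominant) allele, so the
  # recessive homozygote (frequency p^2) is group 0
  expect_equal(hwe_group_sizes(0.75, 100), c(56L, 38L, 6L))
  expect_equal(hwe_group_sizes(0.75, 50), c(28L, 19L, 3L))
  expect_equal(hwe_group_sizes(0.75, 25), c(14L, 9L, 2L))
  expect_equal(hwe_group_sizes(0.5, 50), c(13L, 25L, 12L))
  for (p in c(0.3, 0.5, 0.75)) for (N in c(25, 60, 101)) {
    n <- hwe_group_sizes(p, N)
    expect_equal(sum(n), N)
    expect_true(all(n >= 2))
  }
})

test_that("allocation errors when N cannot support three groups", {
  expect_error(hwe_group_sizes(0.5, 5), class = "levenemct_invalid_input")
  expect_error(hwe_group_sizes(1.2, 50), class = "levenemct_invalid_input")
})

test_that("variance profiles encode the inheritance modes on the SD scale", {
  expect_equal(variance_profile("additive", 1), c(1, 2, 3))
  expect_equal(variance_profile("recessive", 0.5), c(1, 1, 2))
  expect_equal(variance_profile("dominant", 0.5), c(1, 2, 2))
  for (m in c("additive", "dominant", "recessive"))
    expect_equal(variance_profile(m, 0), c(1, 1, 1))
  expect_error(variance_profile("codominant", 1))
  expect_error(variance_profile("additive", -1),
               class = "levenemct_invalid_input")
})

test_that("simulation results are reproducible bit-for-bit for a fixed seed", {
  cfg <- simulation_config(0.5, 50, 0.5, "dominant", n_reps = 300, seed = 88)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$rejection_rate, r2$rejection_rate)
  expect_identical(r1$n_excluded, r2$n_excluded)
  cfg_fixed <- simulation_config(0.5, 50, 0.5, "dominant", n_reps = 300,
                                 seed = 88, allocation = "fixed")
  expect_identical(run_simulation(cfg_fixed)$rejection_rate,
                   run_simulation(cfg_fixed)$rejection_rate)
})

test_that("rejection indicators do not depend on the set of tests requested", {
  base <- simulation_config(0.5, 50, 1, "recessive", n_reps = 200, seed = 31)
  all3 <- run_simulation(base)
  lev <- run_simulation(simulation_config(0.5, 50, 1, "recessive",
                                          n_reps = 200, seed = 31,
                                          tests = "levene"))
  ave <- run_simulation(simulation_config(0.5, 50, 1, "recessive",
                                          n_reps = 200, seed = 31,
                                          tests = "mct_ave"))
  expect_identical(all3$rejection_rate[["levene"]],
                   lev$rejection_rate[["levene"]])
  expect_identical(all3$rejection_rate[["mct_ave"]],
                   ave$rejection_rate[["mct_ave"]])
})

test_that("everything rejects at alpha = 1 and nothing exceeds bounds", {
  cfg <- simulation_config(0.5, 30, 0, "additive", n_reps = 100, seed = 6,
                           alpha = 1, allocation = "fixed")
  r <- run_simulation(cfg)
  expect_equal(unname(r$rejection_rate), rep(1, 3))
  expect_true(all(r$mc_se >= 0))
})

test_that("fixed-allocation engine agrees with the single-dataset tests per replicate", {
  cfg <- simulation_config(0.5, 50, 0.5, "dominant", n_reps = 25, seed = 55,
                           allocation = "fixed")
  r <- run_simulation(cfg, keep_details = TRUE)
  n <- cfg$group_sizes; N <- sum(n)
  sigma <- variance_profile(cfg$mode, cfg$delta)
  gidx <- rep.int(1:3, n)
  set.seed(cfg$seed)
  Y <- matrix(rnorm(N * cfg$n_reps), N, cfg$n_reps) * sigma[gidx]
  for (i in c(1, 7, 25)) {
    gt <- grouped_trait(Y[, i], gidx - 1)
    expect_equal(r$details$levene_p[i], levene_test(gt)$p_value,
                 tolerance = 1e-12)
    ave <- mct_test(gt, ave_contrasts(3, weights = n), seed = cfg$seed)
    expect_equal(r$details$mct_ave_max_t[i], max(abs(ave$statistics)),
                 tolerance = 1e-10)
    # critical-value decision agrees with global adjusted p decision
    # (away from the boundary, where integration error could flip either)
    if (abs(ave$global_p - cfg$alpha) > 5e-3)
      expect_equal(r$details$mct_ave_max_t[i] > r$critical_values[["mct_ave"]],
                   ave$global_p < cfg$alpha)
    prs <- mct_test(gt, pairwise_contrasts(3), seed = cfg$seed)
    expect_equal(r$details$mct_pairs_max_t[i], max(abs(prs$statistics)),
                 tolerance = 1e-10)
  }
})

test_that("familywise error of the max-t test is controlled under the null", {
  cfg <- simulation_config(delta = 0, n_reps = 10000, seed = 314,
                           group_sizes = c(30, 30, 30), tests = "mct_ave",
                           ave_weighted = FALSE)
  r <- run_simulation(cfg)
  rate <- r$rejection_rate[["mct_ave"]]
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 10000))
  expect_gte(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("quadratic Levene and max contrast tests agree as global null tests", {
  cfg <- simulation_config(0.5, 90, 0, "dominant", n_reps = 4000, seed = 77,
                           allocation = "fixed")
  r <- run_simulation(cfg)
  expect_lt(abs(r$rejection_rate[["levene"]] - r$rejection_rate[["mct_ave"]]),
            0.01)
  expect_lt(abs(r$rejection_rate[["levene"]] - r$rejection_rate[["mct_pairs"]]),
            0.01)
})

test_that("replicate_table covers the grid with valid rates and SEs", {
  tab <- replicate_table("additive", n_reps = 100, seed = 12,
                         p_values = 0.5, n_values = c(25, 50),
                         deltas = c(0, 1))
  expect_equal(nrow(tab), 2 * 2 * 3)
  expect_true(all(tab$rejection_rate >= 0 & tab$rejection_rate <= 1))
  expect_true(all(tab$mc_se <= 0.05))
  expect_setequal(unique(tab$test), c("levene", "mct_pairs", "mct_ave"))
})

test_that("power increases with delta and N", {
  rates <- sapply(c(0, 0.5, 1), function(d)
    run_simulation(simulation_config(0.5, 75, d, "dominant", n_reps = 600,
                                     seed = 19))$rejection_rate[["levene"]])
  se2 <- 2 * sqrt(0.25 / 600)
  expect_true(all(diff(rates) > -se2))
  rates_n <- sapply(c(25, 100), function(N)
    run_simulation(simulation_config(0.5, N, 0.5, "recessive", n_reps = 600,
                                     seed = 23))$rejection_rate[["mct_ave"]])
  expect_gt(rates_n[2], rates_n[1] - se2)
})

test_that("synthetic fixtures honour HWE and the planted variance signal", {
  fx <- generate_fixture(40, 600, maf_range = c(0.1, 0.5), seed = 77)
  expect_equal(dim(fx$genotypes), c(40L, 600L))
  expect_true(all(fx$genotypes %in% 0:2))
  # genotype frequencies within 4 binomial SEs of HWE expectations
  for (i in seq_len(40)) {
    q <- fx$maf[i]
    exp_het <- 2 * q * (1 - q)
    obs_het <- mean(fx$genotypes[i, ] == 1)
    expect_lt(abs(obs_het - exp_het),
              4 * sqrt(exp_het * (1 - exp_het) / 600) + 1e-9)
  }
  # planted vQTL is detectable at the single-SNP level
  fx2 <- generate_fixture(1, 1000, maf_range = c(0.5, 0.5),
                          vqtl = list(snp = 1, mode = "dominant", delta = 1),
                          seed = 101)
  gt <- grouped_trait(fx2$phenotype, fx2$genotypes[1, ])
  expect_lt(mct_test(gt, seed = 1)$global_p, 1e-6)
  expect_error(generate_fixture(2, 10, maf_range = c(0.6, 0.7)),
               class = "levenemct_invalid_input")
})
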