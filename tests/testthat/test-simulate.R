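small_specs <- function(m = 3, maf = 0.3) {
  data.frame(snp_id = paste0("rs", seq_len(m)),
             gene = "G1",
             ref_allele = "A", alt_allele = "C",
             maf = rep_len(maf, m), stringsAsFactors = FALSE)
}

test_that("configuration validation rejects inconsistent inputs", {
  expect_error(sim_config(10, 10, small_specs(maf = 0.6)), "MAF")
  expect_error(sim_config(10, 10, small_specs(),
                          effects = list(list(snp_ids = c("rs1", "rs2"),
                                              pattern = "d", or = 2))),
               "does not match")
  expect_error(sim_config(10, 10, small_specs(),
                          effects = list(list(snp_ids = "rs9",
                                              pattern = "d", or = 2))),
               "outside the panel")
  # haplotype frequencies must imply the SNP MAFs
  expect_error(sim_config(10, 10, small_specs(),
                          ld_pairs = list(list(pair = c("rs1", "rs2"),
                                               hap_freqs = c(0.7, 0.1,
                                                             0.1, 0.1)))),
               "inconsistent")
})

test_that("genotypes follow Hardy-Weinberg proportions at the set MAF", {
  cfg <- sim_config(5000, 5000, small_specs(1, maf = 0.3),
                    baseline_logit = 0)
  sim <- simulate_cohort(cfg, seed = 97)
  d <- sim$genotypes$dosages[, 1]
  n <- length(d)
  expected <- c(0.49, 0.42, 0.09)
  for (g in 0:2) {
    se <- sqrt(expected[g + 1] * (1 - expected[g + 1]) / n)
    expect_lt(abs(mean(d == g) - expected[g + 1]), 3 * se)
  }
})

test_that("identical configuration and seed reproduce files byte-exactly", {
  cfg <- study_template(n_cases = 30, n_controls = 50, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_tsv_genotypes(s1$genotypes, p1)
  write_tsv_genotypes(s2$genotypes, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(s1$samples$status, s2$samples$status)
})

test_that("LD pairs reproduce their target haplotype frequencies", {
  hf <- c(0.4, 0.2, 0.1, 0.3)
  specs <- small_specs(2)
  specs$maf <- c(hf[3] + hf[4], hf[2] + hf[4])
  cfg <- sim_config(2000, 2000, specs[1:2, ],
                    ld_pairs = list(list(pair = c("rs1", "rs2"),
                                         hap_freqs = hf)),
                    baseline_logit = 0)
  sim <- simulate_cohort(cfg, seed = 101)
  em <- em_haplotype_freqs(sim$genotypes$dosages[, 1],
                           sim$genotypes$dosages[, 2])
  expect_true(all(abs(em$freqs - hf) < 0.03))
})

test_that("quotas are filled exactly and the draw cap raises an error", {
  cfg <- study_template(n_cases = 25, n_controls = 40, seed = 3)
  sim <- simulate_cohort(cfg)
  expect_identical(sum(sim$samples$status == "case"), 25L)
  expect_identical(sum(sim$samples$status == "control"), 40L)
  rare <- sim_config(50, 5, small_specs(), baseline_logit = -12)
  expect_error(simulate_cohort(rare, seed = 1, max_draws = 5e4),
               "baseline_logit")
})

test_that("planted effects act on exposure carriers as configured", {
  cfg <- sim_config(1500, 1500, small_specs(3, maf = 0.4),
                    effects = list(list(snp_ids = c("rs1", "rs2"),
                                        pattern = "dxd", or = 3)),
                    baseline_logit = -1)
  sim <- simulate_cohort(cfg, seed = 103)
  expect_identical(dim(sim$truth$exposures), c(3000L, 1L))
  # realized exposure agrees with the effect-coding conjunction rule
  e <- build_pattern_exposure(sim$genotypes, c("rs1", "rs2"), "dxd")
  expect_identical(unname(sim$truth$exposures[, 1]),
                   unname(e$included & !is.na(e$exposed) & e$exposed))
  # exposed fraction is higher among cases
  status <- sim$samples$status
  expect_gt(mean(sim$truth$exposures[status == "case", 1]),
            mean(sim$truth$exposures[status == "control", 1]))
})

test_that("covariate-only effects confound status but not genotypes", {
  cfg <- sim_config(1000, 1000, small_specs(2), p_male = 0.5,
                    p_smoker = 0.5, beta_male = 0.8, beta_smoker = -0.8,
                    baseline_logit = -0.5)
  sim <- simulate_cohort(cfg, seed = 107)
  sex_tab <- table(sim$samples$sex, sim$samples$status)
  expect_lt(chisq.test(sex_tab)$p.value, 1e-4)
  # genotype distribution identical across status in expectation
  p_case <- mean(sim$genotypes$dosages[sim$samples$status == "case", 1])
  p_ctrl <- mean(sim$genotypes$dosages[sim$samples$status == "control", 1])
  expect_lt(abs(p_case - p_ctrl), 0.1)
})

test_that("the study template mirrors the reference design margins", {
  cfg <- study_template()
  expect_identical(nrow(cfg$snp_specs), 17L)
  expect_identical(cfg$n_cases, 84L)
  expect_identical(cfg$n_controls, 194L)
  expect_identical(sum(cfg$snp_specs$gene == "SFTPA1"), 5L)
  expect_identical(sum(cfg$snp_specs$gene == "SFTPA2"), 4L)
  expect_identical(sum(cfg$snp_specs$gene == "SFTPB"), 4L)
  expect_identical(sum(cfg$snp_specs$gene == "SFTPC"), 2L)
  expect_identical(sum(cfg$snp_specs$gene == "SFTPD"), 2L)
  expect_true(all(cfg$snp_specs$maf >= 0.2 & cfg$snp_specs$maf <= 0.4))
})
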