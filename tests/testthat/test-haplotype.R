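# simulate n subjects as two gametes each from haplotype distribution p
# (order: ref-ref, ref-alt, alt-ref, alt-alt); returns dosage vectors
sim_hap_cohort <- function(n, p) {
  g1 <- sample.int(4, n, replace = TRUE, prob = p)
  g2 <- sample.int(4, n, replace = TRUE, prob = p)
  alt1 <- c(0, 0, 1, 1); alt2 <- c(0, 1, 0, 1)
  list(d1 = alt1[g1] + alt1[g2], d2 = alt2[g1] + alt2[g2])
}

test_that("phase-certain cohorts are solved by direct counting in one iteration", {
  # no double heterozygotes: dosages (0,0), (2,2), (0,2), (1,0), (2,1)
  d1 <- c(0, 2, 0, 1, 2, 2)
  d2 <- c(0, 2, 2, 0, 1, 2)
  em <- em_haplotype_freqs(d1, d2)
  expect_identical(em$n_iter, 1L)
  # direct gamete counts: (0,0)->2x00; (2,2)x2 ->4x11; (0,2)->2x01;
  # (1,0)->00+10; (2,1)->10+11
  counts <- c(`00` = 2 + 1, `01` = 2, `10` = 1 + 1, `11` = 4 + 1)
  expect_equal(unname(em$freqs), unname(counts / sum(counts)),
               tolerance = 1e-12)
})

test_that("perfect LD concentrates mass on the coupled haplotypes", {
  d <- c(0, 1, 2, 2, 1, 0, 0, 2)
  em <- em_haplotype_freqs(d, d)
  q <- mean(d) / 2
  expect_equal(unname(em$freqs[c("01", "10")]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(em$freqs["11"]), q, tolerance = 1e-9)
})

test_that("EM recovers known haplotype frequencies from simulated data", {
  set.seed(53)
  truth <- c(0.4, 0.3, 0.2, 0.1)
  co <- sim_hap_cohort(1000, truth)
  em <- em_haplotype_freqs(co$d1, co$d2)
  expect_true(all(abs(em$freqs - truth) < 0.03))
  expect_identical(sum(is.na(em$freqs)), 0L)
})

test_that("EM log-likelihood is nondecreasing and starts do not matter", {
  set.seed(59)
  truth <- c(0.35, 0.15, 0.05, 0.45)
  co <- sim_hap_cohort(400, truth)
  em <- em_haplotype_freqs(co$d1, co$d2)
  expect_true(all(diff(em$loglik_trace) >= -1e-9))
  for (rep in 1:5) {
    s <- runif(4); s <- s / sum(s)
    em2 <- em_haplotype_freqs(co$d1, co$d2, start = s)
    expect_true(all(diff(em2$loglik_trace) >= -1e-9))
    expect_true(all(abs(em2$freqs - em$freqs) < 1e-6))
  }
})

test_that("estimated haplotype counts account for every gamete", {
  set.seed(61)
  co <- sim_hap_cohort(250, c(0.25, 0.25, 0.25, 0.25))
  em <- em_haplotype_freqs(co$d1, co$d2)
  expect_equal(sum(em$freqs) * 2 * em$n, 2 * 250, tolerance = 1e-6)
})

test_that("unambiguous diplotypes force carrier status", {
  set.seed(67)
  G <- make_G(cbind(rs_a = c(2L, 0L, 1L, 2L), rs_b = c(2L, 0L, 1L, 0L)),
              snp_info(c("rs_a", "rs_b"), ref_allele = c("C", "T"),
                       alt_allele = c("T", "G")))
  S <- make_samples(4)
  res <- haplotype_dominant_test(G, S, c("rs_a", "rs_b"))
  expect_identical(res$haplotype, c("CT", "CG", "TT", "TG"))
  # subject 1 (2,2) must carry alt-alt ("TG"); subject 2 (0,0) must not
  # carry any alt-containing haplotype -- check via exposure counts
  em <- attr(res, "em")
  carrier_tg <- epipattern:::.hap_carrier(G$dosages[, 1], G$dosages[, 2],
                                          4, em$freqs)
  expect_true(carrier_tg[1])
  expect_false(carrier_tg[2])
  carrier_ct <- epipattern:::.hap_carrier(G$dosages[, 1], G$dosages[, 2],
                                          2, em$freqs)
  expect_false(carrier_ct[2])  # (0,0) carries only ref-ref
})

test_that("zero-frequency haplotypes yield flagged NA rows", {
  G <- make_G(cbind(rs_a = rep(c(0L, 2L), 10), rs_b = rep(c(0L, 2L), 10)),
              snp_info(c("rs_a", "rs_b"), ref_allele = c("A", "A"),
                       alt_allele = c("G", "G")))
  S <- make_samples(20)
  res <- haplotype_dominant_test(G, S, c("rs_a", "rs_b"))
  rep_hap <- res[res$haplotype %in% c("AG", "GA"), ]
  expect_true(all(is.na(rep_hap$p)))
  expect_true(all(rep_hap$flags == "zero_frequency"))
})

test_that("haplotype scan defaults to adjacent pairs within genes", {
  set.seed(71)
  dos <- random_dosages(80, 5, miss = 0)
  colnames(dos) <- paste0("rs", 1:5)
  G <- make_G(dos, snp_info(paste0("rs", 1:5),
                            gene = c("G1", "G1", "G1", "G2", "G2"),
                            ref_allele = "A", alt_allele = "C"))
  S <- make_samples(80)
  hs <- haplotype_scan(G, S)
  expect_identical(length(hs$pairs), 3L)  # rs1-rs2, rs2-rs3, rs4-rs5
  expect_identical(nrow(hs$results), 12L)
  expect_equal(hs$results$q, bh_fdr(hs$results$p))
  hs_all <- haplotype_scan(G, S, all_pairs = TRUE)
  expect_identical(length(hs_all$pairs), 10L)
})

test_that("a planted case-enriched haplotype is detected as risk", {
  set.seed(73)
  truth <- c(0.5, 0.2, 0.2, 0.1)
  n <- 600
  co <- sim_hap_cohort(2 * n, truth)
  carrier <- epipattern:::.hap_carrier(co$d1, co$d2, 4, truth)
  logit <- -1 + log(2.4) * carrier
  status <- rbinom(2 * n, 1, plogis(logit))
  G <- make_G(cbind(rs_x = as.integer(co$d1), rs_y = as.integer(co$d2)),
              snp_info(c("rs_x", "rs_y"), ref_allele = c("A", "A"),
                       alt_allele = c("G", "G")))
  S <- make_samples(2 * n, status = ifelse(status == 1, "case", "control"))
  res <- haplotype_dominant_test(G, S, c("rs_x", "rs_y"),
                                 risk_haplotype = "GG")
  expect_identical(res$direction, "risk")
  expect_lt(res$p, 0.05)
  expect_gt(res$or_mh, 1.5)
})
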