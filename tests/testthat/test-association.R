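test_that("stratification partitions included subjects by covariates", {
  set.seed(7)
  G <- make_G(random_dosages(40, 2, miss = 0))
  S <- make_samples(40)
  e <- build_pattern_exposure(G, "rs1", "d")
  st <- stratify(e, S)
  expect_lte(nrow(st$counts), 4)
  expect_equal(sum(st$counts), sum(e$included))

  # single covariate combination -> exactly one stratum
  S1 <- make_samples(40, sex = "male", smoking = "smoker")
  st1 <- stratify(e, S1)
  expect_identical(nrow(st1$counts), 1L)
  expect_identical(st1$labels, "male:smoker")

  # incomplete covariates are dropped and counted
  S2 <- make_samples(40)
  S2$sex[1:3] <- NA
  S2 <- sample_table(S2[1:4])
  st2 <- stratify(e, S2)
  expect_identical(st2$n_dropped, sum(e$included[1:3]))
  expect_equal(sum(st2$counts) + st2$n_dropped, sum(e$included))
})

test_that("Mantel-Haenszel odds ratio matches hand-computed values", {
  # symmetric single stratum
  expect_equal(mantel_haenszel_or(stratified_table(c(10, 10, 10, 10)))$or, 1)
  # two identical strata, direct formula: (2*400/60) / (2*100/60) = 4
  st <- stratified_table(rbind(c(20, 10, 10, 20), c(20, 10, 10, 20)))
  expect_equal(mantel_haenszel_or(st)$or, 4)
  # cross-product on a single stratum of sex-by-status counts
  expect_equal(mantel_haenszel_or(stratified_table(c(59, 25, 124, 70)))$or,
               59 * 70 / (25 * 124), tolerance = 1e-12)
  expect_equal(round(59 * 70 / (25 * 124), 3), 1.332)
})

test_that("zero denominators give infinite or zero OR signals, not errors", {
  inf <- mantel_haenszel_or(stratified_table(c(5, 5, 0, 10)))
  expect_identical(inf$or, Inf)
  expect_match(inf$flags, "infinite_or")
  zero <- mantel_haenszel_or(stratified_table(c(0, 5, 5, 10)))
  expect_identical(zero$or, 0)
  expect_match(zero$flags, "zero_or")
})

test_that("CMH test has its stated null and symmetry behavior", {
  st <- stratified_table(c(10, 10, 10, 10))
  r <- cmh_test(st, continuity = FALSE)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # relabeling exposed <-> unexposed in all strata leaves p unchanged
  set.seed(11)
  for (rep in 1:10) {
    tabs <- random_tables(max_count = 50)
    st1 <- as_strat(tabs)
    st2 <- as_strat(lapply(tabs, function(x) x[c(2, 1, 4, 3)]))
    expect_equal(cmh_test(st1)$p, cmh_test(st2)$p, tolerance = 1e-12)
    # and inverts the odds ratio
    o1 <- mantel_haenszel_or(st1)$or
    o2 <- mantel_haenszel_or(st2)$or
    if (is.finite(o1) && o1 > 0 && is.finite(o2))
      expect_equal(o2, 1 / o1, tolerance = 1e-12)
  }
})

test_that("single-stratum CMH is the exact (n-1)/n transform of the classical 2x2 chi-square", {
  # the hypergeometric variance carries an n-1 term, so the one-stratum CMH
  # statistic equals ((n-1)/n) * Pearson X^2 identically (same correction)
  set.seed(13)
  for (rep in 1:20) {
    tb <- random_tables(n_strata = 1, max_count = 80)[[1]]
    m <- matrix(tb, 2, byrow = TRUE)  # rows: case/control, cols: exp/unexp
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    n <- sum(tb)
    for (cc in c(TRUE, FALSE)) {
      ours <- cmh_test(stratified_table(tb), continuity = cc)
      ref <- suppressWarnings(chisq.test(m, correct = cc))
      expect_equal(ours$statistic, (n - 1) / n * unname(ref$statistic),
                   tolerance = 1e-10)
    }
  }
})

test_that("core agrees with mantelhaen.test and the naive oracle", {
  set.seed(17)
  for (rep in 1:50) {
    tabs <- random_tables()
    st <- as_strat(tabs)
    or <- mantel_haenszel_or(st)
    cm <- cmh_test(st, continuity = FALSE)
    # naive scalar oracle
    expect_equal(or$or, naive_mh_or(tabs), tolerance = 1e-10)
    ci <- naive_rbg_ci(tabs)
    if (all(is.finite(ci)))
      expect_equal(or$ci, ci, tolerance = 1e-10)
    ns <- naive_cmh_stat(tabs, continuity = FALSE)
    expect_equal(cm$statistic, ns$stat, tolerance = 1e-10)
    # stats::mantelhaen.test as an independent reference where defined
    arr <- array(unlist(lapply(tabs, function(x)
      c(x[1], x[3], x[2], x[4]))), dim = c(2, 2, length(tabs)))
    ref <- tryCatch(mantelhaen.test(arr, correct = FALSE, exact = FALSE),
                    error = function(e) NULL)
    if (!is.null(ref) && is.finite(or$or) && or$or > 0) {
      expect_equal(or$or, unname(ref$estimate), tolerance = 1e-10)
      expect_equal(cm$p, ref$p.value, tolerance = 1e-10)
      expect_equal(or$ci, as.numeric(ref$conf.int), tolerance = 1e-8)
    }
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.9)), c(0.003, 0.03, 0.9))
  expect_equal(bh_fdr(rep(0.04, 7)), rep(0.04, 7))
  set.seed(19)
  p <- sort(runif(30))
  q <- bh_fdr(p)
  expect_true(all(diff(q) >= -1e-15))
  expect_true(all(q >= p))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA p-values stay NA and do not perturb the family
  expect_equal(bh_fdr(c(0.01, NA, 0.04))[c(1, 3)], bh_fdr(c(0.01, 0.04)))
})

test_that("assoc_test assembles a complete result row", {
  set.seed(23)
  G <- make_G(random_dosages(120, 2, miss = 0))
  S <- make_samples(120,
                    status = sample(c("case", "control"), 120, TRUE),
                    sex = sample(c("male", "female"), 120, TRUE),
                    smoking = sample(c("smoker", "nonsmoker"), 120, TRUE))
  e <- build_pattern_exposure(G, "rs1", "d")
  row <- assoc_test(e, S)
  expect_identical(row$snp_ids, "rs1")
  expect_identical(row$n_exposed + row$n_unexposed, 120L)
  expect_true(row$p >= 0 && row$p <= 1)
  expect_true(is.finite(row$ci_low) && row$ci_low <= row$or_mh &&
                row$or_mh <= row$ci_high)
})
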