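# Stratified 2x2 machinery: Mantel-Haenszel common odds ratio with the
# Robins-Breslow-Greenland (RBG) variance, the Cochran-Mantel-Haenszel
# chi-square test, and Benjamini-Hochberg FDR adjustment.
#
# The numerical core (.cmh_core) is vectorized across tests -- every column
# of the a/b/c/d matrices is one 2x2xK table -- so that exhaustive scans of
# tens of thousands of pattern hypotheses stay fast. The scalar wrappers
# below feed it single tables.

# a = case/exposed, b = case/unexposed, c = control/exposed,
# d = control/unexposed; strata in rows, tests in columns.
.cmh_core <- function(a, b, c, d, continuity = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b); c <- as.matrix(c); d <- as.matrix(d)
  storage.mode(a) <- storage.mode(b) <- "double"
  storage.mode(c) <- storage.mode(d) <- "double"
  n <- a + b + c + d
  pos <- n > 0
  safe_n <- ifelse(pos, n, 1)  # avoid 0/0; masked below

  ## Mantel-Haenszel estimator and RBG variance of log OR
  R <- ifelse(pos, a * d / safe_n, 0)
  S <- ifelse(pos, b * c / safe_n, 0)
  P <- ifelse(pos, (a + d) / safe_n, 0)
  Q <- ifelse(pos, (b + c) / safe_n, 0)
  sumR <- colSums(R); sumS <- colSums(S)
  or <- ifelse(sumR == 0 & sumS == 0, NA_real_, sumR / sumS)
  var_log <- colSums(P * R) / (2 * sumR^2) +
    colSums(P * S + Q * R) / (2 * sumR * sumS) +
    colSums(Q * S) / (2 * sumS^2)
  var_log[!(sumR > 0 & sumS > 0)] <- NA_real_
  se_log <- sqrt(var_log)
  z <- qnorm(0.975)
  ci_low <- exp(log(or) - z * se_log)
  ci_high <- exp(log(or) + z * se_log)

  ## CMH statistic: hypergeometric mean/variance of the case-exposed cell
  n1 <- a + b          # cases (row margin)
  m1 <- a + c          # exposed (column margin)
  ex <- ifelse(pos, n1 * m1 / safe_n, 0)
  v_ok <- n >= 2
  vv <- ifelse(v_ok,
               n1 * (n - n1) * m1 * (n - m1) /
                 (safe_n^2 * pmax(n - 1, 1)),
               0)
  sum_dev <- colSums(a - ex)
  sum_var <- colSums(vv)
  cc <- if (continuity) 0.5 else 0
  stat <- pmax(abs(sum_dev) - cc, 0)^2 / sum_var
  stat[sum_var == 0] <- NA_real_
  p <- pchisq(stat, df = 1, lower.tail = FALSE)

  n_exposed <- colSums(a + c)
  n_unexposed <- colSums(b + d)
  flags <- character(ncol(a))
  add_flag <- function(flags, which, tag)
    ifelse(which, ifelse(flags == "", tag, paste(flags, tag, sep = ",")),
           flags)
  flags <- add_flag(flags, colSums(n) == 0, "no_subjects")
  flags <- add_flag(flags, colSums(n) > 0 & sum_var == 0, "degenerate")
  flags <- add_flag(flags, is.finite(or) & or == 0, "zero_or")
  flags <- add_flag(flags, is.infinite(or), "infinite_or")
  flags <- add_flag(flags, n_exposed < 5 & colSums(n) > 0, "sparse")

  direction <- rep(NA_character_, length(or))
  direction[!is.na(or) & or > 1] <- "risk"
  direction[!is.na(or) & or < 1] <- "protective"
  direction[!is.na(or) & or == 1] <- "none"

  list(or = or, ci_low = ci_low, ci_high = ci_high, se_log = se_log,
       stat = stat, p = p, n_exposed = n_exposed,
       n_unexposed = n_unexposed, direction = direction, flags = flags)
}

#' Stratified 2x2 tables for a pattern exposure
#'
#' Cross-tabulates case/control status against exposure within each observed
#' sex-by-smoking covariate combination. Included subjects without complete
#' covariates (or absent from the sample table) are dropped and counted;
#' empty strata are omitted.
#'
#' @param exposure a [build_pattern_exposure()] result (or any object with
#'   `subjects`, `included`, `exposed`).
#' @param samples a [sample_table()].
#' @return object of class `stratified_table`: `counts` (strata x 4 matrix
#'   with columns `case_exposed`, `case_unexposed`, `control_exposed`,
#'   `control_unexposed`), `labels`, `n_used`, `n_dropped`.
#' @export
stratify <- function(exposure, samples) {
  stopifnot(inherits(samples, "sample_table"))
  idx <- match(exposure$subjects, samples$subject_id)
  usable <- exposure$included & !is.na(idx)
  usable[usable] <- samples$complete_covariates[idx[usable]]
  n_dropped <- sum(exposure$included) - sum(usable)
  sub <- idx[usable]
  exp_u <- exposure$exposed[usable]
  stratum <- paste(samples$sex[sub], samples$smoking[sub], sep = ":")
  is_case <- samples$status[sub] == "case"
  labs <- sort(unique(stratum))
  counts <- t(vapply(labs, function(s) {
    in_s <- stratum == s
    c(case_exposed = sum(in_s & is_case & exp_u),
      case_unexposed = sum(in_s & is_case & !exp_u),
      control_exposed = sum(in_s & !is_case & exp_u),
      control_unexposed = sum(in_s & !is_case & !exp_u))
  }, numeric(4)))
  if (!length(labs))
    counts <- matrix(numeric(0), ncol = 4, dimnames = list(NULL,
      c("case_exposed", "case_unexposed", "control_exposed",
        "control_unexposed")))
  structure(list(counts = counts, labels = labs,
                 n_used = sum(usable), n_dropped = n_dropped),
            class = "stratified_table")
}

#' Build a stratified table from raw counts
#'
#' Convenience constructor for tests and direct use: one row per stratum,
#' columns case-exposed, case-unexposed, control-exposed, control-unexposed.
#'
#' @param counts numeric matrix or vector of length 4 (single stratum).
#' @param labels optional stratum labels.
#' @return a `stratified_table`.
#' @export
stratified_table <- function(counts, labels = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  stopifnot(ncol(counts) == 4, all(counts >= 0))
  colnames(counts) <- c("case_exposed", "case_unexposed",
                        "control_exposed", "control_unexposed")
  structure(list(counts = counts,
                 labels = labels %||% paste0("stratum", seq_len(nrow(counts))),
                 n_used = sum(counts), n_dropped = 0L),
            class = "stratified_table")
}

#' Mantel-Haenszel common odds ratio with RBG confidence interval
#'
#' OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i); the 95% CI is
#' exp(log OR +/- z * SE) with the Robins-Breslow-Greenland variance of the
#' log odds ratio. A zero denominator yields an infinite OR (reported, not
#' an error).
#'
#' @param st a `stratified_table`.
#' @return list with `or`, `ci` (length-2), `se_log`, `flags`.
#' @export
mantel_haenszel_or <- function(st) {
  stopifnot(inherits(st, "stratified_table"))
  cm <- st$counts
  if (nrow(cm) == 0)
    return(list(or = NA_real_, ci = c(NA_real_, NA_real_),
                se_log = NA_real_, flags = "no_subjects"))
  res <- .cmh_core(cm[, 1], cm[, 2], cm[, 3], cm[, 4])
  list(or = res$or, ci = c(res$ci_low, res$ci_high),
       se_log = res$se_log, flags = res$flags)
}

#' Cochran-Mantel-Haenszel test
#'
#' Chi-square test (1 df) of conditional independence of exposure and
#' case status across strata, using the hypergeometric mean and variance of
#' the case-exposed cell per stratum. With a single stratum and matching
#' correction setting it coincides with the classical 2x2 chi-square test.
#'
#' @param st a `stratified_table`.
#' @param continuity apply the 0.5 continuity correction (default `TRUE`).
#' @return list with `statistic`, `p`, `flags` (`p` is `NA` with a
#'   `degenerate` flag when every stratum has zero variance).
#' @export
cmh_test <- function(st, continuity = TRUE) {
  stopifnot(inherits(st, "stratified_table"))
  cm <- st$counts
  if (nrow(cm) == 0)
    return(list(statistic = NA_real_, p = NA_real_, flags = "no_subjects"))
  res <- .cmh_core(cm[, 1], cm[, 2], cm[, 3], cm[, 4],
                   continuity = continuity)
  list(statistic = res$stat, p = res$p, flags = res$flags)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA` p-values are kept out of the family and
#' returned as `NA`.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Single stratified association test
#'
#' Runs one pattern exposure through [stratify()], [mantel_haenszel_or()]
#' and [cmh_test()] and returns a one-row result data.frame (without a
#' q-value, which is a property of a scan family).
#'
#' @param exposure a `pattern_exposure`.
#' @param samples a `sample_table`.
#' @param continuity continuity correction for the CMH statistic.
#' @return one-row data.frame with columns `snp_ids`, `pattern`,
#'   `n_exposed`, `n_unexposed`, `or_mh`, `ci_low`, `ci_high`, `p`,
#'   `direction`, `flags`.
#' @export
assoc_test <- function(exposure, samples, continuity = TRUE) {
  st <- stratify(exposure, samples)
  if (nrow(st$counts) == 0) {
    return(data.frame(
      snp_ids = paste(exposure$snp_ids, collapse = ","),
      pattern = exposure$pattern, n_exposed = 0L, n_unexposed = 0L,
      or_mh = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p = NA_real_, direction = NA_character_, flags = "no_subjects",
      stringsAsFactors = FALSE))
  }
  res <- .cmh_core(st$counts[, 1], st$counts[, 2], st$counts[, 3],
                   st$counts[, 4], continuity = continuity)
  data.frame(
    snp_ids = paste(exposure$snp_ids, collapse = ","),
    pattern = exposure$pattern,
    n_exposed = as.integer(res$n_exposed),
    n_unexposed = as.integer(res$n_unexposed),
    or_mh = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
    p = res$p, direction = res$direction, flags = res$flags,
    stringsAsFactors = FALSE)
}
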