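# Exhaustive effect-pattern scan. For a panel of m SNPs and order k the
# scan enumerates every C(m, k) SNP tuple crossed with every 3^k effect
# pattern and runs each through the stratified CMH machinery. The counting
# step is vectorized: per-subject component inclusion/indicator matrices
# are combined tuple-by-tuple with a single cross-product against the
# (stratum x status) group design, so a full three-SNP scan of a 17-SNP
# panel (18,360 hypotheses) takes on the order of a second.

#' Exhaustive effect-pattern association scan
#'
#' Tests every SNP combination of the requested order under every effect
#' pattern of that length (3 component codings per SNP, so `3^order`
#' patterns per tuple) with a sex-by-smoking stratified
#' Cochran-Mantel-Haenszel test. Benjamini-Hochberg q-values are computed
#' across the whole scan (each order is its own multiplicity family).
#'
#' @param G a [genotype_matrix()].
#' @param samples a [sample_table()] covering the subjects of `G`.
#' @param order scan order: 1, 2 or 3 SNPs per hypothesis.
#' @param alpha reporting threshold on the raw CMH p-value (default 0.05);
#'   rows with `p < alpha` populate `$results`.
#' @param fdr FDR level; rows with `q <= fdr` get `fdr_significant = TRUE`.
#' @param continuity continuity correction for the CMH statistic
#'   (default `TRUE`; stratum counts are small in cohorts of a few hundred).
#' @param dominant_coding `"deviation"` (default) or `"carrier"`, see
#'   [code_component()].
#' @param keep_all keep the full hypothesis table in `$all` (default
#'   `TRUE`).
#' @return object of class `epi_scan` with elements `results` (rows with
#'   `p < alpha`, ordered by p), `all` (optional full table), `order`,
#'   `n_tests`, `n_subjects`, `alpha`, `fdr`, `continuity`, `snps`.
#' @seealso [snp_frequency_summary()], [summary.epi_scan()]
#' @export
epi_scan <- function(G, samples, order, alpha = 0.05, fdr = 0.05,
                     continuity = TRUE,
                     dominant_coding = c("deviation", "carrier"),
                     keep_all = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"))
  stopifnot(inherits(samples, "sample_table"))
  if (!(length(order) == 1 && order %in% 1:3))
    stop("order must be 1, 2 or 3", call. = FALSE)
  dominant_coding <- match.arg(dominant_coding)

  m <- ncol(G$dosages)
  if (m < order) stop("panel has fewer SNPs than the scan order", call. = FALSE)
  n <- nrow(G$dosages)

  ## group design: one column per (stratum x status) cell
  idx <- match(G$subjects, samples$subject_id)
  usable <- !is.na(idx)
  usable[usable] <- samples$complete_covariates[idx[usable]]
  sub <- idx
  stratum <- rep(NA_character_, n)
  stratum[usable] <- paste(samples$sex[sub[usable]],
                           samples$smoking[sub[usable]], sep = ":")
  is_case <- rep(NA, n)
  is_case[usable] <- samples$status[sub[usable]] == "case"
  labs <- sort(unique(stratum[usable]))
  K <- length(labs)
  if (K == 0) stop("no subjects with complete covariates", call. = FALSE)
  grp <- matrix(0, n, 2 * K)  # columns: case stratum 1..K, control 1..K
  for (s in seq_len(K)) {
    grp[usable & stratum == labs[s] & is_case, s] <- 1
    grp[usable & stratum == labs[s] & !is_case, K + s] <- 1
  }

  ## per-SNP component matrices (n x m per component)
  inc <- exp_ind <- vector("list", 3)
  names(inc) <- names(exp_ind) <- EFFECT_COMPONENTS
  for (comp in EFFECT_COMPONENTS) {
    I <- X <- matrix(0, n, m)
    for (j in seq_len(m)) {
      cc <- code_component(G$dosages[, j], comp,
                           dominant_coding = dominant_coding)
      I[, j] <- as.numeric(cc$include)
      X[, j] <- as.numeric(cc$include & !is.na(cc$indicator) &
                             cc$indicator == 1L)
    }
    inc[[comp]] <- I
    exp_ind[[comp]] <- X
  }

  tuples <- combn(m, order)
  patterns <- effect_patterns(order)
  pat_comp <- lapply(patterns, pattern_components)
  n_pat <- length(patterns)
  n_tests <- ncol(tuples) * n_pat

  tgrp <- t(grp)
  a_mat <- b_mat <- c_mat <- d_mat <- matrix(0, K, n_tests)
  col0 <- 0L
  for (t in seq_len(ncol(tuples))) {
    tup <- tuples[, t]
    incblk <- expblk <- matrix(1, n, n_pat)
    for (pidx in seq_len(n_pat)) {
      comps <- pat_comp[[pidx]]
      for (j in seq_along(tup)) {
        incblk[, pidx] <- incblk[, pidx] * inc[[comps[j]]][, tup[j]]
        expblk[, pidx] <- expblk[, pidx] * exp_ind[[comps[j]]][, tup[j]]
      }
    }
    cnt_inc <- tgrp %*% incblk  # (2K) x n_pat
    cnt_exp <- tgrp %*% expblk
    cols <- col0 + seq_len(n_pat)
    a_mat[, cols] <- cnt_exp[seq_len(K), , drop = FALSE]
    b_mat[, cols] <- cnt_inc[seq_len(K), , drop = FALSE] -
      cnt_exp[seq_len(K), , drop = FALSE]
    c_mat[, cols] <- cnt_exp[K + seq_len(K), , drop = FALSE]
    d_mat[, cols] <- cnt_inc[K + seq_len(K), , drop = FALSE] -
      cnt_exp[K + seq_len(K), , drop = FALSE]
    col0 <- col0 + n_pat
  }

  res <- .cmh_core(a_mat, b_mat, c_mat, d_mat, continuity = continuity)

  snp_id_mat <- matrix(G$snps$snp_id[tuples], nrow = order)
  gene_mat <- matrix(G$snps$gene[tuples], nrow = order)
  tab <- data.frame(
    snp_ids = rep(apply(snp_id_mat, 2, paste, collapse = ","),
                  each = n_pat),
    genes = rep(apply(gene_mat, 2, paste, collapse = ","), each = n_pat),
    pattern = rep(patterns, times = ncol(tuples)),
    n_exposed = as.integer(res$n_exposed),
    n_unexposed = as.integer(res$n_unexposed),
    or_mh = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
    p = res$p, q = bh_fdr(res$p),
    direction = res$direction, flags = res$flags,
    stringsAsFactors = FALSE)
  tab$fdr_significant <- !is.na(tab$q) & tab$q <= fdr

  sig <- tab[!is.na(tab$p) & tab$p < alpha, , drop = FALSE]
  sig <- sig[base::order(sig$p), , drop = FALSE]
  rownames(sig) <- NULL

  structure(list(results = sig, all = if (keep_all) tab else NULL,
                 order = order, n_tests = n_tests, n_subjects = n,
                 n_strata = K, alpha = alpha, fdr = fdr,
                 continuity = continuity, dominant_coding = dominant_coding,
                 snps = G$snps),
            class = "epi_scan")
}

#' @export
print.epi_scan <- function(x, ...) {
  cat(sprintf("epi_scan: order %d, %d hypotheses on %d subjects (%d strata)\n",
              x$order, x$n_tests, x$n_subjects, x$n_strata))
  cat(sprintf("%d hypotheses with p < %g; %d FDR-significant at q <= %g\n",
              nrow(x$results), x$alpha,
              sum(x$results$fdr_significant), x$fdr))
  if (nrow(x$results)) {
    show <- utils::head(x$results[c("snp_ids", "pattern", "or_mh", "p", "q")],
                        10)
    print(show, digits = 3)
    if (nrow(x$results) > 10)
      cat("... and", nrow(x$results) - 10, "more rows\n")
  }
  invisible(x)
}

# gene-panel classes used in summaries: collagen-like hydrophilic
# surfactant proteins vs the hydrophobic ones
.HYDROPHILIC_GENES <- c("SFTPA1", "SFTPA2", "SFTPD")
.HYDROPHOBIC_GENES <- c("SFTPB", "SFTPC")

.gene_class <- function(genes_joined) {
  vapply(strsplit(genes_joined, ",", fixed = TRUE), function(g) {
    g <- g[!is.na(g) & g != "NA"]
    if (!length(g)) return("unknown")
    if (all(g %in% .HYDROPHILIC_GENES)) return("hydrophilic")
    if (all(g %in% .HYDROPHOBIC_GENES)) return("hydrophobic")
    if (all(g %in% c(.HYDROPHILIC_GENES, .HYDROPHOBIC_GENES))) return("mixed")
    "other"
  }, character(1))
}

.is_intragenic <- function(genes_joined) {
  vapply(strsplit(genes_joined, ",", fixed = TRUE), function(g)
    length(g) > 1 && !anyNA(g) && !any(g == "NA") &&
      length(unique(g)) == 1, logical(1))
}

#' Summarize a pattern scan
#'
#' Bookkeeping over the reported (p < alpha) hypotheses: risk/protective
#' split, pattern composition, intragenic interactions (all SNPs in one
#' gene), and hydrophilic/hydrophobic gene-class composition for
#' surfactant-protein panels.
#'
#' @param object an `epi_scan`.
#' @param ... unused.
#' @return object of class `summary.epi_scan` (a list of small tables).
#' @export
summary.epi_scan <- function(object, ...) {
  r <- object$results
  out <- list(
    order = object$order,
    n_tests = object$n_tests,
    n_reported = nrow(r),
    n_fdr_significant = sum(r$fdr_significant),
    by_direction = table(factor(r$direction,
                                levels = c("risk", "protective"))),
    by_pattern = sort(table(r$pattern), decreasing = TRUE),
    intragenic = sum(.is_intragenic(r$genes)),
    by_gene_class = table(.gene_class(r$genes)),
    or_range = if (nrow(r)) range(r$or_mh[is.finite(r$or_mh)]) else
      c(NA_real_, NA_real_),
    p_range = if (nrow(r)) range(r$p) else c(NA_real_, NA_real_))
  class(out) <- "summary.epi_scan"
  out
}

#' @export
print.summary.epi_scan <- function(x, ...) {
  cat(sprintf("order-%d scan: %d hypotheses, %d reported, %d FDR-significant\n",
              x$order, x$n_tests, x$n_reported, x$n_fdr_significant))
  cat(sprintf("direction: %d risk / %d protective; %d intragenic\n",
              x$by_direction["risk"], x$by_direction["protective"],
              x$intragenic))
  if (x$n_reported) {
    cat("patterns:\n"); print(x$by_pattern)
    cat("gene classes:\n"); print(x$by_gene_class)
    cat(sprintf("OR range %.3g-%.3g, p range %.3g-%.3g\n",
                x$or_range[1], x$or_range[2], x$p_range[1], x$p_range[2]))
  }
  invisible(x)
}

#' SNP membership frequency among significant interactions
#'
#' For each SNP, the number of reported significant interactions in which it
#' participates, sorted descending. Counts sum to
#' `order x number of significant interactions`.
#'
#' @param scan an `epi_scan`, or a results data.frame with a `snp_ids`
#'   column.
#' @return data.frame with columns `snp_id`, `count`.
#' @export
snp_frequency_summary <- function(scan) {
  r <- if (inherits(scan, "epi_scan")) scan$results else scan
  if (!nrow(r))
    return(data.frame(snp_id = character(0), count = integer(0)))
  ids <- unlist(strsplit(r$snp_ids, ",", fixed = TRUE))
  tt <- sort(table(ids), decreasing = TRUE)
  data.frame(snp_id = names(tt), count = as.integer(tt),
             stringsAsFactors = FALSE, row.names = NULL)
}
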