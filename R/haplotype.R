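# Two-locus haplotype analysis: EM frequency estimation from unphased
# genotypes, most-probable-diplotype carrier assignment, and carrier-model
# (dominant) association tests through the stratified CMH machinery.
#
# Every diplotype is phase-certain except the double heterozygote, whose
# two resolutions (ref-ref/alt-alt vs ref-alt/alt-ref) are fractionally
# assigned from the current frequency estimates each E-step.

# 3x3 genotype-class counts from two dosage vectors (pairwise-complete)
.pair_counts <- function(d1, d2) {
  ok <- !is.na(d1) & !is.na(d2)
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2)
    tab[i + 1, j + 1] <- sum(d1[ok] == i & d2[ok] == j)
  tab
}

# multinomial log-likelihood of the genotype classes given haplotype
# frequencies p = (ref-ref, ref-alt, alt-ref, alt-alt)
.hap_loglik <- function(tab, p) {
  probs <- c(p[1]^2, 2 * p[1] * p[2], p[2]^2,
             2 * p[1] * p[3], 2 * (p[1] * p[4] + p[2] * p[3]),
             2 * p[2] * p[4],
             p[3]^2, 2 * p[3] * p[4], p[4]^2)
  cnt <- as.vector(t(tab))  # order (d1,d2) = 00,01,02,10,11,12,20,21,22
  use <- cnt > 0
  if (any(use & probs <= 0)) return(-Inf)
  sum(cnt[use] * log(probs[use]))
}

#' Two-locus haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies (ref-ref, ref-alt, alt-ref,
#' alt-alt) of an ordered biallelic SNP pair from unphased alt-allele
#' dosages. Subjects missing either dosage are dropped. With no double
#' heterozygotes the maximum-likelihood estimate is direct gamete counting
#' and the algorithm stops after one iteration.
#'
#' @param d1,d2 dosage vectors (0/1/2/`NA`) at the two SNPs.
#' @param tol convergence tolerance on the maximum frequency change
#'   (default `1e-8`).
#' @param max_iter iteration cap (default 1000).
#' @param start optional length-4 starting frequency vector; default is the
#'   linkage-equilibrium product of the observed allele frequencies.
#' @return object of class `hap_freqs`: `freqs` (named length-4 vector),
#'   `loglik`, `loglik_trace`, `n_iter`, `n` (informative subjects).
#' @export
em_haplotype_freqs <- function(d1, d2, tol = 1e-8, max_iter = 1000,
                               start = NULL) {
  tab <- .pair_counts(d1, d2)
  n <- sum(tab)
  if (n == 0) {
    return(structure(list(freqs = setNames(rep(NA_real_, 4),
                                           c("00", "01", "10", "11")),
                          loglik = NA_real_, loglik_trace = numeric(0),
                          n_iter = 0L, n = 0L),
                     class = "hap_freqs"))
  }
  # phase-certain gamete counts of (h00, h01, h10, h11); the double
  # heterozygote count tab[2,2] is split in the E-step
  fixed <- c(
    2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
    2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
    2 * tab[3, 3] + tab[2, 3] + tab[3, 2])
  n_dh <- tab[2, 2]
  if (is.null(start)) {
    q1 <- (sum(tab[2, ]) + 2 * sum(tab[3, ])) / (2 * n)
    q2 <- (sum(tab[, 2]) + 2 * sum(tab[, 3])) / (2 * n)
    p <- c((1 - q1) * (1 - q2), (1 - q1) * q2, q1 * (1 - q2), q1 * q2)
  } else {
    stopifnot(length(start) == 4, all(start >= 0))
    p <- start / sum(start)
  }
  trace <- numeric(0)
  n_iter <- 0L
  for (iter in seq_len(max_iter)) {
    n_iter <- iter
    cis <- p[1] * p[4]
    trans <- p[2] * p[3]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new <- fixed + n_dh * c(w, 1 - w, 1 - w, w)
    new <- new / (2 * n)
    delta <- max(abs(new - p))
    p <- new
    trace <- c(trace, .hap_loglik(tab, p))
    if (n_dh == 0 || delta < tol) break
  }
  structure(list(freqs = setNames(p, c("00", "01", "10", "11")),
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = n_iter, n = n),
            class = "hap_freqs")
}

#' @export
print.hap_freqs <- function(x, ...) {
  cat(sprintf("hap_freqs (n = %d, %d EM iteration(s), loglik %.4f)\n",
              x$n, x$n_iter, x$loglik))
  print(round(x$freqs, 4))
  invisible(x)
}

# carrier status of haplotype `hap` (1..4 = 00,01,10,11) per subject,
# resolving double heterozygotes to the more probable phase under `p`
# (ties resolved to the cis pair 00/11)
.hap_carrier <- function(d1, d2, hap, p) {
  cis_more <- p[1] * p[4] >= p[2] * p[3]
  # haplotype content of the diplotype for each genotype class (d1, d2);
  # phase is forced except for the double heterozygote
  content <- matrix(FALSE, 9, 4)  # rows: class 3*d1 + d2 + 1
  for (i in 0:2) for (j in 0:2) {
    row <- 3 * i + j + 1
    if (i == 1 && j == 1) {
      content[row, if (cis_more) c(1, 4) else c(2, 3)] <- TRUE
    } else if (i == 1) {        # het at SNP1 only; SNP2 allele fixed at j/2
      content[row, 2 * c(0, 1) + j / 2 + 1] <- TRUE
    } else if (j == 1) {        # het at SNP2 only
      content[row, 2 * (i / 2) + c(0, 1) + 1] <- TRUE
    } else {                    # double homozygote
      content[row, 2 * (i / 2) + j / 2 + 1] <- TRUE
    }
  }
  carrier <- rep(NA, length(d1))
  ok <- !is.na(d1) & !is.na(d2)
  carrier[ok] <- content[3 * d1[ok] + d2[ok] + 1, hap]
  carrier
}

.hap_labels <- function(snps, id1, id2) {
  a1 <- snps[snps$snp_id == id1, ]
  a2 <- snps[snps$snp_id == id2, ]
  r1 <- if (is.na(a1$ref_allele)) "0" else a1$ref_allele
  t1 <- if (is.na(a1$alt_allele)) "1" else a1$alt_allele
  r2 <- if (is.na(a2$ref_allele)) "0" else a2$ref_allele
  t2 <- if (is.na(a2$alt_allele)) "1" else a2$alt_allele
  c(paste0(r1, r2), paste0(r1, t2), paste0(t1, r2), paste0(t1, t2))
}

#' Carrier-model haplotype association test
#'
#' Estimates pooled-cohort haplotype frequencies for a SNP pair by EM,
#' assigns each subject the most probable diplotype, and tests carriers of
#' a candidate risk haplotype against non-carriers with the stratified CMH
#' machinery (a dominant haplotype effect). When `risk_haplotype` is `NULL`
#' all four haplotypes are tested.
#'
#' @param G a [genotype_matrix()].
#' @param samples a [sample_table()].
#' @param snp_pair length-2 character vector of SNP ids (ordered).
#' @param risk_haplotype two-letter allele label (e.g. `"TG"`) built from
#'   the pair's ref/alt alleles, or `NULL` for all four.
#' @param continuity continuity correction for the CMH test.
#' @return data.frame with one row per tested haplotype: `snp_pair`,
#'   `haplotype`, `hap_freq`, `effect_model`, `n_exposed`, `n_unexposed`,
#'   `or_mh`, `ci_low`, `ci_high`, `p`, `direction`, `flags`. Haplotypes
#'   with estimated frequency 0 give an `NA` row flagged
#'   `zero_frequency`.
#' @export
haplotype_dominant_test <- function(G, samples, snp_pair,
                                    risk_haplotype = NULL,
                                    continuity = TRUE) {
  stopifnot(inherits(G, "genotype_matrix"), length(snp_pair) == 2)
  unknown <- setdiff(snp_pair, G$snps$snp_id)
  if (length(unknown))
    stop("unknown SNP id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  d1 <- G$dosages[, snp_pair[1]]
  d2 <- G$dosages[, snp_pair[2]]
  em <- em_haplotype_freqs(d1, d2)
  labels <- .hap_labels(G$snps, snp_pair[1], snp_pair[2])
  test_idx <- if (is.null(risk_haplotype)) 1:4 else {
    ti <- match(risk_haplotype, labels)
    if (is.na(ti))
      stop("risk_haplotype '", risk_haplotype, "' is not one of: ",
           paste(labels, collapse = ", "), call. = FALSE)
    ti
  }
  pair_lab <- paste(snp_pair, collapse = ",")
  rows <- lapply(test_idx, function(h) {
    base <- data.frame(snp_pair = pair_lab, haplotype = labels[h],
                       hap_freq = unname(em$freqs[h]),
                       effect_model = "dominant",
                       stringsAsFactors = FALSE)
    if (is.na(em$freqs[h]) || em$freqs[h] == 0) {
      return(cbind(base, data.frame(
        n_exposed = NA_integer_, n_unexposed = NA_integer_,
        or_mh = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        p = NA_real_, direction = NA_character_,
        flags = "zero_frequency", stringsAsFactors = FALSE)))
    }
    carrier <- .hap_carrier(d1, d2, h, em$freqs)
    expo <- structure(list(snp_ids = snp_pair, pattern = "carrier",
                           included = !is.na(carrier), exposed = carrier,
                           subjects = G$subjects),
                      class = "pattern_exposure")
    res <- assoc_test(expo, samples, continuity = continuity)
    cbind(base, res[c("n_exposed", "n_unexposed", "or_mh", "ci_low",
                      "ci_high", "p", "direction", "flags")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "em") <- em
  out
}

# adjacent SNP pairs within each gene, in panel order
.adjacent_pairs <- function(snps) {
  pairs <- list()
  for (g in unique(snps$gene)) {
    ids <- snps$snp_id[!is.na(snps$gene) & snps$gene %in% g]
    if (length(ids) >= 2)
      for (i in seq_len(length(ids) - 1))
        pairs[[length(pairs) + 1]] <- c(ids[i], ids[i + 1])
  }
  pairs
}

#' Haplotype association scan over SNP pairs
#'
#' Runs [haplotype_dominant_test()] for all four haplotypes of each pair
#' and applies Benjamini-Hochberg adjustment across the whole haplotype
#' family. The default pair set is every adjacent SNP pair within a gene
#' (panel order); pass `pairs` explicitly (or `all_pairs = TRUE`) to
#' override.
#'
#' @param G a [genotype_matrix()].
#' @param samples a [sample_table()].
#' @param pairs list of length-2 SNP-id vectors; default adjacent pairs
#'   within each gene.
#' @param all_pairs test every SNP pair in the panel (overrides `pairs`).
#' @param fdr FDR level for the `fdr_significant` column.
#' @param continuity continuity correction for the CMH tests.
#' @return object of class `hap_scan`: `results` data.frame (with `q`),
#'   `pairs`, `fdr`.
#' @export
haplotype_scan <- function(G, samples, pairs = NULL, all_pairs = FALSE,
                           fdr = 0.05, continuity = TRUE) {
  if (all_pairs) {
    cmb <- combn(G$snps$snp_id, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  if (is.null(pairs)) pairs <- .adjacent_pairs(G$snps)
  if (!length(pairs)) stop("no SNP pairs to test", call. = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pr)
    haplotype_dominant_test(G, samples, pr, continuity = continuity)))
  res$q <- bh_fdr(res$p)
  res$fdr_significant <- !is.na(res$q) & res$q <= fdr
  rownames(res) <- NULL
  structure(list(results = res, pairs = pairs, fdr = fdr),
            class = "hap_scan")
}

#' @export
print.hap_scan <- function(x, ...) {
  cat(sprintf("hap_scan: %d pairs, %d haplotype tests, %d FDR-significant\n",
              length(x$pairs), nrow(x$results),
              sum(x$results$fdr_significant, na.rm = TRUE)))
  print(utils::head(x$results[c("snp_pair", "haplotype", "hap_freq",
                                "or_mh", "p", "q")], 12), digits = 3)
  invisible(x)
}
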