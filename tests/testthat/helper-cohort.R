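# Small in-code fixtures: genotype matrices, sample tables, and a VCF
# writer used to check reader equivalence.

make_G <- function(dos, snps = NULL) {
  if (is.null(rownames(dos)))
    rownames(dos) <- sprintf("S%03d", seq_len(nrow(dos)))
  if (is.null(colnames(dos)))
    colnames(dos) <- sprintf("snp%d", seq_len(ncol(dos)))
  genotype_matrix(dos, snps)
}

make_samples <- function(n, status = NULL, sex = NULL, smoking = NULL,
                         ids = sprintf("S%03d", seq_len(n))) {
  sample_table(data.frame(
    subject_id = ids,
    status = status %||% rep(c("case", "control"), length.out = n),
    sex = sex %||% rep(c("male", "female"), length.out = n),
    smoking = smoking %||% rep(c("smoker", "nonsmoker"), length.out = n),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a genotype_matrix as a minimal VCF (one ALT, GT-only FORMAT)
write_vcf_fixture <- function(G, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", G$subjects), collapse = "\t"))
  gt_of <- function(d) c("0/0", "0/1", "1/1")[d + 1]
  rows <- vapply(seq_len(ncol(G$dosages)), function(j) {
    ref <- G$snps$ref_allele[j]; alt <- G$snps$alt_allele[j]
    if (is.na(ref)) ref <- "A"
    if (is.na(alt)) alt <- "G"
    gts <- ifelse(is.na(G$dosages[, j]), "./.", gt_of(G$dosages[, j]))
    paste(c("1", j, G$snps$snp_id[j], ref, alt, ".", "PASS", ".", "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# genotypes drawn from HWE for io round-trip property tests
random_dosages <- function(n, m, maf = 0.3, miss = 0.05) {
  d <- matrix(rbinom(n * m, 2, maf), n, m)
  d[runif(n * m) < miss] <- NA
  rownames(d) <- sprintf("S%03d", seq_len(n))
  colnames(d) <- sprintf("rs%d", seq_len(m))
  d
}
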