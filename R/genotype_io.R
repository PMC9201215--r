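# Genotype and sample-table containers plus VCF/TSV readers and writers.
# Dosages count copies of the ALT allele as given in the input file; the
# package never re-orients alleles by frequency, so odds-ratio directions
# are always relative to the declared ALT allele.

#' SNP annotation table
#'
#' Builds and validates the per-SNP annotation used by a [genotype_matrix()]:
#' identifier, gene symbol and the ref/alt allele pair that orients the
#' dosage coding.
#'
#' @param snp_id character vector of unique, non-empty SNP identifiers.
#' @param gene gene symbol per SNP (free-form; recycled if length 1).
#' @param ref_allele,alt_allele single-character alleles; may be `NA` when
#'   unknown (e.g. plain dosage TSV input), but where both are present they
#'   must differ.
#' @return data.frame with columns `snp_id`, `gene`, `ref_allele`,
#'   `alt_allele`.
#' @export
snp_info <- function(snp_id, gene = NA_character_,
                     ref_allele = NA_character_, alt_allele = NA_character_) {
  snp_id <- as.character(snp_id)
  if (any(is.na(snp_id) | snp_id == ""))
    stop("snp_id must be non-empty", call. = FALSE)
  if (anyDuplicated(snp_id))
    stop("duplicated snp_id: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    snp_id = snp_id,
    gene = rep_len(as.character(gene), length(snp_id)),
    ref_allele = rep_len(as.character(ref_allele), length(snp_id)),
    alt_allele = rep_len(as.character(alt_allele), length(snp_id)),
    stringsAsFactors = FALSE
  )
  both <- !is.na(out$ref_allele) & !is.na(out$alt_allele)
  if (any(both & out$ref_allele == out$alt_allele))
    stop("ref_allele must differ from alt_allele", call. = FALSE)
  out
}

#' Genotype matrix container
#'
#' A subjects-by-SNPs matrix of alt-allele dosages (0, 1, 2 or `NA` for a
#' missing call) together with its SNP annotation. This is the raw input to
#' every scan.
#'
#' @param dosages integer matrix, subjects in rows, SNPs in columns; row
#'   names are subject identifiers, column names SNP identifiers.
#' @param snps optional [snp_info()] table matching the columns; built from
#'   the column names when omitted.
#' @return object of class `genotype_matrix` with elements `dosages`,
#'   `snps`, `subjects`.
#' @export
genotype_matrix <- function(dosages, snps = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(rownames(dosages)))
    stop("dosage matrix needs subject identifiers as row names", call. = FALSE)
  if (is.null(colnames(dosages)))
    stop("dosage matrix needs SNP identifiers as column names", call. = FALSE)
  if (anyDuplicated(rownames(dosages)))
    stop("duplicated subject identifiers", call. = FALSE)
  if (is.null(snps)) snps <- snp_info(colnames(dosages))
  if (!identical(snps$snp_id, colnames(dosages)))
    stop("snp annotation does not match dosage columns", call. = FALSE)
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage %s at subject '%s', SNP '%s' (must be 0/1/2/NA)",
                 dosages[bad][1], rownames(dosages)[idx[1]],
                 colnames(dosages)[idx[2]]), call. = FALSE)
  }
  structure(list(dosages = dosages, snps = snps,
                 subjects = rownames(dosages)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  genes <- unique(x$snps$gene[!is.na(x$snps$gene)])
  if (length(genes)) cat("genes:", paste(genes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# single-GT string -> dosage; "." anywhere in the call -> NA
.gt_to_dosage <- function(gt) {
  gt[is.na(gt)] <- "."
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(al) {
    if (any(al == "." | al == "")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(al))
    if (anyNA(ai) || any(ai > 1L))
      return(NA_integer_)  # non-biallelic call; caller filters records
    sum(ai)
  }, integer(1))
}

#' Read genotypes from a VCF file
#'
#' Reads GT calls from a VCF into a [genotype_matrix()] of alt-allele
#' dosages. Phased (`|`) and unphased (`/`) separators are treated
#' identically; any call containing `.` becomes a missing dosage.
#' Multi-allelic records are skipped with a warning by default (the
#' surfactant-protein study panel is strictly biallelic).
#'
#' @param path VCF file (plain text or bgzipped).
#' @param multiallelic `"skip"` (default, with a warning) or `"error"`.
#' @param gene_map optional named character vector mapping SNP ids to gene
#'   symbols for the annotation table.
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path, multiallelic = c("skip", "error"), gene_map = NULL) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("VCF parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  id <- unname(fix[, "ID"])
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multi-allelic records: ", paste(id[multi], collapse = ", "),
           call. = FALSE)
    warning(sum(multi), " multi-allelic record(s) skipped: ",
            paste(id[multi], collapse = ", "), call. = FALSE)
  }
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in VCF", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  samples <- colnames(gt)
  if (anyDuplicated(samples))
    stop("duplicated sample names in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  gt <- gt[keep, , drop = FALSE]
  dos <- apply(gt, 2, .gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = sum(keep),
                                       dimnames = list(NULL, samples))
  dos <- t(dos)  # subjects x snps
  colnames(dos) <- id[keep]
  rownames(dos) <- samples
  genes <- if (is.null(gene_map)) NA_character_ else
    unname(gene_map[id[keep]])
  genotype_matrix(dos, snp_info(id[keep], gene = genes,
                                ref_allele = unname(fix[keep, "REF"]),
                                alt_allele = unname(fix[keep, "ALT"])))
}

#' Read genotypes from a dosage TSV
#'
#' Tab-separated dialect: optional leading `#` comment lines, then a header
#' row `subject_id` followed by SNP ids, then one row per subject with cells
#' in `{0, 1, 2, NA}`. SNP annotation (gene, ref/alt alleles) may be carried
#' in structured `#snp` comment lines, which [write_tsv_genotypes()] emits;
#' the two functions round-trip bit-exactly.
#'
#' @param path TSV file.
#' @param snps optional [snp_info()] annotation for the panel; overrides any
#'   `#snp` annotation lines in the file.
#' @return a `genotype_matrix`.
#' @export
read_tsv_genotypes <- function(path, snps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(snps)) {
    ann <- grep("^#snp\t", readLines(path, n = 1000), value = TRUE)
    if (length(ann)) {
      parts <- do.call(rbind, strsplit(ann, "\t", fixed = TRUE))
      na_if <- function(x) ifelse(x == MISSING_TOKEN, NA_character_, x)
      snps <- snp_info(parts[, 2], gene = na_if(parts[, 3]),
                       ref_allele = na_if(parts[, 4]),
                       alt_allele = na_if(parts[, 5]))
    }
  }
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", check.names = FALSE,
                   na.strings = character(0))
  if (ncol(df) < 2 || names(df)[1] != "subject_id")
    stop("genotype TSV must start with a 'subject_id' column", call. = FALSE)
  subj <- df[[1]]
  if (anyDuplicated(subj))
    stop("duplicated subject_id: ",
         paste(unique(subj[duplicated(subj)]), collapse = ", "), call. = FALSE)
  cells <- as.matrix(df[, -1, drop = FALSE])
  ok <- matrix(cells %in% c("0", "1", "2", MISSING_TOKEN), nrow = nrow(cells))
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype cell '%s' at row %d (subject '%s'), column '%s'",
                 cells[!ok][1], idx[1], subj[idx[1]],
                 colnames(cells)[idx[2]]), call. = FALSE)
  }
  dos <- suppressWarnings(matrix(as.integer(cells), nrow = nrow(cells),
                                 dimnames = list(subj, colnames(cells))))
  genotype_matrix(dos, snps)
}

#' Write genotypes as a dosage TSV
#'
#' SNP annotation (gene, ref/alt alleles), where present, is written as
#' `#snp` comment lines so that [read_tsv_genotypes()] can restore it.
#'
#' @param G a `genotype_matrix`.
#' @param path output file.
#' @param provenance optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_genotypes <- function(G, path, provenance = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  has_ann <- !is.na(G$snps$gene) | !is.na(G$snps$ref_allele) |
    !is.na(G$snps$alt_allele)
  if (any(has_ann)) {
    na_tok <- function(x) ifelse(is.na(x), MISSING_TOKEN, x)
    writeLines(sprintf("#snp\t%s\t%s\t%s\t%s", G$snps$snp_id,
                       na_tok(G$snps$gene), na_tok(G$snps$ref_allele),
                       na_tok(G$snps$alt_allele)), con)
  }
  writeLines(paste(c("subject_id", G$snps$snp_id), collapse = "\t"), con)
  body <- apply(G$dosages, 1, function(r)
    paste(ifelse(is.na(r), MISSING_TOKEN, r), collapse = "\t"))
  writeLines(paste(G$subjects, body, sep = "\t"), con)
  invisible(path)
}

.STATUS_LEVELS <- c("case", "control")
.SEX_LEVELS <- c("male", "female")
.SMOKING_LEVELS <- c("smoker", "nonsmoker")

#' Sample table construction and validation
#'
#' Checks the closed vocabularies (`status`: case/control, `sex`:
#' male/female, `smoking`: smoker/nonsmoker) and subject uniqueness.
#' Missing covariates are permitted and flagged in a `complete_covariates`
#' column; such subjects are dropped from stratified tests with a logged
#' count.
#'
#' @param df data.frame with columns `subject_id`, `status`, `sex`,
#'   `smoking`.
#' @return validated data.frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  need <- c("subject_id", "status", "sex", "smoking")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[need]
  for (col in need) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  check_vocab <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad))
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                   paste(unique(x[bad]), collapse = ", "),
                   paste(levels, collapse = "/")), call. = FALSE)
  }
  check_vocab(df$status, .STATUS_LEVELS, "status")
  check_vocab(df$sex, .SEX_LEVELS, "sex")
  check_vocab(df$smoking, .SMOKING_LEVELS, "smoking")
  if (anyNA(df$status))
    stop("status may not be missing", call. = FALSE)
  df$complete_covariates <- !is.na(df$sex) & !is.na(df$smoking)
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from TSV
#'
#' @param path TSV file with columns `subject_id`, `status`, `sex`,
#'   `smoking` (leading `#` comment lines allowed).
#' @return a `sample_table`; the number of subjects with incomplete
#'   covariates is reported via `message()`.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   colClasses = "character", na.strings = MISSING_TOKEN,
                   check.names = FALSE)
  st <- sample_table(df)
  n_inc <- sum(!st$complete_covariates)
  if (n_inc > 0)
    message(n_inc, " subject(s) with incomplete covariates; ",
            "they are excluded from stratified tests")
  st
}

#' Write a sample table as TSV
#'
#' @param samples a `sample_table`.
#' @param path output file.
#' @param provenance optional `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  df <- samples[c("subject_id", "status", "sex", "smoking")]
  writeLines(paste(names(df), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(df, function(x)
    ifelse(is.na(x), MISSING_TOKEN, x)), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}
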