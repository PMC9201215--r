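# Run orchestration and tabular reporting: provenance-stamped TSV output,
# a run manifest, and an end-to-end pipeline driver that chains the
# simulator / readers, pattern scans, haplotype scan and text summary.

#' Run manifest
#'
#' Stable provenance record embedded as `#` header lines in every output
#' file: tool, package version, seed and a digest of the configuration.
#' Reruns with an identical manifest produce byte-identical outputs, so
#' volatile fields (timestamps, paths) are deliberately excluded.
#'
#' @param command short command description (e.g. `"scan --order 3"`).
#' @param seed integer seed of the run (or `NA`).
#' @param config any R object describing the run configuration.
#' @return named character vector of class `run_manifest`.
#' @export
run_manifest <- function(command, seed = NA_integer_, config = NULL) {
  digest <- if (is.null(config)) "none" else
    sprintf("%08x",
            sum(utf8ToInt(paste(deparse(config), collapse = ""))) %%
              .Machine$integer.max)
  structure(c(tool = "epipattern",
              version = as.character(packageVersion("epipattern")),
              command = command,
              seed = as.character(seed),
              config_digest = digest),
            class = "run_manifest")
}

#' Write a results table with provenance header
#'
#' @param df data.frame.
#' @param path output file.
#' @param manifest optional [run_manifest()] written as `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path, manifest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest))
    writeLines(sprintf("# %s: %s", names(manifest), manifest), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = MISSING_TOKEN)
  invisible(path)
}

#' Read a results table written by [write_results_tsv()]
#'
#' @param path TSV file with optional `#` header lines.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             na.strings = MISSING_TOKEN, stringsAsFactors = FALSE)
}

#' Plain-text summary of a pattern scan
#'
#' Renders the [summary.epi_scan()] bookkeeping (risk/protective split,
#' pattern composition, intragenic and gene-class counts) as a character
#' vector suitable for writing to a report file.
#'
#' @param scan an `epi_scan`.
#' @return character vector of report lines.
#' @export
scan_report_lines <- function(scan) {
  s <- summary(scan)
  lines <- c(
    sprintf("order-%d scan: %d hypotheses tested", s$order, s$n_tests),
    sprintf("reported (p < %g): %d; FDR-significant (q <= %g): %d",
            scan$alpha, s$n_reported, scan$fdr, s$n_fdr_significant),
    sprintf("direction: %d risk, %d protective",
            s$by_direction["risk"], s$by_direction["protective"]),
    sprintf("intragenic interactions: %d", s$intragenic))
  if (s$n_reported > 0) {
    lines <- c(lines, "pattern composition:",
               sprintf("  %s: %d", names(s$by_pattern),
                       as.integer(s$by_pattern)),
               "gene-class composition:",
               sprintf("  %s: %d", names(s$by_gene_class),
                       as.integer(s$by_gene_class)),
               sprintf("OR range: %.3g-%.3g", s$or_range[1], s$or_range[2]),
               sprintf("p range: %.3g-%.3g", s$p_range[1], s$p_range[2]))
  }
  lines
}

#' Run the full analysis pipeline
#'
#' Chains the stages of a run: obtain a cohort (simulate, or read genotype
#' and sample files), run the requested scan orders, optionally the
#' haplotype scan, and write all outputs as provenance-stamped TSVs plus a
#' text summary.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{sim}{a [sim_config()] to simulate, \emph{or}}
#'     \item{genotypes, samples}{paths to input files (`genotype_format`
#'       is `"tsv"` (default) or `"vcf"`).}
#'     \item{orders}{integer vector of scan orders (default `c(1, 2, 3)`).}
#'     \item{haplotype}{run the haplotype scan (default `TRUE` when allele
#'       annotation is available).}
#'     \item{alpha, fdr, continuity}{analysis settings, see [epi_scan()].}
#'   }
#' @param out_dir output directory (created if needed).
#' @param seed seed for any simulation stage.
#' @return invisibly, a list with the scan objects, output paths and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- run_manifest("run_pipeline", seed = seed, config = config)
  if (!is.null(config$sim)) {
    sim <- simulate_cohort(config$sim, seed = seed)
    G <- sim$genotypes; S <- sim$samples
    write_tsv_genotypes(G, file.path(out_dir, "genotypes.tsv"),
                        provenance = sprintf("%s: %s", names(manifest),
                                             manifest))
    write_samples(S, file.path(out_dir, "samples.tsv"),
                  provenance = sprintf("%s: %s", names(manifest), manifest))
  } else {
    fmt <- config$genotype_format %||% "tsv"
    G <- if (fmt == "vcf") read_vcf(config$genotypes)
         else read_tsv_genotypes(config$genotypes)
    S <- read_samples(config$samples)
  }
  orders <- config$orders %||% c(1, 2, 3)
  alpha <- config$alpha %||% 0.05
  fdr <- config$fdr %||% 0.05
  continuity <- config$continuity %||% TRUE
  scans <- list()
  paths <- character(0)
  report <- character(0)
  for (k in orders) {
    sc <- epi_scan(G, S, order = k, alpha = alpha, fdr = fdr,
                   continuity = continuity)
    scans[[as.character(k)]] <- sc
    p <- file.path(out_dir, sprintf("scan_order%d.tsv", k))
    write_results_tsv(sc$results, p, manifest)
    paths <- c(paths, p)
    if (k >= 2) {
      fs <- snp_frequency_summary(sc)
      pf <- file.path(out_dir, sprintf("snp_frequency_order%d.tsv", k))
      write_results_tsv(fs, pf, manifest)
      paths <- c(paths, pf)
    }
    report <- c(report, scan_report_lines(sc), "")
  }
  hap <- NULL
  do_hap <- config$haplotype %||% !all(is.na(G$snps$ref_allele))
  if (isTRUE(do_hap) && length(.adjacent_pairs(G$snps))) {
    hap <- haplotype_scan(G, S, fdr = fdr, continuity = continuity)
    ph <- file.path(out_dir, "haplotypes.tsv")
    write_results_tsv(hap$results, ph, manifest)
    paths <- c(paths, ph)
    report <- c(report,
                sprintf("haplotype scan: %d pairs, %d tests, %d FDR-significant",
                        length(hap$pairs), nrow(hap$results),
                        sum(hap$results$fdr_significant, na.rm = TRUE)))
  }
  rp <- file.path(out_dir, "summary.txt")
  writeLines(c(sprintf("# %s: %s", names(manifest), manifest), report), rp)
  paths <- c(paths, rp)
  invisible(list(scans = scans, haplotype = hap, paths = paths,
                 manifest = manifest))
}
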