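# Additive / dominant / recessive binary contrasts and their conjunction
# into multi-SNP effect-pattern exposures.
#
# Each component binarizes a SNP's genotype for a 2x2 table:
#   a  -- homozygote contrast: include dosages {0, 2}, exposed iff 2
#   d  -- heterozygote deviation: include all, exposed iff dosage 1
#   r  -- recessive: include all, exposed iff dosage 2
# A missing dosage excludes the subject under every component. The dominant
# component is the heterozygote-deviation indicator by default (the d x d
# exemplar group is the double heterozygote); a carrier coding (dosage >= 1)
# is available for sensitivity analysis.

EFFECT_COMPONENTS <- c("a", "d", "r")

#' Binary contrast coding of one SNP
#'
#' Converts an alt-allele dosage vector into the inclusion mask and exposure
#' indicator of a single effect component.
#'
#' @param dosages integer vector with values 0/1/2 or `NA`.
#' @param component `"a"` (additive homozygote contrast), `"d"`
#'   (dominant) or `"r"` (recessive).
#' @param dominant_coding for `component = "d"`: `"deviation"` (exposed iff
#'   heterozygote, the default) or `"carrier"` (exposed iff dosage >= 1).
#' @return list with logical `include` and integer `indicator` (`NA` where
#'   excluded).
#' @export
code_component <- function(dosages, component,
                           dominant_coding = c("deviation", "carrier")) {
  component <- match.arg(component, EFFECT_COMPONENTS)
  dominant_coding <- match.arg(dominant_coding)
  dosages <- as.integer(dosages)
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad))
    stop("dosage values must be 0/1/2/NA; saw ",
         paste(unique(dosages[bad]), collapse = ", "), call. = FALSE)
  nonmiss <- !is.na(dosages)
  include <- switch(component,
    a = nonmiss & dosages != 1L,
    d = nonmiss,
    r = nonmiss)
  indicator <- switch(component,
    a = as.integer(dosages == 2L),
    d = if (dominant_coding == "deviation") as.integer(dosages == 1L)
        else as.integer(dosages >= 1L),
    r = as.integer(dosages == 2L))
  indicator[!include] <- NA_integer_
  list(include = include, indicator = indicator)
}

#' Effect-pattern labels
#'
#' `effect_patterns(k)` enumerates all `3^k` component assignments for a
#' k-SNP tuple as labels like `"dxdxa"`; `pattern_components()` parses a
#' label back into its component vector.
#'
#' @param k tuple length (1, 2 or 3).
#' @return character vector of pattern labels, in lexicographic component
#'   order (`a` < `d` < `r`).
#' @export
effect_patterns <- function(k) {
  stopifnot(k %in% 1:3)
  g <- do.call(expand.grid, c(rep(list(EFFECT_COMPONENTS), k),
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE))
  sort(apply(as.matrix(g), 1, paste, collapse = "x"))
}

#' @rdname effect_patterns
#' @param label pattern label such as `"dxa"`.
#' @export
pattern_components <- function(label) {
  comps <- strsplit(tolower(label), "x", fixed = TRUE)[[1]]
  if (!length(comps) || !all(comps %in% EFFECT_COMPONENTS))
    stop("malformed pattern label: '", label, "'", call. = FALSE)
  comps
}

#' Multi-SNP pattern exposure
#'
#' Applies an effect pattern to a SNP tuple: a subject is *included* when
#' every component's inclusion rule holds at its SNP (and no tuple genotype
#' is missing), and *exposed* when additionally every component indicator is
#' simultaneously on (conjunction rule). The unexposed group is the pooled
#' set of included, non-exposed subjects.
#'
#' @param G a [genotype_matrix()].
#' @param snp_ids ordered SNP identifier tuple, all present in `G`.
#' @param pattern a pattern label (e.g. `"dxdxa"`) of the same length.
#' @param dominant_coding passed to [code_component()].
#' @return object of class `pattern_exposure`: list with `snp_ids`,
#'   `pattern`, logical `included`, logical `exposed` (`NA` where not
#'   included) and the subject identifiers.
#' @export
build_pattern_exposure <- function(G, snp_ids, pattern,
                                   dominant_coding = c("deviation", "carrier")) {
  stopifnot(inherits(G, "genotype_matrix"))
  dominant_coding <- match.arg(dominant_coding)
  comps <- pattern_components(pattern)
  if (length(comps) != length(snp_ids))
    stop("pattern length ", length(comps), " does not match tuple length ",
         length(snp_ids), call. = FALSE)
  unknown <- setdiff(snp_ids, G$snps$snp_id)
  if (length(unknown))
    stop("unknown SNP id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- nrow(G$dosages)
  included <- rep(TRUE, n)
  exposed <- rep(TRUE, n)
  for (j in seq_along(snp_ids)) {
    cc <- code_component(G$dosages[, snp_ids[j]], comps[j],
                         dominant_coding = dominant_coding)
    included <- included & cc$include
    exposed <- exposed & !is.na(cc$indicator) & cc$indicator == 1L
  }
  exposed[!included] <- NA
  structure(list(snp_ids = snp_ids, pattern = paste(comps, collapse = "x"),
                 included = included, exposed = exposed,
                 subjects = G$subjects),
            class = "pattern_exposure")
}

#' @export
print.pattern_exposure <- function(x, ...) {
  cat(sprintf("pattern_exposure %s on (%s): %d included, %d exposed\n",
              x$pattern, paste(x$snp_ids, collapse = ", "),
              sum(x$included), sum(x$exposed, na.rm = TRUE)))
  invisible(x)
}
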