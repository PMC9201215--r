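# Cross-disease comparison of scan outputs: two diseases scanned against a
# shared control group are matched on canonical SNP sets and classified by
# whether they share effect patterns and odds-ratio directions.

#' Canonical form of a SNP tuple and pattern
#'
#' Sorts the SNP identifiers lexicographically and permutes the pattern
#' components in lockstep, so that `"dxa"` on `(s2, s1)` and `"axd"` on
#' `(s1, s2)` yield the same key. Idempotent.
#'
#' @param snp_ids character vector of SNP ids (or a single comma-joined
#'   string).
#' @param pattern pattern label of matching length.
#' @return list with `snp_ids` (sorted), `pattern` (permuted label) and
#'   `key` (a single string).
#' @export
canonicalize <- function(snp_ids, pattern) {
  if (length(snp_ids) == 1 && grepl(",", snp_ids, fixed = TRUE))
    snp_ids <- strsplit(snp_ids, ",", fixed = TRUE)[[1]]
  comps <- pattern_components(pattern)
  if (length(comps) != length(snp_ids))
    stop("pattern length does not match tuple length", call. = FALSE)
  ord <- base::order(snp_ids)
  ids <- snp_ids[ord]
  lab <- paste(comps[ord], collapse = "x")
  list(snp_ids = ids, pattern = lab,
       key = paste(paste(ids, collapse = ","), lab, sep = "|"))
}

.canon_df <- function(results) {
  if (!nrow(results))
    return(data.frame(snp_set = character(0), pattern = character(0),
                      or = numeric(0), stringsAsFactors = FALSE))
  can <- lapply(seq_len(nrow(results)), function(i)
    canonicalize(results$snp_ids[i], results$pattern[i]))
  data.frame(
    snp_set = vapply(can, function(x) paste(x$snp_ids, collapse = ","),
                     character(1)),
    pattern = vapply(can, function(x) x$pattern, character(1)),
    or = results$or_mh,
    stringsAsFactors = FALSE)
}

#' Compare significant interactions between two diseases
#'
#' Takes the significant results of two scans of the same order and SNP
#' panel (e.g. two diseases against a shared control group), matches
#' interactions on canonical SNP sets, and classifies each set:
#' \describe{
#'   \item{unique_a / unique_b}{significant in only one disease.}
#'   \item{same_pattern_concordant}{at least one shared effect pattern,
#'     all shared patterns with odds ratios on the same side of 1.}
#'   \item{same_pattern_discordant}{a shared effect pattern whose odds
#'     ratios fall on opposite sides of 1 (risk in one disease,
#'     protective in the other).}
#'   \item{different_pattern}{significant in both diseases but under
#'     disjoint effect patterns.}
#' }
#' A SNP set significant under several patterns yields one record carrying
#' all of them (`;`-joined).
#'
#' @param a,b `epi_scan` objects, or data.frames with `snp_ids`, `pattern`,
#'   `or_mh` columns.
#' @param labels length-2 character vector naming the two analyses.
#' @return object of class `epi_comparison`: a data.frame with columns
#'   `snp_set`, `category`, `patterns_a`, `ors_a`, `directions_a`,
#'   `patterns_b`, `ors_b`, `directions_b`.
#' @export
compare_scans <- function(a, b, labels = c("A", "B")) {
  get_res <- function(x) if (inherits(x, "epi_scan")) x$results else x
  ra <- get_res(a); rb <- get_res(b)
  if (inherits(a, "epi_scan") && inherits(b, "epi_scan") &&
      a$order != b$order)
    stop("cannot compare scans of different orders (", a$order, " vs ",
         b$order, ")", call. = FALSE)
  ka <- .canon_df(ra); kb <- .canon_df(rb)
  sets <- sort(unique(c(ka$snp_set, kb$snp_set)))
  dirs <- function(or) ifelse(is.na(or), NA_character_,
                              ifelse(or > 1, "risk",
                                     ifelse(or < 1, "protective", "none")))
  rows <- lapply(sets, function(s) {
    ea <- ka[ka$snp_set == s, , drop = FALSE]
    eb <- kb[kb$snp_set == s, , drop = FALSE]
    category <- if (!nrow(eb)) "unique_a" else if (!nrow(ea)) "unique_b"
    else {
      shared <- intersect(ea$pattern, eb$pattern)
      if (!length(shared)) "different_pattern" else {
        discordant <- any(vapply(shared, function(pt) {
          oa <- ea$or[ea$pattern == pt]
          ob <- eb$or[eb$pattern == pt]
          any(outer(oa, ob, function(x, y)
            (x > 1 & y < 1) | (x < 1 & y > 1)))
        }, logical(1)))
        if (discordant) "same_pattern_discordant"
        else "same_pattern_concordant"
      }
    }
    data.frame(
      snp_set = s, category = category,
      patterns_a = paste(ea$pattern, collapse = ";"),
      ors_a = paste(signif(ea$or, 4), collapse = ";"),
      directions_a = paste(dirs(ea$or), collapse = ";"),
      patterns_b = paste(eb$pattern, collapse = ";"),
      ors_b = paste(signif(eb$or, 4), collapse = ";"),
      directions_b = paste(dirs(eb$or), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(snp_set = character(0), category = character(0),
               patterns_a = character(0), ors_a = character(0),
               directions_a = character(0), patterns_b = character(0),
               ors_b = character(0), directions_b = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  class(out) <- c("epi_comparison", "data.frame")
  out
}

#' @export
print.epi_comparison <- function(x, ...) {
  labs <- attr(x, "labels") %||% c("A", "B")
  cat(sprintf("epi_comparison (%s vs %s): %d SNP sets\n",
              labs[1], labs[2], nrow(x)))
  print(table(x$category))
  invisible(x)
}

#' Single-SNP cross-disease table
#'
#' For two order-1 scans, lists each SNP significant in either disease with
#' its direction of effect in each: the textual equivalent of a shared /
#' unique-SNP Venn classification with direction arrows.
#'
#' @param a,b order-1 `epi_scan` objects (or results data.frames).
#' @param labels names for the two analyses.
#' @return data.frame with columns `snp_id`, `shared`, `direction_a`,
#'   `direction_b`.
#' @export
single_snp_comparison <- function(a, b, labels = c("A", "B")) {
  get_res <- function(x) if (inherits(x, "epi_scan")) x$results else x
  ra <- get_res(a); rb <- get_res(b)
  dir_of <- function(r, id) {
    d <- unique(r$direction[r$snp_ids == id])
    if (!length(d)) NA_character_ else paste(d, collapse = ";")
  }
  ids <- sort(unique(c(ra$snp_ids, rb$snp_ids)))
  out <- data.frame(
    snp_id = ids,
    shared = ids %in% ra$snp_ids & ids %in% rb$snp_ids,
    direction_a = vapply(ids, dir_of, character(1), r = ra),
    direction_b = vapply(ids, dir_of, character(1), r = rb),
    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[3:4] <- paste0("direction_", tolower(labels))
  out
}
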