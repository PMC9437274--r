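#' Compare two keyword sets
#'
#' Exact three-way partition of two keyword sets by keyword-id equality:
#' used to contrast the pipeline-derived keywords of a SNP with an external
#' curated list (e.g. condition terms). Both sets must be keyed by the same
#' normalization; pass free-text external terms through
#' [normalizeExternalTerms()] first.
#'
#' @param a,b Character vectors of keyword ids (duplicates ignored).
#' @return An [OverlapResult-class].
#' @examples
#' r <- compareKeywordSets(c("disease:gitelman syndrome", "disease:hypertension"),
#'   "disease:gitelman syndrome")
#' r
#' @export
compareKeywordSets <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  new("OverlapResult",
    onlyA = sort(setdiff(a, b), method = "radix"),
    onlyB = sort(setdiff(b, a), method = "radix"),
    both = sort(intersect(a, b), method = "radix")
  )
}

#' Pool overlap results across SNPs
#'
#' Totals a list of per-SNP [OverlapResult-class]s. With
#' `mode = "per-snp"` (default) counts are summed per SNP, so a concept
#' appearing under two SNPs counts twice -- the per-SNP tallies a pooled
#' set-comparison figure reports. With `mode = "deduplicated"` the three
#' concept sets are unioned across SNPs before counting (a concept counts
#' once; a concept in `both` for any SNP is removed from the only-sets).
#'
#' @param results List of [OverlapResult-class], optionally named by SNP.
#' @param mode `"per-snp"` or `"deduplicated"`.
#' @return List with `only_a_total`, `only_b_total`, `both_total`, `mode`,
#'   and `per_snp` (a `data.frame` with one audit row per input result).
#' @export
pooledOverlap <- function(results, mode = c("per-snp", "deduplicated")) {
  mode <- match.arg(mode)
  snps <- names(results)
  if (is.null(snps)) snps <- as.character(seq_along(results))
  perSnp <- data.frame(
    snp = snps,
    only_a = vapply(results, function(r) length(r@onlyA), 0L),
    only_b = vapply(results, function(r) length(r@onlyB), 0L),
    both = vapply(results, function(r) length(r@both), 0L),
    stringsAsFactors = FALSE
  )
  rownames(perSnp) <- NULL
  if (mode == "per-snp") {
    tot <- list(
      only_a_total = sum(perSnp$only_a),
      only_b_total = sum(perSnp$only_b),
      both_total = sum(perSnp$both)
    )
  } else {
    aAll <- unique(unlist(lapply(results, function(r) c(r@onlyA, r@both))))
    bAll <- unique(unlist(lapply(results, function(r) c(r@onlyB, r@both))))
    both <- intersect(aAll, bAll)
    tot <- list(
      only_a_total = length(setdiff(aAll, both)),
      only_b_total = length(setdiff(bAll, both)),
      both_total = length(both)
    )
  }
  c(tot, list(mode = mode, per_snp = perSnp))
}

#' Normalize external keyword terms
#'
#' Passes free-text external terms (e.g. curated condition names) through
#' the same normalization as corpus mentions, with category `"disease"`, so
#' they are comparable with pipeline keyword ids. Terms carrying no concept
#' identifier are keyed by normal form.
#'
#' @param terms Character vector of terms.
#' @param category Category to assign (default `"disease"`).
#' @return Character vector of kids (one per non-empty term).
#' @export
normalizeExternalTerms <- function(terms, category = "disease") {
  nf <- normalizeTerm(terms)
  nf <- nf[nzchar(nf)]
  unique(paste(category, nf, sep = ":"))
}

#' Read per-SNP external keyword lists
#'
#' Two-column TSV (`snp`, `term`; optional header detected when column 1
#' equals `"snp"`). Terms are normalized with [normalizeExternalTerms()].
#'
#' @param path TSV path.
#' @param category Category assigned to external terms.
#' @return Named list: rsID -> character vector of kids.
#' @export
readExternalKeywords <- function(path, category = "disease") {
  con <- openText(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- if (identical(tolower(parts[[1]][1]), "snp")) 2L else 1L
  out <- list()
  for (i in seq(start, length.out = max(0L, length(parts) - start + 1L))) {
    p <- parts[[i]]
    if (length(p) < 2L) stop(sprintf("row %d: expected 2 tab-separated columns", i))
    rsid <- normalizeRsid(p[1])
    if (is.na(rsid)) stop(sprintf("row %d: malformed rsid '%s'", i, p[1]))
    out[[rsid]] <- c(out[[rsid]], p[2])
  }
  lapply(out, normalizeExternalTerms, category = category)
}

#' Compare an index against external keyword lists
#'
#' For every SNP present in both the index and the external list, compares
#' the SNP's pipeline-derived keywords of the external category (default:
#' diseases only, since curated condition lists carry diseases) with the
#' external set, and pools the totals.
#'
#' @param index An [AssociationIndex-class].
#' @param external Named list rsID -> kids, from [readExternalKeywords()].
#' @param category Restrict index keywords to this category; `NULL` keeps
#'   all categories.
#' @param mode Pooling mode, see [pooledOverlap()].
#' @return As [pooledOverlap()], plus `results` (the per-SNP
#'   [OverlapResult-class] list).
#' @export
compareIndexWithExternal <- function(index, external, category = "disease",
                                     mode = c("per-snp", "deduplicated")) {
  mode <- match.arg(mode)
  snps <- intersect(names(index@profiles), names(external))
  results <- lapply(snps, function(s) {
    p <- index@profiles[[s]]
    kids <- names(p@df)
    if (!is.null(category)) {
      kids <- kids[sub(":.*$", "", kids) == category]
    }
    # external lists are keyed by normal form; compare on normal form for
    # index keywords too, so concept-id keys and text keys meet
    kw <- p@keywords
    nf <- structure(
      paste(kw$category, kw$normal_form, sep = ":"),
      names = kw$kid
    )
    compareKeywordSets(unique(unname(nf[kids])), external[[s]])
  })
  names(results) <- snps
  pooled <- pooledOverlap(results, mode)
  c(pooled, list(results = results))
}
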