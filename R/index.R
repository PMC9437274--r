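INDEX_FORMAT_VERSION <- "1"

# rbind a list of data.frames, ignoring NULL entries; NULL when all are
rbindRows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# One row per retained mention across the corpus: pmid, kid, category,
# ident, normal_form, surface.
corpusKeywordRows <- function(records, synonyms = NULL) {
  rows <- lapply(records, function(r) {
    normalizeMentionTable(r@mentions, rep(r@pmid, nrow(r@mentions)))
  })
  out <- rbindRows(rows)
  if (is.null(out)) out <- normalizeMentionTable(emptyMentions())
  applySynonyms(out, synonyms)
}

keywordMeta <- function(kwRows) {
  first <- !duplicated(kwRows$kid)
  meta <- kwRows[first, c("kid", "category", "ident", "normal_form"),
    drop = FALSE
  ]
  disp <- collectDisplayForms(kwRows$kid, kwRows$surface)
  meta$display_form <- unname(disp[meta$kid])
  meta <- meta[order(meta$kid, method = "radix"), , drop = FALSE]
  rownames(meta) <- NULL
  meta
}

countsFromRows <- function(kwRows, nDocs, countMode) {
  if (countMode == "document") {
    pres <- unique(kwRows[, c("pmid", "kid")])
  } else {
    pres <- kwRows[, c("pmid", "kid")]
  }
  df <- structure(integer(0), names = character(0))
  if (nrow(pres)) {
    tab <- table(pres$kid)
    df <- as.integer(tab)
    names(df) <- names(tab)
    df <- df[order(names(df), method = "radix")]
  }
  # pairs are always document-granular: docs mentioning both keywords
  docPres <- unique(kwRows[, c("pmid", "kid")])
  co <- new.env(parent = emptyenv())
  for (doc in unique(docPres$pmid)) {
    kids <- sort(docPres$kid[docPres$pmid == doc], method = "radix")
    nk <- length(kids)
    if (nk < 2L) next
    for (i in seq_len(nk - 1L)) {
      for (j in seq(i + 1L, nk)) {
        key <- paste(kids[i], kids[j], sep = "\r")
        co[[key]] <- get0(key, envir = co, ifnotfound = 0L) + 1L
      }
    }
  }
  keys <- sort(ls(co), method = "radix")
  coDf <- data.frame(
    kid1 = character(0), kid2 = character(0), co = integer(0),
    stringsAsFactors = FALSE
  )
  if (length(keys)) {
    sp <- strsplit(keys, "\r", fixed = TRUE)
    coDf <- data.frame(
      kid1 = vapply(sp, `[`, "", 1L),
      kid2 = vapply(sp, `[`, "", 2L),
      co = vapply(keys, function(k) co[[k]], 0L, USE.NAMES = FALSE),
      stringsAsFactors = FALSE
    )
  }
  list(df = df, co = coDf)
}

#' Build the keyword profile of one SNP
#'
#' Computes the SNP's keyword document frequencies (`df`) and pairwise
#' same-document co-occurrence counts (`co`) over the documents of
#' `docIds` that are present in the corpus. Each document contributes its
#' keyword *set*: a keyword mentioned five times in one abstract adds 1 to
#' its `df` (document counting, the default). With
#' `countMode = "mention"`, `df` counts mentions instead, as a sensitivity
#' analysis; pair counts stay document-granular either way.
#'
#' @param snp rsID (any case; normalized to lowercase `rs` form).
#' @param docIds Character vector of pmids in the SNP's literature set.
#' @param records Corpus: a list of [LiteratureRecord-class], as returned
#'   by [readPubtator()].
#' @param countMode `"document"` or `"mention"`.
#' @param synonyms Optional synonym table from [readSynonymTable()].
#' @return A [SnpProfile-class].
#' @examples
#' recs <- readPubtator(c(
#'   "1|t|Cancer and TP53.", "1|a|",
#'   "1\t0\t6\tCancer\tDisease\tMESH:D009369",
#'   "1\t11\t15\tTP53\tGene\t7157"))
#' buildSnpProfile("rs1", "1", recs)
#' @export
buildSnpProfile <- function(snp, docIds, records,
                            countMode = c("document", "mention"),
                            synonyms = NULL) {
  countMode <- match.arg(countMode)
  rsid <- normalizeRsid(snp)
  if (is.na(rsid)) stop(sprintf("malformed rsid '%s'", snp))
  pmids <- vapply(records, pmid, "")
  docs <- intersect(as.character(docIds), pmids)
  if (!length(docs)) {
    stop(sprintf("SNP %s: none of its documents are present in the corpus", rsid))
  }
  kwRows <- corpusKeywordRows(records[match(docs, pmids)], synonyms)
  counts <- countsFromRows(kwRows, length(docs), countMode)
  new("SnpProfile",
    snp = rsid, nDocs = length(docs), df = counts$df, co = counts$co,
    keywords = keywordMeta(kwRows), countMode = countMode
  )
}

rsidNumber <- function(rsid) as.numeric(sub("^rs", "", rsid))

#' Build the corpus-wide association index
#'
#' Builds a [SnpProfile-class] for every variant in `docMap` with a
#' non-empty document intersection with the corpus (variants whose
#' documents are all absent are skipped with a message), then derives the
#' global keyword table with per-keyword SNP counts and the reverse
#' keyword-to-SNP index. Reverse lists are sorted by `df` descending with
#' ties broken by the numeric part of the rsID ascending.
#'
#' @param docMap Named list rsID -> pmids, from [readVariantDocMap()] or
#'   [deriveVariantDocMap()].
#' @inheritParams buildSnpProfile
#' @return An [AssociationIndex-class].
#' @export
buildIndex <- function(docMap, records, countMode = c("document", "mention"),
                       synonyms = NULL) {
  countMode <- match.arg(countMode)
  pmids <- vapply(records, pmid, "")
  profs <- list()
  skipped <- 0L
  for (snp in names(docMap)) {
    docs <- intersect(as.character(docMap[[snp]]), pmids)
    if (!length(docs)) {
      skipped <- skipped + 1L
      next
    }
    profs[[normalizeRsid(snp)]] <- buildSnpProfile(
      snp, docs, records, countMode, synonyms
    )
  }
  if (skipped > 0L) {
    message(sprintf(
      "skipped %d variant(s) with no documents in the corpus", skipped
    ))
  }
  if (!length(profs)) stop("no variant has documents in the corpus; nothing to index")
  profs <- profs[order(rsidNumber(names(profs)))]

  kwAll <- rbindRows(lapply(profs, function(p) p@keywords))
  meta <- kwAll[!duplicated(kwAll$kid), , drop = FALSE]
  meta <- meta[order(meta$kid, method = "radix"), , drop = FALSE]
  rownames(meta) <- NULL

  # reverse index: for each keyword, (snp, df) sorted df desc, rsid asc
  postings <- rbindRows(lapply(profs, function(p) {
    if (!length(p@df)) return(NULL)
    data.frame(
      kid = names(p@df), snp = p@snp, df = unname(p@df),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(postings)) {
    postings <- data.frame(
      kid = character(0), snp = character(0), df = integer(0),
      stringsAsFactors = FALSE
    )
  }
  postings <- postings[
    order(postings$kid, -postings$df, rsidNumber(postings$snp),
      method = "radix"
    ), ,
    drop = FALSE
  ]
  reverse <- split(
    postings[, c("snp", "df")],
    factor(postings$kid, levels = meta$kid)
  )
  reverse <- lapply(reverse, function(d) {
    rownames(d) <- NULL
    d
  })
  meta$snp_count <- as.integer(vapply(reverse[meta$kid], nrow, 0L))

  new("AssociationIndex", profiles = profs, keywords = meta, reverse = reverse)
}

#' Resolve a user-supplied keyword to an index kid
#'
#' Accepts a compound kid (`"disease:MESH:D009369"`), a bare concept
#' identifier, or free text (matched against normal and display forms
#' after [normalizeTerm()]). Errors when the keyword was never observed in
#' the index, or when a bare identifier is ambiguous across categories.
#'
#' @param index An [AssociationIndex-class].
#' @param key Keyword id, identifier or text.
#' @return The matching kid (length-1 character).
#' @export
resolveKeyword <- function(index, key) {
  kw <- index@keywords
  if (key %in% kw$kid) return(key)
  hit <- kw$kid[kw$ident == key]
  if (!length(hit)) {
    nf <- normalizeTerm(key)
    hit <- kw$kid[kw$normal_form == nf | kw$display_form == key]
  }
  if (!length(hit)) {
    stop(sprintf(
      "keyword '%s' was never observed in the index (not filtered out: the index stores every observed keyword)",
      key
    ))
  }
  if (length(hit) > 1L) {
    stop(sprintf(
      "keyword '%s' is ambiguous across categories: %s",
      key, paste(hit, collapse = ", ")
    ))
  }
  hit
}

#' Rank SNPs for a keyword
#'
#' The reverse search: the SNPs whose literature carries the keyword,
#' ranked by document frequency descending (ties: numeric rsID ascending).
#'
#' @inheritParams resolveKeyword
#' @param limit Maximum number of SNPs to return (0 gives an empty table).
#' @return `data.frame` with columns `snp`, `df`.
#' @export
rankSnpsForKeyword <- function(index, key, limit = 10L) {
  if (limit < 0L) stop("limit must be >= 0")
  kid <- resolveKeyword(index, key)
  lst <- index@reverse[[kid]]
  head(lst, n = limit)
}

# Aggregate co-occurrence across all profiles: sum of per-SNP co per pair.
aggregateCo <- function(index) {
  all <- rbindRows(lapply(index@profiles, function(p) p@co))
  if (is.null(all) || !nrow(all)) {
    return(data.frame(
      kid1 = character(0), kid2 = character(0), co = integer(0),
      stringsAsFactors = FALSE
    ))
  }
  agg <- stats::aggregate(co ~ kid1 + kid2, data = all, FUN = sum)
  agg <- agg[order(agg$kid1, agg$kid2, method = "radix"), , drop = FALSE]
  rownames(agg) <- NULL
  agg$co <- as.integer(agg$co)
  agg
}

#' Keywords most related to a keyword
#'
#' For a keyword, sums its same-document co-occurrence with every partner
#' keyword across all SNP profiles, and ranks partners by that total
#' (descending; ties broken by kid ascending).
#'
#' @inheritParams rankSnpsForKeyword
#' @return `data.frame` with columns `kid`, `total_co`.
#' @export
relatedKeywordsForKeyword <- function(index, key, limit = 10L) {
  if (limit < 0L) stop("limit must be >= 0")
  kid <- resolveKeyword(index, key)
  agg <- aggregateCo(index)
  rel <- rbind(
    data.frame(kid = agg$kid2[agg$kid1 == kid],
      total_co = agg$co[agg$kid1 == kid], stringsAsFactors = FALSE),
    data.frame(kid = agg$kid1[agg$kid2 == kid],
      total_co = agg$co[agg$kid2 == kid], stringsAsFactors = FALSE)
  )
  rel <- rel[order(-rel$total_co, rel$kid, method = "radix"), , drop = FALSE]
  rownames(rel) <- NULL
  head(rel, n = limit)
}

#' Persist an association index as a directory of TSV files
#'
#' Writes `keywords.tsv` (kid, category, ident, normal_form, display_form,
#' snp_count), `snps.tsv` (snp, n_docs, count_mode), `profiles.tsv` (snp,
#' kid, df), `pairs.tsv` (snp, kid1, kid2, co), `reverse.tsv` (kid, snp,
#' df) and `meta.json` (format version). Row order is deterministic, so
#' rebuilding from identical inputs gives byte-identical files.
#'
#' @param index An [AssociationIndex-class].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeIndex <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    utils::write.table(d, file.path(dir, f),
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8"
    )
  }
  wt(index@keywords, "keywords.tsv")
  snps <- data.frame(
    snp = names(index@profiles),
    n_docs = vapply(index@profiles, nDocs, 0L),
    count_mode = vapply(index@profiles, function(p) p@countMode, ""),
    stringsAsFactors = FALSE
  )
  rownames(snps) <- NULL
  wt(snps, "snps.tsv")
  profRows <- rbindRows(lapply(index@profiles, function(p) {
    if (!length(p@df)) return(NULL)
    data.frame(snp = p@snp, kid = names(p@df), df = unname(p@df),
      stringsAsFactors = FALSE)
  }))
  if (is.null(profRows)) {
    profRows <- data.frame(snp = character(0), kid = character(0), df = integer(0))
  }
  wt(profRows, "profiles.tsv")
  pairRows <- rbindRows(lapply(index@profiles, function(p) {
    if (!nrow(p@co)) return(NULL)
    cbind(data.frame(snp = p@snp, stringsAsFactors = FALSE), p@co)
  }))
  if (is.null(pairRows)) {
    pairRows <- data.frame(
      snp = character(0), kid1 = character(0), kid2 = character(0),
      co = integer(0)
    )
  }
  wt(pairRows, "pairs.tsv")
  revRows <- rbindRows(lapply(names(index@reverse), function(k) {
    d <- index@reverse[[k]]
    if (!nrow(d)) return(NULL)
    cbind(data.frame(kid = k, stringsAsFactors = FALSE), d)
  }))
  if (is.null(revRows)) {
    revRows <- data.frame(kid = character(0), snp = character(0), df = integer(0))
  }
  wt(revRows, "reverse.tsv")
  jsonlite::write_json(
    list(format_version = INDEX_FORMAT_VERSION),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' Load an association index written by [writeIndex()]
#'
#' @param dir Directory containing the index TSV files.
#' @return An [AssociationIndex-class].
#' @export
readIndex <- function(dir) {
  rt <- function(f, classes) {
    utils::read.delim(file.path(dir, f),
      colClasses = classes,
      stringsAsFactors = FALSE, quote = "", fileEncoding = "UTF-8"
    )
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  if (!identical(meta$format_version, INDEX_FORMAT_VERSION)) {
    stop(sprintf("unsupported index format version '%s'", meta$format_version))
  }
  kw <- rt("keywords.tsv", c(rep("character", 5), "integer"))
  snps <- rt("snps.tsv", c("character", "integer", "character"))
  profRows <- rt("profiles.tsv", c("character", "character", "integer"))
  pairRows <- rt("pairs.tsv", c(rep("character", 3), "integer"))
  revRows <- rt("reverse.tsv", c("character", "character", "integer"))

  kwMetaCols <- kw[, c("kid", "category", "ident", "normal_form", "display_form")]
  profs <- lapply(seq_len(nrow(snps)), function(i) {
    s <- snps$snp[i]
    pr <- profRows[profRows$snp == s, , drop = FALSE]
    df <- structure(pr$df, names = pr$kid)
    df <- df[order(names(df), method = "radix")]
    co <- pairRows[pairRows$snp == s, c("kid1", "kid2", "co"), drop = FALSE]
    rownames(co) <- NULL
    new("SnpProfile",
      snp = s, nDocs = snps$n_docs[i], df = df, co = co,
      keywords = kwMetaCols[kwMetaCols$kid %in% names(df), , drop = FALSE],
      countMode = snps$count_mode[i]
    )
  })
  names(profs) <- snps$snp
  reverse <- split(revRows[, c("snp", "df")], factor(revRows$kid, levels = kw$kid))
  reverse <- lapply(reverse, function(d) {
    rownames(d) <- NULL
    d
  })
  new("AssociationIndex", profiles = profs, keywords = kw, reverse = reverse)
}
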