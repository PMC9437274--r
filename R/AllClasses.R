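#' @import methods
NULL

KEYWORD_CATEGORIES <- c("disease", "gene", "chemical")
MENTION_CATEGORIES <- c(KEYWORD_CATEGORIES, "variant", "other")

emptyMentions <- function() {
  data.frame(
    start = integer(0), end = integer(0), surface = character(0),
    category = character(0), concept_id = character(0),
    stringsAsFactors = FALSE
  )
}

#' LiteratureRecord: one entity-annotated document
#'
#' A single annotated document as it flows through the pipeline: a PubMed
#' identifier, title, abstract, and the entity mentions annotated on the
#' combined text. The combined text is `title + " " + abstract`, and mention
#' offsets are 0-based, end-exclusive character offsets into that string.
#'
#' @slot pmid Document identifier, a non-empty digit string.
#' @slot title Title text.
#' @slot abstract Abstract text (may be empty).
#' @slot mentions A `data.frame` with columns `start`, `end` (integer
#'   offsets), `surface` (text as printed), `category` (one of `"disease"`,
#'   `"gene"`, `"chemical"`, `"variant"`, `"other"`), and `concept_id`
#'   (normalized identifier, `NA` when absent). Rows are kept sorted by
#'   `(start, end)`; overlapping mentions are permitted.
#'
#' @seealso [readPubtator()], [writePubtator()], [combinedText()]
#' @export
setClass("LiteratureRecord",
  representation(
    pmid = "character",
    title = "character",
    abstract = "character",
    mentions = "data.frame"
  ),
  prototype(pmid = "0", title = "", abstract = "", mentions = emptyMentions())
)

setValidity("LiteratureRecord", function(object) {
  msg <- character(0)
  if (length(object@pmid) != 1L || !grepl("^[0-9]+$", object@pmid)) {
    msg <- c(msg, "pmid must be a single non-empty digit string")
  }
  m <- object@mentions
  need <- c("start", "end", "surface", "category", "concept_id")
  if (!all(need %in% names(m))) {
    msg <- c(msg, sprintf(
      "mentions must have columns %s", paste(need, collapse = ", ")
    ))
    return(msg)
  }
  if (nrow(m)) {
    if (any(m$start >= m$end)) {
      msg <- c(msg, "every mention must satisfy start < end")
    }
    if (!all(m$category %in% MENTION_CATEGORIES)) {
      msg <- c(msg, sprintf(
        "mention category must be one of %s",
        paste(MENTION_CATEGORIES, collapse = ", ")
      ))
    }
    o <- order(m$start, m$end)
    if (!identical(o, seq_len(nrow(m)))) {
      msg <- c(msg, "mentions must be sorted by (start, end)")
    }
    textLen <- nchar(paste(object@title, object@abstract), type = "chars")
    if (any(m$start < 0L) || any(m$end > textLen)) {
      msg <- c(msg, "mention spans must lie within title + ' ' + abstract")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LiteratureRecord
#'
#' @param pmid Digit-string document identifier.
#' @param title Title text.
#' @param abstract Abstract text, `""` when absent.
#' @param mentions `data.frame` of mentions (see
#'   [LiteratureRecord-class]); rows are sorted by `(start, end)`
#'   automatically.
#' @return A validated [LiteratureRecord-class] object.
#' @examples
#' LiteratureRecord("1", "A study of cancer.", "",
#'   mentions = data.frame(start = 11L, end = 17L, surface = "cancer",
#'     category = "disease", concept_id = "MESH:D009369"))
#' @export
LiteratureRecord <- function(pmid, title, abstract = "", mentions = emptyMentions()) {
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  mentions$surface <- as.character(mentions$surface)
  mentions$category <- as.character(mentions$category)
  mentions$concept_id <- as.character(mentions$concept_id)
  if (nrow(mentions)) {
    mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
    rownames(mentions) <- NULL
  }
  new("LiteratureRecord",
    pmid = as.character(pmid), title = title, abstract = abstract,
    mentions = mentions
  )
}

#' @describeIn LiteratureRecord-class combined annotation text
#'   (`title + " " + abstract`), the string mention offsets index into.
#' @param record A [LiteratureRecord-class].
#' @export
combinedText <- function(record) paste(record@title, record@abstract)

#' @rdname LiteratureRecord-class
#' @param object,x A `LiteratureRecord`.
#' @export
setMethod("show", "LiteratureRecord", function(object) {
  cat(sprintf(
    "LiteratureRecord pmid=%s | %d mention(s)\n  %s\n",
    object@pmid, nrow(object@mentions),
    substr(object@title, 1, 70)
  ))
})

#' @rdname LiteratureRecord-class
#' @export
pmid <- function(x) x@pmid

#' @rdname LiteratureRecord-class
#' @export
mentions <- function(x) x@mentions

#' SnpProfile: per-SNP keyword counts
#'
#' Document-level keyword statistics for one SNP's literature set. The
#' significance of a keyword--SNP association is its document frequency
#' `df` (number of the SNP's documents mentioning the keyword at least
#' once), and the significance of a keyword pair is `co`, the number of
#' the SNP's documents mentioning both. Keywords are identified by a
#' compound id `kid = "<category>:<ident>"` where `ident` is the concept
#' identifier when available, else the normalized text form.
#'
#' Invariants (document counting mode): `1 <= df[k] <= nDocs` for every
#' keyword, and for every stored pair
#' `max(0, df1 + df2 - nDocs) <= co <= min(df1, df2)`. Pairs are stored
#' sparsely (`co >= 1` only), unordered (`kid1 < kid2`), never self-pairs.
#'
#' @slot snp rsID of the SNP (lowercase `rs` form).
#' @slot nDocs Number of documents in the SNP's literature set present in
#'   the corpus.
#' @slot df Named integer vector of document frequencies, names are kids.
#' @slot co `data.frame` with columns `kid1`, `kid2`, `co`.
#' @slot keywords `data.frame` keyed by `kid` with columns `kid`,
#'   `category`, `ident`, `normal_form`, `display_form`.
#' @slot countMode `"document"` (default) or `"mention"`; in mention mode
#'   `df` counts mentions rather than documents and the `df <= nDocs`
#'   bound does not apply.
#'
#' @seealso [buildSnpProfile()], [buildSnpGraph()]
#' @export
setClass("SnpProfile",
  representation(
    snp = "character", nDocs = "integer", df = "integer",
    co = "data.frame", keywords = "data.frame", countMode = "character"
  ),
  prototype(
    snp = "rs0", nDocs = 1L, df = integer(0),
    co = data.frame(kid1 = character(0), kid2 = character(0), co = integer(0)),
    keywords = data.frame(
      kid = character(0), category = character(0), ident = character(0),
      normal_form = character(0), display_form = character(0)
    ),
    countMode = "document"
  )
)

setValidity("SnpProfile", function(object) {
  msg <- character(0)
  if (!grepl("^rs[0-9]+$", object@snp)) {
    msg <- c(msg, "snp must match ^rs[0-9]+$")
  }
  if (object@nDocs < 1L) msg <- c(msg, "nDocs must be >= 1")
  if (!object@countMode %in% c("document", "mention")) {
    msg <- c(msg, "countMode must be 'document' or 'mention'")
  }
  df <- object@df
  if (length(df)) {
    if (is.null(names(df)) || anyNA(names(df))) {
      msg <- c(msg, "df must be a named vector")
    }
    if (any(df < 1L)) msg <- c(msg, "df values must be >= 1")
    if (object@countMode == "document" && any(df > object@nDocs)) {
      msg <- c(msg, "df must not exceed nDocs in document mode")
    }
  }
  co <- object@co
  if (nrow(co)) {
    if (any(co$kid1 >= co$kid2)) {
      msg <- c(msg, "pairs must be stored with kid1 < kid2 (no self-pairs)")
    }
    if (!all(c(co$kid1, co$kid2) %in% names(df))) {
      msg <- c(msg, "pair endpoints must appear in df")
    }
    if (object@countMode == "document") {
      lo <- pmax(0L, df[co$kid1] + df[co$kid2] - object@nDocs)
      hi <- pmin(df[co$kid1], df[co$kid2])
      if (any(co$co > hi) || any(co$co < lo) || any(co$co < 1L)) {
        msg <- c(msg, "co must satisfy max(0, df1+df2-nDocs) <= co <= min(df1, df2)")
      }
    }
  }
  if (!all(names(df) %in% object@keywords$kid)) {
    msg <- c(msg, "every df keyword must be described in the keywords table")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SnpProfile-class
#' @param object A `SnpProfile`.
#' @export
setMethod("show", "SnpProfile", function(object) {
  cat(sprintf(
    "SnpProfile %s: %d doc(s), %d keyword(s), %d pair(s) [%s counting]\n",
    object@snp, object@nDocs, length(object@df), nrow(object@co),
    object@countMode
  ))
  if (length(object@df)) {
    top <- sort(object@df, decreasing = TRUE)
    top <- top[seq_len(min(5L, length(top)))]
    cat("  top keywords:", paste(sprintf("%s=%d", names(top), top),
      collapse = ", "
    ), "\n")
  }
})

#' @rdname SnpProfile-class
#' @param x A `SnpProfile`.
#' @export
snpDf <- function(x) x@df

#' @rdname SnpProfile-class
#' @export
snpCo <- function(x) x@co

#' @rdname SnpProfile-class
#' @export
nDocs <- function(x) x@nDocs

#' AssociationIndex: corpus-wide SNP-keyword association store
#'
#' Holds every buildable [SnpProfile-class], the global keyword table with
#' per-keyword SNP counts (how many SNPs carry the keyword in their
#' profile), and the reverse keyword-to-SNP index: for each keyword, the
#' SNPs carrying it ranked by document frequency descending, ties broken
#' by the numeric part of the rsID ascending.
#'
#' @slot profiles Named list of [SnpProfile-class], names are rsIDs.
#' @slot keywords `data.frame` with columns `kid`, `category`, `ident`,
#'   `normal_form`, `display_form`, `snp_count`.
#' @slot reverse Named list (names are kids) of `data.frame`s with columns
#'   `snp`, `df`, sorted as above.
#'
#' @seealso [buildIndex()], [rankSnpsForKeyword()], [buildGlobalGraph()]
#' @export
setClass("AssociationIndex",
  representation(
    profiles = "list", keywords = "data.frame", reverse = "list"
  )
)

setValidity("AssociationIndex", function(object) {
  msg <- character(0)
  if (!length(object@profiles)) msg <- c(msg, "index must contain at least one profile")
  if (!all(vapply(object@profiles, is, TRUE, class2 = "SnpProfile"))) {
    msg <- c(msg, "profiles must all be SnpProfile objects")
  }
  kw <- object@keywords
  if (!all(c("kid", "snp_count") %in% names(kw))) {
    msg <- c(msg, "keywords table must carry kid and snp_count")
  } else {
    if (!setequal(names(object@reverse), kw$kid)) {
      msg <- c(msg, "reverse index keys must equal the keyword table kids")
    }
    nrev <- vapply(object@reverse, nrow, 0L)
    if (!identical(unname(nrev[kw$kid]), as.integer(kw$snp_count))) {
      msg <- c(msg, "snp_count must equal the reverse list length for every keyword")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname AssociationIndex-class
#' @param object An `AssociationIndex`.
#' @export
setMethod("show", "AssociationIndex", function(object) {
  cat(sprintf(
    "AssociationIndex: %d SNP profile(s), %d distinct keyword(s)\n",
    length(object@profiles), nrow(object@keywords)
  ))
})

#' @rdname AssociationIndex-class
#' @param x An `AssociationIndex`.
#' @export
profiles <- function(x) x@profiles

#' @rdname AssociationIndex-class
#' @export
keywordTable <- function(x) x@keywords

#' @rdname AssociationIndex-class
#' @export
reverseIndex <- function(x) x@reverse

#' KeywordGraph: weighted, categorized keyword graph
#'
#' The renderable product of the pipeline: keywords as nodes (node weight
#' is the keyword's significance -- per-SNP document frequency or global
#' SNP count) and same-document co-occurrence as edges (edge weight is the
#' co-occurrence count). Weights are raw integers; visual scaling is the
#' renderer's job.
#'
#' @slot nodes `data.frame` with columns `kid`, `category`, `label`,
#'   `weight`.
#' @slot edges `data.frame` with columns `a`, `b`, `weight`; unordered
#'   pairs stored once with `a < b`, no self-loops, endpoints always
#'   present among the nodes.
#' @slot meta List describing provenance: `scope` (`"per-snp"` or
#'   `"global"`) plus the source SNP or filter parameters.
#'
#' @seealso [buildSnpGraph()], [buildGlobalGraph()], [exportGraph()]
#' @export
setClass("KeywordGraph",
  representation(nodes = "data.frame", edges = "data.frame", meta = "list"),
  prototype(
    nodes = data.frame(
      kid = character(0), category = character(0),
      label = character(0), weight = integer(0)
    ),
    edges = data.frame(a = character(0), b = character(0), weight = integer(0)),
    meta = list(scope = "per-snp")
  )
)

setValidity("KeywordGraph", function(object) {
  msg <- character(0)
  n <- object@nodes
  e <- object@edges
  if (!all(c("kid", "category", "label", "weight") %in% names(n))) {
    msg <- c(msg, "nodes need columns kid, category, label, weight")
  }
  if (!all(c("a", "b", "weight") %in% names(e))) {
    msg <- c(msg, "edges need columns a, b, weight")
  }
  if (length(msg)) return(msg)
  if (anyDuplicated(n$kid)) msg <- c(msg, "node kids must be unique")
  if (nrow(e)) {
    if (any(e$a == e$b)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$a > e$b)) msg <- c(msg, "edges must be stored with a < b")
    if (anyDuplicated(paste(e$a, e$b))) {
      msg <- c(msg, "each unordered pair may appear at most once")
    }
    if (!all(c(e$a, e$b) %in% n$kid)) {
      msg <- c(msg, "every edge endpoint must be a listed node")
    }
    if (any(e$weight < 1L)) msg <- c(msg, "edge weights must be >= 1")
  }
  if (nrow(n) && any(n$weight < 1L)) msg <- c(msg, "node weights must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname KeywordGraph-class
#' @param object A `KeywordGraph`.
#' @export
setMethod("show", "KeywordGraph", function(object) {
  cat(sprintf(
    "KeywordGraph [%s]: %d node(s), %d edge(s)\n",
    if (is.null(object@meta$scope)) "?" else object@meta$scope,
    nrow(object@nodes), nrow(object@edges)
  ))
})

#' @rdname KeywordGraph-class
#' @param x A `KeywordGraph`.
#' @export
graphNodes <- function(x) x@nodes

#' @rdname KeywordGraph-class
#' @export
graphEdges <- function(x) x@edges

#' OverlapResult: three-way partition of two keyword sets
#'
#' Result of comparing a pipeline-derived keyword set against an external
#' one (e.g. curated condition terms) for one SNP: keywords only in the
#' first set, only in the second, and in both. The three slots are
#' pairwise disjoint and partition the union.
#'
#' @slot onlyA Character vector of kids present only in set A.
#' @slot onlyB Character vector of kids present only in set B.
#' @slot both Character vector of kids present in both.
#' @seealso [compareKeywordSets()], [pooledOverlap()]
#' @export
setClass("OverlapResult",
  representation(onlyA = "character", onlyB = "character", both = "character")
)

setValidity("OverlapResult", function(object) {
  sets <- list(object@onlyA, object@onlyB, object@both)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      if (length(intersect(sets[[i]], sets[[j]]))) {
        return("onlyA, onlyB and both must be pairwise disjoint")
      }
    }
  }
  TRUE
})

#' @rdname OverlapResult-class
#' @param object An `OverlapResult`.
#' @export
setMethod("show", "OverlapResult", function(object) {
  cat(sprintf(
    "OverlapResult: only A %d | both %d | only B %d\n",
    length(object@onlyA), length(object@both), length(object@onlyB)
  ))
})
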