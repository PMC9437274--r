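# Irregular plural -> singular map for vocabulary common in biomedical
# abstracts; consulted before the suffix rules.
IRREGULAR_SINGULAR <- c(
  analyses = "analysis", diagnoses = "diagnosis", prognoses = "prognosis",
  metastases = "metastasis", neuroses = "neurosis", psychoses = "psychosis",
  stenoses = "stenosis", thromboses = "thrombosis", fibroses = "fibrosis",
  scleroses = "sclerosis", necroses = "necrosis", apoptoses = "apoptosis",
  mitoses = "mitosis", crises = "crisis", hypotheses = "hypothesis",
  bacteria = "bacterium", mitochondria = "mitochondrion", criteria = "criterion",
  phenomena = "phenomenon", carcinomata = "carcinoma",
  women = "woman", men = "man", children = "child", feet = "foot",
  teeth = "tooth", mice = "mouse", fungi = "fungus", nuclei = "nucleus",
  loci = "locus", foci = "focus", genera = "genus", indices = "index",
  vertebrae = "vertebra", larvae = "larva"
)

# Words that look plural but are not (or whose lemma equals the surface).
PLURAL_INVARIANT <- c(
  "diabetes", "measles", "rabies", "herpes", "species", "series", "caries",
  "scabies", "mumps", "pertussis", "lupus", "asbestos", "molasses"
)

#' Singularize an English noun token
#'
#' Lightweight plural-to-singular inflection used for the final token of a
#' keyword phrase: an irregulars dictionary (medical `-ses`/`-sis` plurals,
#' Latin/Greek plurals, common irregular nouns), a plural-invariant list
#' (`diabetes`, `species`, ...), then suffix rules (`studies -> study`,
#' `viruses -> virus`, `branches -> branch`, plain `-s` stripping). Tokens
#' ending in `-ss`, `-us` or `-is` are left unchanged. Idempotent on its
#' own output.
#'
#' @param token Character vector of single tokens.
#' @return Character vector of singular forms.
#' @examples
#' singularize(c("tumors", "studies", "viruses", "diabetes", "metastases"))
#' @export
singularize <- function(token) {
  vapply(token, function(t) {
    low <- tolower(t)
    if (low %in% PLURAL_INVARIANT) return(t)
    if (low %in% names(IRREGULAR_SINGULAR)) {
      out <- IRREGULAR_SINGULAR[[low]]
      # preserve an initial capital ("Analyses" -> "Analysis")
      if (substr(t, 1, 1) == toupper(substr(t, 1, 1)) &&
        grepl("^[A-Z]", t)) {
        substr(out, 1, 1) <- toupper(substr(out, 1, 1))
      }
      return(out)
    }
    nc <- nchar(t)
    if (nc > 4L && grepl("ies$", t)) return(paste0(substr(t, 1, nc - 3L), "y"))
    if (grepl("(ches|shes|sses|xes|zes|uses|oes)$", t)) {
      return(substr(t, 1, nc - 2L))
    }
    if (grepl("(ss|us|is)$", t)) return(t)
    if (nc > 2L && grepl("s$", t) && !grepl("[0-9]s$", t)) {
      return(substr(t, 1, nc - 1L))
    }
    t
  }, "", USE.NAMES = FALSE)
}

isGeneSymbolToken <- function(token) {
  n <- nchar(token)
  n >= 2L & n <= 6L & grepl("^[A-Z0-9-]+$", token) & grepl("[A-Z]", token)
}

#' Normalize raw keyword text
#'
#' Builds the canonical text form of a keyword phrase: (1) whitespace and
#' punctuation trimmed at both ends, (2) each whitespace token case-folded
#' unless it looks like a gene symbol (2--6 characters, all uppercase
#' letters/digits/hyphens with at least one letter -- `BRCA1`, `TP53`,
#' `AD` keep their case), (3) the final token singularized via
#' [singularize()]. Idempotent.
#'
#' @param text Character vector of raw surface forms.
#' @return Character vector of normal forms (`""` for empty input).
#' @examples
#' normalizeTerm(c("Tumors", "Breast Cancers", "BRCA1", "  hypertension. "))
#' @export
normalizeTerm <- function(text) {
  vapply(text, function(s) {
    s <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", s)
    if (!nzchar(s)) return("")
    toks <- strsplit(s, "[[:space:]]+")[[1]]
    toks <- ifelse(isGeneSymbolToken(toks), toks, tolower(toks))
    last <- length(toks)
    if (!isGeneSymbolToken(toks[last])) {
      toks[last] <- singularize(toks[last])
    }
    paste(toks, collapse = " ")
  }, "", USE.NAMES = FALSE)
}

#' Normalize an entity mention into a keyword key
#'
#' Converts one annotated mention into the canonical keyword identity the
#' pipeline counts. Only the three retained categories produce a keyword
#' (`disease`, `gene`, `chemical`); `variant` and `other` mentions return
#' `NULL`. The keyword's `ident` is the concept identifier when present and
#' non-placeholder (not `"-"`, not empty), else the normalized text form;
#' the compound id `kid` is `"<category>:<ident>"`, so two mentions with the
#' same category and concept id merge regardless of surface form.
#'
#' @param surface Surface text of the mention.
#' @param category Mention category string.
#' @param conceptId Concept identifier or `NA`.
#' @return A list with elements `kid`, `category`, `ident`, `normal_form`,
#'   or `NULL` when the category is not retained or the surface normalizes
#'   to the empty string.
#' @examples
#' normalizeMention("Tumors", "disease")
#' normalizeMention("BRCA1", "gene", "672")
#' normalizeMention("rs334", "variant") # NULL
#' @export
normalizeMention <- function(surface, category, conceptId = NA_character_) {
  if (!category %in% KEYWORD_CATEGORIES) return(NULL)
  nf <- normalizeTerm(surface)
  if (!nzchar(nf)) return(NULL)
  id <- conceptId
  if (is.na(id) || !nzchar(trimws(id)) || identical(trimws(id), "-")) id <- nf
  list(
    kid = paste(category, id, sep = ":"),
    category = category, ident = id, normal_form = nf
  )
}

# Vectorized normalization of a mentions data.frame -> keyword rows.
# Returns one row per retained mention: pmid (if given), kid, category,
# ident, normal_form, surface.
normalizeMentionTable <- function(m, pmids = NULL) {
  keep <- m$category %in% KEYWORD_CATEGORIES
  m <- m[keep, , drop = FALSE]
  if (!is.null(pmids)) pmids <- pmids[keep]
  if (!nrow(m)) {
    return(data.frame(
      pmid = character(0), kid = character(0), category = character(0),
      ident = character(0), normal_form = character(0), surface = character(0),
      stringsAsFactors = FALSE
    ))
  }
  nf <- normalizeTerm(m$surface)
  id <- m$concept_id
  bad <- is.na(id) | !nzchar(trimws(id)) | trimws(id) == "-"
  id[bad] <- nf[bad]
  ok <- nzchar(nf)
  data.frame(
    pmid = if (is.null(pmids)) rep(NA_character_, sum(ok)) else pmids[ok],
    kid = paste(m$category[ok], id[ok], sep = ":"),
    category = m$category[ok], ident = id[ok], normal_form = nf[ok],
    surface = m$surface[ok], stringsAsFactors = FALSE
  )
}

#' Choose display forms for keywords
#'
#' The display form of a keyword is its most frequent observed surface
#' form; ties are broken by the lexicographically smallest surface in
#' code-point order (so `"AD"` beats `"ad"` at equal counts).
#'
#' @param kids Character vector of keyword ids (one per observation).
#' @param surfaces Character vector of surface forms, parallel to `kids`.
#' @return Named character vector: kid -> display form.
#' @examples
#' collectDisplayForms(rep("disease:x", 3), c("cancer", "cancer", "Cancer"))
#' @export
collectDisplayForms <- function(kids, surfaces) {
  stopifnot(length(kids) == length(surfaces))
  if (!length(kids)) return(structure(character(0), names = character(0)))
  tab <- as.data.frame(table(kid = kids, surface = surfaces),
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab <- tab[order(tab$kid, -tab$Freq, tab$surface, method = "radix"), ,
    drop = FALSE
  ]
  first <- !duplicated(tab$kid)
  structure(tab$surface[first], names = tab$kid[first])
}

#' Read and apply a user synonym table
#'
#' A synonym table is a two-column TSV (`from_ident`, `to_ident`, optional
#' header) of manual keyword merges applied after normalization: every
#' keyword whose ident equals `from_ident` is re-keyed to `to_ident`
#' within the same category.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `from_ident`, `to_ident`.
#' @export
readSynonymTable <- function(path) {
  tab <- utils::read.delim(path,
    header = FALSE, colClasses = "character",
    col.names = c("from_ident", "to_ident")
  )
  if (nrow(tab) && tolower(tab$from_ident[1]) == "from_ident") {
    tab <- tab[-1, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

applySynonyms <- function(kwRows, synonyms) {
  if (is.null(synonyms) || !nrow(synonyms)) return(kwRows)
  map <- structure(synonyms$to_ident, names = synonyms$from_ident)
  hit <- kwRows$ident %in% names(map)
  kwRows$ident[hit] <- unname(map[kwRows$ident[hit]])
  kwRows$kid[hit] <- paste(kwRows$category[hit], kwRows$ident[hit], sep = ":")
  kwRows
}
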