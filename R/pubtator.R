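#' Default PubTator type-to-category mapping
#'
#' Maps PubTator annotation type strings to the pipeline's mention
#' categories. Types absent from the table fall back to `"other"`. The
#' table is an argument of [readPubtator()] because PubTator type
#' vocabularies drift across versions.
#'
#' @return Named character vector: names are PubTator type strings, values
#'   are mention categories.
#' @export
pubtatorTypeMap <- function() {
  c(
    Disease = "disease",
    Gene = "gene",
    Chemical = "chemical",
    Mutation = "variant",
    DNAMutation = "variant",
    ProteinMutation = "variant",
    SNP = "variant",
    Other = "other"
  )
}

# category -> canonical PubTator type string used on write
categoryTypeMap <- function() {
  c(
    disease = "Disease", gene = "Gene", chemical = "Chemical",
    variant = "Mutation", other = "Other"
  )
}

openText <- function(path) {
  if (inherits(path, "connection")) return(path)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a PubTator-format annotated corpus
#'
#' Parses the PubTator plain-text export format: per document a title line
#' `<pmid>|t|<title>`, an abstract line `<pmid>|a|<abstract>`, then zero or
#' more tab-separated annotation lines
#' `<pmid>\t<start>\t<end>\t<surface>\t<type>\t<concept id>` (the id column
#' may be absent), with documents separated by blank lines. Offsets are
#' 0-based, end-exclusive character offsets into `title + " " + abstract`.
#'
#' Annotation spans are checked against the surface column: on mismatch the
#' surface column is trusted and a warning is issued (annotation sources
#' are inconsistent about the title/abstract separator); `strict = TRUE`
#' turns the warning into an error. Duplicate annotation lines (identical
#' 6-tuples) are collapsed with a message. Duplicate pmids across blocks
#' are an error.
#'
#' @param path File path (gzip accepted by `.gz` extension), connection, or
#'   a character vector of lines (length > 1, or containing newlines).
#' @param typeMap Named character vector mapping PubTator type strings to
#'   categories; see [pubtatorTypeMap()]. Unlisted types become `"other"`.
#' @param strict Logical; if `TRUE`, a span/surface mismatch is an error.
#' @return List of [LiteratureRecord-class] objects, in input order.
#' @examples
#' lines <- c("1|t|A study of cancer.", "1|a|",
#'   "1\t11\t17\tcancer\tDisease\tMESH:D009369")
#' recs <- readPubtator(lines)
#' mentions(recs[[1]])
#' @export
readPubtator <- function(path, typeMap = pubtatorTypeMap(), strict = FALSE) {
  if (is.character(path) && (length(path) != 1L || any(grepl("\n", path)))) {
    # a vector of lines; elements containing newlines are split, blank
    # lines preserved
    lines <- unlist(lapply(path, function(x) {
      if (!grepl("\n", x)) x else strsplit(x, "\n", fixed = TRUE)[[1]]
    }), use.names = FALSE)
    if (is.null(lines)) lines <- character(0)
  } else if (is.character(path) && grepl("\\|t\\|", path)) {
    lines <- path
  } else {
    con <- openText(path)
    on.exit(close(con), add = TRUE)
    lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  }

  records <- list()
  i <- 1L
  n <- length(lines)
  dupAnnotations <- 0L
  while (i <= n) {
    if (!nzchar(lines[i])) {
      i <- i + 1L
      next
    }
    if (!grepl("^[0-9]+\\|t\\|", lines[i])) {
      stop(sprintf("line %d: expected a '<pmid>|t|<title>' header", i))
    }
    blockPmid <- sub("\\|.*$", "", lines[i])
    title <- sub("^[0-9]+\\|t\\|", "", lines[i])
    i <- i + 1L
    abstract <- ""
    if (i <= n && grepl("^[0-9]+\\|a\\|", lines[i])) {
      aPmid <- sub("\\|.*$", "", lines[i])
      if (aPmid != blockPmid) {
        stop(sprintf("line %d: abstract pmid %s does not match block pmid %s",
          i, aPmid, blockPmid))
      }
      abstract <- sub("^[0-9]+\\|a\\|", "", lines[i])
      i <- i + 1L
    }
    ann <- character(0)
    linenos <- integer(0)
    while (i <= n && nzchar(lines[i])) {
      if (grepl("^[0-9]+\\|[ta]\\|", lines[i])) {
        stop(sprintf("line %d: header line inside annotation block of pmid %s",
          i, blockPmid))
      }
      ann <- c(ann, lines[i])
      linenos <- c(linenos, i)
      i <- i + 1L
    }
    m <- emptyMentions()
    if (length(ann)) {
      parts <- strsplit(ann, "\t", fixed = TRUE)
      nc <- lengths(parts)
      bad <- which(!nc %in% c(5L, 6L))
      if (length(bad)) {
        stop(sprintf("line %d: annotation has %d columns, expected 5 or 6",
          linenos[bad[1]], nc[bad[1]]))
      }
      rows <- lapply(seq_along(parts), function(j) {
        p <- parts[[j]]
        if (p[1] != blockPmid) {
          stop(sprintf("line %d: annotation pmid %s does not match block pmid %s",
            linenos[j], p[1], blockPmid))
        }
        if (!grepl("^[0-9]+$", p[2]) || !grepl("^[0-9]+$", p[3])) {
          stop(sprintf("line %d: non-integer offsets '%s', '%s'",
            linenos[j], p[2], p[3]))
        }
        data.frame(
          start = as.integer(p[2]), end = as.integer(p[3]), surface = p[4],
          type = p[5], concept_id = if (length(p) == 6L) p[6] else NA_character_,
          stringsAsFactors = FALSE
        )
      })
      m <- do.call(rbind, rows)
      ndup <- sum(duplicated(m))
      if (ndup > 0L) {
        dupAnnotations <- dupAnnotations + ndup
        m <- m[!duplicated(m), , drop = FALSE]
      }
      m$category <- unname(typeMap[m$type])
      m$category[is.na(m$category)] <- "other"
      m$concept_id[m$concept_id %in% c("-", "")] <- NA_character_
      text <- paste(title, abstract)
      span <- substr(rep(text, nrow(m)), m$start + 1L, m$end)
      mismatch <- span != m$surface
      if (any(mismatch)) {
        note <- sprintf(
          "pmid %s: %d annotation span(s) do not match the surface column; trusting the surface text",
          blockPmid, sum(mismatch)
        )
        if (strict) stop(note) else warning(note, call. = FALSE)
      }
      m <- m[, c("start", "end", "surface", "category", "concept_id")]
    }
    rec <- LiteratureRecord(blockPmid, title, abstract, m)
    if (blockPmid %in% vapply(records, pmid, "")) {
      stop(sprintf("duplicate pmid %s in input", blockPmid))
    }
    records[[length(records) + 1L]] <- rec
  }
  if (dupAnnotations > 0L) {
    message(sprintf("collapsed %d duplicate annotation line(s)", dupAnnotations))
  }
  names(records) <- vapply(records, pmid, "")
  records
}

#' Write records in canonical PubTator format
#'
#' Emits one block per record: the two header lines, annotation lines
#' sorted by `(start, end)` with the canonical type string per category, a
#' single blank line between blocks and a trailing newline. Mentions with
#' no concept id are written as 5-column lines. `readPubtator()` of the
#' output reproduces the records structurally, and rewriting a canonically
#' formatted file is byte-identical.
#'
#' @param records List of [LiteratureRecord-class].
#' @param path Output file path, or `NULL` to return the text invisibly.
#' @return The serialized text, invisibly.
#' @export
writePubtator <- function(records, path = NULL) {
  typeOf <- categoryTypeMap()
  blocks <- vapply(records, function(r) {
    head <- c(
      sprintf("%s|t|%s", r@pmid, r@title),
      sprintf("%s|a|%s", r@pmid, r@abstract)
    )
    m <- r@mentions
    ann <- character(0)
    if (nrow(m)) {
      m <- m[order(m$start, m$end), , drop = FALSE]
      ann <- ifelse(
        is.na(m$concept_id),
        sprintf("%s\t%d\t%d\t%s\t%s", r@pmid, m$start, m$end, m$surface,
          typeOf[m$category]),
        sprintf("%s\t%d\t%d\t%s\t%s\t%s", r@pmid, m$start, m$end, m$surface,
          typeOf[m$category], m$concept_id)
      )
    }
    paste(c(head, ann), collapse = "\n")
  }, "")
  text <- if (length(blocks)) paste0(paste(blocks, collapse = "\n\n"), "\n") else ""
  if (!is.null(path)) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(charToRaw(enc2utf8(text)), con)
  }
  invisible(text)
}

normalizeRsid <- function(x) {
  x <- trimws(x)
  ok <- grepl("^[Rr][Ss][0-9]+$", x)
  x[ok] <- paste0("rs", sub("^[Rr][Ss]", "", x[ok]))
  x[!ok] <- NA_character_
  x
}

#' Read a variant-to-document mapping
#'
#' Reads a two-column TSV (`rsid`, `pmid`) in the style of variant-centric
#' literature services. A header row is detected when the first column of
#' the first row equals `"rsid"`. rsIDs are normalized to lowercase `rs`
#' form; duplicate `(rsid, pmid)` rows collapse to a single membership.
#'
#' @param path File path (gzip by extension) or connection.
#' @return Named list: rsID -> character vector of pmids (sorted, unique).
#' @export
readVariantDocMap <- function(path) {
  con <- openText(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  startRow <- 1L
  if (identical(tolower(parts[[1]][1]), "rsid")) startRow <- 2L
  out <- new.env(parent = emptyenv())
  for (i in seq(startRow, length.out = max(0L, length(parts) - startRow + 1L))) {
    p <- parts[[i]]
    if (length(p) < 2L) stop(sprintf("row %d: expected 2 tab-separated columns", i))
    rsid <- normalizeRsid(p[1])
    if (is.na(rsid)) stop(sprintf("row %d: malformed rsid '%s'", i, p[1]))
    doc <- trimws(p[2])
    if (!grepl("^[0-9]+$", doc)) stop(sprintf("row %d: non-digit pmid '%s'", i, p[2]))
    out[[rsid]] <- c(get0(rsid, envir = out, ifnotfound = character(0)), doc)
  }
  envToSortedList(out)
}

envToSortedList <- function(env) {
  nm <- sort(ls(env), method = "radix")
  res <- lapply(nm, function(k) sort(unique(env[[k]])))
  names(res) <- nm
  res
}

#' Derive the variant-to-document mapping from the corpus itself
#'
#' Scans variant-category mentions: a mention whose concept id (or, failing
#' that, surface text) normalizes to a valid rsID contributes its document
#' to that variant's set. Mentions not normalizable to `rs<digits>` form
#' (e.g. HGVS protein notation) are skipped, with a summary message.
#'
#' @param records List of [LiteratureRecord-class].
#' @return Named list: rsID -> character vector of pmids (sorted, unique).
#' @export
deriveVariantDocMap <- function(records) {
  out <- new.env(parent = emptyenv())
  skipped <- 0L
  for (r in records) {
    m <- r@mentions
    m <- m[m$category == "variant", , drop = FALSE]
    if (!nrow(m)) next
    cand <- ifelse(is.na(m$concept_id), m$surface, m$concept_id)
    rsid <- normalizeRsid(cand)
    skipped <- skipped + sum(is.na(rsid))
    for (v in unique(rsid[!is.na(rsid)])) {
      out[[v]] <- c(get0(v, envir = out, ifnotfound = character(0)), r@pmid)
    }
  }
  if (skipped > 0L) {
    message(sprintf("skipped %d variant mention(s) without an rsID", skipped))
  }
  envToSortedList(out)
}
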