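#' Specification of a synthetic annotated corpus
#'
#' Describes a corpus with known planted structure: a keyword inventory per
#' category, per-SNP literature sets, and for each SNP a planted keyword
#' set with per-keyword inclusion probabilities (association strengths).
#' Every document of a SNP includes each planted keyword independently with
#' its strength, plus background noise keywords whose count per document is
#' Poisson(`noiseRate`), drawn uniformly with replacement from the whole
#' inventory and deduplicated at document level. Keyword surfaces appear
#' with occasional plural/case variants (rate `variantRate`) and may be
#' mentioned twice in a document (probability `dupProb`), so normalization
#' and document-granularity counting are both exercised. All randomness is
#' fixed by `seed`.
#'
#' @param nSnps Number of SNPs.
#' @param docsPerSnp Integer range `c(min, max)` of documents per SNP.
#' @param inventorySizes Named integer vector with entries `disease`,
#'   `gene`, `chemical`.
#' @param plantedPerSnp Planted keywords per SNP (must not exceed the total
#'   inventory).
#' @param strengthRange Range the planted inclusion probabilities are drawn
#'   from (distinct values, so planted rankings are recoverable). Ignored
#'   when `strengths` is given.
#' @param strengths Optional numeric vector of length `plantedPerSnp`: the
#'   exact inclusion probabilities assigned (in order) to every SNP's
#'   planted keywords, instead of drawing them from `strengthRange`. Use
#'   well-separated values (e.g. `c(1, 0.4, 0.1)`) when planted rankings
#'   must be recoverable from finite samples.
#' @param noiseRate Expected noise keywords per document (Poisson rate).
#' @param dupProb Probability a present keyword is mentioned twice.
#' @param variantRate Probability a mention uses a plural/case variant
#'   surface.
#' @param seed Integer seed fixing all randomness.
#' @return A validated `PlantSpec` (a classed list).
#' @export
plantSpec <- function(nSnps = 10L,
                      docsPerSnp = c(8L, 20L),
                      inventorySizes = c(disease = 12L, gene = 8L, chemical = 6L),
                      plantedPerSnp = 3L,
                      strengthRange = c(0.3, 0.95),
                      strengths = NULL,
                      noiseRate = 2,
                      dupProb = 0.1,
                      variantRate = 0.2,
                      seed = 1L) {
  spec <- list(
    nSnps = as.integer(nSnps), docsPerSnp = as.integer(docsPerSnp),
    inventorySizes = inventorySizes, plantedPerSnp = as.integer(plantedPerSnp),
    strengthRange = strengthRange, strengths = strengths,
    noiseRate = noiseRate, dupProb = dupProb,
    variantRate = variantRate, seed = as.integer(seed)
  )
  stopifnot(
    spec$nSnps >= 1L,
    length(spec$docsPerSnp) == 2L, spec$docsPerSnp[1] >= 1L,
    spec$docsPerSnp[1] <= spec$docsPerSnp[2],
    all(c("disease", "gene", "chemical") %in% names(inventorySizes)),
    all(inventorySizes >= 0L), sum(inventorySizes) >= 1L,
    spec$plantedPerSnp >= 0L,
    all(strengthRange >= 0 & strengthRange <= 1),
    is.null(strengths) ||
      (length(strengths) == spec$plantedPerSnp &&
        all(strengths >= 0 & strengths <= 1)),
    noiseRate >= 0, dupProb >= 0 && dupProb <= 1,
    variantRate >= 0 && variantRate <= 1
  )
  if (spec$plantedPerSnp > sum(inventorySizes)) {
    stop("keyword inventory is smaller than the planted set size")
  }
  class(spec) <- "PlantSpec"
  spec
}

# Deterministic keyword inventory: kid, category, ident, surface
syntheticInventory <- function(spec) {
  sz <- spec$inventorySizes
  rows <- list()
  if (sz[["disease"]] > 0L) {
    i <- seq_len(sz[["disease"]])
    rows$disease <- data.frame(
      category = "disease", ident = sprintf("MESH:D%06d", i),
      surface = sprintf("dis%03doma", i), stringsAsFactors = FALSE
    )
  }
  if (sz[["gene"]] > 0L) {
    i <- seq_len(sz[["gene"]])
    rows$gene <- data.frame(
      category = "gene", ident = as.character(9000L + i),
      surface = sprintf("GN%dA", i), stringsAsFactors = FALSE
    )
  }
  if (sz[["chemical"]] > 0L) {
    i <- seq_len(sz[["chemical"]])
    rows$chemical <- data.frame(
      category = "chemical", ident = sprintf("MESH:C%06d", i),
      surface = sprintf("chem%03dol", i), stringsAsFactors = FALSE
    )
  }
  inv <- rbindRows(rows)
  inv$kid <- paste(inv$category, inv$ident, sep = ":")
  inv
}

# RNG prefix shared by generateCorpus() and expectedCounts(): per-SNP
# document counts, planted keyword sets and strengths.
plantAssignments <- function(spec) {
  set.seed(spec$seed, kind = "Mersenne-Twister")
  inv <- syntheticInventory(spec)
  lapply(seq_len(spec$nSnps), function(s) {
    nd <- if (spec$docsPerSnp[1] == spec$docsPerSnp[2]) {
      spec$docsPerSnp[1]
    } else {
      sample(seq(spec$docsPerSnp[1], spec$docsPerSnp[2]), 1L)
    }
    planted <- if (spec$plantedPerSnp > 0L) {
      sort(sample(inv$kid, spec$plantedPerSnp), method = "radix")
    } else {
      character(0)
    }
    p <- if (!is.null(spec$strengths)) {
      spec$strengths
    } else if (spec$strengthRange[1] == spec$strengthRange[2]) {
      rep(spec$strengthRange[1], length(planted))
    } else {
      stats::runif(length(planted), spec$strengthRange[1], spec$strengthRange[2])
    }
    list(
      snp = sprintf("rs%d", 1000L + s), nDocs = nd,
      planted = planted, p = structure(p, names = planted)
    )
  })
}

surfaceVariant <- function(surface, category) {
  if (category == "gene") return(surface) # symbols have no inflected form
  if (stats::runif(1) < 0.5) {
    paste0(surface, "s")
  } else {
    sub("^(.)", "\\U\\1", surface, perl = TRUE)
  }
}

#' Generate a synthetic annotated corpus with planted associations
#'
#' Realizes a [plantSpec()]: synthesizes PubTator-style documents whose
#' combined text contains every chosen keyword surface at a recorded,
#' valid offset, an rsID variant mention per document, and annotation rows
#' carrying category and synthetic concept ids. Identical spec and seed
#' give byte-identical output ([writePubtator()] of the records).
#'
#' @param spec A `PlantSpec` from [plantSpec()].
#' @return List with `records` (list of [LiteratureRecord-class]),
#'   `docMap` (rsID -> pmids), `truth` (`data.frame` snp, kid,
#'   inclusion probability of every planted keyword), and `inventory`.
#' @export
generateCorpus <- function(spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  inv <- syntheticInventory(spec)
  plants <- plantAssignments(spec)
  set.seed(spec$seed + 1L, kind = "Mersenne-Twister")
  invIdx <- structure(seq_len(nrow(inv)), names = inv$kid)

  records <- list()
  docMap <- list()
  nextPmid <- 1000001L
  for (pl in plants) {
    pmids <- character(pl$nDocs)
    for (d in seq_len(pl$nDocs)) {
      docPmid <- as.character(nextPmid)
      nextPmid <- nextPmid + 1L
      pmids[d] <- docPmid

      inPlanted <- pl$planted[stats::runif(length(pl$planted)) < pl$p]
      nNoise <- stats::rpois(1L, spec$noiseRate)
      noise <- if (nNoise > 0L) sample(inv$kid, nNoise, replace = TRUE) else character(0)
      kids <- unique(c(inPlanted, noise))
      kids <- sort(kids, method = "radix")
      dup <- kids[stats::runif(length(kids)) < spec$dupProb]

      title <- sprintf("Report %s on variant %s.", docPmid, pl$snp)
      rsStart <- nchar(sprintf("Report %s on variant ", docPmid))
      ment <- data.frame(
        start = rsStart, end = rsStart + nchar(pl$snp), surface = pl$snp,
        category = "variant", concept_id = pl$snp, stringsAsFactors = FALSE
      )
      base <- nchar(title) + 1L # combined text: title + " " + abstract
      abstract <- ""
      appendMention <- function(prefix, kid) {
        abstract <<- paste0(abstract, prefix)
        row <- inv[invIdx[[kid]], ]
        surf <- row$surface
        if (stats::runif(1) < spec$variantRate) {
          surf <- surfaceVariant(surf, row$category)
        }
        start <- base + nchar(abstract)
        abstract <<- paste0(abstract, surf)
        ment <<- rbind(ment, data.frame(
          start = start, end = start + nchar(surf), surface = surf,
          category = row$category, concept_id = row$ident,
          stringsAsFactors = FALSE
        ))
      }
      if (length(kids)) {
        appendMention("Findings involved ", kids[1])
        for (k in kids[-1]) appendMention(", ", k)
        abstract <- paste0(abstract, ".")
      } else {
        abstract <- "No entities were reported."
      }
      if (length(dup)) {
        appendMention(" Repeated observations concerned ", dup[1])
        if (length(dup) > 1L) for (k in dup[-1]) appendMention(" and ", k)
        abstract <- paste0(abstract, ".")
      }
      records[[docPmid]] <- LiteratureRecord(docPmid, title, abstract, ment)
    }
    docMap[[pl$snp]] <- pmids
  }
  truth <- rbindRows(lapply(plants, function(pl) {
    if (!length(pl$planted)) return(NULL)
    data.frame(
      snp = pl$snp, kid = pl$planted, p = unname(pl$p),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(truth)) {
    truth <- data.frame(snp = character(0), kid = character(0), p = numeric(0))
  }
  list(records = records, docMap = docMap, truth = truth, inventory = inv)
}

#' Closed-form expected counts for a synthetic corpus
#'
#' Analytic oracle for [generateCorpus()]. With planted inclusion
#' probability `p_k` (0 for unplanted keywords), noise rate `lambda` and
#' inventory size `I`, the per-document noise count of each keyword is
#' Poisson(`lambda / I`) independently across keywords (Poisson
#' splitting), so a keyword is present in a document with probability
#' `q_k = 1 - (1 - p_k) * exp(-lambda / I)`, presence is independent
#' across keywords and documents, `E[df_k] = n_docs * q_k`, and
#' `E[co_{k1,k2}] = n_docs * q_k1 * q_k2`. Mention duplication and surface
#' variants do not affect document-granularity counts.
#'
#' @param spec A `PlantSpec`.
#' @return List with `df` (`data.frame` snp, kid, expected_df, q) and
#'   `co` (`data.frame` snp, kid1, kid2, expected_co); `co` is restricted
#'   to pairs where at least one keyword is planted, plus it always
#'   includes all planted-planted pairs.
#' @export
expectedCounts <- function(spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  inv <- syntheticInventory(spec)
  plants <- plantAssignments(spec)
  I <- nrow(inv)
  noiseKeep <- exp(-spec$noiseRate / I)
  dfRows <- list()
  coRows <- list()
  for (pl in plants) {
    p <- structure(rep(0, I), names = inv$kid)
    p[pl$planted] <- pl$p
    q <- 1 - (1 - p) * noiseKeep
    keep <- q > 0
    dfRows[[pl$snp]] <- data.frame(
      snp = pl$snp, kid = names(q)[keep], q = unname(q[keep]),
      expected_df = pl$nDocs * unname(q[keep]), stringsAsFactors = FALSE
    )
    rel <- names(q)[q > 0 & (names(q) %in% pl$planted | spec$noiseRate > 0)]
    rel <- sort(rel, method = "radix")
    if (length(rel) >= 2L) {
      idx <- utils::combn(length(rel), 2L)
      k1 <- rel[idx[1, ]]
      k2 <- rel[idx[2, ]]
      keepPair <- k1 %in% pl$planted | k2 %in% pl$planted
      coRows[[pl$snp]] <- data.frame(
        snp = pl$snp, kid1 = k1[keepPair], kid2 = k2[keepPair],
        expected_co = pl$nDocs * q[k1[keepPair]] * q[k2[keepPair]],
        stringsAsFactors = FALSE
      )
    }
  }
  emptyDf <- data.frame(snp = character(0), kid = character(0), q = numeric(0),
    expected_df = numeric(0))
  emptyCo <- data.frame(snp = character(0), kid1 = character(0),
    kid2 = character(0), expected_co = numeric(0))
  df <- rbindRows(dfRows)
  co <- rbindRows(coRows)
  list(
    df = if (is.null(df)) emptyDf else df,
    co = if (is.null(co)) emptyCo else co
  )
}

#' Write a variant-to-document mapping as TSV
#'
#' Inverse of [readVariantDocMap()]: emits a header row and one
#' `(rsid, pmid)` row per membership, deterministically ordered.
#'
#' @param docMap Named list rsID -> pmids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVariantDocMap <- function(docMap, path) {
  rows <- rbindRows(lapply(names(docMap), function(s) {
    data.frame(rsid = s, pmid = sort(unique(as.character(docMap[[s]]))),
      stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(rsid = character(0), pmid = character(0))
  rows <- rows[order(rsidNumber(rows$rsid), rows$pmid, method = "radix"), ,
    drop = FALSE
  ]
  utils::write.table(rows, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}
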