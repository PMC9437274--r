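# Build a record whose abstract lists the given keyword surfaces with
# correct combined-text offsets (title + single space + abstract).
toyRecord <- function(pmid, keywords, rsid = NULL) {
  title <- sprintf("Doc %s.", pmid)
  base <- nchar(title) + 1L
  abstract <- ""
  ment <- data.frame(
    start = integer(0), end = integer(0), surface = character(0),
    category = character(0), concept_id = character(0),
    stringsAsFactors = FALSE
  )
  addSurface <- function(prefix, surface, category, concept_id) {
    abstract <<- paste0(abstract, prefix)
    start <- base + nchar(abstract)
    abstract <<- paste0(abstract, surface)
    ment <<- rbind(ment, data.frame(
      start = start, end = start + nchar(surface), surface = surface,
      category = category, concept_id = concept_id, stringsAsFactors = FALSE
    ))
  }
  if (!is.null(rsid)) addSurface("Variant ", rsid, "variant", rsid)
  if (nrow(keywords)) {
    for (i in seq_len(nrow(keywords))) {
      addSurface(if (nzchar(abstract)) ", " else "Mentions ",
        keywords$surface[i], keywords$category[i], keywords$concept_id[i])
    }
  }
  abstract <- paste0(abstract, ".")
  LiteratureRecord(pmid, title, abstract, ment)
}

kwRow <- function(surface, category, concept_id = NA_character_) {
  data.frame(surface = surface, category = category, concept_id = concept_id,
    stringsAsFactors = FALSE)
}

# The worked toy SNP: 3 documents; d1 {cancer, TP53}, d2 {cancer},
# d3 {cancer, TP53, tamoxifen}.
toyCorpusRs1 <- function() {
  cancer <- kwRow("cancer", "disease", "MESH:D009369")
  tp53 <- kwRow("TP53", "gene", "7157")
  tam <- kwRow("tamoxifen", "chemical", "MESH:D013629")
  list(
    "101" = toyRecord("101", rbind(cancer, tp53), rsid = "rs1"),
    "102" = toyRecord("102", cancer, rsid = "rs1"),
    "103" = toyRecord("103", rbind(cancer, tp53, tam), rsid = "rs1")
  )
}

KID_CANCER <- "disease:MESH:D009369"
KID_TP53 <- "gene:7157"
KID_TAM <- "chemical:MESH:D013629"

# Independent brute-force oracle for df/co: binary document-by-keyword
# incidence matrix, df = column sums, co = crossproduct. A different
# computational route from the per-document pair accumulation in the
# package.
oracleCounts <- function(records, docIds) {
  pmids <- vapply(records, pmid, "")
  docs <- intersect(as.character(docIds), pmids)
  rows <- do.call(rbind, lapply(records[match(docs, pmids)], function(r) {
    m <- mentions(r)
    m <- m[m$category %in% c("disease", "gene", "chemical"), , drop = FALSE]
    if (!nrow(m)) return(NULL)
    nf <- normalizeTerm(m$surface)
    id <- ifelse(is.na(m$concept_id) | trimws(m$concept_id) %in% c("", "-"),
      nf, m$concept_id)
    data.frame(pmid = pmid(r), kid = paste(m$category, id, sep = ":"),
      stringsAsFactors = FALSE)[nzchar(nf), , drop = FALSE]
  }))
  if (is.null(rows) || !nrow(rows)) {
    return(list(
      df = structure(integer(0), names = character(0)),
      co = data.frame(kid1 = character(0), kid2 = character(0), co = integer(0))
    ))
  }
  rows <- unique(rows)
  kids <- sort(unique(rows$kid), method = "radix")
  M <- matrix(0L, nrow = length(docs), ncol = length(kids),
    dimnames = list(docs, kids))
  M[cbind(rows$pmid, rows$kid)] <- 1L
  df <- structure(as.integer(colSums(M)), names = kids)
  C <- crossprod(M)
  co <- data.frame(kid1 = character(0), kid2 = character(0), co = integer(0),
    stringsAsFactors = FALSE)
  if (length(kids) >= 2L) {
    idx <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
    if (nrow(idx)) {
      co <- data.frame(
        kid1 = kids[idx[, 1]], kid2 = kids[idx[, 2]],
        co = as.integer(C[idx]), stringsAsFactors = FALSE
      )
      co <- co[order(co$kid1, co$kid2, method = "radix"), , drop = FALSE]
      rownames(co) <- NULL
    }
  }
  list(df = df, co = co)
}

# Varied random corpus specs for property tests (small sizes).
randomPlantSpec <- function(seed) {
  set.seed(seed)
  plantSpec(
    nSnps = sample(1:4, 1),
    docsPerSnp = sort(sample(1:25, 2, replace = TRUE)),
    inventorySizes = c(
      disease = sample(2:20, 1), gene = sample(1:15, 1),
      chemical = sample(1:15, 1)
    ),
    plantedPerSnp = sample(0:4, 1),
    noiseRate = sample(c(0, 0.5, 1, 2, 4), 1),
    dupProb = stats::runif(1, 0, 0.4),
    variantRate = stats::runif(1, 0, 0.5),
    seed = seed
  )
}

expect_counts_match_oracle <- function(index, sim) {
  for (snp in names(profiles(index))) {
    p <- profiles(index)[[snp]]
    orc <- oracleCounts(sim$records, sim$docMap[[snp]])
    expect_identical(snpDf(p), orc$df, label = sprintf("df for %s", snp))
    expect_identical(snpCo(p), orc$co, label = sprintf("co for %s", snp))
  }
}
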