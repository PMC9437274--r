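test_that("readPubtator parses a hand-written block", {
  expect_identical(readPubtator(character(0)), structure(list(), names = character(0)))

  recs <- readPubtator(c(
    "1|t|A study of cancer.", "1|a|",
    "1\t11\t17\tcancer\tDisease\tMESH:D009369"
  ))
  expect_length(recs, 1L)
  r <- recs[[1]]
  expect_identical(pmid(r), "1")
  m <- mentions(r)
  expect_identical(m$start, 11L)
  expect_identical(m$end, 17L)
  expect_identical(m$surface, "cancer")
  expect_identical(m$category, "disease")
  expect_identical(m$concept_id, "MESH:D009369")
  # the annotated span of the combined text is the surface itself
  expect_identical(substr(combinedText(r), 12, 17), "cancer")
})

test_that("readPubtator maps PubTator types and placeholder ids", {
  recs <- readPubtator(c(
    "9|t|BRCA1 rs334 water unknowns.",
    "9|a|",
    "9\t0\t5\tBRCA1\tGene\t672",
    "9\t6\t11\trs334\tSNP\trs334",
    "9\t12\t17\twater\tChemical\t-",
    "9\t18\t26\tunknowns\tSpeciesX\tfoo"
  ))
  m <- mentions(recs[[1]])
  expect_identical(m$category, c("gene", "variant", "chemical", "other"))
  expect_true(is.na(m$concept_id[3])) # "-" is a placeholder
})

test_that("readPubtator rejects malformed input with line numbers", {
  expect_error(
    readPubtator(c("1|t|T.", "1|a|", "1\t0\t1")),
    "line 3.*columns"
  )
  expect_error(
    readPubtator(c("1|t|T.", "1|a|", "1\tzero\t1\tT\tDisease\tX")),
    "line 3.*offsets"
  )
  expect_error(
    readPubtator(c("1|t|T.", "1|a|", "2\t0\t1\tT\tDisease\tX")),
    "does not match block pmid"
  )
  expect_error(
    readPubtator(c("1|t|T.", "1|a|", "", "1|t|T again.", "1|a|")),
    "duplicate pmid"
  )
})

test_that("span/surface mismatch warns by default and errors in strict mode", {
  lines <- c("5|t|abcdef.", "5|a|", "5\t0\t3\tzzz\tDisease\tX")
  expect_warning(readPubtator(lines), "trusting the surface")
  expect_error(readPubtator(lines, strict = TRUE), "surface")
})

test_that("duplicate annotation lines collapse with a message", {
  expect_message(
    recs <- readPubtator(c(
      "2|t|cancer here.", "2|a|",
      "2\t0\t6\tcancer\tDisease\tMESH:D009369",
      "2\t0\t6\tcancer\tDisease\tMESH:D009369"
    )),
    "1 duplicate annotation"
  )
  expect_identical(nrow(mentions(recs[[1]])), 1L)
})

test_that("PubTator write/read round-trips", {
  # read(write(R)) structurally equal to R, over generated corpora
  for (seed in c(2, 11)) {
    sim <- generateCorpus(randomPlantSpec(seed))
    text <- writePubtator(sim$records)
    back <- readPubtator(text, strict = TRUE)
    expect_identical(unname(lapply(back, identity)), unname(sim$records))
    # write(read(S)) byte-identical on a canonically formatted S
    expect_identical(writePubtator(back), text)
  }
  # degenerate cases
  expect_identical(writePubtator(list()), "")
  oneRec <- LiteratureRecord("3", "Title only.", "")
  expect_identical(writePubtator(list(oneRec)), "3|t|Title only.\n3|a|\n")
})

test_that("writePubtator emits 5-column lines for id-less mentions", {
  r <- toyRecord("7", kwRow("cancer", "disease"))
  text <- writePubtator(list(r))
  ann <- strsplit(strsplit(text, "\n")[[1]][3], "\t")[[1]]
  expect_length(ann, 5L)
  back <- readPubtator(text)
  expect_true(is.na(mentions(back[[1]])$concept_id))
})

test_that("gzip-compressed corpora are read by extension", {
  sim <- generateCorpus(plantSpec(nSnps = 2, seed = 4))
  gz <- tempfile(fileext = ".pubtator.gz")
  writePubtator(sim$records, gz)
  expect_identical(readPubtator(gz), sim$records)
})

test_that("readVariantDocMap normalizes and collapses duplicates", {
  path <- tempfile()
  writeLines(c("rsid\tpmid", "rs1\t10", "rs1\t10", "rs1\t11", "RS334\t5"), path)
  m <- readVariantDocMap(path)
  expect_identical(m, list(rs1 = c("10", "11"), rs334 = "5"))

  writeLines(character(0), path)
  expect_identical(readVariantDocMap(path), structure(list(), names = character(0)))

  writeLines(c("chr1:123A>G\t10"), path)
  expect_error(readVariantDocMap(path), "row 1.*malformed rsid")
  writeLines(c("rs1\tPMC10"), path)
  expect_error(readVariantDocMap(path), "row 1.*non-digit pmid")
})

test_that("deriveVariantDocMap collects rs-form variant mentions only", {
  expect_identical(
    deriveVariantDocMap(list(toyRecord("1", kwRow("cancer", "disease")))),
    structure(list(), names = character(0))
  )
  # concept id present on one mention, HGVS-only surface on another
  r <- toyRecord("7", kwRow("cancer", "disease"))
  m <- mentions(r)
  m <- rbind(m, data.frame(start = 0L, end = 3L, surface = "p.Glu6Val",
    category = "variant", concept_id = NA_character_))
  m$end[nrow(m)] <- 9L
  r2 <- LiteratureRecord("7", r@title, r@abstract, m)
  r3 <- toyRecord("8", kwRow("x", "disease"), rsid = "rs334")
  expect_message(
    map <- deriveVariantDocMap(list(r2, r3)),
    "skipped 1 variant mention"
  )
  expect_identical(map, list(rs334 = "8"))

  # two docs mentioning the same variant
  docs <- list(
    toyRecord("21", kwRow("a", "disease"), rsid = "rs7903146"),
    toyRecord("22", kwRow("b", "disease"), rsid = "rs7903146")
  )
  expect_identical(deriveVariantDocMap(docs), list(rs7903146 = c("21", "22")))
})

test_that("derived mapping is monotone under corpus growth", {
  sim <- generateCorpus(plantSpec(nSnps = 3, seed = 9))
  full <- deriveVariantDocMap(sim$records)
  sub <- deriveVariantDocMap(sim$records[seq(1, length(sim$records), by = 2)])
  for (snp in names(sub)) {
    expect_true(all(sub[[snp]] %in% full[[snp]]))
  }
})

test_that("parsed mentions always satisfy the span and category invariants", {
  for (seed in c(5, 6)) {
    sim <- generateCorpus(randomPlantSpec(seed))
    back <- readPubtator(writePubtator(sim$records), strict = TRUE)
    for (r in back) {
      m <- mentions(r)
      expect_true(all(m$start < m$end))
      expect_true(all(m$category %in%
        c("disease", "gene", "chemical", "variant", "other")))
      expect_true(validObject(r))
    }
  }
})
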