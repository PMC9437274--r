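test_that("buildSnpProfile reproduces the worked toy example", {
  recs <- toyCorpusRs1()
  p <- buildSnpProfile("rs1", c("101", "102", "103"), recs)
  expect_identical(nDocs(p), 3L)
  df <- snpDf(p)
  expect_identical(unname(df[KID_CANCER]), 3L)
  expect_identical(unname(df[KID_TP53]), 2L)
  expect_identical(unname(df[KID_TAM]), 1L)
  co <- snpCo(p)
  key <- function(a, b) co$co[co$kid1 == min(a, b) & co$kid2 == max(a, b)]
  expect_identical(key(KID_CANCER, KID_TP53), 2L)
  expect_identical(key(KID_CANCER, KID_TAM), 1L)
  expect_identical(key(KID_TP53, KID_TAM), 1L)
  expect_identical(nrow(co), 3L)
})

test_that("one document with one keyword yields df 1 and no pairs", {
  recs <- list(toyRecord("1", kwRow("cancer", "disease", "MESH:D009369")))
  p <- buildSnpProfile("rs1", "1", recs)
  expect_identical(unname(snpDf(p)), 1L)
  expect_identical(nrow(snpCo(p)), 0L)
})

test_that("a document mentioning a keyword five times contributes 1 to df", {
  kws <- do.call(rbind, replicate(5, kwRow("cancer", "disease", "MESH:D009369"),
    simplify = FALSE))
  recs <- list(toyRecord("1", kws))
  p <- buildSnpProfile("rs1", "1", recs)
  expect_identical(unname(snpDf(p)[KID_CANCER]), 1L)
  # the mention-counting sensitivity mode sees all five
  pm <- buildSnpProfile("rs1", "1", recs, countMode = "mention")
  expect_identical(unname(snpDf(pm)[KID_CANCER]), 5L)
})

test_that("empty document intersection is an error naming the SNP", {
  recs <- toyCorpusRs1()
  expect_error(buildSnpProfile("rs9", "999", recs), "rs9")
  expect_error(buildSnpProfile("nonsense", "101", recs), "malformed rsid")
})

test_that("df and co match the brute-force oracle on random corpora", {
  for (seed in 101:110) {
    sim <- generateCorpus(randomPlantSpec(seed))
    index <- suppressMessages(buildIndex(sim$docMap, sim$records))
    expect_counts_match_oracle(index, sim)
  }
})

test_that("stored pairs respect the co-occurrence bounds", {
  for (seed in c(31, 32, 33)) {
    sim <- generateCorpus(randomPlantSpec(seed))
    index <- suppressMessages(buildIndex(sim$docMap, sim$records))
    for (p in profiles(index)) {
      df <- snpDf(p)
      co <- snpCo(p)
      if (!nrow(co)) next
      expect_true(all(co$co <= pmin(df[co$kid1], df[co$kid2])))
      expect_true(all(co$co >= pmax(0L, df[co$kid1] + df[co$kid2] - nDocs(p))))
    }
  }
})

test_that("buildIndex derives the global table and reverse index", {
  # two SNPs sharing "cancer": rs2 with df 5, rs1 with df 3
  cancer <- kwRow("cancer", "disease", "MESH:D009369")
  recs <- c(
    lapply(1:3, function(i) toyRecord(as.character(i), cancer)),
    lapply(4:8, function(i) toyRecord(as.character(i), cancer))
  )
  names(recs) <- as.character(1:8)
  docMap <- list(rs1 = as.character(1:3), rs2 = as.character(4:8))
  index <- buildIndex(docMap, recs)
  kw <- keywordTable(index)
  expect_identical(kw$snp_count[kw$kid == KID_CANCER], 2L)
  expect_identical(
    reverseIndex(index)[[KID_CANCER]],
    data.frame(snp = c("rs2", "rs1"), df = c(5L, 3L))
  )
  expect_identical(rankSnpsForKeyword(index, "cancer", 1),
    data.frame(snp = "rs2", df = 5L))
})

test_that("reverse ties break by numeric rsid ascending", {
  cancer <- kwRow("cancer", "disease", "MESH:D009369")
  recs <- list("1" = toyRecord("1", cancer), "2" = toyRecord("2", cancer))
  index <- buildIndex(list(rs10 = "1", rs2 = "2"), recs)
  expect_identical(reverseIndex(index)[[KID_CANCER]]$snp, c("rs2", "rs10"))
})

test_that("a singleton index lists every keyword once in reverse", {
  recs <- toyCorpusRs1()
  index <- buildIndex(list(rs1 = c("101", "102", "103")), recs)
  p <- profiles(index)[["rs1"]]
  for (k in names(snpDf(p))) {
    expect_identical(
      reverseIndex(index)[[k]],
      data.frame(snp = "rs1", df = unname(snpDf(p)[k]))
    )
  }
})

test_that("reverse index, snp counts and profiles agree exhaustively", {
  for (seed in c(55, 56)) {
    sim <- generateCorpus(randomPlantSpec(seed))
    index <- suppressMessages(buildIndex(sim$docMap, sim$records))
    kw <- keywordTable(index)
    rev <- reverseIndex(index)
    # snp_count == reverse list length
    expect_identical(kw$snp_count, unname(vapply(rev[kw$kid], nrow, 0L)))
    # every reverse posting matches its profile, and ordering is df-descending
    for (k in kw$kid) {
      lst <- rev[[k]]
      expect_true(all(diff(lst$df) <= 0))
      for (i in seq_len(nrow(lst))) {
        expect_identical(
          unname(snpDf(profiles(index)[[lst$snp[i]]])[k]), lst$df[i]
        )
      }
      carriers <- names(Filter(function(p) k %in% names(snpDf(p)), profiles(index)))
      expect_setequal(lst$snp, carriers)
    }
  }
})

test_that("adding a document never decreases df or co", {
  sim <- generateCorpus(plantSpec(nSnps = 1, docsPerSnp = c(10L, 10L), seed = 77))
  docs <- sim$docMap[[1]]
  snp <- names(sim$docMap)[1]
  pSmall <- buildSnpProfile(snp, docs[1:9], sim$records)
  pFull <- buildSnpProfile(snp, docs, sim$records)
  dfS <- snpDf(pSmall)
  dfF <- snpDf(pFull)
  expect_true(all(dfF[names(dfS)] >= dfS))
  coS <- snpCo(pSmall)
  coF <- snpCo(pFull)
  if (nrow(coS)) {
    keyS <- paste(coS$kid1, coS$kid2)
    keyF <- paste(coF$kid1, coF$kid2)
    expect_true(all(keyS %in% keyF))
    expect_true(all(coF$co[match(keyS, keyF)] >= coS$co))
  }
})

test_that("related keywords aggregate co across profiles symmetrically", {
  recs <- toyCorpusRs1()
  # second SNP re-uses docs 101 and 103 so cancer-TP53 co accumulates
  index <- buildIndex(
    list(rs1 = c("101", "102", "103"), rs2 = c("101", "103")), recs
  )
  rel <- relatedKeywordsForKeyword(index, "cancer", 10)
  expect_identical(rel$total_co[rel$kid == KID_TP53], 2L + 2L)
  # symmetry: related(k1) containing (k2, c) implies the converse
  rel2 <- relatedKeywordsForKeyword(index, "TP53", 10)
  expect_identical(
    rel2$total_co[rel2$kid == KID_CANCER],
    rel$total_co[rel$kid == KID_TP53]
  )
  # limits clamp
  expect_identical(nrow(rankSnpsForKeyword(index, "cancer", 0)), 0L)
  expect_identical(nrow(rankSnpsForKeyword(index, "cancer", 99)), 2L)
})

test_that("unknown keywords raise a 'never observed' error", {
  index <- buildIndex(list(rs1 = c("101", "102", "103")), toyCorpusRs1())
  expect_error(rankSnpsForKeyword(index, "aspirin"), "never observed")
  expect_error(relatedKeywordsForKeyword(index, "aspirin"), "never observed")
})

test_that("index persistence round-trips and is byte-deterministic", {
  sim <- generateCorpus(plantSpec(nSnps = 3, seed = 21))
  index <- buildIndex(sim$docMap, sim$records)
  d1 <- file.path(tempfile(), "idx1")
  d2 <- file.path(tempfile(), "idx2")
  writeIndex(index, d1)
  writeIndex(buildIndex(sim$docMap, sim$records), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = f)
  }
  back <- readIndex(d1)
  expect_identical(keywordTable(back), keywordTable(index))
  expect_identical(reverseIndex(back), reverseIndex(index))
  for (s in names(profiles(index))) {
    expect_identical(snpDf(profiles(back)[[s]]), snpDf(profiles(index)[[s]]))
    expect_identical(snpCo(profiles(back)[[s]]), snpCo(profiles(index)[[s]]))
  }
})
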