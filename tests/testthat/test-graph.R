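toyProfile <- function() {
  buildSnpProfile("rs1", c("101", "102", "103"), toyCorpusRs1())
}

test_that("buildSnpGraph filters by df and keeps surviving edges", {
  p <- toyProfile()
  g <- buildSnpGraph(p, topN = 10, minDf = 1)
  expect_identical(nrow(graphNodes(g)), 3L)
  expect_identical(nrow(graphEdges(g)), 3L)
  w <- structure(graphNodes(g)$weight, names = graphNodes(g)$kid)
  expect_identical(unname(w[KID_CANCER]), 3L)
  expect_identical(unname(w[KID_TP53]), 2L)
  expect_identical(unname(w[KID_TAM]), 1L)

  # top-2 by df keeps cancer and TP53 with their single edge of weight 2
  g2 <- buildSnpGraph(p, topN = 2, minDf = 1)
  expect_setequal(graphNodes(g2)$kid, c(KID_CANCER, KID_TP53))
  expect_identical(graphEdges(g2)$weight, 2L)

  # min_df beyond n_docs empties the graph; topN 0 likewise; negatives error
  expect_identical(nrow(graphNodes(buildSnpGraph(p, 10, minDf = 4))), 0L)
  expect_identical(nrow(graphNodes(buildSnpGraph(p, 0, 1))), 0L)
  expect_error(buildSnpGraph(p, -1, 1), ">= 0")
})

test_that("global graph applies the dual exclusion rule once, pre-filter", {
  # keyword q: high SNP count but few partners -> excluded at (10, 5)
  q <- kwRow("qterm", "disease", "MESH:Q")
  partner <- kwRow("partner", "gene", "77")
  recs <- list()
  docMap <- list()
  for (i in 1:12) {
    pm <- as.character(i)
    recs[[pm]] <- toyRecord(pm, if (i <= 3) rbind(q, partner) else q)
    docMap[[sprintf("rs%d", i)]] <- pm
  }
  index <- buildIndex(docMap, recs)
  kw <- keywordTable(index)
  expect_identical(kw$snp_count[kw$kid == "disease:MESH:Q"], 12L)
  g <- buildGlobalGraph(index, minTotalCount = 10, minConnections = 5)
  expect_false("disease:MESH:Q" %in% graphNodes(g)$kid)
  # with thresholds (0, 0) everything survives
  g0 <- buildGlobalGraph(index, 0, 0)
  expect_setequal(graphNodes(g0)$kid, kw$kid)
  expect_identical(graphEdges(g0)$weight, 3L) # aggregate co of the one pair
})

test_that("graph filters are monotone in every threshold", {
  sim <- generateCorpus(plantSpec(nSnps = 4, noiseRate = 3, seed = 42))
  index <- buildIndex(sim$docMap, sim$records)
  p <- profiles(index)[[1]]
  lastN <- Inf
  lastE <- Inf
  for (minDf in 0:4) {
    g <- buildSnpGraph(p, topN = 100, minDf = minDf)
    expect_lte(nrow(graphNodes(g)), lastN)
    expect_lte(nrow(graphEdges(g)), lastE)
    lastN <- nrow(graphNodes(g))
    lastE <- nrow(graphEdges(g))
  }
  lastN <- Inf
  for (topN in c(20, 10, 5, 2, 1, 0)) {
    g <- buildSnpGraph(p, topN = topN, minDf = 1)
    expect_lte(nrow(graphNodes(g)), min(lastN, topN))
    lastN <- nrow(graphNodes(g))
  }
  lastN <- Inf
  for (thr in 0:5) {
    g <- buildGlobalGraph(index, minTotalCount = thr, minConnections = 0)
    expect_lte(nrow(graphNodes(g)), lastN)
    lastN <- nrow(graphNodes(g))
  }
  lastN <- Inf
  for (thr in c(0, 2, 4, 8, 16)) {
    g <- buildGlobalGraph(index, minTotalCount = 0, minConnections = thr)
    expect_lte(nrow(graphNodes(g)), lastN)
    lastN <- nrow(graphNodes(g))
  }
})

test_that("every edge endpoint is an exported node, in every format", {
  sim <- generateCorpus(plantSpec(nSnps = 3, noiseRate = 2, seed = 13))
  index <- buildIndex(sim$docMap, sim$records)
  g <- buildSnpGraph(profiles(index)[[1]], topN = 8, minDf = 1)
  expect_true(all(c(graphEdges(g)$a, graphEdges(g)$b) %in% graphNodes(g)$kid))
  json <- jsonlite::fromJSON(exportGraph(g, "node-link-json"), simplifyVector = TRUE)
  if (length(json$links)) {
    expect_true(all(c(json$links$source, json$links$target) %in% json$nodes$id))
  }
  back <- parseGraphML(exportGraph(g, "graphml"))
  expect_true(all(c(graphEdges(back)$a, graphEdges(back)$b) %in%
    graphNodes(back)$kid))
})

test_that("exports are deterministic and GraphML round-trips", {
  p <- toyProfile()
  g <- buildSnpGraph(p, 10, 1)
  for (fmt in c("node-link-json", "graphml", "tsv")) {
    expect_identical(exportGraph(g, fmt), exportGraph(g, fmt))
  }
  back <- parseGraphML(exportGraph(g, "graphml"), meta = g@meta)
  ord <- function(gr) varlit:::orderGraph(gr)
  expect_identical(ord(back), ord(g))
  # weights survive export exactly as integers
  expect_identical(sort(graphNodes(back)$weight), sort(graphNodes(g)$weight))
  expect_identical(sort(graphEdges(back)$weight), sort(graphEdges(g)$weight))
  # empty graph is valid in each format
  e <- buildSnpGraph(p, 0, 1)
  expect_no_error(jsonlite::fromJSON(exportGraph(e, "node-link-json")))
  expect_identical(nrow(graphNodes(parseGraphML(exportGraph(e, "graphml")))), 0L)
  expect_match(exportGraph(e, "tsv"), "#nodes")
  expect_error(exportGraph(g, "dot"), "supported formats")
})

test_that("keywordSubgraph induces the closed neighborhood", {
  g <- buildSnpGraph(toyProfile(), 10, 1)
  sub <- keywordSubgraph(g, KID_TAM)
  expect_setequal(graphNodes(sub)$kid, c(KID_TAM, KID_CANCER, KID_TP53))
  expect_identical(nrow(graphEdges(sub)), 3L)
  # idempotent on the same key
  expect_identical(keywordSubgraph(sub, KID_TAM)@nodes, sub@nodes)
  # isolated node
  iso <- buildSnpGraph(toyProfile(), 1, 1)
  s <- keywordSubgraph(iso, KID_CANCER)
  expect_identical(nrow(graphNodes(s)), 1L)
  expect_identical(nrow(graphEdges(s)), 0L)
  expect_error(keywordSubgraph(g, "disease:nonexistent"), "filtered out")
})
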