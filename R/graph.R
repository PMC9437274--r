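emptyNodes <- function() {
  data.frame(
    kid = character(0), category = character(0), label = character(0),
    weight = integer(0), stringsAsFactors = FALSE
  )
}

emptyEdges <- function() {
  data.frame(a = character(0), b = character(0), weight = integer(0),
    stringsAsFactors = FALSE)
}

labelsFor <- function(keywords, kids) {
  lab <- structure(keywords$display_form, names = keywords$kid)
  out <- unname(lab[kids])
  out[is.na(out)] <- kids[is.na(out)]
  out
}

#' Build the keyword graph of one SNP
#'
#' Nodes are the SNP's keywords with document frequency at least `minDf`,
#' reduced to the `topN` highest-df keywords (ties broken by kid
#' ascending); node weight is the keyword's df. Edges are the profile's
#' co-occurrence entries restricted to surviving node pairs; edge weight is
#' the co count. Tightening either filter mirrors the dynamic keyword
#' filtering of the rendered network.
#'
#' @param profile A [SnpProfile-class].
#' @param topN Maximum number of nodes (0 gives an empty graph).
#' @param minDf Minimum document frequency for a node.
#' @return A [KeywordGraph-class] with `meta$scope == "per-snp"`.
#' @export
buildSnpGraph <- function(profile, topN = 50L, minDf = 1L) {
  if (topN < 0L || minDf < 0L) stop("topN and minDf must be >= 0")
  df <- profile@df
  df <- df[df >= minDf]
  ord <- order(-df, names(df), method = "radix")
  keep <- names(df)[ord][seq_len(min(topN, length(df)))]
  nodes <- emptyNodes()
  edges <- emptyEdges()
  if (length(keep)) {
    nodes <- data.frame(
      kid = keep,
      category = sub(":.*$", "", keep),
      label = labelsFor(profile@keywords, keep),
      weight = unname(profile@df[keep]),
      stringsAsFactors = FALSE
    )
    co <- profile@co
    co <- co[co$kid1 %in% keep & co$kid2 %in% keep, , drop = FALSE]
    if (nrow(co)) {
      edges <- data.frame(a = co$kid1, b = co$kid2, weight = co$co,
        stringsAsFactors = FALSE)
      edges <- edges[order(edges$a, edges$b, method = "radix"), , drop = FALSE]
    }
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("KeywordGraph",
    nodes = nodes, edges = edges,
    meta = list(scope = "per-snp", snp = profile@snp,
      top_n = as.integer(topN), min_df = as.integer(minDf))
  )
}

#' Build the global keyword graph
#'
#' Candidate nodes are all keywords of the index; a node's weight is its
#' SNP count (the number of SNPs carrying it) and its connection count is
#' the number of distinct partner keywords with which its aggregate
#' co-occurrence (summed over all SNP profiles) is at least 1. Keywords
#' with weight below `minTotalCount` *or* connections below
#' `minConnections` are excluded; the exclusion is applied once against the
#' pre-filter connection counts (no iterative re-pruning). Edges are the
#' aggregate co-occurrence between surviving nodes. The defaults mirror the
#' published global graph's exclusion rule (fewer than ten total counts or
#' 50 connections).
#'
#' @param index An [AssociationIndex-class].
#' @param minTotalCount Minimum keyword SNP count.
#' @param minConnections Minimum pre-filter distinct-partner count.
#' @return A [KeywordGraph-class] with `meta$scope == "global"`.
#' @export
buildGlobalGraph <- function(index, minTotalCount = 10L, minConnections = 50L) {
  if (minTotalCount < 0L || minConnections < 0L) {
    stop("minTotalCount and minConnections must be >= 0")
  }
  kw <- index@keywords
  agg <- aggregateCo(index)
  conn <- table(c(agg$kid1, agg$kid2))
  connections <- structure(as.integer(conn), names = names(conn))
  connOf <- function(k) {
    v <- connections[k]
    ifelse(is.na(v), 0L, v)
  }
  keep <- kw$kid[kw$snp_count >= minTotalCount & connOf(kw$kid) >= minConnections]
  nodes <- emptyNodes()
  edges <- emptyEdges()
  if (length(keep)) {
    sel <- kw[match(keep, kw$kid), , drop = FALSE]
    nodes <- data.frame(
      kid = sel$kid, category = sel$category, label = sel$display_form,
      weight = as.integer(sel$snp_count), stringsAsFactors = FALSE
    )
    agg <- agg[agg$kid1 %in% keep & agg$kid2 %in% keep, , drop = FALSE]
    if (nrow(agg)) {
      edges <- data.frame(a = agg$kid1, b = agg$kid2, weight = agg$co,
        stringsAsFactors = FALSE)
    }
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  new("KeywordGraph",
    nodes = nodes, edges = edges,
    meta = list(scope = "global",
      min_total_count = as.integer(minTotalCount),
      min_connections = as.integer(minConnections))
  )
}

#' Induced neighborhood subgraph around one keyword
#'
#' The subgraph induced on a keyword plus its direct neighbors, with all
#' node and edge weights unchanged -- the keyword-focused view of a graph.
#' Idempotent when re-applied to the same key.
#'
#' @param graph A [KeywordGraph-class].
#' @param key A node kid (resolved against node kids, then labels).
#' @return A [KeywordGraph-class].
#' @export
keywordSubgraph <- function(graph, key) {
  kids <- graph@nodes$kid
  kid <- if (key %in% kids) key else kids[graph@nodes$label == key][1]
  if (is.na(kid) || !length(kid) || !kid %in% kids) {
    stop(sprintf(
      "keyword '%s' is not a node of this graph (it may have been filtered out by the graph thresholds)",
      key
    ))
  }
  e <- graph@edges
  nb <- unique(c(e$b[e$a == kid], e$a[e$b == kid]))
  keep <- unique(c(kid, nb))
  nodes <- graph@nodes[graph@nodes$kid %in% keep, , drop = FALSE]
  edges <- e[e$a %in% keep & e$b %in% keep, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  meta <- graph@meta
  meta$focus <- kid
  new("KeywordGraph", nodes = nodes, edges = edges, meta = meta)
}

orderGraph <- function(graph) {
  n <- graph@nodes
  e <- graph@edges
  if (nrow(n)) {
    n <- n[order(-n$weight, n$kid, method = "radix"), , drop = FALSE]
    rownames(n) <- NULL
  }
  if (nrow(e)) {
    e <- e[order(e$a, e$b, method = "radix"), , drop = FALSE]
    rownames(e) <- NULL
  }
  list(nodes = n, edges = e)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Serialize a keyword graph
#'
#' Deterministic text serialization: nodes sorted by weight descending then
#' kid, edges by `(a, b)`. Formats:
#' \describe{
#'   \item{`node-link-json`}{`{"nodes": [{"id","label","category","weight"}],
#'     "links": [{"source","target","weight"}]}`, ready for force-directed
#'     renderers that map weight to node size / edge width and category to
#'     color.}
#'   \item{`graphml`}{GraphML with declared `label`, `category` (node) and
#'     `weight` (node and edge) attributes; parse back with
#'     [parseGraphML()].}
#'   \item{`tsv`}{A `#nodes` section and a `#edges` section of
#'     tab-separated tables.}
#' }
#' Two exports of the same graph are byte-identical.
#'
#' @param graph A [KeywordGraph-class].
#' @param format One of `"node-link-json"`, `"graphml"`, `"tsv"`.
#' @param path Optional output file path.
#' @return The serialized text (length-1 character), invisibly when `path`
#'   is given.
#' @export
exportGraph <- function(graph, format = c("node-link-json", "graphml", "tsv"),
                        path = NULL) {
  if (!is.character(format) || !format[1] %in% c("node-link-json", "graphml", "tsv")) {
    stop("unknown format; supported formats: node-link-json, graphml, tsv")
  }
  format <- format[1]
  g <- orderGraph(graph)
  n <- g$nodes
  e <- g$edges
  text <- switch(format,
    "node-link-json" = {
      nodes <- if (nrow(n)) {
        lapply(seq_len(nrow(n)), function(i) list(
          id = n$kid[i], label = n$label[i], category = n$category[i],
          weight = n$weight[i]
        ))
      } else list()
      links <- if (nrow(e)) {
        lapply(seq_len(nrow(e)), function(i) list(
          source = e$a[i], target = e$b[i], weight = e$weight[i]
        ))
      } else list()
      paste0(jsonlite::toJSON(list(nodes = nodes, links = links),
        auto_unbox = TRUE, pretty = TRUE
      ), "\n")
    },
    "graphml" = {
      nodeXml <- if (nrow(n)) {
        sprintf(
          "    <node id=\"%s\">\n      <data key=\"label\">%s</data>\n      <data key=\"category\">%s</data>\n      <data key=\"weight\">%d</data>\n    </node>",
          xmlEscape(n$kid), xmlEscape(n$label), xmlEscape(n$category), n$weight
        )
      } else character(0)
      edgeXml <- if (nrow(e)) {
        sprintf(
          "    <edge source=\"%s\" target=\"%s\">\n      <data key=\"eweight\">%d</data>\n    </edge>",
          xmlEscape(e$a), xmlEscape(e$b), e$weight
        )
      } else character(0)
      paste0(paste(c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
        "  <key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
        "  <key id=\"category\" for=\"node\" attr.name=\"category\" attr.type=\"string\"/>",
        "  <key id=\"weight\" for=\"node\" attr.name=\"weight\" attr.type=\"int\"/>",
        "  <key id=\"eweight\" for=\"edge\" attr.name=\"weight\" attr.type=\"int\"/>",
        "  <graph edgedefault=\"undirected\">",
        nodeXml, edgeXml,
        "  </graph>",
        "</graphml>"
      ), collapse = "\n"), "\n")
    },
    "tsv" = {
      nodeLines <- c(
        "#nodes", "kid\tcategory\tlabel\tweight",
        if (nrow(n)) sprintf("%s\t%s\t%s\t%d", n$kid, n$category, n$label, n$weight)
      )
      edgeLines <- c(
        "#edges", "a\tb\tweight",
        if (nrow(e)) sprintf("%s\t%s\t%d", e$a, e$b, e$weight)
      )
      paste0(paste(c(nodeLines, edgeLines), collapse = "\n"), "\n")
    }
  )
  if (!is.null(path)) {
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(charToRaw(enc2utf8(text)), con)
    return(invisible(text))
  }
  text
}

#' Parse a GraphML document written by [exportGraph()]
#'
#' @param text GraphML text or a file path.
#' @param meta Optional meta list to attach to the rebuilt graph.
#' @return A [KeywordGraph-class].
#' @export
parseGraphML <- function(text, meta = list(scope = "per-snp")) {
  doc <- xml2::read_xml(text)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodeEls <- xml2::xml_find_all(doc, ".//g:node", ns)
  edgeEls <- xml2::xml_find_all(doc, ".//g:edge", ns)
  dataOf <- function(el, key) {
    xml2::xml_text(xml2::xml_find_first(
      el, sprintf("./g:data[@key='%s']", key), ns
    ))
  }
  nodes <- emptyNodes()
  if (length(nodeEls)) {
    nodes <- data.frame(
      kid = xml2::xml_attr(nodeEls, "id"),
      category = vapply(nodeEls, dataOf, "", key = "category"),
      label = vapply(nodeEls, dataOf, "", key = "label"),
      weight = as.integer(vapply(nodeEls, dataOf, "", key = "weight")),
      stringsAsFactors = FALSE
    )
  }
  edges <- emptyEdges()
  if (length(edgeEls)) {
    edges <- data.frame(
      a = xml2::xml_attr(edgeEls, "source"),
      b = xml2::xml_attr(edgeEls, "target"),
      weight = as.integer(vapply(edgeEls, dataOf, "", key = "eweight")),
      stringsAsFactors = FALSE
    )
  }
  new("KeywordGraph", nodes = nodes, edges = edges, meta = meta)
}
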