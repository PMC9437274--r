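# varlit

Keyword association networks from variant-centred biomedical literature.

## The problem

Interpreting a single-nucleotide polymorphism (SNP) found in a sequencing
report means asking what the biomedical literature already says about it:
which diseases, genes and chemicals co-occur with the variant, how
consistently, and how those concepts relate to each other. Curated variant
databases answer this slowly and partially; raw literature search answers it
as an unreadable list of papers. `varlit` implements the middle path for R
users: an automated, fully offline pipeline that turns entity-annotated
abstracts (PubTator plain-text format) plus a variant-to-document mapping
(rsID → PMID, as produced by variant-centric literature services) into
quantitative, renderable association summaries. It is aimed at
bioinformaticians building variant-interpretation tooling and at anyone who
wants reproducible keyword networks from an annotated corpus snapshot.

## The statistics

For a SNP *s* with literature set *D(s)* and normalized keywords *k* (each a
disease, gene or chemical concept):

- **Association significance**: the document frequency
  `df(s, k) = |{d ∈ D(s) : k mentioned in d}|`. Each document contributes
  its keyword **set** — five mentions in one abstract count once.
- **Keyword-pair significance**: the same-document co-occurrence
  `co(s, k₁, k₂) = |{d ∈ D(s) : both k₁ and k₂ mentioned in d}|`, which
  always satisfies `max(0, df₁ + df₂ − |D(s)|) ≤ co ≤ min(df₁, df₂)`.
- **Reverse index**: for every keyword, the SNPs carrying it ranked by `df`
  descending (ties: numeric rsID ascending) — concept-first search.
- **Graphs**: keywords as nodes (weight `df`, or SNP count globally), pairs
  as edges (weight `co`, aggregated over SNPs globally), with dynamic
  filtering by `top_n` / `min_df` per SNP and a dual exclusion rule
  globally (drop keywords with fewer than `min_total_count` SNPs **or**
  fewer than `min_connections` co-occurrence partners; defaults 10 and 50).

Keywords are normalized before counting: concept identifiers are the merge
key when the annotator provides them; otherwise text is trimmed,
case-folded (except short all-caps gene symbols such as `TP53` or `AD`,
which keep their case) and the final token is singularized, so "Tumors" and
"tumor" are one keyword.

## Worked example

A two-document corpus about rs1042522 ships with the package:

```r
library(varlit)
recs   <- readPubtator(system.file("extdata", "example_corpus.pubtator",
                                   package = "varlit"), strict = TRUE)
docMap <- deriveVariantDocMap(recs)   # rsIDs mined from the variant mentions
index  <- buildIndex(docMap, recs)
profiles(index)[["rs1042522"]]
#> SnpProfile rs1042522: 2 doc(s), 3 keyword(s), 3 pair(s) [document counting]
#>   top keywords: disease:MESH:D009369=2, gene:7157=2, chemical:MESH:D013629=1
```

Both documents mention "cancer"/"cancers" (merged by the shared MeSH id,
df = 2) and the gene TP53 (df = 2); tamoxifen appears in one (df = 1). The
pair counts follow the same-document rule — cancer and TP53 co-occur in
both documents, the pairs involving tamoxifen only in the first:

```r
snpCo(profiles(index)[["rs1042522"]])
#>                    kid1                 kid2 co
#> 1 chemical:MESH:D013629 disease:MESH:D009369  1
#> 2 chemical:MESH:D013629            gene:7157  1
#> 3  disease:MESH:D009369            gene:7157  2

rankSnpsForKeyword(index, "cancer", 5)   # reverse search
#>         snp df
#> 1 rs1042522  2

cat(exportGraph(buildSnpGraph(profiles(index)[["rs1042522"]], 10, 1), "tsv"))
#> #nodes
#> kid	category	label	weight
#> disease:MESH:D009369	disease	cancer	2
#> gene:7157	gene	TP53	2
#> chemical:MESH:D013629	chemical	Tamoxifen	1
#> #edges
#> a	b	weight
#> chemical:MESH:D013629	disease:MESH:D009369	1
#> chemical:MESH:D013629	gene:7157	1
#> disease:MESH:D009369	gene:7157	2
```

`exportGraph()` also emits node-link JSON and GraphML (round-trippable via
`parseGraphML()`); node weights map to sizes and categories to colors in
any renderer. `buildGlobalGraph()` produces the corpus-wide keyword graph,
`compareIndexWithExternal()` contrasts per-SNP keywords with an external
curated list (per-SNP or deduplicated pooling), and `generateCorpus()`
synthesizes seeded corpora with planted association strengths plus their
analytic expectations (`expectedCounts()`).

## Command line

A thin wrapper over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "varlit.R", package = "varlit"))')
Rscript "$CLI" simulate    --out-dir demo --seed 7
Rscript "$CLI" build-index --corpus demo/corpus.pubtator \
               --variant-map demo/variant_map.tsv --out-dir demo
Rscript "$CLI" snp-graph   --rsid rs1001 --out-dir demo --format graphml
Rscript "$CLI" keyword     --term dis001oma --out-dir demo
```

Subcommands: `build-index`, `snp-graph`, `global-graph`, `keyword`,
`compare`, `simulate`. Every option can also come from a YAML config file
(`--config`); flags take precedence. Exit codes: 0 success, 2 usage error,
1 runtime error. Outputs are byte-deterministic for identical inputs.

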