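---
title: "Methods: variant-centred keyword association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-centred keyword association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varlit)
```

## The model

`varlit` quantifies what a literature corpus says about a single-nucleotide
polymorphism (SNP) by counting, not by modelling language. Given a corpus of
entity-annotated documents and a mapping from rsIDs to the PubMed documents
that discuss them, the pipeline computes for each SNP $s$ with document set
$D(s)$:

* the **document frequency** of every keyword $k$,
  $\mathrm{df}(s,k) = |\{d \in D(s) : k \in K(d)\}|$, where $K(d)$ is the
  *set* of normalized keywords of document $d$ — the significance of the
  keyword–SNP association;
* the **same-document co-occurrence** of every keyword pair,
  $\mathrm{co}(s,k_1,k_2) = |\{d \in D(s) : k_1 \in K(d) \wedge k_2 \in
  K(d)\}|$ — the significance of the keyword–keyword association within
  that SNP's literature.

Both are raw counts: no enrichment statistic, document weighting or recency
adjustment is applied, because the associations are meant to be read as "how
much literature connects these", and the renderable products (node sizes,
edge widths) map directly onto them. Two consequences of document-set
granularity are worth stating explicitly: a keyword mentioned many times in
one abstract counts once, and the bounds
$\max(0, \mathrm{df}_1 + \mathrm{df}_2 - |D(s)|) \le \mathrm{co} \le
\min(\mathrm{df}_1, \mathrm{df}_2)$ hold for every stored pair (they are
enforced by the `SnpProfile` validity method and property-tested).

Aggregating over SNPs gives the corpus-level objects: the keyword table with
each keyword's **SNP count** (how many SNPs carry it), the **reverse index**
mapping each keyword to its SNPs ranked by `df`, and the global keyword
graph whose edges sum `co` across all profiles. The reverse-query direction
(`rankSnpsForKeyword()`, `relatedKeywordsForKeyword()`) aggregates pair
counts across profiles rather than recomputing over the pooled document
union; the two differ when the same document backs several SNPs, and the
per-profile aggregation was chosen because the pooled alternative would let
one heavily shared document dominate every keyword's ranking.

### Assumptions

* Annotation quality is inherited from the upstream entity annotator; the
  pipeline merges mentions by concept identifier and does not attempt
  ontology mapping, abbreviation expansion or fuzzy clustering.
* Only titles and abstracts are considered, which matches the common export
  of annotated literature and keeps offsets well-defined.
* Documents listed for a variant but absent from the corpus snapshot are
  skipped at counting time (partial dumps are the normal case); a profile is
  only built when at least one document is present.

## Keyword normalization

Mentions of category disease, gene or chemical become keywords; variant and
other mentions do not (variant mentions are instead usable to derive the
rsID-to-document mapping when none is supplied). The keyword identity is
`category:ident`, where `ident` is the annotator's concept identifier when
present and non-placeholder, else the normalized text. Text normalization
is deliberately light:

1. trim punctuation/whitespace at the ends;
2. case-fold every token **except** plausible gene symbols — 2–6
   characters, all uppercase letters/digits/hyphens with at least one
   letter — so `TP53`, `EGFR`, `AD` keep their conventional casing while
   `Cancer` folds to `cancer`;
3. singularize the final token (`tumors → tumor`, `studies → study`,
   `metastases → metastasis`).

The singularizer is a compact rule set plus dictionaries for medical
`-ses/-sis` plurals, Latin/Greek plurals and plural-invariant nouns
(`diabetes`, `species`). It is intentionally not a full lemmatizer: only
noun-phrase-final plural inflection is normalized, which is what actually
varies across annotated surface forms, and the function is idempotent —
re-normalizing a normal form is a no-op, which tests rely on. Display
labels are chosen separately as each keyword's modal observed surface form,
with ties broken by code-point order so the choice is deterministic.

A two-column synonym table (`from_ident`, `to_ident`) can be supplied for
manual merges the identifiers miss; it is applied after normalization.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `countMode` | `"document"` | `df` counts documents; `"mention"` counts mentions as a sensitivity analysis. Pair counts stay document-granular in both modes, and the `df ≤ n_docs` bound is only meaningful (and only enforced) in document mode. |
| `topN`, `minDf` (per-SNP graph) | 50, 1 | Dynamic filtering of a SNP's network: keep keywords with `df ≥ minDf`, then the `topN` by `df` (ties by keyword id). Node and edge counts are non-increasing as either tightens. |
| `minTotalCount`, `minConnections` (global graph) | 10, 50 | A keyword is excluded when its SNP count is below the first **or** its number of distinct co-occurrence partners is below the second. The OR combination is the stricter reading of the exclusion rule; both thresholds are arguments (and CLI flags), so the AND behaviour is one wrapper away. Connection counts are taken once, against the unfiltered graph — no iterative re-pruning — so the output is a single-pass, order-independent function of the index. |
| overlap `mode` | `"per-snp"` | Pooled overlap totals sum per-SNP counts (a concept under two SNPs counts twice). The `"deduplicated"` mode counts each concept once across SNPs; reports label which mode produced them. |

## Degenerate inputs and numerical choices

* `topN = 0` or `minDf > n_docs` give a valid empty graph, not an error;
  negative thresholds are errors.
* All orderings are explicit and total: reverse lists sort by `df`
  descending then numeric rsID ascending; related keywords by aggregate
  `co` then keyword id; exports sort nodes by weight descending then id and
  edges by endpoint pair. Radix sorting keeps comparisons locale-independent,
  so identical inputs give byte-identical outputs everywhere — index TSVs,
  GraphML, node-link JSON.
* Mention offsets are 0-based, end-exclusive, into `title + " " + abstract`.
  Annotation sources disagree about the separator, so a span/surface
  mismatch trusts the surface column with a warning; `strict = TRUE`
  escalates to an error (the synthetic generator's output parses strictly).
* Unknown query keywords raise a "never observed" error, distinct from the
  "filtered out by the graph thresholds" error for keywords absent from a
  filtered graph — the two situations call for different user action.

## The synthetic corpus generator

`generateCorpus(plantSpec(...))` emulates the upstream acquisition stage so
every downstream stage is testable offline. Each SNP receives a planted
keyword set; each of its documents includes planted keyword $k$
independently with strength $p_k$, plus a Poisson(λ) number of noise
keywords drawn uniformly (with replacement, deduplicated per document) from
the inventory of size $I$. By Poisson splitting the per-keyword noise count
is Poisson(λ/I) independently across keywords, so presence probabilities
are exactly
$q_k = 1 - (1 - p_k)\,e^{-\lambda/I}$, independent across keywords and
documents, giving the closed forms `expectedCounts()` reports:
$E[\mathrm{df}] = n\,q_k$ and $E[\mathrm{co}] = n\,q_{k_1} q_{k_2}$.
Surface forms carry occasional plural/case variants (rate 0.2 by default)
and duplicate mentions (probability 0.1), exercising normalization and
document-granularity counting without affecting the expectations. All
randomness is fixed by one seed; identical specs are byte-identical.

Default generator conditions — 10 SNPs, 8–20 documents each, a 26-keyword
inventory (12 diseases, 8 genes, 6 chemicals), 3 planted keywords per SNP
with strengths uniform on [0.3, 0.95], noise rate λ = 2 — were chosen to
look like the sparse end of real variant literature: small per-variant
document sets, a handful of genuinely associated concepts, and background
concepts appearing a couple of times per abstract. What the generator does
**not** emulate: natural-language text (abstracts are templated sentences),
annotator errors (offsets are exact by construction, concept ids never
wrong), citation or recency structure, and correlated noise between related
concepts. Passing tests therefore certify the counting, ranking, filtering
and serialization machinery — not robustness to noisy annotation, which is
the upstream annotator's responsibility.

## Validation protocol

The test suite validates the pipeline at these sizes (also recomputed from
scratch by `scripts/acceptance.R`):

* **Oracle equivalence**: on 200 random corpora (1–4 SNPs, up to 25
  documents each, up to 50 keywords, noise rates 0–4), `df` and `co` match
  an independent brute-force recount — a binary document-by-keyword
  incidence matrix with `df = colSums` and `co = crossprod` — exactly, a
  different computational route from the per-document pair accumulation in
  the package.
* **Bounds and consistency**: the co-occurrence bounds on every stored pair
  across 60 corpora; exhaustive agreement of profiles, reverse lists and
  SNP counts (including ordering and tie-breaks) across 20 corpora.
* **Planted-truth recovery**: 50 zero-noise corpora with strengths
  (1, 0.4, 0.1) and 15 documents per SNP — the top keyword of every SNP and
  the top SNP of every strength-1 keyword must equal the planted optimum in
  all runs (with strength 1 the dominant count is deterministic, so any
  miss is a defect, not sampling noise); under noise λ = 2 with 200
  documents per SNP, realized `df/n` must lie within 3 binomial standard
  errors of $q_k$ for ≥ 95% of keyword–SNP pairs.
* **Round-trips and determinism**: PubTator write/read and GraphML
  export/parse-back identities on 100 generated instances; repeated exports
  and full index rebuilds byte-identical.

## Known limitations

* Keyword merging is only as good as the concept identifiers; mentions
  lacking ids merge by normalized text, so near-synonyms with different
  wording remain distinct keywords (exact matching is also what the overlap
  comparison uses, deliberately).
* Raw document frequency favours heavily studied topics; a keyword common
  across all of biomedicine ranks high for many SNPs. The global graph's
  exclusion thresholds mitigate the display problem but no statistical
  correction is applied.
* HGVS variant notation is not resolved; variants enter as rsIDs (a
  digits-only form is coerced with a warning) or via a user-supplied
  mapping table.
* The co-occurrence store is sparse but quadratic per document in the
  number of distinct keywords; abstracts keep this small, full text would
  not.
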