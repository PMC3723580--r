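---
title: "Methods: integrated correlation, coexpression and enrichment analysis of multi-omics tables"
author: "OmicsBridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated multi-omics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OmicsBridge)
```

## The data model

One omics *layer* is a numeric matrix: rows are molecules, columns are
experimental conditions or time points, in upload order. The layer fixes
the identifier namespace — transcripts carry Entrez Gene IDs (digits),
proteins UniProtKB accessions, metabolites PubChem CIDs (digits) — and the
namespace is enforced at load time, so a file mixing identifier types is
rejected rather than silently reinterpreted. Condition labels are opaque
strings: time ordering is taken from column order, never parsed from
labels. Empty cells and the token `NA` are missing measurements; any
other non-numeric cell is a parse error naming its row and column, because
a silently coerced zero would flow into every downstream correlation.
The tool the package models did not document a missing-data policy, so the
policy here is the package's own: accept missing cells and handle them
per-analysis (pairwise-complete correlations; dropped rows in
coexpression).

Reference annotation lives in a `KnowledgeBase`: five flat TSV tables
(transcript–protein–metabolite relation triples, metabolite pathway sets,
GO annotations, OMIM-style phenotype records, name synonyms). A missing
table disables the analyses that need it rather than failing the load.
Flat files were chosen over a relational store to keep the artifact
dependency-free and diffable; the `evidence` column of the triples is a
free string so that a future online text-mining source can plug in without
a schema change. Parsers for native KEGG/HumanCyc/OMIM/UniProt dump
formats are deliberately out of scope; users convert snapshots to the
five-column schema.

## Correlation networks

Pearson correlation is computed between every molecule pair over
pairwise-complete conditions (`stats::cor`). Three situations make a
correlation *undefined*: fewer than `minSharedObs` (default 3) jointly
observed conditions, a zero-variance profile over the shared conditions,
or both. Undefined entries are `NA`, never 0 — a crucial distinction,
since 0 is a legitimate correlation and `NA` must produce *no edge* while
leaving the rest of the run intact (one flat housekeeping gene should not
abort an analysis).

An edge requires r **strictly greater** than the threshold (default 0.9).
Only positive correlations connect by default; the original tool drew only
positive correlations and never addressed negative ones, so signed
thresholding is the default and `useAbsolute = TRUE` exposes the
absolute-value variant as an explicit choice rather than a silent one.
Edges are undirected and stored once, canonicalised by lexicographic ID
order.

In two-layer runs the missing layer is bridged: every molecule of the
absent namespace that co-occurs in a relation triple with at least one
input molecule enters the network as a *literature node*, joined by
unweighted literature edges (dotted in the SVG). Bridged molecules carry
no expression vector, so they can never form correlation edges. All
co-occurring molecules are returned — no per-molecule cap — and the
threshold/size options of the network prune the display instead.

Clusters are connected components of size ≥ 2, ranked by decreasing size;
singletons are drawn but not ranked. Ties on size break by the
lexicographically smallest member, purely for determinism. Literature
edges participate in connectivity by default (bridged metabolites appear
inside clusters), with `includeLiteratureEdges = FALSE` to cluster on
measured correlations only — the underlying question (is a dotted edge
"real" connectivity?) is genuinely open, so it is a flag, not a fixed
decision. Component extraction delegates to `igraph::components`; the
test suite checks it against an independent transitive-closure oracle on
hundreds of random graphs.

The layout is a small force-directed loop: all pairs repel with magnitude
proportional to `repulsion`/d², edges attract with magnitude d/`attraction`,
displacement capped by a geometrically cooling step. The defaults 160
(repulsion) and 80 (attraction) follow the original tool's network
controls, and the 0.01/0.1 scale factors place the equilibrium edge length
at a few units for networks of tens of nodes. Initial positions are the
only random element and come from a dedicated seed, so layouts (and the
SVG bytes derived from them) are reproducible. A graph-description-language
export for a proprietary renderer was dropped in favour of SIF plus the
internal SVG/PNG writer; SIF imports directly into Cytoscape.

## Coexpression heatmaps

Rows and columns are clustered by agglomerative hierarchical clustering on
Euclidean distances. The distance is the documented choice; the linkage
is not, so complete linkage — the common heatmap default of the R stack
the original tool ran on — is the default with single/average available.
Clustering delegates to `stats::hclust`; when two merge candidates are at
exactly equal distance the library's own deterministic tie-break is
adopted rather than re-implementing a bespoke rule, since ties occur only
on degenerate (hand-crafted) inputs and determinism is what matters.
Oracle tests compare cophenetic distances against a naive agglomeration on
tie-free random matrices.

Cells are coloured by the raw input value by default ("heat colorized by
the input expression value"): the global minimum maps to cyan, the maximum
to pink, linearly in RGB; a constant matrix maps everything to the
midpoint 0.5 rather than dividing by zero. Row z-scoring
(`scale = "row_z"`) is available behind a flag; it drops constant rows
(their z-score is undefined) and guarantees mean 0, variance 1 per
retained row. Rows with any missing value are dropped with a warning —
imputation would silently invent data in a display whose whole point is
the observed values. Row edge colours encode the omics source: green
(transcriptomics), red (proteomics), blue (metabolomics). No optimal
leaf-order rotation is attempted.

## Pathway enrichment

Enrichment mode takes an overall metabolite set A (size `N`) and a
significant subset B (size `n`, strictly a subset — offenders are listed
in the error). For a pathway with `m` members in A and `x` in B the score
is the lower-tail cumulative hypergeometric probability P(X ≤ x), and the
table is ranked by it, descending. The lower tail — rather than the
conventional upper tail — is the reading consistent with the tool being
reproduced: its formula text asks for "x or fewer" successes and its
worked example ranks a probability of 0.74 near the top of a descending
list, which only the lower tail produces. Because a lower-tail number
read as a p-value misleads, the conventional upper tail P(X ≥ x) is
always reported in the next column. `N` is the size of the uploaded
overall set, not of the whole pathway database, following the formula's
own definitions. Pathways sharing no member with A (`m = 0`) are omitted;
no further minimum-m filter is applied. Ranking ties break by pathway ID.
Normal mode needs only set A and ranks by coverage `m`. Pathway topology
or impact analysis is explicitly out of scope — this is set
over-representation only.

The tails themselves are computed in-package by log-space summation of the
hypergeometric PMF via `lchoose`, with the largest term factored out of
the log-sum-exp; this is exact to ~1e-15 against integer-arithmetic
summation for small populations (verified exhaustively for N ≤ 25) and
stable for populations up to ~1e5.

## GO enrichment

Per term: a 2×2 table of query/background × in-term/not-in-term, one-sided
(greater) Fisher's exact test, which for fixed margins is the upper
hypergeometric tail. The default method is EASE — replace the observed
success count k by max(k − 1, 0) before computing p — mirroring the
"modified Fisher's exact test" of the DAVID service the original tool
called; a term supported by a single gene is thereby deflated to p = 1.
Plain Fisher is a flag. FDR is Benjamini–Hochberg (`stats::p.adjust`)
computed *within* each ontology (BP/CC/MF), matching the sectioned
three-ontology report format. Terms with p < 0.05 form the display set
(bar chart of −log10 p); the full table is retained. The background
defaults to every gene annotated in the knowledgebase — the original
service never documented its background, and "all annotated genes" is the
choice that makes the test self-contained; any explicit background is
accepted, and query genes outside it are an error at the function level
(the pipeline first intersects the input with the background, logging the
drop, as an annotation-coverage step).

## Phenotype mapping

Transcripts match phenotype records by gene identity; proteins are first
translated to genes through the relation triples (a protein with no gene
relation is skipped with a warning — inventing a mapping would be worse).
Metabolite-only input is rejected up front: phenotype records relate
*genes* to phenotypes. One output row per matched phenotype aggregates
all matching inputs, sorted by phenotype ID, with an external reference
URL per record.

## The capability matrix and the pipeline

Seven modes (T-P-M, T-P, P-M, T-M, T, P, M) × five analyses are encoded in
`capabilityMatrix()`, including the bridging annotations for the three
two-layer modes. `planAnalyses()` fails fast, quoting the cell, when a
forbidden analysis is requested. GO enrichment consumes genes only, so in
mixed modes it runs on the transcriptomics layer alone. The pipeline runs
stages in a fixed order (bridge → correlation → clusters → coexpression →
enrichments → phenotype), writes one file per table/image plus
`manifest.json` (parameters, completed stages, outputs — no timestamps, so
manifests are seed-reproducible), logs to stderr and `run.log`, and aborts
naming the failing stage. Input files are not copied into the output
directory unless asked — the modelled service deleted uploads after
processing, and the local analogue of that confidentiality default is to
write no input copies. A thin `optparse` CLI
(`inst/scripts/omicsbridge.R`) wraps `runPipeline` for shell use.

## Synthetic data and what the tests do (and do not) show

`generateKnowledgeBaseFixture()` writes a seeded synthetic knowledgebase
(identifier pools, triples, pathways, GO terms, phenotypes, synonyms) with
one planted enriched pathway and one planted GO term recorded in a
manifest; `simulateOmics()` generates omics tables as latent condition
profiles plus i.i.d. Gaussian noise, with block membership recorded as
ground truth. Latent profiles are drawn once per design from a standard
normal, centred, orthogonalised (Gram–Schmidt) and scaled to unit
variance: orthogonal profiles make between-block population correlations
zero, so recovery tests measure the method, not profile collisions. With
unit-variance profiles and the default `noiseSd = 0.05`, within-block
correlations concentrate near 1/(1 + 0.05²) ≈ 0.9975, comfortably above
the 0.9 threshold — these generator defaults define the validation
conditions and are not tuned per test.

What this emulates: block-correlated expression across layers, planted
set over-representation, deterministic annotation joins. What it does
not: heavy-tailed noise, batch effects, dependent genes within GO terms,
realistic pathway overlap structure, identifier ambiguity at scale.
Passing the recovery suites therefore demonstrates correctness of the
algorithms under their stated model, not robustness on noisy real-world
data.

Problem sizes used by the validation suite — exhaustive hypergeometric
checks to N = 25, 500 Fisher tables, 200 random networks of up to 50
nodes, 50 two-block recovery seeds, 100 planted-enrichment and 200 null
replicates — were chosen as the smallest scales at which each property is
exercised across its full combinatorial range; all complete in seconds.

## Numerical and degenerate-input choices

* Hypergeometric tails: log-space `lchoose` summation, infeasible terms
  contribute zero, results clamped to [0, 1]; full-support and
  empty-category cases short-circuit to exactly 1.
* Correlations: strict `>` at the threshold; exact ties at the threshold
  are excluded (a tie at 0.9 is "not greater than 0.9").
* Undefined correlations produce no edge, never an error or a zero.
* CSV writing emits the shortest decimal that round-trips the double
  (15 significant digits, widened to 17 where needed), so
  write∘read is the identity on finite values.
* Heatmap colour scale: degenerate (constant) matrices map to 0.5.
* All stochastic components (fixture generation, simulation, layout) take
  explicit seeds and restore the caller's RNG state afterwards.

## Known limitations

* Human-centric identifier conventions only; no cross-species support.
* Bridged molecules never influence correlation values (they have no
  expression vector) — they only add connectivity.
* The lower-tail pathway "probability" is a ranking score, not a p-value;
  users wanting significance should read the upper-tail column.
* No live database access of any kind: annotation quality is exactly the
  quality of the local snapshot provided.
* The force layout is for orientation, not publication-grade graph
  aesthetics; SIF export exists precisely so a dedicated editor can take
  over.
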