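---
title: "Cell-type similarity and network-based cell-type prediction with ctsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type similarity and network-based cell-type prediction with ctsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsim)
```

## The problem

Two questions come up constantly in cell reprogramming and cancer
heterogeneity work: *how similar are two cell types*, and *which cell type
does a list of highly expressed genes point to*? Direct assays cannot cover
the thousands of recognized human cell types, so ctsim answers both
computationally, from two public resources: the structure of a cell-type
ontology (a DAG of terms linked by `is_a` relations, such as the Cell
Ontology with its roughly 2,160 terms) and a compendium of per-cell-type
TF→gene regulatory edges with confidence scores (such as the FANTOM-derived
networks covering 258 normal and 130 cancer cell types).

## Semantic similarity over the ontology

Every ontology term `t` is assigned an occurrence probability

$$P(t) = \frac{|\mathrm{desc}(t)|}{N},$$

where `desc(t)` is the *inclusive* descendant closure of `t` (the term plus
all its progeny) and `N` the number of non-obsolete admitted terms. Its
information content is `IC(t) = −log P(t)` in nats: 0 at the root, maximal
at the rarest leaves. For a pair `(t, u)` the most informative common
ancestor (MICA) is the shared ancestor of maximal IC, and the Lin similarity
is

$$\mathrm{sim}(t, u) = \frac{2\,IC(\mathrm{MICA})}{IC(t) + IC(u)} \in [0, 1].$$

Assumptions worth spelling out:

* **Closure convention.** Closures are reflexive, so `P(leaf) = 1/N > 0`
  and IC is always finite; a term is its own MICA, making
  `sim(t, t) = 1` consistent with the formula for every non-root term.
* **Root case.** At the root the ratio is 0/0; self-similarity is *defined*
  as 1. A pair whose only shared ancestor has zero IC scores 0.
* **Edges admitted.** Only `is_a` edges by default — the conservative
  backbone reading. `part_of` / `develops_from` can be admitted through
  `parse_obo(..., relation_types = )`; doing so changes descendant counts
  and therefore every IC.
* **Log base.** Natural log. Lin's ratio is base-invariant, so the choice
  affects only displayed IC values, never similarities.
* **Obsolete terms** are dropped before `N` is counted.
* **Multiple roots** can occur in synthetic fixtures; a pair with no common
  ancestor gets similarity 0 (no shared information) with a warning.

A score below 0.1 is read as a weak/strange relationship, 0.1–0.4 moderate,
0.4–0.7 significant, and 0.7–1 a strong correlation
(`similarity_band()`). All-vs-all matrices feed `score_distribution()`
(strict upper triangle, each unordered pair once; default bin width 0.01 —
the published distribution figure does not state its binning, so this is a
display default, not a modelling choice) and `cluster_cells()`, which
clusters matrix *rows* by Euclidean distance. Only the distance is fixed by
the method description; the linkage is not, and we default to average
linkage as the usual choice for similarity-profile clustering (complete,
single and Ward are available). `rank_similar()` breaks score ties
lexicographically by term id so rankings are reproducible.

## Regulatory networks: filtering, specificity, sharing

Confidence scores in FANTOM-style compendia show an evident fault at 0.01;
edges below it are treated as weak or noise. `filter_edges()` therefore
removes edges with score strictly below the threshold (exactly 0.01 is
kept). Filtering is idempotent and monotone in the threshold.

`cell_specific_networks()` then keeps, within each category (normal and
cancer processed independently throughout), only the `(tf, target)` pairs
occurring in exactly one cell — each cell's unique regulatory signature.
`shared_network()` reports the edges two cells have in common. Sharing is
computed on *filtered* networks, before unique-edge extraction: after
extraction no edge could be shared by construction, so the two views are
complementary (specific networks for prediction, filtered networks for
sharing). A shared edge is displayed with the smaller of the two cells'
scores — a conservative choice, since the displayed score should not exceed
the confidence either cell assigns. Duplicate `(tf, target)` rows within
one cell collapse to the maximum score on load; gene symbols are uppercased
and trimmed, with no alias resolution.

`common_network_label()` annotates a cell pair as "Common Network" (both
have networks and share an edge), "`<cell>` Network" (exactly one has a
network) or "No Network". When both cells have networks but share no edge
we also report "No Network", since the label describes the shared network's
availability.

## Predicting cell types from a gene list

A query `Q` (normalized, deduplicated symbols; `num(Q)` counts all
submitted distinct genes, whether or not they occur in any universe) is
scored against each cell's gene universe `M` — every TF and target in its
cell-specific network, the inclusive reading of "the genes of the network"
and the one validated by the planted-query simulations:

$$R_{net} = \frac{|Q \cap M|}{num(M)}, \qquad
  R_{query} = \frac{|Q \cap M|}{num(Q)}.$$

Candidates are ranked by `R_net` descending (the primary column of the
reported tables), ties by `R_query`, then cell id. Both are raw ratios: no
enrichment p-value or multiple-testing correction is applied, by design.
Queries under 10 genes warn, as single-gene swings then move the ratios by
more than 10 percentage points. `radar_series()` exposes the two ratio
vectors over the top-ranked cells as plot-ready series ("net map" and
"gene list map"), drawn by `plot_radar()`.

## What the synthetic generators emulate

`generate_dag()` grows a single-root DAG: term *i* draws 1–`max_parents`
parents uniformly from earlier terms. It reproduces the structural features
the similarity machinery depends on — acyclicity, a single root, multiple
inheritance — but not the Cell Ontology's depth profile or branching
anatomy, so absolute score distributions on synthetic DAGs are not
comparable to CL's.

`generate_compendium()` samples per-cell edges from a TF×gene grid with
scores from a mixture of 85% Uniform(0.01, 0.4) and 15% Uniform(0, 0.01),
mimicking the 0.01 fault; it does not model FANTOM's score distribution
beyond that threshold structure, nor TF out-degree heterogeneity.

`generate_query()` plants `⌈f·n⌉` genes from one cell's universe and pads
with `DECOY_`-prefixed symbols guaranteed absent from all universes. The
recovery simulations use 8 cells drawn from a 40 TF × 200 gene pool at 50
edges per cell, so cell-specific universes are largely distinct — the
regime the real compendium (tens of thousands of genes) operates in. With a
deliberately tiny symbol pool, universes overlap heavily and recovery
degrades; that reflects the fixture, not the scoring rule. Consequently,
passing tests demonstrate correctness of the computations and recovery
under realistic sparsity, not performance on any particular real
compendium release.

All generators are fully deterministic under their `seed` argument.

## Numerical and degenerate-input choices

* Cycle detection at parse time (Kahn's algorithm) rejects cyclic inputs,
  naming one offending term.
* Edges pointing at obsolete or unknown terms are dropped with a warning
  rather than failing the whole parse.
* An empty filtered network is retained (with a warning) so downstream
  joins keep the cell visible with zero edges.
* Exported tables round floats to 4 decimals — the precision of the
  published similarity tables — while full precision is kept in memory.
* Problem sizes in the test-suite simulations (DAGs of ≤ 50 terms,
  compendia of ≤ 20 cells, 100 planted-query replicates) were chosen so
  the whole suite exercises every property at desk scale.

## Known limitations

* Reproducing published similarity values for real cell-type pairs depends
  on the ontology release: descendant counts, hence IC and Lin scores,
  drift between releases. The reference checks in the test suite accept
  ±0.02 and require a user-supplied `cl.obo` snapshot.
* Only Lin similarity is implemented; Resnik and Jiang–Conrath variants are
  deliberate non-goals, as is OWL parsing and synonym resolution.
* The prediction ratios carry no null model; a high `R_net` against a tiny
  universe is not evidence of enrichment, only of overlap.
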