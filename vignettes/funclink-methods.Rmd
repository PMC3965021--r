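---
title: "Methods: calibrating, integrating and mining cofunctional gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrating, integrating and mining cofunctional gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funclink)
```

## The problem

A cofunctional gene network is an undirected, weighted graph over a genome in
which an edge asserts that two genes participate in the same biological
process, with the weight measuring confidence. Such networks are built by
combining heterogeneous evidence — co-expression across microarray
compendia, co-inheritance across reference genomes, co-citation in the
literature, protein interactions, and so on — and they power
guilt-by-association (GBA) genetics: a gene is a candidate for a pathway or
phenotype insofar as it is strongly linked to that pathway's known members.

funclink implements the full construction-and-use cycle for such networks at
whatever scale the user's data supports: raw-evidence scoring, benchmarking
against a gold standard, probabilistic integration, evaluation, and three
network-search tools. Everything is testable offline because a seeded
synthetic-data module generates all input types with planted structure.

## Gene pairs, networks and gold standards

All containers are built on canonical unordered pairs: identifiers are
uppercased and endpoints stored in lexicographic order, so `(x, y)` and
`(y, x)` are the same link; self-links are rejected everywhere. A
`fl_network` is an edge list with a data-type tag; a gold standard is a pair
of disjoint sets of pairs derived from pathway annotations by
`gold_from_annotations()`: **positives** are pairs co-annotated to at least
one pathway, **negatives** are pairs where both genes are annotated somewhere
but never share a pathway. Requiring both genes of a negative to be
annotated is the standard construction — an unannotated gene is ignorance,
not evidence of non-interaction.

## Calibration: from raw scores to log-likelihood scores

Each evidence type produces raw scores on its own scale (Pearson *r*, mutual
information, −log~10~ *p*). Only the *ranking* of pairs is used downstream.
`calibrate()` sorts the gold-evaluable pairs by descending raw score, splits
them into consecutive disjoint bins of `bin_size` pairs (default 1000; use
much smaller bins for toy data), and scores each bin by its log-likelihood
score,

$$\mathrm{LLS} = \ln \frac{(p + c)\,/\,(n + c)}{P\,/\,N},$$

where $p$ and $n$ are the bin's positive and negative counts, $P$ and $N$
the gold-standard totals, and $c$ a symmetric pseudocount (default 0.5)
keeping empty cells finite without materially distorting bins of realistic
size. Natural-log units are used throughout. An LLS of 0 means the bin
carries no information beyond the prior.

Three choices here were genuinely open and are worth recording:

* **Monotone smoothing.** Sampling noise can make a lower-ranked bin
  outscore a higher-ranked one even when the evidence is genuinely
  monotone. We enforce a non-increasing LLS sequence by
  pool-adjacent-violators: violating neighbours are merged and the pooled
  LLS recomputed from the *summed counts*, so the merged contingency — not
  an average of logs — defines the pooled value and total counts are
  preserved exactly.
* **Bin composition.** Bins count gold-evaluable pairs only. If bins were
  cut over all pairs, their information content would depend on how much of
  the evidence the gold standard happens to cover, confounding calibration
  with gold coverage.
* **Score transfer.** `apply_calibration()` assigns an LLS to *every*
  scored pair, evaluable or not, by interpolating linearly on mean raw
  score between pooled-bin knots; scores beyond the knot range clamp to the
  first/last bin's LLS. Pairs with LLS ≤ 0 are dropped — they carry no
  positive evidence. Linear interpolation (rather than a step function)
  avoids ties between pairs that straddle bin boundaries; because the knot
  values are monotone, raw-score order can never invert LLS order.

Ties in raw score are broken by canonical pair order everywhere, so every
stage is deterministic.

## Integration: weighted sum with rank decay

Given one LLS per evidence type for a pair, sorted $L_0 \ge L_1 \ge \dots$,
the integrated score is

$$WS = L_0 + \sum_{i \ge 1} \frac{L_i}{D \cdot i}, \qquad D \ge 1 .$$

$D$ interpolates between naive summation of log-odds ($D = 1$, appropriate
if evidence types were independent) and taking only the single best line of
evidence ($D \to \infty$, appropriate if they were fully redundant). A
geometric decay $L_i / D^i$ is available as an option and recorded in the
output attributes. Edges with $WS$ below the retention threshold `T`
(default 0) are dropped; per-network LLS ≤ 0 edges were already dropped, so
the default keeps any pair with positive integrated log-odds. Multiple
datasets of one type must be pre-integrated within-type with the same
function, so each tag contributes one value; within- and cross-type
integration default to the same `D`, though nothing prevents different
values.

The paper trail for $D$ is deliberately empirical: `tune_D()` grids over
candidates and picks the value maximizing the area under the cumulative
precision-recall curve on a *held-out* gold standard, with ties going to the
smallest $D$. Keeping the validation gold standard disjoint from the
calibration one is the caller's responsibility.

## Evaluation

**Precision-recall.** `pr_curve()` walks the ranked edges cumulatively and
records, at every `bin_size` edges, precision over the gold-evaluable edges
seen so far and recall as *genome coverage* — the fraction of the genome's
coding genes (an explicit `genome_size` argument; 5887 is the conventional
yeast figure) touched by at least one edge. Unevaluable edges advance
recall but not the precision denominator.

**LOO-GBA AUC.** `loo_gba_scores()` scores every network gene by its summed
link weight to phenotype members *other than itself* and computes the
ROC AUC of that single ranking with members as positives, using the
Mann–Whitney midrank formula. Because a member's own membership cannot
contribute to its score, each member is implicitly held out — leave-one-out
in one pass. Genes absent from the network are excluded from the ranking;
they have no links to score, and including them would only shift every AUC
by a constant attributable to coverage, which `pr_curve()` already measures.
One consequence worth knowing: at small network sizes the chance level sits
slightly *below* 0.5 (members have one fewer potential partner than
non-members); the deficit shrinks as $1/\text{(set size × genome size)}$
and is invisible at genome scale.

**Extreme-tail phenotype sets.** `extreme_tail_sets()` turns one
quantitative parameter (e.g. a morphology screen column) into up to two
candidate gene sets by fitting a normal location/scale and cutting both
tails at a per-side probability threshold (10⁻⁴ is the conventional
morphology choice, 10⁻⁷ for sensitivity screens), dropping sets below
`min_size` (default 5). One-sided tails per side are used, which is what
makes "two sets per parameter" the natural outcome; an empirical-quantile
mode is available when normality is implausible.

**Paired comparison.** `wilcoxon_signed_rank()` compares two networks'
per-phenotype AUC vectors with a one-sided signed-rank test. For up to 25
non-zero differences the exact null distribution of the positive-rank sum
is computed by polynomial convolution over (doubled) midranks — exact even
under ties, which the textbook enumeration and the standard implementation
both decline to be; beyond that, a normal approximation with tie correction
and continuity correction takes over.

## Hypothesis generation

All three tools are deterministic and share one scoring contract with the
benchmark (summed LLS, never edge counts or maxima):

* `find_new_members()` ranks non-query genes by summed linkage to the query
  set — the same scorer as LOO-GBA, so the prediction tool is exactly the
  thing the benchmark validates.
* `infer_functions()` tests the query gene's neighbors for enrichment in
  each annotation term by the hypergeometric upper tail and lists the 30
  most enriched terms (configurable). The universe is the annotated network
  genes; restricting to network genes avoids rewarding terms merely for
  being large outside the network, and the caller can pre-filter the
  annotation collection to change the background.
* `find_modulators()` tests every hub-neighbor set against a DEG query the
  same way. Hub-neighbor sets include the hub by default (the hub's own
  transcriptional state is informative when present, harmless when not);
  the flag `include_hub = FALSE` reverses this. A hub need not be a DEG to
  rank first — that is the tool's point. The universe defaults to the
  network's genes; passing `universe_size` switches to a genome-wide
  universe in which all DEGs are assumed to lie. P-values are ranked raw,
  with Benjamini–Hochberg values reported as a column: the search is a
  ranking exercise, not a discovery procedure with error control, but the
  adjusted column lets users impose one.

## The synthetic-data generators

`make_network()` plants disjoint modules: within-module pairs are linked
with probability `p_in` and weights from Normal(2.0, 0.5), background pairs
with probability `p_out` and Normal(0.5, 0.5), truncated at zero. The
constants are arbitrary and recorded; all tests depend on the *ordering*
they induce, never the values. `make_expression()` gives module genes a
shared latent factor, $x = \sqrt{\rho}\, f + \sqrt{1-\rho}\,\varepsilon$,
so the expected within-module Pearson correlation is exactly `rho`.
`make_gold()` treats modules as pathway annotations. `make_deg_query()`
samples a hub's neighbors (never the hub) plus noise genes, planting a
modulator that is not itself differentially expressed.

Every generator takes an explicit seed, uses a private RNG scope, and
restores the caller's random state. What the generators *do not* emulate:
scale-free degree distributions, correlated noise across evidence types,
microarray normalization artifacts, annotation bias. Passing tests
therefore demonstrate that the machinery recovers planted structure under
clean conditions, not that any particular biological dataset will calibrate
well.

## Problem sizes used in the test suite

The suite runs entirely on synthetic data at deliberately small scale,
chosen so each property is measured where it is informative: calibration
worlds of a few thousand pairs with bins of 400–500 (null-calibration LLS
bounds), planted-module expression of 60 genes × 120 conditions at
ρ = 0.75 (end-to-end recovery, AUC > 0.9), modulator recovery over 100
seeds of a 200-gene background, and the chance-level GBA experiment with
200 random sets on a 200-gene random network. The acceptance script
(`scripts/acceptance.R`) re-runs the two boundary-value experiments from
scratch at those same sizes.

## Known limitations

* The per-data-type linkage-discovery algorithms for domain co-occurrence,
  gene neighborhood, genetic interaction, high-throughput and curated PPI,
  and protein-structure evidence are not reimplemented; those evidence
  types enter through the generic scored-pair interface
  (`read_evidence()`), and funclink's own scorers cover co-expression,
  phylogenetic profiles and co-citation.
* Plug-in mutual information is biased upward by roughly
  $1/(2N\ln 2)$ per degree of freedom at $N$ genomes; with thousands of
  reference genomes this is far below the rank resolution calibration
  needs, but for small genome panels a bias-corrected estimator would be
  preferable.
* Calibration assumes the gold standard is unbiased with respect to the
  evidence ranking; a gold standard enriched for well-studied genes will
  inflate LLS for literature-derived evidence.
* `integrate_networks()` materializes the union of all edge lists in
  memory; at a few million edges this is a few hundred MB, beyond which a
  chunked implementation would be needed.
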