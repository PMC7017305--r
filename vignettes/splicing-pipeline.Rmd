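---
title: "Methods: two-factor splicing-panel differential expression and PPI topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-factor splicing-panel differential expression and PPI topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicenet)
```

## Scope

`splicenet` analyzes deregulation of the splicing machinery (spliceosomal
snRNP complexes and auxiliary factors) in a two-factor microarray design:
central-nervous-system tissue (motor cortex, spinal cord) crossed with
disease state (CTRL, and the two transcriptome-defined sporadic-ALS
subtypes SALS1, SALS2). The pipeline has five stages — normalization,
panel restriction and probe collapsing, per-gene two-way ANOVA with
fold-change screening, gene-set overrepresentation, and first-order PPI
network topology — plus a synthetic-data generator that plants known
structure for validation.

## Normalization

Raw intensities are thresholded to 1, log2-transformed, and baselined by
subtracting each probe's across-sample median. Vendor suites typically
insert a per-sample percentile shift between the log2 and baselining
steps; because that step's exact dialect varies by tool, it is exposed as
the optional `percentile_shift` argument (nearest-rank percentile, e.g.
`0.75`) and is **off** by default, so the canonical path is exactly the
three explicit steps. After baselining every probe row has median zero;
note this invariant holds at probe level, not after probes are averaged
into gene rows.

Probes are restricted to an a-priori splicing-gene panel before testing,
and collapsed to genes by the per-sample arithmetic mean. Collapsing
happens before the ANOVA: the statistics below are gene-level. (In the
generator, a gene's probes share its cell means plus independent noise,
which makes the mean the correct collapsing estimator.)

## Differential expression

Per gene, `lm(y ~ tissue * state)` is fitted on the log2 scale and
effects are tested with marginal (Type-III) sums of squares under
sum-to-zero contrasts, via `car::Anova()`. Type III is the conventional
choice for unbalanced factorials with an interaction term; the design
here is unbalanced (18/13/10 and 17/13/10 samples per state within
tissue). Sequential Type-I sums of squares are available with
`ss_type = "I"`; the two agree exactly on balanced designs, which the
test suite exploits as a cross-check, alongside an independent
projection-matrix oracle.

Each effect's p-values are Benjamini–Hochberg adjusted **per effect**
across genes (whether the original tooling adjusted per effect or jointly
is not documented; per-effect is the standard reading and is what we
implement). Genes with zero residual variance are flagged `degenerate`
and reported with limiting values (F = 0, p = 1 when the effect carries
no variation; F = Inf, p = 0 otherwise) rather than erroring, so a
constant probe cannot abort a 2000-gene run.

Fold changes are differences of group means on the log2 scale, so the
linear magnitude is `2^|log2FC|`. A gene is a DEG for a contrast when its
relevant adjusted p is **strictly** below `alpha = 0.05` and its linear
|FC| is **strictly** above `fc_cut = 2` (the thresholds are worded as
strict inequalities, and a boundary gene with |FC| exactly 2 is
excluded). Which ANOVA effect gates which contrast is a genuinely open
choice; the default ties disease-state contrasts to
`q_state | q_interaction` and tissue contrasts to
`q_tissue | q_interaction`, with `gating = "any"` as the permissive
alternative. Selection is monotone: relaxing `alpha` or `fc_cut` never
removes a selected gene.

## Overrepresentation

DEG lists are tested against annotation terms with the one-sided
(greater) hypergeometric tail — Fisher's exact test for
overrepresentation; under-representation is out of scope. The reference
universe is the filtered array gene list (the panel), i.e. enrichment is
relative to what was measured, not to the genome. Bonferroni correction
runs over the terms actually tested: terms with no member in the universe
are skipped and excluded from the multiplier. The per-term direction
summary (up/down when more than half of the overlapping DEGs share a
sign, else mixed) is a reporting heuristic, not part of the test.

## Network topology

DEG seeds (duplicates averaged by log2FC mean) are matched into a scored
tissue-specific interactome and expanded to their first-order
neighborhood: seeds, direct partners, and all induced edges. The
interactome may first be filtered to the top 15% of edges; since the
exact percentile dialect of the original tooling is unpublished, the
default is a top-count rule (retain `ceiling(f*m)` edges by |score|, ties
broken by stable input order) with a nearest-rank value-threshold mode as
the alternative. Betweenness is unweighted and unnormalized; edge scores
drive filtering only, never path lengths.

The degree cutoff for hub-bottlenecks is `mean + 2*SD` of the network's
degree distribution using the **population** SD (the node set is the
entire population, not a sample); `sd_sample = TRUE` switches to N-1.
The worked star-graph example (cutoff exactly 4.0 on K1,4) depends on
this convention. Nonhub-bottlenecks must lie below the cutoff, have
positive betweenness in the top 50% of the distribution (descending rank
<= ceiling(N/2); the separate "with a betweenness value" clause is read
as b > 0), and touch at least two hub-bottlenecks. The cutoff is frozen
per network: deleting a hub does not re-classify other nodes unless the
topology is recomputed.

Degree and betweenness are computed on the assembled first-order network.
One consequence worth noting: a node guaranteed to be a hub on the *full*
interactome need not clear the cutoff inside a first-order subnetwork,
whose neighborhood-biased degree distribution raises `mean + 2*SD`. The
synthetic generator's planted-hub guarantee therefore holds on the
unfiltered full graph, which is where the end-to-end validation asserts
it.

## The synthetic generator

`design_spec()`/`simulate_expression()` draw probe intensities
`2^(baseline + cell shift + noise)` with i.i.d. Gaussian noise on the
log2 scale — the common microarray assumption. Defaults are fixed once:
baseline 7 (mid-range log2 intensity), noise SD 0.5 (typical residual
log2 spread for arrays), 2 probes per gene, and the cohort's unbalanced
group sizes, which deliberately exercise the unbalanced-ANOVA code path.
Planted effects are declared per gene as cell-shift matrices constrained
to their kind (tissue main, state main, interaction), and the truth table
is derived from the additive decomposition of the summed shifts, so
unplanted genes are all-negative by construction. No effect-size
distribution for real DEGs is available, so the planted 4-fold shifts are
chosen for testability, not realism.

`simulate_interactome()` grows a connected preferential-attachment graph
(igraph), then adds attachments to each planted hub until it clears the
`mean + 2*SD` cutoff, and scores edges i.i.d. standard normal (the
original database's score semantics are not reproduced).
`simulate_annotations()` plants one term verbatim and samples background
terms uniformly (sizes 5–50). All randomness flows from a single integer
seed through one generator; identical seeds give bit-identical output.

What the generator does **not** emulate: scanner artifacts, dye and
spatial effects, correlated probes, heavy-tailed noise, annotation
hierarchies, or biologically structured interactome scores. Passing tests
therefore validate the statistical machinery and its contracts, not
recovery of the original cohort's specific gene lists — those depend on
the external accessions and database releases and are explicitly not
reproduced.

## Validation sizes and numerics

The test suite uses: 2000 null genes at the cohort layout for ANOVA
calibration (per-effect rejection at raw p < 0.05 within [0.035, 0.065]);
1000 genes with 100 planted 4-fold state effects for recovery
(sensitivity >= 0.9, realized FDR <= 0.10 at BH 0.05 and FC > 2);
exhaustive hypergeometric-tail enumeration for all universes N <= 25
(agreement to 1e-12); 100 random graphs of <= 7 nodes against a
simple-path-enumeration betweenness oracle (exact agreement); hand-computed
factorial and graph worked examples; and a 300-gene end-to-end synthetic
study run twice for byte-identical determinism. These sizes keep a full
run in a few minutes on one core while leaving the Monte-Carlo bands
meaningful. Floating point in all output tables is written with 12
significant digits; comparisons in tests use the defaults of
`testthat::expect_equal()` except where exactness is the point.

## Known limitations

- No moderated (empirical-Bayes) variance shrinkage: the method under
  study is plain per-gene ANOVA, which is noisier at small n.
- The normalization's unspecified vendor step is approximated by an
  optional percentile shift; quantile normalization is intentionally not
  offered.
- Enrichment assumes term memberships are correct and independent of the
  DEG selection; no hierarchy-aware pruning.
- Topology classes depend on the assembled network's degree distribution,
  so they are not comparable across networks of very different density.
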