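---
title: "Unifying gene annotations across assembly versions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unifying gene annotations across assembly versions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(liftmerge)
library(dplyr)
```

## The problem

Crop genome projects tend to reformulate their gene models with every
assembly release, often without publishing a mapping to the previous
catalogue. Experimental results keyed to the old identifiers — expression
matrices, markers, structure predictions — then become hard to reuse, and
genes that the new annotation pipeline missed silently disappear. A concrete
instance is the potato double-monoploid reference, where two v4-era
annotation sets (one with full mRNA structures, one CDS-only) coexist with a
newer long-read assembly whose gene models were predicted afresh.

`liftmerge` implements the reconciliation protocol for this situation. Its
inputs are GFF3 files that all live on the *same* (new) assembly:

* a **query** set — the old annotation transferred onto the new assembly by
  a liftover tool, possibly in several *flank variants* (liftover runs that
  padded each gene with 0, 500, ... nt of flanking sequence before
  alignment), plus the list of query genes the liftover failed to place;
* a **target** set — the annotation native to the new assembly.

The output is a unified annotation: all target models, plus the query genes
the target annotation has no counterpart for, carried over under their
original identifiers, together with a translation table linking every
identifier across the sets.

## The model

For a query gene $q$ and target gene $t$ on the same sequence, the overlap
fraction is

$$F(q,t) \;=\; \frac{|q \cap t|}{|q|},$$

the intersection length of the two gene spans divided by the query gene-span
length — the minimum-overlap fraction familiar from `bedtools intersect -F`.
Overlap is computed on gene spans (not exon unions) and is strand-agnostic
by default, matching the bedtools defaults the protocol was defined with; a
same-strand mode is available for stricter reruns.

Each query gene's best coverage $F^\ast = \max_t F(q,t)$, taken in the flank
variant where it is highest, drives a four-way classification:

| fate | rule | action |
|------|------|--------|
| `matched` | $F^\ast \ge F_\text{match}$ | keep the target model(s) |
| `rescued_overlapping` | $F_\text{int} \le F^\ast < F_\text{match}$ | add the query model |
| `rescued_intergenic` | mapped, $F^\ast < F_\text{int}$ | add the query model |
| `unmapped` | placed by no lift variant | translation table only |

The defaults are $F_\text{match} = 0.30$ (the calibrated optimum for the
potato v4/v6 pair) and $F_\text{int} = 10^{-4}$, a near-zero cutoff that
separates genes genuinely lying between target models from marginal
overlaps. Both are tunable through `merge_config()`; the only constraint is
$0 < F_\text{int} < F_\text{match} \le 1$. The categories are exhaustive and
mutually exclusive, so category counts always sum to the query universe, and
the unified gene count obeys

$$|\text{unified}| = |\text{target}| + |\text{rescued}| - |\text{collapsed pairs}|.$$

### Design choices in the open points

The protocol as published leaves several details open; the package fixes
them as follows, and each is testable in isolation:

* **Best-lift ties.** When two flank variants achieve the same $F^\ast$ for
  a gene, the configured `variant_preference` order decides; the default
  prefers the variant supplied first (conventionally the un-padded lift,
  whose coordinates carry no flanking-alignment artifacts).
* **Multi-target matches.** A query reaching $F \ge F_\text{match}$ against
  several targets is matched to *all* of them: each such target's
  translation row lists the query, so a many-to-fewer mapping (old models
  collapsing onto new ones) is representable without losing edges.
* **Rescued known pairs.** When the two query sources are linked by a known
  pair table and both members of a pair are rescued at overlapping
  positions, a single gene is emitted (first-column ID primary, partner
  recorded in `merge_collapsed_with` and the translation table). This keeps
  the unified set free of duplicated loci.
* **Boundary semantics.** Coordinates are 1-based inclusive throughout (the
  GFF3 contract); book-ended genes (`end + 1 == start`) do not overlap — at
  least one shared base is required, as in bedtools.
* **Provenance.** Every unified gene carries machine-readable attributes
  (`merge_origin`, and for rescued genes `merge_variant`, `merge_category`,
  `merge_f`), so downstream tools never need the run logs to know where a
  model came from.

## Threshold calibration

The match threshold is calibrated from a reference table of
known-equivalent query pairs (e.g. the published pairing of the two old
annotation sets). `sweep_threshold()` evaluates a grid of candidate
thresholds against the per-gene best-coverage data already computed — no
re-intersection — and reports, per threshold $f$:

* `n_query_matched`, `n_target_matched` — match counts at $\ge f$;
* `pair_concordance` — among pairs whose two members *both* map at
  $\ge f$, the fraction sharing at least one common target at $\ge f$.

The concordance is deliberately conditional. The unconditional fraction
(concordant pairs over all pairs) can only shrink as $f$ rises, because the
record set only shrinks; it would always be maximized at the smallest grid
value and could never justify an interior optimum. Conditioning on
both-mapped pairs lets a rising threshold *remove* spuriously mapped,
discordant pairs from the denominator, which is exactly the behaviour that
makes an interior threshold optimal. `select_optimal_threshold()` then
returns the smallest maximizer of concordance (preferring the most
permissive threshold among equally good ones), or alternatively the `knee`
of the matched-count curve — the grid point with the steepest drop per unit
threshold.

The default grid
`{0.0001, 0.001, 0.01, 0.05, 0.1, 0.2, 0.25, 0.3, 0.4, 0.5, 0.75, 0.9, 1}`
spans the conventional sweep range from $10^{-4}$ to 1 with extra
resolution around the region where optima are typically found; it is fully
configurable.

## What the synthetic fixtures emulate

Because the real inputs (two genome releases plus liftover runs) are far
too large for routine testing, the package ships a first-class generator
with analytic ground truth:

* `simulate_annotation()` lays out non-overlapping gene models
  (mRNA/exon/CDS children, or CDS-only rows to mimic a CDS-only source)
  with configurable length and gap ranges.
* `sample_edits()` + `apply_edits()` derive a target set by the documented
  reannotation events — keep, shift, resize, split, merge, delete, move,
  strand inversion, chimeric fusion with a neighbour, and lift failure —
  and compute, from the edit geometry and the configured thresholds
  *alone*, the gene fate and overlap-graph cardinality (`1:1`, `1:N`,
  `N:1`, `N:M`) the pipeline must recover. The truth table is therefore a
  genuine oracle: it never runs the code it checks.
* `simulate_evidence()`, `simulate_paired_set()` and
  `simulate_calibration_truth()` plant transcript support, a second query
  source with a known-pair table, and a calibration fixture whose pairs
  diverge only below a chosen threshold.

Two generator conventions matter for interpreting results. First,
`merge`/`chimera` edits consume the immediate right neighbour, which keeps
every edit's geometry independent of all others — that independence is what
makes 100% analytic truth recovery a fair expectation. Second, the strand
inversion is realized as a strand flip in place (window = the gene's own
span): after a real inversion both the lifted query and the target end up
at the same re-mapped locus, so the observable signal at the gene level is
the strand difference, which is exactly what the same-strand regression
mode must detect. A literal coordinate mirror of only the target would
instead destroy the overlap and test nothing.

What passing these tests does *not* show: the fixtures contain no
alignment noise (the liftover itself is out of scope, so coverage values
are exact functions of the edit geometry), no nested or overlapping genes
in the base set, no partial-exon structure differences, and no assembly
gaps. On real data, coverage fractions are noisy near the thresholds and
borderline genes can change category between flank variants; the
per-variant best-coverage selection and the explicit `merge_f` provenance
are there precisely so such cases can be audited.

## Numerical and degenerate-input choices

* Gene spans are intersected with integer arithmetic; fractions are exact
  ratios of integers, so threshold comparisons (`>=`) are reproducible.
* Zero-length features are rejected at parse time (`start <= end`
  enforced); malformed coordinates abort with the offending line number.
* Duplicate gene IDs are an error naming both lines; duplicated gene-span
  rows reaching the overlap layer are merged to their enclosing interval
  with a warning.
* Features whose parent chain reaches no gene are wrapped under a
  synthetic, flagged gene rather than dropped; nothing is silently lost
  (feature counts are conserved between parse and write).
* The topological sort is a deterministic total order — natural
  seqid order, genes by (start, end, ID), children after parents, siblings
  by (start, type rank, ID) — so identical inputs give byte-identical
  outputs regardless of input row order.
* An empty overlap between seqid vocabularies warns (it is usually a
  chromosome-naming mismatch) and returns an empty, well-typed record set.

## Problem sizes used in the test suite

The shipped tests run the complete protocol on simulated sets of 100–500
genes across 1–5 seqids, 20 seeds for the oracle-equivalence checks and 5
seeds for truth recovery, with an all-pairs brute-force scan as the
independent oracle for the interval index. These sizes exercise every code
path (all edit types, all cardinalities, both hierarchy flavours) while
keeping the default suite fast; the protocol itself is linear in the
number of overlap records and has been run at realistic genome scale
(tens of thousands of genes) without modification.

## A worked example

```{r example}
base <- simulate_annotation(120, 2, seed = 42)
fx <- apply_edits(base, sample_edits(base, seed = 43))
variant <- lift_variant("flank0", fx$query, fx$unmapped_ids)

sel <- select_best_variant(variant, fx$target)
fates <- classify_genes(sel)
glance(fates)

unified <- merge_annotations(fates, variant, fx$target)
glance(unified)

tab <- build_translation_table(fates, fx$target,
                               collapsed = unified$collapsed)
count(tab, category)
```

The overlap graph separates clean one-to-one matches from the complex loci
that need manual curation:

```{r components}
comps <- overlap_components(sel$records)
count(comps, cardinality)
```

And the sweep recovers a planted threshold:

```{r calibration}
cal <- simulate_calibration_truth(0.3, n_pairs = 40, seed = 44)
sw <- sweep_threshold(select_best_variant(lift_variant("l0", cal$query),
                                          cal$target),
                      cal$pairs)
select_optimal_threshold(sw)
```

## Known limitations

* Overlap is gene-span based; exon- or CDS-level fractions are out of
  scope, so a query gene nested in a long target intron still counts as
  overlapping.
* No reciprocal-best-hit or sequence-identity logic: two unrelated genes
  that happen to overlap are matched if the fraction clears the threshold.
* The liftover itself is consumed, not performed; coordinate errors made
  upstream propagate into the classification.
* The GFF3 writer preserves the source hierarchy verbatim; it does not
  synthesize mRNA rows for CDS-only rescued genes.
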