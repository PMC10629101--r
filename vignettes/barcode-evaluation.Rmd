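---
title: "Evaluating DNA barcodes for a pair of closely related species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcodes for a pair of closely related species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

## The problem

Two closely related species — say a protected timber tree and its cheaper
congener — often cannot be told apart morphologically or anatomically. DNA
barcoding asks whether a short, standardised genomic region (or a
concatenation of several) separates them. This package implements the four
evaluation methods usually applied together, over single markers and
combined barcodes, plus a simulator that produces datasets with known truth
so every stage of the workflow can be tested without external sequence data.

## Distance model

All distances are Kimura two-parameter (K2P). For a pair of aligned
sequences, comparison is restricted to columns where both carry an
unambiguous base (*pairwise deletion*; gaps and IUPAC ambiguity codes never
count). With $P$ the transition and $Q$ the transversion proportion over the
compared sites,

$$d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).$$

Two situations invalidate a pair rather than propagate nonsense: fewer than
`min_overlap` comparable sites (default 50 — markers differ in missingness,
and very short overlaps make $P,Q$ unstable), and a non-positive logarithm
argument (substitution saturation). Invalid pairs are excluded from every
summary and their count is reported; the tree builder refuses matrices
containing them rather than guessing.

Group summaries follow the conventions of the barcoding literature. The
published "theta" and "coalescence depth" columns are not given closed
forms in most publications, so this package states its own: *theta* is the
per-species mean intraspecific pairwise distance averaged across species,
*coalescence depth* the per-species maximum averaged across species; species
with fewer than two samples contribute nothing to either. Per-species values
are also returned so alternate conventions can be recomputed. Standard
errors are analytic over the pair (or species) sets — the familiar "±"
presentation — and are an approximation, since pairwise distances sharing a
sample are not independent.

The *barcoding gap* is defined distribution-free: present iff the minimum
interspecific distance exceeds the maximum intraspecific distance; otherwise
the overlap interval is reported. Histograms use left-closed bins of width
0.005 starting at 0 (distances in substitutions/site rarely exceed 0.1 in
this setting, so ~20 bins resolve the usual figures).

## Comparing markers: Wilcoxon signed-rank

Interspecific distance vectors of two markers are compared with the Wilcoxon
signed-rank test. The paired unit is the *interspecific sample pair*: a pair
(i, j) contributes its distance in marker A and in marker B, provided it is
present and valid in both. Published tables do not state their pairing rule;
the matched-pair rule is recorded in output, and a `pairing = "sorted"` mode
(sorted pooled vectors) is available for sensitivity analysis. Zero
differences are dropped (Wilcoxon's convention, count reported); midranks
handle ties. For $n \le 25$ tie-free differences the two-sided p-value is
exact — computed from the null distribution of the positive rank sum, which
the test suite cross-checks against full $2^n$ enumeration — otherwise a
normal approximation with tie correction and continuity correction is used.
Two-sided p-values are reported, matching common statistical-package
defaults.

## Character-based diagnosis

A diagnostic rule is a conjunction of `position = nucleotide` clauses
satisfied by every sample of one species and by no sample of the other. Gaps
and ambiguity codes never satisfy a clause (published formulae use only
A/C/G/T states). Induction searches single positions first and reports
*every* pure single-position clause as an alternative (the disjunctive "or"
form seen in published rule tables), with the lowest position as the primary
formula; if no single position separates a class, pairs of
within-species-fixed clauses are searched exhaustively, and larger
conjunctions (up to `max_clauses`, default 2 — the largest printed formulas
have two clauses per branch) by greedy set cover. A species with no rule at
`max_clauses` is reported rule-less, not an error.

Because the software behind published cc/wc/nc tables does not document its
resampling, evaluation here defaults to honest leave-one-out: each sample is
classified by rules induced on the remainder. `cc` is the percentage of a
species' samples classified to it, `wc` classified to the other species or
caught in a rule conflict, `nc` unclassified; `cc + wc + nc = 100`.
Resubstitution is available for comparison; exact replication of published
non-100% cells is not promised.

## Best-match identification

Querying a live online database is not reproducible, so identification runs
against a local labeled reference library, leave-one-out by default (each
sequence against all others). Percent identity comes from a global pairwise
alignment with free end gaps (match +1, mismatch −1, gap −2 per position;
identity = matches / aligned columns, end gaps excluded), standing in for an
E-value-thresholded search; the default acceptance threshold is 97%
identity, a customary species-level cutoff for plant barcodes. The top
hit(s) — exact ties by default, `tie_margin` widens this — classify the
query: *success* if all top hits are conspecific, *error* if none are,
*ambiguous* if mixed; the three counts partition the thresholded query set.
An optional reverse-complement normalisation (off by default) handles
markers prone to orientation inversions.

## Trees and monophyly

Neighbor-joining uses the Studier–Keppler Q-criterion with a deterministic
lowest-index tie-break, so taxon input order never changes the result beyond
the documented rule. Negative branch estimates are clamped to zero with the
excess moved to the sibling branch, preserving the joined pair's distance.
Bootstrap support is standard column resampling (the published "1000 random
addition replicates" is read as the conventional NJ bootstrap of alignment
columns): each replicate recomputes the K2P matrix and NJ tree; replicates
producing invalid distances are dropped and counted. Support of an original
bipartition is the percentage of retained replicates containing it.

Trees stay unrooted. Species monophyly is tested as a bipartition property —
some split of the unrooted tree has exactly that species' samples on one
side — which avoids committing to any display rooting; single-sample species
are trivially monophyletic.

## The synthetic world

`simulate_dataset()` generates, per marker: an ancestral sequence at a
target GC; two species ancestors evolved from it along branches of
`inter_divergence / 2` under the K2P process (closed-form substitution
probabilities, transition/transversion ratio `kappa`, default 2 — a typical
plastid value); optional planted diagnostic columns overwritten with fixed
differing states; and per-sample terminal branches of `intra_divergence / 2`.
The expected interspecific pairwise distance is therefore
`inter_divergence + intra_divergence` (ancestral separation plus two
terminal branches), which is what the recovery tests check against.

One design choice deserves emphasis: **every column where the species
ancestors differ is treated as a diagnostic truth column and is immune to
within-species mutation** (planted columns by contract; ancestor-branch
differences by the same rule, flagged `planted = FALSE` in the truth table).
This makes fixed interspecific differences genuinely fixed — the regime a
usable barcode assumes, and the regime in which perfect leave-one-out rule
recovery is a meaningful target. Real data violate it: within-species
variation can erode diagnostic sites (published ITS2 rule tables with
cc < 100 show exactly that). A green rule-recovery test therefore
establishes correctness of the induction and scoring machinery in a clean
world, not robustness to eroding diagnostics; eroded-site behaviour is
exercised separately with hand-built alignments. Other things the generator
does not emulate: indels and alignment error (alignments are simulated
gap-free; a `gap_rate` option masks random cells only to exercise pairwise
deletion), rate heterogeneity across sites, within-species genealogy
(samples are independent draws from the species ancestor), and base
composition drift.

The `dalbergia_specs()` preset emulates a published two-species study's
per-marker regimes: aligned lengths 256–866 bp, GC 28–64%, per-marker sample
counts 14–37 of 38 (missingness = 1 − n/38), and divergence regimes from
"no variable sites" through "clean gap" (interspecific 0.028, intraspecific
0) to "noisy" (intraspecific exceeding interspecific). Ancestral separation
is derived as `max(0, mean_inter − mean_intra)` of the published per-marker
distance table, because reported mean interspecific distances include
within-species variation. All randomness flows from one seed with
per-marker substreams (`seed + marker index`); identical seeds give
byte-identical FASTA and report bundles.

## Numerical and degenerate-input choices

* Site classification ignores columns with fewer than two unambiguous bases
  entirely (neither conserved nor variable), and classifies the rest from
  A/C/G/T counts only — ambiguity codes are excluded, not expanded, which
  keeps counts deterministic; the rule is stated in output headers.
  GC is pooled over the matrix, not averaged per sequence, which is stable
  under unequal missingness.
* Concatenation intersects sample sets (a sample missing from any member
  marker is dropped from the combination) — the behaviour implied by
  published combined-marker sample counts being at most the minimum of the
  singles — and retains partition boundaries so rule positions on a
  combined barcode map back to (marker, local position).
* All-zero difference vectors make the signed-rank test undefined (error);
  a single replicate bootstrap yields supports of exactly 0 or 100; equal
  distances produce a star-like NJ tree with zero-length internal edges.
* Identity threshold failures produce no species/genus call rather than a
  forced guess; summaries count them separately.

## Limitations

Exact replication of legacy-software output (distance software's θ/depth
estimators, rule-induction binaries, online search rankings) is explicitly
out of scope; the package states its own definitions and keeps them
testable. The Wilcoxon "n" of published tables cannot be fully
reverse-engineered, so the matched-pair rule here is a documented choice.
Bootstrap and identification are quadratic-and-worse in samples; the preset
sizes (tens of samples, hundreds of sites) run in seconds to minutes.
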