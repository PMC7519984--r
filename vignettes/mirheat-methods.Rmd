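---
title: "Methods: from heat-stress time courses to miRNA-target regulatory modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from heat-stress time courses to miRNA-target regulatory modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirheat)
```

## The problem mirheat addresses

Plant microRNAs regulate gene expression by guiding cleavage of their
target mRNAs or by inhibiting their translation, and they are central
players in the heat-stress response of rice. A common experimental
design profiles miRNA and mRNA expression jointly on microarrays over a
short heat time course — here a 0-min control followed by 10 min,
20 min, 60 min and 2 h at elevated temperature, with two replicate
arrays per timepoint. The analytical question is which miRNA families
respond to the stress, which of their predicted targets respond in the
*opposite* direction (the signature of active miRNA regulation), and
how those family–target pairs organize into coregulatory modules once
protein–protein interactions among the targets are added.

mirheat implements this inference chain end to end: detection-flag
filtering, quantile normalization with per-probe median centering,
per-timepoint differential expression against the control, aggregation
of mature miRNAs into families, plant target-site prediction by
expectation-penalty scoring, anti-correlation pairing, and assembly of
a heterogeneous family–gene–PPI network whose connected components are
the candidate coregulatory modules. A fully seeded synthetic-data
generator with planted ground truth makes every stage testable without
access to array repositories.

## Preprocessing

Arrays carry per-cell detection calls: `P` (present), `A` (absent),
`M` (marginal). A probe is kept when at least `min_present` of its
calls are `P`; the default generalizes the common "6 of 10 arrays"
rule as `ceiling(0.6 * n_samples)` so the same code runs on simulated
designs of any size.

Quantile normalization forces every array onto the common distribution
given by the cross-array mean of order statistics. We delegate to
`limma::normalizeQuantiles(ties = TRUE)`, whose tie handling — tied
values receive the mean of the tied target quantiles — is the
deterministic convention we document and test. Normalization is
followed by *baseline to median*: each probe's median log2 intensity
across all arrays is subtracted, so probe rows are centered at zero.
This transform is idempotent and rank-preserving within each row.

The pipeline operates on log2 intensities throughout; raw-scale input
is clipped at a configurable floor (default 1.0) before the log to
avoid infinite values.

One consequence worth knowing: quantile normalization compresses
differences near the edges of the intensity distribution. A
low-abundance gene that is strongly downregulated can lose a large
part of its apparent fold change because the lowest ranks of every
array are forced onto nearly the same values. The synthetic-data tests
exhibit this honestly — planted effects on probes with baselines near
the low end are recovered with attenuated fold changes, and a few fall
below the calling threshold.

## Differential expression

For each treatment timepoint $t$ versus the control, the log2 fold
change of entity $g$ is the difference of group means, and a two-sided
p-value comes from one of two tests:

* `student_t` — the pooled-variance two-sample t test with
  $n_1 + n_2 - 2$ degrees of freedom. With two replicates per group
  the pooled test is used rather than Welch's, whose degrees-of-freedom
  estimate degenerates at $n = 2$. Probes with zero pooled variance get
  $p = 1$.
* `moderated_t` (default) — an empirical-Bayes variant that shrinks
  each probe's pooled variance $s_g^2$ toward a prior variance $s_0^2$
  with weight $d_0$ prior degrees of freedom:
  $\tilde{s}_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$, with the t
  statistic referred to $d_0 + d$ degrees of freedom. The prior is fit
  by the method of moments under a scaled-inverse-chi-square model:
  writing $c$ for the squared coefficient of variation of the observed
  variances, $d_0 = (4cd + 2d - 4)/(cd - 2)$ when $cd > 2$ and
  $d_0 = \infty$ (complete pooling) otherwise, and
  $s_0^2 = \bar{s}^2 (d_0 - 2)/d_0$. With $d_0 = 0$ the moderated test
  reduces exactly to the plain t, which the tests assert. With two
  replicates per group the raw variance has only 2 degrees of freedom,
  which is why moderation is the default.

An entity is significant at $t$ when $|\log_2 FC| \ge 1.0$
(*inclusive*) and $p < 0.05$ (*strict*), and differentially expressed
(DE) overall when significant at one or more timepoints. No
multiple-testing correction enters the calls — this matches the raw
p-value convention of the array workflow the package models — but a
Benjamini–Hochberg column is emitted for reference.

## Family aggregation

Mature miRNA identifiers collapse to families by stripping variant
letters and arm/isoform suffixes: `osa-miR169g`, `osa-miR169n` and
`osa-miR169o` all belong to `osa-miR169`, and `osa-miR397b.2` to
`osa-miR397`. Only DE members enter aggregation. Per timepoint, a
family is `up` when at least one member is significantly up and none
down, `down` symmetrically, `conflict` when both occur, `none` when
neither. The overall label is `up` (`down`) only when every
significant member call at every timepoint agrees, and `up_down`
otherwise — the three-symbol direction alphabet used throughout the
result tables.

## Target-site scoring

Plant miRNA targets are predicted by complementarity. The *expectation*
of a miRNA–site duplex is a cumulative penalty over aligned positions,
counted from the miRNA 5' end:

| defect | penalty |
|---|---|
| Watson–Crick match | 0 |
| G:U wobble | 0.5 |
| mismatch | 1.0 |
| gapped position | 2.0 |

Every penalty is doubled in the seed region, positions 2–13. A perfect
complement scores 0; sites with expectation at most the cutoff
(default 3, chosen to suppress spurious targets) are reported. The
scheme is fully configurable through `scoring_scheme()`, and the
package treats it as the documented, fixed definition of the score —
reproducing any particular web service's proprietary scoring byte for
byte is a non-goal.

The scanner evaluates the antiparallel duplex of the miRNA against
every transcript window, enumerating the gapless register and, with
`max_gaps = 1` (the default; typical plant duplexes have at most one
bulge), every single-bulge variant on either strand. A bulged
transcript base between miRNA positions $j$ and $j{+}1$ is charged at
position $j{+}1$ for seed doubling; an unpaired miRNA base is charged
at its own position. Coordinates are 1-based and fully closed on the
transcript 5'→3'. Overlapping sites collapse to the best-scoring one,
ties broken by smallest start, so output is deterministic. The inner
loop is compiled (Rcpp); an independent pure-R brute-force enumerator
in the test suite verifies the compiled scanner exactly on random
instances.

Regulation mode is read off the alignment: disruption (mismatch or
gap) of the central positions 10–11 — where plant miRNA-guided
cleavage occurs — classifies the site as `translation_inhibition`;
otherwise it is `cleavage`. G:U wobbles do not disrupt cleavage.

Family members are near-identical in sequence, so several members
usually predict the same gene; `predict_targets()` therefore
deduplicates at the family level, keeping the best member site per
(family, gene).

## Anti-correlation pairing

A candidate pair is a DE family and a DE predicted target. The
high-confidence rule keeps pairs whose two sides moved in opposite
directions. The source convention "altered in the opposite direction
within any time period" admits two readings, and both are implemented:

* `strict` (default): there is a timepoint at which both sides are
  significant with opposite directions; supporting timepoints are
  reported. We default to the stricter reading because it is the one
  that actually ties the two expression changes to the same moment of
  the response.
* `lenient`: the overall direction labels oppose each other, an
  `up_down` side being compatible with any opposite call (it contains
  both directions).

A family timepoint labelled `conflict` supports no pair at that
timepoint; an `up_down` family supports pairs in either direction at
timepoints where its direction is defined. The retained pair set is
invariant under a simultaneous global up/down relabel of both sides, a
symmetry the tests check.

## Network and modules

The heterogeneous network has family and gene nodes from the
high-confidence pairs. Family→gene edges carry the regulation kind of
the pair's best site; gene–gene edges carry PPIs whose combined
confidence score (normalized to $[0,1]$) *strictly* exceeds 0.7 and
whose endpoints are both network genes — no isolated PPI-only proteins
are imported. Construction inserts nodes and edges in sorted order, so
identical inputs give byte-identical GraphML.

A *coregulatory module* is operationalized as a connected component
containing at least two family nodes: groups of miRNA families joined
through shared targets and/or interactions among their target
proteins. No community-detection algorithm is applied beyond
connectivity — the simplest definition consistent with modules formed
by a shared target gene or by a PPI bridge between two families'
targets. Within a module the hub is the family of maximum degree, ties
broken lexicographically. Raising the PPI cutoff can only remove
edges, so the module count is non-decreasing in the cutoff — a
monotonicity the tests assert.

## The synthetic-data generator

`simulation_config()` fixes the study design the generator emulates:
five timepoints with two replicates (ten arrays), per-entity log2
baselines uniform on $[6, 14]$, replicate noise $\sigma = 0.2$ log2
units, planted effects of 2.0 log2 units, 10% of miRNAs and genes DE,
and 150 miRNA + 1850 mRNA probes — 2000 entities, which keeps a
complete simulated run at desk scale (about a minute on one CPU).
Planted effects follow a *ramp* profile by default (one quarter, half,
three quarters, full effect over the four treatment timepoints),
mirroring responses that build toward the last timepoint; a *step*
profile is available. Anti-correlated pairs tie 30% of the DE genes to
an opposite-signed DE family. Cells below 7 log2 units are flagged
absent with probability 0.3, emulating low-intensity dropout.
Families have one or two members; members differ by a single
substitution outside the seed region, so members cross-predict each
other's planted sites the way real family members do.

Sequence simulation embeds, for every planted pair, a target site
constructed by `make_target_site()` to score an exact chosen
expectation (0–2, occasionally with a central mismatch so both
regulation modes occur), and plants decoy near-sites in non-target
genes constructed to score at least 0.5 above the cutoff — decoys must
never be predicted, which the tests assert. PPI simulation scores all
within-module gene pairs uniform on $[0.75, 0.99]$ and background
pairs on $[0, 0.65]$, so the 0.7 cutoff separates planted modules from
background with margin; module genes are drawn from planted pairs
whose gene probe sits far enough above the dropout threshold that flag
filtering cannot remove it, keeping planted modules recoverable by
construction. The module-recovery check accordingly runs the module
finder on the network of planted pairs plus the simulated PPI table,
where that margin guarantee holds exactly; recovery through the noisy
expression path is covered separately by the pair-recovery check with
its 0.9 tolerance.

All randomness flows from the single config seed through a local RNG
(the caller's RNG state is untouched); expression, sequence and PPI
stages use fixed small offsets of that seed so each stage is
individually reproducible.

What the generator deliberately does **not** emulate: probe-level
array artifacts (spatial effects, dye bias, background), heavy-tailed
or intensity-dependent noise, partial-complementarity target sites
beyond the planted/decoy dichotomy, correlated expression between
non-paired entities, and realistic PPI topology. Passing the planted
recovery tests therefore demonstrates correctness of the inference
chain under its own model assumptions, not performance on real arrays.

## Numerical and degenerate-input conventions

* Quantile-normalization ties: mean of the tied target quantiles.
* Zero pooled variance: $p = 1$ under the plain t; rescued by the
  prior under moderation.
* DE thresholds: fold change inclusive ($\ge$), p-value strict ($<$).
* PPI cutoff: strict ($> 0.7$); duplicate undirected PPI edges keep
  the maximum score; self edges are dropped with a warning.
* Site overlap: lowest expectation wins, then smallest start.
* Hub ties: lexicographically smallest family id.
* Sample order is canonical (timepoint, then replicate); node and edge
  insertion order is sorted — identical inputs give identical output
  bytes, which the determinism tests assert end to end.
* Sequences are held in the RNA alphabet internally; `T` is accepted
  on input and unified to `U`.

## Problem sizes used by the test suite

Unit tests run on matrices of tens to hundreds of probes and
transcripts of 60–400 nt; the scanner-versus-brute-force comparison
uses 50 random instances with 18–22 nt miRNAs and 60–200 nt
transcripts; the end-to-end recovery checks run the full default
design (2000 entities) once. These sizes were chosen so the whole
suite completes in a few minutes while every check retains its
discriminating power.

## Known limitations

* The expectation scheme is a documented, fixed re-specification of
  plant target-predictor penalty structure, not a byte-level clone of
  any web service; absolute site lists can differ from service output
  even where the biology agrees.
* Target-site accessibility and duplex energetics (RNAup-style) are
  out of scope, as is degradome support for cleavage validation.
* Modules are connected components; finer community structure inside
  a large component is not resolved.
* With $n = 2$ replicates, any t-type test has limited power; the
  moderated default mitigates but cannot remove this.
* GO-Slim and characterized-gene summaries are annotation joins
  against user-supplied or packaged snapshot tables; enrichment
  statistics are deliberately not computed.
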