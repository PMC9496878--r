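---
title: "Temporal stability of dynamic brain networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal stability of dynamic brain networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the pipeline answers

Resting-state functional connectivity is not static: the correlation
structure between brain regions reorganises over seconds to minutes. A
case-control question that follows naturally is whether a patient group's
connectivity patterns are *less stable in time* than controls', globally or
within particular functional systems, and whether that instability tracks a
clinical score. `dynstab` implements the standard sliding-window /
proportional-threshold / temporal-correlation protocol for that question,
together with its statistical layer and a generative model for testing the
whole chain without access to patient data.

## From time series to dynamic networks

Each subject enters as a node-by-time matrix of region-of-interest signals
with a known repetition time (TR). The protocol has three fixed stages:

1. **Windowing.** A window of `length_seconds` (default 100 s) slides in
   steps of `step_seconds` (default 6 s). Seconds are converted to samples
   by truncation; windows are anchored at the first sample and an
   incomplete trailing window is dropped, so
   `W = floor((T - L)/S) + 1`. At TR 2 s a 240-volume series gives 64
   windows of 50 samples stepping by 3 — truncation is the only rounding
   rule that reproduces that count.
2. **Windowed correlation.** Pairwise Pearson correlation of all nodes
   within each window. A zero-variance node in any window is an error, not
   a silent `NaN`.
3. **Proportional thresholding.** At density `d` the
   `K = max(1, floor(d * N(N-1)/2))` strongest connections are kept as
   edges (value 1), the rest set to 0, over a grid of densities 0.01-0.50
   in steps of 0.01. Ranking is by **signed** correlation by default —
   a strongly negative correlation is never an edge — with
   `rank = "absolute"` available because the literature is split on this
   convention. Ties at the cut are broken towards the lexicographically
   smallest node pair so results are bit-reproducible across platforms.
   Because thresholding is top-`K`, the network at a lower density is
   always a subgraph of the network at a higher density in the same
   window.

## The temporal correlation coefficient

For a stack of `W` binary layers, node `i`'s stability is

$$C_i = \frac{1}{W-1} \sum_{t=1}^{W-1}
  \frac{\sum_j a_{ij}(t)\,a_{ij}(t+1)}
       {\sqrt{\left[\sum_j a_{ij}(t)\right]\left[\sum_j a_{ij}(t+1)\right]}},$$

the co-neighbour count between consecutive windows normalised by the
geometric mean of the two degrees. Two conventions are ambiguous in parts
of the literature and are therefore explicit, switchable arguments:

* **Denominator** (`denominator = "geometric"`, default): the geometric
  mean `sqrt(k_i(t) k_i(t+1))` follows the public dynamic-graph-metrics
  implementations and guarantees `C_i <= 1`; the plain product is offered
  for sensitivity analysis only, since it deflates the coefficient.
* **Degenerate terms** (`isolated = "zero"`, default): if a node is
  isolated in either window of a consecutive pair the term is 0/0; the
  default counts it as zero overlap and keeps it in the `W - 1` divisor
  (absent neighbourhoods share nothing), `"skip"` removes it from both.
  At the default density grid this matters only for very sparse networks.

`C_i` is computed at every density, averaged (unweighted) across the grid,
and aggregated: the whole-brain value is the mean over *all* nodes
regardless of network assignment; each network value is the mean over that
network's nodes as declared in the node table. The production
implementation shares one ranking of each window's correlations across the
whole density grid rather than materialising 50 binary networks; its exact
equality with the explicit modular composition, and with a brute-force
quadruple-loop evaluation of the formula, is enforced in the test suite at
`1e-12`.

## The node table

All aggregation is driven by a plain mapping file (`index`, `label`,
`network`), validated for contiguous indices and a declared label set of
nine networks plus `"unassigned"`. The shipped 90-region anatomical
mapping is a best-effort reconstruction of the nine-network scheme commonly
used with that atlas — the authoritative per-study assignment should be
supplied by the user; every computation is mapping-agnostic. An
`#index_base=1` directive supports 1-based atlas files without silent
off-by-one errors.

## Statistical layer

`run_study_statistics()` reproduces the full design of a case-control
stability study:

* subjects with mean framewise displacement strictly above 0.2 mm are
  excluded before anything else;
* demographics: two-sample t tests (both pooled and Welch variants are
  implemented, because published tables often mix them; the harness
  default is Welch) and the Pearson chi-square *without* continuity
  correction, which is what published 2x2 values almost always are;
* group differences: ANCOVA adjusting for age, sex (0/1 indicator,
  female = 1 by default, switchable) and education. The group term is the
  partial F of its coefficient, which for a two-level factor equals the
  type-III F and, without covariates, the squared pooled t. The
  whole-brain comparison is reported uncorrected; the nine network
  comparisons form one Benjamini-Hochberg family.
* clinical correlations: for every level that survives, Spearman
  correlations (midranks) with the total symptom score and the ordinal
  suicidality item in patients, BH-corrected as a second family. The
  family compositions are deliberately narrow — corrections are applied
  within each reported analysis block, not across the entire output.
* post-hoc and validation analyses: illness-duration and dose
  correlations, drug-naive vs medicated ANCOVA, dose-partial Spearman
  (both variables' ranks residualised on the covariate's ranks, tested on
  `n - 3` degrees of freedom), and a proportional-odds model of the
  ordinal item on the default-mode stability value (fit by maximum
  likelihood via `MASS::polr`; separation or an unusable Hessian is an
  explicit error, never a silently huge slope).

Missing data are handled complete-case per analysis with `n_used`
reported; individual analysis failures warn and skip rather than abort the
run.

## The synthetic cohort generator

No public data accompany this design, so the generator is a first-class
module: it must make "temporal stability of dynamic connectivity" a real,
tunable property of the data, with group effects and a clinical coupling
whose recovery through the *estimation* pipeline is informative.

Each functional network (block of nodes) carries a hidden state sequence
with geometrically distributed dwell times (mean `dwell_mean_*`, in
samples; successive states always differ). Within a state every node of
the block loads on a shared AR(1) latent factor with weight
`±sqrt(rho)`: state 1 is the fully coherent configuration (all positive,
within-block correlation `rho`), higher states are "fragmented"
configurations with fixed random sign patterns, so a switch re-arranges
which pairs are positively coupled. Independent AR(1) noise of standard
deviation `noise_sd` is added on top. Blocks switch independently.

A design note on why the states fragment rather than simply switch
coherence on and off: with 100 s windows stepping by 6 s, consecutive
windows share 94% of their samples, so windowed correlation estimates are
strongly smoothed. If states only modulated the *strength* of a fixed
correlation pattern, fast switching would time-average into a stable
static-like structure and the measured stability would *rise* with the
switching rate — the opposite of the construct. With sign-fragmentation
states the time average of fast switching carries pairs towards zero
correlation (edge ranks then churn at noise level), while long dwells keep
strongly coupled pairs stably at the top of the ranking; measured
stability then increases monotonically with dwell time, which is the
property the whole validation rests on and is verified as a seeded test.
Temporal smoothness (`ar_phi = 0.95`, about a 40 s autocorrelation time at
TR 2 s) mimics band-limited haemodynamic signals and gives windowed
estimates realistic sampling variability.

### Default study conditions

| Parameter | Default | Why |
|---|---|---|
| groups | 52 patients / 21 controls | the emulated study design |
| nodes, volumes, TR | 90, 240, 2 s | 90-region atlas; 250 acquired minus 10 discarded |
| `n_states` | 6 | enough fragmented patterns that fast switching destroys rank structure |
| `rho` | 0.95 | strong within-state coherence, the regime where dwell drives stability |
| `noise_sd` | 0.2 | moderate measurement noise |
| `ar_phi` | 0.95 | band-limited signal smoothness |
| control dwell | 120 samples (4 min) | slowly reorganising, stable regime |
| patient global dwell | 84 samples | modest global destabilisation |
| targeted factor | 0.15 | strong extra destabilisation of default-mode and subcortical blocks |
| dwell multiplier sdlog | 0.4 | between-subject stability heterogeneity |
| `score_coupling` | -2.5 | ordinal item tracks the true default-mode latent |

The ordinal suicidality item is drawn from a proportional-odds model whose
linear predictor is `score_coupling` times each patient's *standardised
realised default-mode dwell* (the log mean segment length actually drawn
for that subject). Coupling to the generative truth rather than to the
estimated stability means that recovering the negative score-stability
correlation through the pipeline measures estimation fidelity, not a
circular restatement. Demographic covariates are drawn to match the
published group summaries (age, education, sex balance, motion, symptom
scores, medication mix) but are independent of the stability mechanism.

These defaults were fixed at design time by calibrating the generator so
that its intended effects are recoverable at the emulated sample size —
the point of a recovery suite — and then frozen. Because patients' targeted
blocks churn strongly, proportional thresholding lets their edges displace
other networks' edges near the density cut, so mild group differences can
appear outside the targeted systems; that spillover is a real property of
rank-based thresholding, worth remembering when interpreting network-level
specificity on real data too.

### What passing tests do and do not show

The generator produces block-structured, state-switching Gaussian data. It
does not model haemodynamic response functions, scanner artefacts, head
motion beyond a mean-FD column, spatial geometry, or inter-network
coupling. Recovery of the built-in effects therefore validates the
*pipeline's arithmetic and statistical machinery*, not the
neurobiological claim; on real data the effect sizes, the appropriate
density range and the stability baseline will differ.

## Problem sizes used in validation

The seeded recovery suite runs the full 52 + 21 design with the standard
240-volume, 64-window, 50-density protocol at a 45-node parcellation, 10
effect cohorts and 10 null cohorts. 45 nodes is the smallest table whose
proportional network quotas are all integers; below that the subcortical
network (8/90 of the atlas) drops to one or two nodes and its stability is
dominated by the realisation noise of a handful of edges — a resolution
limit of the parcellation, not of the method. The acceptance script runs
one cohort at the full 90-node scale. Single-subject metric checks use
3-12 nodes where brute-force oracles are exact and instant.

## Numerical choices

* Seconds-to-samples conversion truncates; edge counts use
  `floor` with a minimum of one edge (`rounding = "round"` available).
* Rank ties at the density cut break towards the lexicographically
  smallest `(i, j)` pair.
* The motion rule is a strict inequality (`> 0.2 mm` excludes).
* The proportional-odds predictor is standardised internally before
  fitting; the Wald z is scale-invariant. Slopes with `|beta| > 15` on the
  standardised scale, or an unusable Hessian, are treated as
  non-convergence.
* All randomness flows from one master seed; each subject's stream is
  derived from it, so cohorts are reproducible subject-by-subject.

## Known limitations

* The shipped 90-region network mapping is a documented best effort, not
  an authoritative atlas product.
* Tapered windows, state-clustering approaches and weighted (unthresholded)
  dynamic networks are out of scope.
* The generator's independence assumptions (between blocks, and between
  covariates and the stability mechanism) are simplifications; ANCOVA
  covariate adjustment is exercised but not stress-tested against
  confounded designs.
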