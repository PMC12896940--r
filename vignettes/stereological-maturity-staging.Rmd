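---
title: "Stereological maturity staging of fish ovaries: methods and design"
author: "StereoMaturity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereological maturity staging of fish ovaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StereoMaturity)
```

## The problem

Fisheries stock assessment needs accurate maturity data: the maturity ogive
and the length at 50% maturity (L50) feed directly into spawning-stock
biomass and minimum-landing-size decisions. Maturity of female flatfish is
routinely staged *macroscopically* — visual inspection of the ovary at sea
or at the market, stages 1–4 — but the gold standard is histological.
Quantitative histology (stereology) goes one step further than qualitative
slide reading: a grid of 500–600 equidistant points is laid over a scanned
ovarian cross section and every point is assigned to one of 19 cellular
structures, so that tissue composition becomes a vector of counts rather
than an expert impression. This package implements everything downstream of
those counts: area-fraction estimation, rule-based phase classification,
reader-calibration statistics, comparison against macroscopic staging, and
the maturity ogive.

## The fraction estimator

For a slide with `total_points` grid points, the estimated area fraction of
structure $s$ is

$$\widehat{f}_s \;=\; \frac{100}{\text{total\_points}} \times
\text{hit\_points}_s ,$$

a percentage over *all* sampled points; the technical categories
"unnatural emptiness" (`v`) and "undetermined" (`i`) stay in the
denominator, so fractions always sum to 100. Counts are the single source
of truth: the package stores integer hits and always derives percentages
(`fractionEstimates()`), which makes the estimator exactly homogeneous of
degree zero — doubling every count changes nothing.

The 19-structure taxonomy distinguishes 12 germline categories (oogonia
`og`; primary oocytes `po1`, `po2`; cortical alveoli `cao`; vitellogenic
`vit1`–`vit3`; hydrating/hydrated `pho`, `ho`; post-ovulatory follicles
`POF`; alpha/beta atretic oocytes `oaA`, `oaB`) from 7 somatic or technical
ones. Both historical spellings of the atretic codes (`aoA`/`oaA`,
`aoB`/`oaB`) occur in practice; the package resolves the aliases
deterministically and treats any other unknown code as a hard error —
silently dropping a miscoded structure would corrupt the classifier.

## The phase classification model

A slide is assigned one of five maturity phases by presence/absence and
atresia rules, evaluated in a fixed order with D as the fallback:

* **A — immature.** Every germline hit is `og`, `po1` or `po2`, and at
  least one of them is present.
* **B — developing.** `cao`, `vit1` or `vit2` present; alpha atresia at
  most 50% of the follicles quantified; `POF`, `oaB`, `vit3`, `pho`, `ho`
  all absent.
* **C — spawning.** `vit3`, `pho` or `ho` present; alpha atresia at most
  50%; `oaB` absent; and `POF` not exceeding the `ho` count. `POF = 0`
  marks the beginning of spawning (`rule_fired = "C-early"`), recently
  collapsed `POF` up to the hydrated-oocyte count the end of it
  (`"C-late"`); more `POF` than `ho` means spawning has finished and the
  slide falls through to D.
* **E — omitted spawning.** No `POF` and *strictly more* than 50% alpha
  atresia.
* **D — regressing/regenerating.** Everything else. D is deliberately
  never modeled positively: the structures present in a regressing ovary
  (degenerating `POF` of mixed ages, atretic follicles at several stages, a
  new oocyte cohort) are too heterogeneous to capture without inventing
  thresholds, so D is exactly the complement of the other four rules.

Three modeling choices deserve emphasis, all exposed in
`classifierConfig()`:

* **The atresia denominator** ("total follicles quantified") is the hit
  sum over all 12 germline codes, including `POF` and the atretic oocytes
  themselves. The taxonomy stars all 12 as main germline cells and nothing
  narrows the set, but the denominator is configurable so its sensitivity
  can be examined.
* **The 50% boundary.** The B/C rules admit *at most* 50% atresia while E
  demands *at least* 50%, so a slide at exactly 50% satisfies both
  phrasings. Ordered evaluation (A, B, C, E, D) resolves the overlap:
  exactly 50% stays in B or C, and E effectively requires a strict
  majority of alpha-atretic follicles. `atresia_pct` is returned so
  boundary cases are visible.
* **Presence means at least one grid hit.** The rules are presence/absence
  statements about counted structures; any higher cut would be an invented
  parameter. (`requiredPresenceMinHits` allows raising it for sensitivity
  analyses.) Whether hydrating (`pho`) oocytes should count toward the
  late-spawning `POF` bound is genuinely open; the default compares
  against `ho` only, with `pofComparisonCodes` making the alternative a
  one-line change.

Gonadal-wall thickness, intercellular space and connective tissue are never
used as features: "thin" and "scarce" cannot be quantified without
subjectivity, and their on-slide proportions are corrupted by sectioning
artefacts.

`classifyCohort()` stages one designated slide per fish — by convention the
median section of the ventral ovary (V, position 2) — reporting fish with
no designated slide explicitly and refusing ambiguous duplicates.

## Reader calibration

Stereology replaces one subjectivity (staging) with another (point
identification), so reader calibration is part of the method. Three
statistics are provided:

* **Reading-error index** (`readingErrorIndex()`): per structure, the
  maximum absolute pairwise difference in estimated fractions between
  readers of the same slide; differences strictly over 3 percentage points
  flag the slide for review and protocol refinement.
* **Percentage agreement** (`percentAgreement()`): the mean, over aligned
  grid points, of the proportion of rater pairs assigning the same code.
  The mean-pairwise form is used because it extends gracefully from three
  raters down to two; the stricter all-raters-agree variant is available
  via `allAgree = TRUE`. Items are individual grid points with aligned
  placements across raters — the only itemization under which a per-slide
  kappa is well defined — and pre-aggregated point-by-code tallies are
  accepted for alternative itemizations.
* **Fleiss' kappa** (`fleissKappa()`): chance-corrected multi-rater
  agreement. When a single code is used for every rating the chance
  agreement is 1 and kappa is undefined; the package returns `NA` under a
  classed warning rather than propagating `NaN`, and
  `summarizeCalibration()` excludes undefined entries while reporting
  their count (sample sd uses the n−1 denominator).

The packaged calibration table (`calibrationFixture()`) contains the
published per-slide indices of a 20-slide, 2–3-reader exercise; its
per-slide raw readings are not available, so only the summary statistics —
not individual slides — are reproduction targets.

## Comparing the two staging methods

`buildConfusion()` cross-tabulates stereological phases (A–E) against
macroscopic stages (1–4). Overall agreement (`overallAccuracy()`) matches
stage $k$ with the phase of the same rank (A↔1 … D↔4); omitted spawning
(E) has no macroscopic counterpart and can never be matched.
`conditionalPercentages()` gives the distribution of one method's labels
conditional on the other's, with `NA` (not a division error) on empty
margins. On the packaged 151-fish confusion fixture this reproduces an
overall agreement of 40.4% — the package's headline illustration of why
macroscopic staging is problematic. (One published conditional, 7.4% of
stage-4 fish classified B, is inconsistent with the underlying table,
which gives 8/46 = 17.4%; the package reports the value computed from the
table.)

## The maturity ogive

`fitOgive()` fits $P(\text{mature}) = \text{logit}^{-1}(\beta_0 + \beta_1
L)$ by Newton/IRLS on the Bernoulli likelihood, implemented in-repo because
the computation is the package's contract and must be self-verifying;
`glm()` serves only as an independent cross-check in the tests. Numerical
choices: convergence at gradient norm $<10^{-8}$ or 50 iterations; step
halving guarantees a non-decreasing likelihood trace (asserted in tests);
quasi-complete separation is detected from pinned fitted probabilities and
flagged with a warning, the point estimate then being unbounded and only
the bootstrap interval meaningful. $L_{50} = -\beta_0/\beta_1$, with a
nonparametric bootstrap percentile CI (fish resampled with replacement,
explicit seed; resamples that lose one maturity class are redrawn).
How the original study's software computed its intervals is not stated, so
percentile intervals are this package's documented choice and a divergence
risk when comparing CI endpoints. Goodness of fit is reported as the
Nagelkerke pseudo-R², labeled as such because pseudo-R² variants are not
interchangeable.

Binarization (`toBinaryMaturity()`) maps A→immature and B, C, D, E→mature
(macroscopic 1 vs 2–4): a fish leaves the immature state when cortical
alveoli oocytes are produced, and both regressing/regenerating and
omitted-spawning fish have entered the mature cycle — misassigning D would
invert the macroscopic ogive, since most regressing fish are large.

## The synthetic cohort generator

Real cohorts require slide scanning and reading, so the generator
(`simulateCohort()`) makes every pipeline stage testable from code alone.
Per fish it draws: a true phase (default probabilities proportional to the
151-fish cohort's phase totals 23/53/9/65/1), a sampling month (weights
from the study calendar), a length from a per-phase normal model, a slide
composition from a Dirichlet centred on the phase's template
(`concentration` × template, default concentration 300 — compositions
visibly jittered but far from rule boundaries), a grid size uniform on
500–600, multinomial hit counts, and a macroscopic stage from the
phase-conditional rows of the packaged confusion matrix — making the
published confusion structure the generative truth, so the simulated
macroscopic-vs-stereology agreement has expectation 40.4% by construction.

Templates are hand-set compositions, not a mechanistic oogenesis model:
structures a phase's rule requires present have proportion ≥ 0.02 (so
sampling zeros cannot flip presence rules), structures a rule requires
absent have proportion exactly 0 (so sampling cannot create them), and
oogonia are kept at 0.5% because they are small and easily missed on real
slides — the A rule therefore keys on primary oocytes in practice.
Rule-consistency is asserted at construction: each template's expected
counts classify back to its own phase, and with `concentration = Inf`
(largest-remainder rounded expected counts) a cohort is recovered at 100%.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: within-gonad position effects, seasonal phase
dynamics beyond month weights, reader drift over time, correlated
misreadings of similar structures, and real phase-conditional length
distributions (the defaults are loose, plaice-scale synthetic values, not
estimates). `simulateRaters()` perturbs each rater's point labels
independently through a structure-confusion matrix (default: 5%
relabeling to "undetermined"), which suffices to exercise the agreement
statistics but is simpler than real reader disagreement.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; the same config and seed
give byte-identical outputs. The test suite exercises: classifier
equivalence with an independently coded literal rule transcription on
10,000 random count vectors (including exact-threshold and `POF = ho`
boundary constructions); L50 recovery at n = 2,000 and 95% bootstrap-CI
coverage over 500 replicates at n = 200 with 300 resamples each; and 200
simulated 151-fish cohorts for the expected method agreement. These sizes
are the package's choices, balancing sampling error against run time.

## Limitations

* The classifier encodes prose rules for one determinate batch spawner;
  other species need different rules, which is why every threshold and
  code set is a config parameter.
* The published per-slide calibration readings and the raw cohort are not
  shipped; fixture-based checks cover only the printed summary tables,
  and the published L50 values (28.6 cm macroscopic vs 20.6 cm
  stereological) are documentation and generator defaults, not quantities
  recomputable from packaged data.
* D-phase fish are a fallback class; no Da/Db sub-phases are
  distinguished, and no probabilistic (soft) classification is offered.
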