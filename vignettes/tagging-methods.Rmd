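---
title: "Methods: thinning-and-aggregating ensemble QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thinning-and-aggregating ensemble QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagging)
```

## The problem

Dense linkage maps (pseudomarker spacings of 0.2 cM are now routine in
multi-family RIL panels such as maize NAM) are a mixed blessing for QTL
mapping by stepwise multiple regression.  Adjacent markers are nearly
collinear, so marker selection becomes unstable, effect estimates are
biased, and relaxed selection thresholds overfit badly.  Genome-wide
prediction models (GBLUP) handle density gracefully but give no locus-level
interpretation.

TAGGING (thinning and aggregating) sits between the two: partition the
dense map into `s` disjoint thinned sub-maps, fit one ordinary stepwise QTL
model per sub-map on the *same* training lines, and average the
predictions.  Each base learner faces an `s`-fold less collinear hypothesis
space; the ensemble recovers the information the thinning discarded because
every marker appears in exactly one sub-map.  The package implements this
framework end to end, together with the single-model and subagging
comparators, GBLUP companions, cross-validated evaluation, and a synthetic
NAM-like panel generator so the whole pipeline is testable at desk scale.

## Models

**Single-family (SF).** Within family $f$, on sub-map $s$:
$Y^f = 1\mu + X\beta + \varepsilon$, where $X$ holds dosages of the
non-reference-parent allele at the selected loci and $\beta$ are additive
substitution effects relative to the shared reference parent.  Markers
enter/leave by stepwise selection at a predefined partial-F threshold
$\alpha$; the resulting path is then pruned to the step with minimal 5-fold
split-sample CV error inside the training set, and the surviving loci are
refitted by OLS.

**Joint-family (JF).** All $P$ families together:
$Y = A\mu + \sum_{i=1}^{K} X_i\beta_i + \varepsilon$, with $A$ the
family-incidence matrix (one intercept per family) and $\beta_i$
family-specific allele effects at locus $i$.  A candidate locus contributes
one design *block* — a dosage-times-family-indicator column for every
family in which it segregates in the training lines — and the block enters
or leaves as a unit, tested by a joint partial F over its columns.  We
chose the joint test (rather than a pooled single-effect test) because it
matches the per-family effect vector in the model; this is a reading of the
method, not the only possible one.

**Ensembles.** EJF/ESF fit the JF/SF learner once per thinned sub-map and
predict by $\hat F(x) = a_0 + \sum_s a_s f_s(x)$ with $a_0 = 0$,
$a_s = 1/S$ — an arithmetic mean.  Base learners are independent by
construction (zero memory, order-invariant).  A base learner that cannot
fit (e.g. no segregating markers for a family) degrades to an
intercept-only model rather than being dropped, so the weights stay $1/S$.
Subagging, the comparator, instead draws 10 within-family 80% subsamples of
the training lines *without* replacement and fits the full map each time;
without-replacement sampling avoids the duplicated lines that bootstrap
resampling would add to an already collinear problem.

**GBLUP.** $y = X\mu + g + e$, $g \sim (0, G\sigma^2_g)$, with $G$ the
VanRaden method-1 realized relationship matrix.  Within-family $G$ on
linkage-marker dosages tracks within-family IBD (SGBLUP, grand-mean fixed
effect); a panel-wide $G$ gives the joint model (JGBLUP, per-family fixed
means mirroring the JF intercepts — the fixed-effect structure is our
choice, as is REML over ML for the variance components).  Any externally
computed $G$ (e.g. from genome-wide SNP calls) plugs into the same engine.
REML is profiled over the single ratio $\lambda = \sigma^2_e/\sigma^2_g$
via the spectral decomposition of the projected training kernel, so a fit
costs one eigendecomposition plus a 1-D optimization; predictions are
$\hat g_{test} = G_{test,train}(G_{train,train}+\lambda I)^{-1}(y - X\hat\mu)$.
Because fully inbred dosages double the HWE allelic variance, the VanRaden
diagonal is near 2, and the reported heritability uses
$\bar{G}_{ii}\sigma^2_g / (\bar{G}_{ii}\sigma^2_g + \sigma^2_e)$.

**Evaluation.** Stratified CV draws 80% of each family per repeat.
Prediction ability is the signed squared Pearson correlation
($\mathrm{sign}(r)\,r^2$) within family, averaged over repeats and then
families.  Across repeats, each line's predictions decompose as
bias² + irreducible error (squared deviation of the observed value from the
mean prediction; the two cannot be separated without the true genotypic
value) plus prediction variance (1/R population form around that mean), an
identity that holds exactly per line and is asserted to 1e-8 in the tests.
An optional guard excludes predictions outside the global mean ± 100
standard errors of that mean before decomposition — collinearity blow-ups
in single resamples otherwise dominate the variance — and never applies to
R².  RMIP reports, per marker, the fraction of resamples in which it was
tested and selected; for an ensemble, selected in any base learner.  The
denominator defaults to all resamples, with a `tested_samples` policy
offered because the defining phrase is ambiguous.

**Model averaging and pseudo-optimal weights.** Heterogeneous predictors
(TAGGING ensembles, GBLUP variants) combine by fixed simplex weights
(pairs at 0.5/0.5; presets for 1/3 each and 1/4–1/4–1/2), by full factorial
enumeration of equal-weight subsets ($2^k - 1$ combinations), or by
Nelder–Mead search over the weight simplex maximizing mean within-family
R² across CV repeats.  The simplex constraint is enforced by optimizing
$k-1$ free logits through a softmax; runs start from every vertex plus
seeded random points, so the result provably dominates every single
component.  Because the objective uses test-set phenotypes, this is an
idealistic upper bound and is labelled `uses_test_phenotypes` in its
output.

## The synthetic panel

`simulate_panel()` emulates a NAM-like design: `n_families` biparental RIL
families sharing a reference parent, a uniform pseudomarker map (default
5 groups × 200 markers at 0.2 cM, matching the density regime the method
targets), fully inbred dosages in {0, 1}, and additive QTL with
family-specific effects.  Founder alleles are polymorphic against the
reference with probability 0.9 per marker per family, so loci can segregate
in some families and be constant in others — the structure the JF blocks
depend on.  RIL genomes follow a Markov walk with Haldane (no-interference)
recombination inflated to the selfing scale $R = 2r/(1+2r)$; Haldane was
chosen over Kosambi and is recorded in the truth record so tests cannot
conflate map functions.  The default architecture places eight QTL (four
large, base effect 1.0; four small, 0.4) on linkage groups 1–4, leaving
QTL-free chromosome arms as negative controls; family effects are modulated
deterministically in [0.7, 1.3].  Environmental noise is scaled from the
*realized* panel-level genetic variance so line-mean heritability hits the
target (default 0.7) exactly in expectation; heritability is enforced at
the panel level, not per family.  Genetic values use the latent
(pre-masking) dosage at the QTL marker, so a QTL may be invisible at its
own position in a family yet tagged by neighbours — as with real QTL that
are not themselves markers.

What the generator does *not* emulate: epistasis, dominance,
genotype-by-environment interaction, residual heterozygosity (available as
fractional dosage but off by default), segregation distortion, and
non-uniform marker spacing.  Passing tests therefore demonstrate correct
mechanics and the ensemble's behaviour under a clean additive architecture,
not performance on real data.

## Numerical and design choices

- **Thinning phase.** The stride restarts at each linkage group's first
  marker by default (genetic distance is meaningless across groups); a
  `continuous` policy is available for exact-replication attempts.  Unequal
  sub-map sizes are kept as-is; no padding or reuse.  Uniform spacing is
  detected with an absolute 1e-9 cM tolerance.
- **Distance-based thinning** windows each group from its first marker and
  takes the k-th marker of each window; the guard rejects targets below
  the minimum adjacent spacing (where no thinning can occur), while gaps
  wider than the target simply leave empty windows.
- **Stepwise details.** Entry and stay share one $\alpha$.  Ties resolve
  to the lowest map position then lexicographic id (callers pass blocks in
  map order).  A candidate whose columns are numerically within the span
  of the current design is skipped and flagged; a partially collinear JF
  block is tested on its effective rank.  Backward elimination runs after
  each entry, worst block first, and only when at least two blocks are in
  the model (a just-entered sole block always has $p < \alpha$).
  `max_steps` defaults to 200 to bound relaxed-$\alpha$ runs on dense maps.
- **Split-sample reduction.** Fold assignment is a seeded shuffle followed
  by striping (line *i* of the shuffle to fold *i* mod 5) — deterministic
  and reproducible; ties in CV error go to the smaller model, then the
  earlier step.
- **G stabilization.** `1e-8 × mean(diag)` is added to the diagonal before
  factorization.
- **Aggregation** sums each line's weighted base predictions in sorted
  order, making the ensemble bit-identical under any permutation of base
  learners.
- **Nelder–Mead convergence**: relative objective change below 1e-8 or 500
  iterations, vertex starts plus 3 seeded random restarts.

## Problem sizes

The test suite and the reproduction script run everything at desk scale,
chosen so the full pipeline exercises on one CPU in minutes: the study
panel is 5 families × 200 lines on 1 000 markers with 8 QTL at h² = 0.7;
the ensemble comparison uses 20 stratified CV replicates of EJF (s = 25,
α = 0.01) against dense-map JF at α ∈ {1e-4, 1e-3}; RMIP uses 10
resamples; the reproduction script (`scripts/acceptance.R`) runs a 7-model
grid under 5 CV repeats.  The empirical maize NAM analyses that motivated
the method (≈4 350 RILs × 7 386 markers × 25 families, 10–50 CV repeats)
are orders of magnitude larger and are not reproduced here.

## Known limitations

- With few, fully marker-tagged QTL and moderate heritability, the single
  dense-map JF model already approaches the attainable R², so the
  ensemble's advantage shrinks to within replicate noise; the method's
  large gains belong to architectures with many small QTL where single
  models leave a wide gap to heritability.
- A finite fixed panel can host chance marker–phenotype associations that
  are selected consistently across overlapping CV resamples; RMIP peaks on
  QTL-free regions of a *single* simulated panel are expected occasionally
  and are a property of resampling one panel, not of the estimator.
- The within-family "IBD" G is VanRaden method 1 applied to linkage-marker
  dosages within each family — a literal, simple reading; pedigree-based
  segment tracking is not implemented.
- The stepwise engine is OLS-based; mixed-model QTL scans, interval
  mapping, epistasis, and Bayesian whole-genome regressions are out of
  scope.
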