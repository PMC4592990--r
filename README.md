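# tagging

Ensemble learning for QTL mapping in multi-family RIL panels by **thinning
and aggregating** (TAGGING), with GBLUP companions, cross-validated
evaluation, and a synthetic NAM-like panel simulator.

## The problem and the method

On dense linkage maps (0.2-cM pseudomarker spacing is routine in nested
association mapping panels), adjacent markers are nearly collinear, which
destabilizes stepwise QTL selection and biases effect estimates, while
purely polygenic predictors (GBLUP) say nothing about where the QTL are.
TAGGING partitions the dense map into *s* disjoint sub-maps by stride
sampling (sub-map *k* takes markers *k, k+s, k+2s, …* within each linkage
group), fits one stepwise QTL model per sub-map on the *same* training
lines, and averages the predictions:

    F̂(x) = a₀ + Σₛ aₛ fₛ(x),   a₀ = 0, aₛ = 1/S.

Two base learners are provided.  The single-family model (SF, per
biparental family)

    Yᶠ = 1μ + Xβ + ε

regresses family phenotypes on dosages of the non-reference-parent allele,
and the joint-family model (JF, all P families with family intercepts A and
family-specific allele effects)

    Y = Aμ + Σᵢ Xᵢβᵢ + ε.

Marker selection is forward–backward stepwise at a partial-F threshold α,
followed by 5-fold split-sample CV pruning within the training set and an
OLS refit.  The ensembles of these learners over thinned maps are ESF and
EJF.  Around them the package provides: subagging comparators (ensembles
over within-family 80% line subsamples instead of marker subsets), VanRaden
method-1 relationship matrices and a spectral-REML GBLUP engine
(within-family SGBLUP, panel-wide JGBLUP, external-G HGBLUP), stratified
80/20 cross-validation with signed within-family prediction R²
(sign(r)·r²), exact bias²/variance decomposition of prediction error across
resamples, resample model inclusion probabilities (RMIP), equal-weight and
factorial model averaging across QTL and GBLUP predictions, and Nelder–Mead
pseudo-optimal ensemble weights on the simplex.

## Worked example

```r
library(tagging)

# a 3-family NAM-like panel: 300 RILs, 1000 markers at 0.2 cM, 8 QTL, h2 = 0.7
sim <- simulate_panel(sim_config(n_families = 3, lines_per_family = 100, seed = 7))
sim$panel
#> genotype panel: 300 lines in 3 families x 1000 markers

plan <- make_cv_plan(sim$phen, n_repeats = 2, seed = 7)
sp <- plan$splits[[1]]

# single joint-family stepwise model on the full dense map
jf <- fit_jf(sim$panel, sim$phen, sim$panel$map,
             selection_settings(alpha = 1e-3, seed = 1), lines = sp$train)
jf
#> JF QTL fit: 5 selected of 1000 tested markers

# TAGGING: 25 disjoint thinned maps, one JF base learner each
ejf <- fit_tagging(sim$panel, sim$phen, sp$train,
                   thin_map(sim$panel$map, 25), "JF",
                   selection_settings(alpha = 0.01, seed = 1))
ejf
#> tagging ensemble of 25 JF base learners

r2_jf  <- within_family_r2(list(predict_qtl(jf, sim$panel, sp$test)), sim$phen)
r2_ejf <- within_family_r2(list(predict_ensemble(ejf, sim$panel, sp$test)), sim$phen)
round(c(JF = r2_jf$mean_r2, EJF = r2_ejf$mean_r2), 3)
#>    JF   EJF
#> 0.653 0.684
```

The two numbers are mean within-family prediction R² on the held-out 20%
of each family: the proportion of trait variance explained in the test
set, averaged over families.  Here the ensemble of 25 thinned-map models
outperforms the single dense-map model on the same split; with
heritability 0.7, both are bounded above by ≈0.7 in expectation.
`rmip()` over repeated resamples then localizes the QTL, and
`fit_gblup()`/`combine_predictions()` add polygenic predictions and model
averaging.

A thin command-line wrapper for shell pipelines lives at
`inst/cli/tagging-cli.R` (`simulate`, `thin`, `run`).

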