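---
title: "Phenomic-assisted seed-yield selection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenomic-assisted seed-yield selection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phenosel)
```

phenosel implements an analysis pipeline for phenomic-assisted selection of
seed yield in multi-environment soybean-style breeding trials: canopy
hyperspectral reflectance, canopy area (CA) and canopy temperature (CT) are
used to predict genotype yield *rank* via random forests, the spectral
predictor set is compressed to four camera-deployable wavebands by a
genetic-algorithm wrapper, and the breeding value of the resulting models is
summarised by selection-intensity classification metrics. Because field data
of this kind are rarely released, the package ships a synthetic trial
generator with fully known genetic architecture; every statistical claim the
package makes is tested against that known truth.

## The trial model

All plot-level traits follow the all-random alpha-lattice model

$$y_{ijkl} = \mu + E_i + R_{j(i)} + B_{k(ij)} + G_l + GE_{il} +
\varepsilon_{ijkl},$$

with environments $E$, replicates $R$ nested in environments, incomplete
blocks $B$ nested in replicates, genotypes $G$, genotype-by-environment
interaction $GE$, and i.i.d. residuals. Fits are REML via lme4
(`fit_mixed_model()`); nested factors are expanded to unique levels
internally, and random terms with fewer than two observed levels are dropped
so reduced models (e.g. a single environment) come out of the same code
path. Genotype BLUPs are extracted two ways:

* **Method 1** (by-environment): the model is refit within each environment
  with every environment-level term removed
  ($y = \mu + R + B(R) + G + \varepsilon$), one genotype BLUP per
  environment. This matches programs where some environments carry sparse
  sensor data and each environment stands alone.
* **Method 2** (across-environment): one fit of the full model over all
  environments, a single genotype BLUP.

Exported values default to predicted genotype means ($\hat\mu +$ BLUP); the
centred BLUP deviation is available via `blup_value = "blup"`.

Outliers are flagged once per trait by conditional residuals studentized as
$r_i / (\hat\sigma\sqrt{1-h_{ii}})$ with the hat values of the mixed-model
fit, cut at $\pm 3$, and the model is refit a single time; we do not iterate
the flagging because repeated refitting changes the cutoff's meaning and
rarely changes the flagged set.

## Preprocessing

Plot quality control mirrors standard trial practice: plots whose stand
count falls more than two interquartile ranges below the first quartile of
their environment are discarded (type-7 linear-interpolation quantiles; a
plot exactly at the threshold survives because the rule is a strict
inequality); yield observations with pre-harvest shatter scores $\geq 4$
are excluded from yield analyses while their phenomics are retained; yield
is rescaled to a 13% moisture basis by the dry-matter-preserving
$y_{13} = y_{wet}(1-m)/0.87$ (the literature rarely prints its exact
formula; this is the standard one). Canopy temperature is centred within
each data-collection pass, which removes additive ambient drift while
leaving within-pass genotype contrasts untouched; z-scoring was rejected
because it would also rescale genetic variance per pass.

Spectra arrive as two scans per plot which are averaged per band; a missing
scan falls back to the remaining one with a warning. Entry-mean band
repeatability

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{g\times e}/e +
\sigma^2_\varepsilon/(re)}$$

is computed per band from the full REML fit, with negative component
estimates truncated at zero so $H^2 \in [0,1]$; bands with $H^2$ strictly
below 0.3 are dropped. Retained bands are binned into contiguous 10-nm
blocks anchored at the lowest wavelength of each contiguous segment, with
trailing partial blocks dropped — this reproduces exactly the 1780 → 178
feature count of a full-resolution spectrometer after repeatability
filtering. Features are labelled by block centre (`R705` averages
700–709 nm). Vegetation indices use their standard literature definitions
(NDVI, VREI2, NWI, RARSb, RARSc, NMDI), reading each $R_\lambda$ from the
feature whose block contains $\lambda$; the registry (`vi_registry()`) is a
plain tibble and can be replaced wholesale when a different index set is
wanted. A zero denominator gives `NaN` with a warning rather than an error,
since single degenerate plots should not abort a batch.

## Genomic parameters

Markers pass the usual QC (missing rate > 10% dropped, marker-mean
imputation, then MAF < 5% dropped — mean imputation replaces haplotype
phasing tools, which is adequate below 10% missingness). The additive
relationship matrix is VanRaden's
$A = WW^\top / 2\sum_k p_k(1-p_k)$ on frequency-centred codes.

SNP heritability fits $y = \mu + Zu + \varepsilon$,
$u \sim N(0, A\sigma^2_g)$, with $y$ the Method-2 BLUPs. The implementation
eigen-rotates by $A$, reducing REML to a one-dimensional profile over the
variance ratio, maximised by golden-section search over
$\log\lambda \in [-12, 12]$; the standard error of
$h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$ comes from the numerically
differentiated observed information and the delta method. Genetic
correlations come from the bivariate model with genetic covariance
$G_0 \otimes A$ and residual covariance $R_0 \otimes I$: after the same
rotation the restricted likelihood factors into per-genotype $2\times 2$
blocks and is maximised directly over log-Cholesky factors of $G_0$ and
$R_0$ (Nelder-Mead, means profiled out by GLS), which keeps both matrices
positive semidefinite by construction — the reason we chose direct
maximisation over an EM sketch. $r_g$ is clipped to $[-1,1]$ with a warning
when the optimum sits on the boundary, and flagged undefined when a genetic
variance collapses below $10^{-6}$ of the trait's total. Both estimators
are cross-checked in the tests against brute-force dense-matrix restricted
likelihoods.

At these panel sizes the sampling error of $h^2_{SNP}$ is intrinsically
large (essentially unrelated accessions give the GRM little leverage), so
recovery checks compare medians over 20 simulation seeds, not single draws.

## Prediction experiments

Random forests (ranger, 500 trees, single-threaded and seeded for
determinism) map trait-table predictors to yield BLUPs. When mtry is not
tuned we use the classical regression default of one third of the
predictors; tuning, when requested, is a small mtry grid scored by repeated
k-fold cross-validation inside the training set (5-fold, 1 repeat by
default — a desk-scale default; heavier schemes are one argument away).
Out-of-bag $R^2$ and RMSE are recorded with every fit.

Two cross-validation scenarios mirror breeding questions: CV1 predicts
untested genotypes in observed environments (random 80/20 genotype split,
all environments); CV2 predicts untested genotypes in an unseen environment
(for each complete environment, training uses the other environments'
rows of the training genotypes only). Test genotypes never contribute
training rows in either scenario. With 292 accessions the splits are
234/58 at 80/20 and 175/117/58 at the 60/40/20% training fractions. The
experiment grid (`run_cohort_experiment()`) pairs CV1 and CV2 on the same
genotype partitions within an iteration, so the scenario contrast is not
confounded with partition luck; accuracy is the Spearman rank correlation,
computed within each test environment and averaged (pooled correlation
available by flag, since reports in this field rarely state which was
used). Predictor cohorts — canopy, vegetation indices, canopy+VI, and
binned wavebands — reference trait-table columns by name, so custom cohorts
are trivial.

## Waveband optimization

The genetic algorithm searches subsets of `n_select = 4` spectral bins,
matching the four-filter budget of customizable multispectral cameras. A
chromosome is a set of distinct bins; by default each bin contributes its
feature at both growth stages (8 model features), honouring a camera that
flies at every stage — the alternative reading (4 stage-tagged features
from the doubled space) is available via `stage_shared = FALSE`. Fitness is
the mean Spearman correlation of a reduced forest (100 trees) over an
internal genotype k-fold of the *training* rows only; the held-out test set
is never touched by the search, and fitness values are cached by chromosome
key. Operators are tournament selection (size 3), uniform crossover
repaired to distinctness, per-gene mutation to an unused bin, elitism (2),
with early stopping after a stalled patience window. The defaults
(population 50, 30 generations, crossover 0.8, mutation 0.1) are standard
wrapper-selection settings; the published studies' exact settings are not
recoverable, so all are configurable. The final multisensor model retrains
a full 500-tree forest on the selected bins plus the vegetation index of
largest $|r_g|$ with yield and the canopy traits.

## Selection metrics

At selection intensity $\alpha$ (default 20%), "positive" means membership
in the top $k = \max(1, \mathrm{round}(\alpha n))$ by rank, determined
separately for observed and predicted values with ties broken by the stable
order of genotype identifiers. From the counts,
$SPE = TN/(TN+FP)$, $FS = 2TP/(2TP+FP+FN)$, and balanced accuracy
$BAC = (TPR + TNR)/2$ — the standard definition; printed formulas for this
quantity in the applied literature are frequently garbled, and the mean of
sensitivity and specificity is the interpretation consistent with its name.

## The synthetic trial generator

`simulate_panel()` generates, under one seed, everything the pipeline
consumes, with ground truth recorded for recovery tests. Defaults mirror a
diverse-accession study: 292 genotypes in 6 environments (2 replicates,
30 incomplete blocks), 35k biallelic SNPs with 200 causal markers behind
the yield genetic value, spectra on a 1-nm grid over 350–2500 nm at two
growth stages, and two of the six environments carrying yield but no
phenomics. Key constructions:

* **Yield** follows the trial model above. The genotypic variance is derived
  from `h2_yield` so the entry-mean repeatability equals it exactly; the
  default variance ratios make genotype-by-environment variance four times
  the genotypic variance (a diverse panel across variable site-years) while
  environment main effects are kept modest — they are nuisance for
  rank-based evaluation, and large values mostly stress the learner with
  level variance unrelated to ranking.
* **Spectra** are a smooth vegetation baseline plus, per band: a
  genotype-level genetic deviation whose correlation with the yield genetic
  value follows a smooth bump peaking at each informative region's centre
  (flat profiles are unrealistic and would cancel in band-difference
  indices); a genotype-by-environment deviation correlated with yield G×E;
  environment offsets (smooth across bands); and plot/scan noise. Band
  genetic variances are sized from a target repeatability profile
  (0.15–0.40 background, up to 0.8 at region centres).
* **Reaction-norm heterogeneity.** The coupling of spectral G×E to yield
  G×E, and the expression strength of each informative region, vary by
  environment (expression is normalised to mean 1 over the
  phenomics-complete environments so planted targets hold on average).
  This is what makes an unseen environment genuinely harder to predict:
  which spectral regions carry signal, and how strongly, differs by
  environment, so a model without training data from the target
  environment weights regions suboptimally there.
* **Canopy traits** carry genetic correlations with yield of 0.33/0.25 (CA
  at the two stages) and −0.44 (CT), their own G×E partially aligned with
  yield G×E, and CT carries per-pass ambient drift for the normalization
  step to remove.
* **Plot degradation**: 1% of plots get very low stand counts and 1% get
  shatter scores ≥ 4, so the quality filters always have work to do.

What the generator does *not* emulate: radiative-transfer realism of
spectra, weather, spatial field trends beyond the block structure, linkage
disequilibrium or population structure in the marker panel, and non-additive
genetic architecture. Passing tests therefore demonstrate the pipeline's
statistical correctness and its qualitative behaviour under a known
G×E-dominated architecture — not calibrated performance on any particular
real dataset, whose headline accuracies depend on unreleased field data.

## Problem sizes used in the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) run at
desk scale, chosen as the smallest sizes at which the estimators' sampling
error does not swamp the effects being demonstrated: parameter recovery at
300 genotypes × 6 environments over 20 seeds (2000 markers for the genomic
parameters); the planted-signal experiments on a 250-genotype ×
6-environment panel with a 10-nm spectral grid over 400–2170 nm (178 bins
per stage — the size of the full-resolution search space after
repeatability filtering — with four planted informative regions),
genetic-algorithm settings of population 24 over 12 generations with
3-fold fitness evaluation (the ten recovery replicates share one fixed
fitness objective, i.e. the same folds and fitness-forest seed, so they are
replicate searches of a single landscape), 3 paired iterations of the
cohort grid, and 3 iterations per training fraction of the
selection-intensity study. Panel size matters for the waveband-recovery
experiment specifically: in panels much smaller than ~250 genotypes, chance
genotype-level correlations of high-repeatability background bands become
genuinely informative in the realized sample and a correct optimizer will
pick some of them; region recovery is therefore asserted at a panel size
where planted regions dominate chance. The full-resolution defaults remain
available for users with more patience.

## Known limitations

Method-2 BLUP tables are computed once from all environments, so in CV2 the
across-environment BLUPs of training genotypes technically contain signal
from the held-out environment (the published design has the same property;
test genotypes are still never seen). The bivariate REML's standard errors
rely on numerical Hessians and can be unstable near the $|r_g| = 1$
boundary. The emergence filter assumes stand counts are comparable within
an environment; it is not a spatial model. And the genetic-algorithm
fitness is itself a random variable — with small fitness forests, reruns
under different seeds can select neighbouring bins within the same region,
which is why recovery is asserted at region, not bin, resolution.
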