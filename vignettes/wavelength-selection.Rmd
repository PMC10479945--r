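---
title: "Wavelength selection for diffuse reflectance tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection for diffuse reflectance tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specsel)
```

## The problem

Broadband diffuse reflectance spectroscopy (DRS) measures how strongly a
tissue reflects light across hundreds to thousands of wavelength bins. For
surgical guidance — for example distinguishing bone cement from cortical
bone, marrow, cartilage, muscle and trabecular bone during revision
arthroplasty — a full spectrometer is impractical; the instrument one
actually wants is a handful of LEDs at well-chosen wavelengths. The
statistical obstacle is severe multicollinearity: neighbouring wavelength
bins are nearly identical, so many different small subsets classify equally
well, while most univariate rankings return an uninformative cluster of
adjacent bins.

`specsel` implements four complete wavelength-selection frameworks that
attack this problem from different directions, a common one-versus-rest
(OVR) evaluation protocol, the spectral preprocessing chain that precedes
them, and a synthetic-spectra generator with planted, known ground truth so
that every framework can be validated end to end without access to any
proprietary dataset.

## Preprocessing model

A measurement arrives as five consecutive raw repeats per spectrometer
channel, a reflectance-standard reference and a dark background. The chain
is applied in acquisition order:

1. **Repeat averaging** — element-wise mean over repeats.
2. **Reflectance calibration** — `(S_raw - S_bkgd) / (S_ref - S_bkgd)`,
   element-wise. Calibrated values are *not* clipped to [0, 1]: downstream
   methods are scale-tolerant and clipping would bias peak picking near
   strong absorbers.
3. **Splicing** — the fine channel (~0.76 nm bins, 355–1100 nm) and the
   coarse channel (1.6 nm bins, 1100–1850 nm) are merged at the 1100 nm
   junction using natural cubic splines; the target axis is the
   concatenation of the two native grids with near-duplicate bins within
   half a coarse bin of the junction dropped, the low band winning at the
   junction bin itself. Both bands must reach within 10 nm of the junction
   or a gap error is raised.
4. **Savitzky–Golay smoothing** — frame 5, polynomial order 2, applied per
   row. Boundary bins use the filter's least-squares polynomial edge fits
   rather than mirror padding: mirror padding is *not* exact for
   polynomials at the edges, whereas the least-squares scheme preserves any
   quadratic to machine precision over the whole axis, which is the
   property the test suite pins down. The axis length is preserved.

All wavelength bookkeeping is done by nm value rather than by index, so the
mixed-resolution axis is handled uniformly; nearest-bin lookup breaks ties
toward the lower wavelength.

## Evaluation protocol

Every task is binary one-versus-rest: the positive class against everything
else. The metric is **balanced accuracy**, the arithmetic mean of
sensitivity and specificity,

$$\mathrm{BA} = \tfrac12\left(\frac{TP}{TP+FN} + \frac{TN}{TN+FP}\right),$$

which is 0.5 for any constant predictor regardless of class imbalance. The
protocol holds out a stratified 20% split, and scores feature subsets by
stratified 10-fold cross-validation with 10 repeats on the training split.
Six reference classifiers are pinned explicitly rather than left to library
defaults that drift across versions: ridge-penalized logistic regression
(lambda = 1/n, the C = 1 convention — unpenalized maximum likelihood is
ill-posed when features outnumber samples), LDA, random forest (100 trees),
k-nearest neighbours (k = 5), Gaussian naive Bayes, and an RBF SVM (cost 1,
variance-scaled gamma = 1/(p·var X)). No feature standardisation is applied —
the methods operate on raw calibrated reflectance, and overall intensity is
itself informative. Score ties break toward the negative class. LDA is the
default scoring classifier because it is consistently the strongest of the
six on this kind of data.

## The four selection frameworks

All frameworks return a ranked subset of at most *k* = 10 wavelengths plus
top-1/top-10 cross-validated and holdout balanced accuracies.

**PCA framework.** Centred PCA (via SVD) on the training split; the first
30 components form the pool. Simulated annealing (600 iterations) searches
for the 10 components that jointly maximise LDA CV accuracy; the search is
skipped when the deterministic initial state (leading components) already
scores 100%. Candidate wavelengths are then read off the selected
eigenvectors: each |loading| vector is normalised to max 1, local maxima at
or above 20% height become candidates, and peaks within 20 nm of a stronger
peak are removed (candidates are pooled across components before the 20 nm
rule). The final subset is produced by ANOVA-F-ranked greedy collinearity
removal. Eigenvector sign ambiguity is resolved by taking absolute loadings.

**Moving-window LDA framework.** The axis is tiled with non-overlapping
windows of 25, 50, 75, 100, 150, 200 and 300 nm; a binary LDA fitted inside
each window nominates its largest-|coefficient| feature. Pooled nominations
are deduplicated with a 30 nm separation rule, the top 75% survive a
collinearity-aware re-ranking (LDA refit on the candidate set), and
simulated annealing (2000 iterations, always active) picks the final 10 by
LDA CV accuracy. Tiling was chosen over overlapping strides because
overlaps only inflate duplicates that the 30 nm rule removes again.

**Backward interval PLS (biPLS) framework.** The axis is tiled into
intervals of 20, 40, 60, 70, 80 and 95 nm. For each interval size and each
of five fixed CV shuffles, the interval whose deletion most lowers the PLS
RMSECV is removed recursively, starting from the all-feature baseline,
until no deletion improves (the class is regressed as a 0/1-coded PLS1
response; component count is chosen per fit by the RMSECV minimum). Every
feature inside a surviving interval earns one vote per run. Features at the
highest vote levels form the candidate pool, expanded level by level until
it contains at least 3k candidates that are 20 nm-separable; the final 10
are the least collinear by VIP (variable importance in projection, computed
from weights, score variances and explained response variance, so that
mean(VIP²) = 1 — an identity asserted in the tests). The inner PLS is
evaluated in kernel form on per-fold Gram matrices, which makes the
thousands of interval-deletion evaluations per run affordable; this is an
algebraically exact reformulation, verified against the plain NIPALS fit to
machine precision.

**Ensemble framework.** Three univariate filters each rank 100 features:
mRMR (relevance = ANOVA F expressed on its point-biserial correlation scale
so the difference criterion against mean |Pearson| redundancy is
meaningful), mutual information (nearest-neighbour estimator for the
continuous-feature/discrete-label pair, with a plug-in fallback for
near-discrete features), and binary ReliefF (10 neighbours, all instances).
Their union enters a shadow-feature random-forest wrapper: in each
iteration every candidate competes against the maximum importance among
column-permuted shadow copies, and a two-sided binomial test at alpha 0.05
confirms or rejects it (100 iterations maximum, 200 trees, early exit when
all features are decided). The confirmed rank is finalized two ways:
**SB** (spectral band) takes the top 10 by ANOVA F with no separation
constraint, typically yielding one narrow contiguous band; **LC** (least
collinear) first enforces a 20 nm minimum separation — the bandwidth of a
typical LED — then applies greedy collinearity removal. Tree-SHAP
contributions (exact, from the gradient-boosted trees' `predcontrib`
output) explain the final model on the holdout split; local accuracy
(base value + contributions = margin) holds within 1e-6 with the default
boosting configuration (30 rounds, depth 3, eta 0.05), which is deliberately
moderate so that single-precision contribution sums stay tight. The
framework can be run per spectral range (VIS 355–700, VIS/NIR 355–1000,
VIS/NIR/SWIR 355–1850 nm) and aggregated incrementally.

### Shared machinery and its edge cases

* **Greedy collinearity removal** accepts the most relevant remaining
  candidate and discards the single remaining candidate most
  |Pearson|-correlated with it — but only while the pool still exceeds what
  is needed to reach *k*, so an uncorrelated pool of size *k* is returned
  whole. An alternative discard-all-above-threshold variant is exposed as
  an argument. Relevance ties break toward the lower wavelength;
  zero-variance columns get relevance 0 and correlation 0 so degenerate
  inputs never break the pipeline.
* **Simulated annealing** starts from the deterministic top-k-by-relevance
  state, proposes uniform single swaps, accepts improvements always and
  deteriorations with probability exp(delta/T) under geometric cooling
  (t0 = 0.05, cooling 0.995 — chosen to match the 600/2000-iteration
  budgets), and returns the best state ever visited. Because accuracies are
  bounded by 1, the search also halts once the incumbent reaches that
  bound; for unbounded costs this cap can be disabled.
* **LC-path separation.** Least-collinear finalization applies the 20 nm
  minimum-separation rule before correlation removal. On contiguous-bin
  pools, correlation removal alone cannot guarantee spectrally distinct
  features (it discards one neighbour per acceptance while clusters are
  many bins wide); the separation-then-decorrelation combination is what
  makes the final subsets realisable with LEDs of typical FWHM.

## The synthetic generator

Real extended-wavelength DRS data of this kind is not publicly deposited,
so the package ships a generator that emulates its structure with known
ground truth. Each spectrum of class *c* is

$$x_i(\lambda) = s_i \, b_c \, B(\lambda)\,
  \exp\!\Big(-\sum_b a_{cb}\,\xi_{ib}\, G(\lambda;\mu_b,w_b)\Big)
  + \varepsilon_i(\lambda),$$

a Beer–Lambert-style attenuation of a smooth shared broadband baseline
$B(\lambda)$ scaled per class ($b_c$), with unit-height Gaussian
chromophore bands $G$ (hemoglobin 550/576 nm, collagen 1200/1500/1725 nm,
lipid 1210 nm, water 1440 nm), iid additive noise $\varepsilon$
(sd 0.02), a per-measurement intensity factor
$s_i = e^{N(0,\,0.08^2)}$ emulating probe-coupling variability, and
per-measurement band-amplitude factors $\xi_{ib} = e^{N(0,\,0.30^2)}$
emulating between-specimen chromophore variability. The two jitter terms
are what make the task realistically imperfect: with iid per-bin noise
alone, any classifier that pools ~1450 bins averages the noise away and
every task saturates at 100%. With the default settings the hardest task
(cortical bone vs rest) sits near 95% balanced accuracy with all features,
while bone cement vs rest remains fully separable — the qualitative
pattern expected of a non-biological specimen with a distinct overall
intensity and no chromophore absorption.

The six default classes are parameterised as caricatures of their tissues:
marrow lipid-rich, cartilage water-rich, muscle blood-rich, cortical bone
collagen-rich, trabecular bone intermediate, bone cement band-free. The
amplitudes were chosen so that each benchmarked OVR task has a small set of
**task truth bands** — bands whose positive-class amplitude differs from
*every* rest class (beyond a 0.05 tolerance): lipid 1210 and water 1440 for
bone cement; collagen 1500 and 1725 for cortical bone. Recovery is scored
against a band's spectral extent (centre ± FWHM/2) plus a 20 nm slack,
because broad overlapping bands displace the discriminative optimum tens of
nm from the nominal centre while remaining inside the absorption feature —
distance-to-extent is the quantity that matters for LED placement.

What the generator does *not* emulate: wavelength-dependent scattering
slopes, instrument etaloning, detector nonlinearity, specimen-level
(hierarchical) correlation between repeated measurements, and class-overlap
from genuinely mixed tissue volumes. Passing the recovery tests therefore
shows that the frameworks find planted, localised, class-consistent
absorption differences under realistic intensity and amplitude jitter — it
does not certify performance on any particular instrument's data.

## Numerical choices and problem sizes

* All randomness flows from a single seed per run; splits, CV folds, SA
  moves, filter jitter, the RF wrapper and synthesis derive child streams
  deterministically, so every report is byte-reproducible (the JSON
  serialization excludes wall-clock runtime for exactly this reason).
* Internal SA costs use 3-fold single-repeat LDA CV: the cost only ranks
  subsets, and the cheaper fold shape keeps the 600/2000-iteration budgets
  practical on a single core.
* The biPLS framework exposes `bin_step` (wavelength subsampling),
  `row_frac`, `folds` and `max_components` as desk-scale controls; the
  packaged validation runs it with every 12th bin, 3 folds and 5
  components on ~600-spectrum datasets, where one full framework run takes
  tens of seconds. At full resolution the elimination sweep is quadratic in
  the interval count and is the dominant cost of the whole package.
* The end-to-end validation suite runs each framework on both OVR tasks
  across 10 generator seeds (~600 spectra, ~1450 bins each) and checks that
  every task truth band is recovered in at least 8 of 10 seeds, that LC
  finals are pairwise ≥ 20 nm apart (30 nm at the LDA candidate stage) with
  no perfectly correlated pair, and that the ensemble-LC sequential-
  inclusion curve plateaus within 3–4 features on three-band data.

## Known limitations

* The moving-window LDA relevance compares |coefficients| across windows of
  different sizes, which is not scale-free; the subsequent refit on the
  pooled candidates mitigates but does not remove this.
* The vote table in biPLS can be nearly saturated when elimination stops
  early (deleting noise intervals does not always lower RMSECV); the
  VIP-ranked finalization is what restores discrimination in that regime.
* The shadow-feature wrapper controls per-feature error via the binomial
  test but makes no multiplicity correction across features; with large
  pure-noise pools a few false confirmations are expected and tolerated by
  design.
* mRMR uses the point-biserial transform of F so that relevance and
  redundancy share the [0, 1] scale; with raw unbounded F the redundancy
  term would be vacuous.

## A minimal run

```{r example, eval = FALSE}
cfg <- default_ewdrs_config(seed = 11)
gen <- generate_dataset(cfg)
protocol <- eval_protocol(seed = 11)
report <- run_pca_framework(gen$dataset, "cortBone", protocol = protocol)
report
bands_recovered(report$subset$nm, ovr_truth(cfg, "cortBone"))
```
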