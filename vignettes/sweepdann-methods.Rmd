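---
title: "Detecting and classifying selective sweeps under simulation-to-genome covariate shift"
author: "sweepdann"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying selective sweeps under simulation-to-genome covariate shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Supervised sweep classifiers are trained on coalescent simulations because
real genomes carry no labels. The implicit assumption — that simulated and
real haplotype data are draws from one distribution — rarely holds: inferred
demographies, recombination maps and selection parameters are imperfect, so
the feature distributions of the two domains differ (covariate shift), and a
classifier fit on simulations alone degrades on the genome it is meant to
scan. `sweepdann` addresses this with a domain-adversarial neural network
(DANN): a convolutional feature extractor is trained so that a 5-class sweep
predictor succeeds on labeled simulations *while* a domain discriminator,
coupled through a gradient-reversal operator, fails to tell simulated from
real feature matrices. The extractor is thereby pushed toward
representations that are both class-informative and domain-invariant, and
training is transductive: the unlabeled target windows to be scanned
participate in training through the discriminator branch.

The five classes are `hard`, `linked_hard`, `soft`, `linked_soft`, and
`neutral`, in that fixed order everywhere in the package. A sweep case has
its selected site inside the central segment (0.475 L, 0.525 L) of the
fragment; linked cases place it outside that segment; neutral cases have
none.

## Feature engineering

Each genomic fragment (simulated case, or a `w` = 1 Mb sliding window
stepped by `s` = 50 kb along a chromosome) becomes a 40 × m feature matrix:

1. **Feature windows.** `n` central SNPs are chosen evenly over the
   eligible range, each defining a window of `2k + 1` SNPs. A fragment with
   fewer than `2k + n` SNPs is excluded. Window position is the mean
   physical position of its SNPs. Because window spans adapt to SNP
   density, diversity troughs widen windows — itself a sweep signal.
2. **Statistics.** 40 summary statistics per window (below).
3. **Positional encoding.** The fragment is cut into `m` equal bp
   intervals; each statistic is averaged over the windows whose positions
   fall in an interval, and empty intervals are zero-filled — zeros *mean*
   "no variation here", which is informative for selection.

Defaults are `n = 200, k = 25, m = 200, w = 1e6, s = 5e4`. The desk-scale
studies in the tests and the acceptance script use `n = 64, k = 12, m = 64`
on 100 kb fragments of 50 haplotypes so that a full
simulate–featurize–train–evaluate cycle fits in minutes on one CPU; these
sizes are stated here once and used consistently.

Feature rows are max–min standardized to [0, 1] per statistic, with the
scale fitted on the source training set and re-applied to validation, test
and target data. Fitting the scale per dataset independently is available
via the `scale` argument of `featurize_cases()`, but re-applying the
training scale is the default because it cannot leak target information
and keeps a single fixed mapping at prediction time. Non-finite statistic
values (e.g. the log-ratio of an empty EHH integral) are clamped to the
finite extremes of their feature row before scaling, so one degenerate
window cannot crush the dynamic range of a whole row.

## The 40 statistics

Three groups, reflecting what each contributes:

* **Polymorphism and SFS shape** (selection vs neutrality): pi, Watterson's
  theta, theta_H, Fay & Wu's H, Tajima's D, number of segregating sites,
  raw moments 1–5 and Shannon entropy of the per-site derived-allele
  frequency distribution, delta-AF (window mean derived frequency minus the
  run baseline), singleton proportion, high-frequency-derived proportion,
  and window bp span (a fixed-SNP window stretches over a diversity trough).
* **Favored-mutation localisation** (selection vs linkage): per-site phi,
  kappa and SAFE summaries (mean/max, plus SAFE at the central SNP), and
  the per-haplotype HAF score summarized as mean, max and variance. SAFE is
  the phi–kappa contrast standardized by the binomial null standard
  deviation at the variant's frequency.
* **Haplotype structure** (hard vs soft): number of distinct haplotypes,
  haplotype heterozygosity and entropy, H1, H12, H123, H2/H1, top-two
  haplotype frequencies, unstandardized iHS and nSL, delta-iHH, and the
  derived/ancestral iHH integrals themselves.

The published roster totals 40 but its full list lives in supplementary
material; the registry (`sweep_stat_registry()`) is therefore an ordered,
named, user-replaceable list — any 40-slot roster reproduces the exact
pipeline shape. EHH decay is integrated by the trapezoid rule over physical
distance (iHS) or SNP count (nSL), truncated at EHH < 0.05 or the window
edge; fixed-size windows make the genome-scan convention of discarding
non-decayed cores inapplicable, so truncation is used instead. Entropy uses
the natural log (any base is absorbed by max–min scaling). Within-run iHS
standardization in 20 derived-frequency bins is provided
(`ihs_standardize()`) for users who want the conventional z-scores; the
registry exposes the unstandardized values, which the max–min step rescales
anyway.

## The model

* **Feature extractor** (the "(1,n)/(m,1)" design): a (1,5) convolution and
  (1,4) max-pool first scan each statistic's positional series in
  isolation; a (3,1) convolution and (2,1) max-pool then mix adjacent
  statistics at a fixed position; two residual bottleneck modules (1×1
  reduce by 4, (3,1) conv, 1×1 expand) mix channels cheaply. Statistic rows
  are deliberately *not* exchangeable: row identity carries meaning, and
  the first stage never blends rows.
* **Classifier**: four fully connected layers (batch-norm after the first
  two, ReLU activations, dropout 0.5, softmax output over the 5 classes).
* **Discriminator**: three fully connected layers ending in a sigmoid;
  source = 0, target = 1, so well-aligned target data scores *below* 0.5.
  The discriminator carries no dropout: this keeps the RNG stream of a
  lambda = 0 run identical to a plain supervised run, making the ablation
  identity exactly testable, and dropout inside a domain critic is not
  conventional anyway.

The objective is `(1/n) sum L_y − lambda (1/N) sum L_d` with 5-class
cross-entropy `L_y` on source cases and binary cross-entropy `L_d` on all
cases; the discriminator reaches the extractor through gradient reversal
(identity forward, gradient scaled by −lambda backward), so a single Adam
loop trains all three parts: the discriminator descends `L_d`, the
extractor ascends it. `lambda` is fixed at 1, the published setting; a
warm-up schedule was considered and not adopted since the source work holds
lambda constant. Optimization uses Adam (lr 1e-3), batch size 64, up to
~40 epochs with early stopping (patience 10) on validation loss, and a
validation-selected checkpoint. Every run is seeded: same config and seed,
same model, bit for bit.

**Deep ensembling** trains `M` models from independent initializations
(consecutive seeds) and averages their predictive distributions; `M = 5` by
default (unstated in the source work; 5 balances variance reduction against
cost). **smoothGrad saliency** reports the mean absolute input gradient of
the predicted-class score (the pre-softmax activation — probability
gradients vanish once the classifier saturates) over Gaussian-perturbed
copies of an input grid (noise sd 0.1 on the [0,1] feature scale, 25
samples).

A note on gradient checking: with zero-initialized biases, rectified units
whose inputs are exactly zero sit on the ReLU kink where the subgradient is
ambiguous; finite-difference tests therefore jitter parameters away from
zero first. This is a property of testing, not of training.

## Synthetic data

`fixture_sweep_generator()` is a parametric, coalescent-free generator used
for all self-contained training and testing (an external discoal-compatible
binary can be plugged into `simulate_case()`; the package builds the
command line and parses ms-format output). It emulates:

* a neutral background with `E[S] = theta a_n` segregating sites, neutral
  SFS (`p(c) ∝ 1/c`), exchangeable carrier assignment, uniform positions;
* sweeps by copying a swept subset of haplotypes (final beneficial
  frequency drawn on [0.7, 0.98]) from one founder (hard) or 2–3 founders
  (soft) over a contiguous segment around the selected site, with
  exponentially distributed per-side extents playing the role of the
  nearest recombination breakpoints. The mean extent is the classical
  hitchhiking width `s / (2 r ln(4 Ne s))`. The diagnostic helper
  `sweep_footprint()` implements the printed approximation
  `s / (4 Ne r ln(Ne s))` (natural log), which is this width up to a
  ~2 Ne factor; the generator uses the bp-scale version because its decay
  length must live on the physical axis.
* per-case selection coefficients drawn log-uniformly from
  `s_range = [0.005, 0.1]` under the source scenario, so training spans
  weak-to-strong sweeps the way simulation studies draw `s` from a prior;
  mismatch-grid scenarios fix `s` instead, since each grid cell *is* a
  single parameter combination.

Defaults (`Ne = 1e4, mu = 1.25e-8, L = 1e5, 50 haplotypes`) give roughly
220 segregating sites per fragment — ordinary values for a human-like
population. The default recombination rate is `r = 1e-7` so that a 100 kb
desk-scale fragment carries the same per-fragment recombination budget —
and therefore the same footprint-to-fragment-length geometry across the
selection-coefficient prior — as a megabase scan window at the human-like
`1e-8`; full-scale runs should pair `r = 1e-8` with `L = 1e6`. What the generator does **not** emulate: genealogical
correlation between sites (background LD), demography-driven SFS
distortions, background selection (only a real simulator produces it —
the BGS robustness scenario is reachable only through the external
backend), gene conversion, and sequencing artifacts. Tests passing on
fixtures therefore certify the pipeline and the statistics, and the
*relative* behavior of architectures and training modes, not absolute
real-genome performance.

The 16-scenario mismatch grid crosses four recombination rates
{3.125e-9, 1.25e-8, 2.75e-8, 3.75e-8} with four selection coefficients
{0.0075, 0.025, 0.075, 0.2}, containing the published corner values.
Robustness transforms implement missing contiguous regions (default 20% of
fragment bp), recombination-rate heterogeneity (piecewise rate maps applied
to a configurable fraction of cases, default 50%), low-recombination
scenarios (r divided by 5/10/50/100), and class imbalance (resampling to
given weights).

## Diagnostics

Distribution mismatch between domains is quantified three ways, mirroring
the verification logic of the source study: per-statistic two-sample K–S
and Mann–Whitney tests (raw p plus Benjamini–Hochberg q, since 40 tests run
in parallel), joint PCA of pooled feature summaries, and a cross-validated
RBF-SVM domain-classifier AUC with label-shuffle negative controls. The CV
AUC is the mean of per-fold AUCs — decision values from different fold
models live on different scales and must not be rank-pooled. AUC itself is
computed by the rank formula, making the AUC = U/(n1 n0) identity explicit.
For evaluation, sweep classes are positive and linked + neutral negative;
the model's scalar sweep score is P(hard) + P(soft), per-type ROCs are
one-vs-rest against the linked + neutral negatives, and classical
single-statistic comparisons use the extreme absolute statistic over the
central [0.45 L, 0.55 L] region. Confusion matrices put true labels in
columns and predictions in rows, column-normalized.

## Numerical and design choices

* Positional intervals are left-open/right-closed; position 0 joins
  interval 1. Central-SNP spacing uses
  `round(k + t (total − 2k − 1)/(n − 1))`.
* Constant feature rows standardize to 0; apply-mode scaling clips to
  [0, 1].
* EHH cores must split the window into carrier sets of at least 2; when the
  central SNP cannot, the nearest eligible site is used, and when none is,
  the EHH-family entries are 0.
* Coordinates are 0-based half-open throughout; overlapping sliding-window
  predictions are reported per fragment, unmerged.
* Master seeds expand deterministically into per-stage streams, so every
  pipeline stage is independently reproducible and resumable.
* VCF input uses the `AA` ancestral-allele INFO field when present;
  otherwise the data are folded to major/minor coding with a warning, which
  changes the meaning of the polarization-dependent statistics (theta_H, H,
  iHS, HAF, SAFE) and should be interpreted accordingly.

## Known limitations

The fixture generator's mosaic-free collapse makes sweep signals somewhat
cleaner than coalescent simulations produce; accuracies on fixtures at a
given training size are therefore optimistic relative to discoal-based
training. The desk-scale architecture comparison preserves directions, not
published magnitudes. Real-genome scans additionally require phased,
polarized variants and enough SNP density to pass the `2k + n` rule per
megabase; fragments failing it are skipped and logged, exactly as the
exclusion rule dictates.
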