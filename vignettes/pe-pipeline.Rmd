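---
title: "Modelling reward prediction-error fMRI with pefmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward prediction-error fMRI with pefmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pefmri implements a complete analysis chain for studies of reward
prediction-error (PE) signalling in early psychosis: a probabilistic
monetary learning task, Q-learning modelling of choices, first-level fMRI
GLMs with a value-balanced PE contrast, and group-level permutation
inference with threshold-free cluster enhancement (TFCE). Because raw
patient data of this kind cannot be redistributed, the package ships a
synthetic-cohort generator calibrated to the published group-level
statistics; the generator is first-class, tested code, and everything the
inference machinery reports is computed from data the generator produced.

## The task

Participants choose between two abstract stimuli on each of 90 trials, 30
per pair type:

* **reward pairs** — one stimulus wins £1 with probability 0.8 (neutral
  feedback otherwise), the other with probability 0.2;
* **bivalent pairs** — either stimulus wins or loses £1 with probability
  0.5 each;
* **neutral pairs** — two kinds of neutral feedback with 80/20
  probabilities; no money changes hands.

`generate_schedule()` builds the trial list. Trial order is
pseudo-randomised by a constrained shuffle (no more than four consecutive
trials of one pair type — the constraint actually used in the original
experiment is not documented, so this run-length rule is the package's own
choice), and the side of the high-probability stimulus is exactly
counterbalanced within pair type, which is why the per-pair trial count
must be even. In bivalent (and neutral) pairs the designation of a
"correct" stimulus is arbitrary; it is fixed per schedule so that choice
preferences can be scored.

## The Q-learning model

Choices are modelled with the standard single-learning-rate
Rescorla–Wagner/softmax agent. The chosen stimulus's value is updated by

$$\delta_t = r_t - Q_t, \qquad Q_{t+1} = Q_t + \alpha\,\delta_t,$$

with values maintained independently per pair and the unchosen stimulus
untouched, and choice probabilities follow a logistic (softmax) rule in the
value difference with inverse temperature $\beta$. Initial values are 0 and
only monetary value enters the update ($r \in \{+1, 0, -1\}$; neutral
feedback is worth 0). This is the standard variant of the model in this
literature; alternatives (separate learning rates for gains and losses,
non-zero initial values) are deliberate non-goals.

`fit_q_model()` estimates $(\alpha, \beta)$ per subject by maximum
likelihood: Nelder–Mead on a logit/log-rescaled parameterisation (so the
optimiser is gradient-free and the bounds $\alpha \in [0.001, 0.999]$,
$\beta \in [0.01, 20]$ are respected exactly), with 10 random restarts by
default and ties broken by lowest negative log-likelihood, then lowest
$\beta$. A fit that lands on a bound is flagged `converged = FALSE`; with
all-identical choices this happens by construction. The $\beta = 0$ model
is nested, so the fitted likelihood can never fall below $n\log 2$; the
test suite asserts this per subject. At 90 trials the learning rate is
recovered with substantial noise (the acceptance tests document mean
absolute error and rank correlation at 50 agents); recovery tightens
markedly at 900 trials, which the property tests check in a scaled form
(90 vs 900 trials, 8 agents).

The PE series that feeds the imaging forward model is the replay of the
recorded choices and outcomes under a given parameter set
(`pe_series()`); with $\alpha = 0$ it degenerates to the raw outcome
values.

## Why the contrast works

At the learned fixed point the value of the high-probability reward
stimulus approaches 0.8, so a £1 win there elicits a small positive PE
(about 0.2), while bivalent values hover around 0 and a bivalent win
elicits a PE near 1. Contrasting **bivalent wins minus reward wins**
therefore isolates high versus low positive PE while both events deliver
exactly £1 — outcome value cancels. The package verifies both halves of
this logic by simulation: a value-only BOLD response (all wins at equal
amplitude) produces a zero expected contrast, and a PE-scaled response
produces a positive one.

## First-level model

`events_from_behaviour()` maps each trial to a cue event and an outcome
event in one of seven regressor classes (three cue types; neutral outcomes
pooled across neutral and reward trials; reward wins; bivalent wins;
bivalent losses). All events last 2 s. `build_design_matrix()` convolves
each regressor's boxcar with a canonical double-gamma HRF (peak 6 s,
undershoot 16 s, unit dispersions, ratio 1/6 — the conventional defaults;
the kernel peaks near 5 s), appends a temporal-derivative column per task
regressor (convolution with the finite-difference kernel), then unconvolved
nuisance columns (six motion parameters in the synthetic data) and an
intercept. Scan timing in the synthetic sessions is TR = 2 s with a 10 s
trial period and outcomes 4 s after cues (458 volumes for the 90-trial
task) — a typical 3T EPI protocol of the period; the original acquisition
details are not recoverable from the main text.

`fit_glm()` is ordinary least squares per voxel with a shared design (no
prewhitening — a stated non-goal), and `pe_contrast()` applies the weights
+1 (bivalent win), −1 (reward win), 0 elsewhere; derivatives and nuisance
carry no weight. A parametric-modulator alternative (`pe_modulator =
TRUE`) regresses all outcome events modulated by their mean-centred PE; the
tests check it agrees in sign with the contrast path on PE-coupled data.

## Group inference

`permutation_fwe()` performs the group test on per-subject contrast maps
within an ROI mask:

1. voxelwise one-way ANOVA F across the three groups (or a one-tailed
   two-sample t in pairwise mode), with the pooled within-group variance
   image Gaussian-smoothed at 3 mm FWHM before forming the statistic — the
   variance-smoothing device recommended for modest samples; the kernel is
   renormalised at mask edges;
2. TFCE with the standard published settings $E = 0.5$, $H = 2$,
   6-connectivity, and step $dh = \max/100$ held fixed across permutations
   (the single-voxel integral has the closed form $h^{H+1}/(H+1)$, which
   the tests match within 1%);
3. max-statistic family-wise error correction: corrected $p$ at a voxel is
   the proportion of the null set (observed labelling included) whose
   image-wide maximum TFCE reaches that voxel's value, so $p \ge
   1/(n_{perm}+1)$ always. Voxels with $p \le 0.05$ (equality counts) form
   the significant set. When fewer distinct labelings exist than requested
   permutations the null set is enumerated exhaustively and flagged.

The default is 5000 permutations for reported analyses and 1000 inside the
pipeline; the test suite uses 300–500. Planned pairwise comparisons follow
the directional hypothesis (controls > at-risk > first-episode psychosis)
one-tailed, both voxelwise (restricted to the ANOVA-significant set via
`voxel_subset`, with correction over that restricted set — whether the
original analysis corrected over the restricted set or the full ROI is
ambiguous, and the restricted choice is made here) and on cluster means
(`extract_cluster_means()`, two-sample permutation tests on per-subject
averages over the significant voxels). Spearman correlations
(tie-corrected, two-sided) relate cluster means to symptom scores.

The behavioural analyses mirror the study: per-pair-type correct rates,
win-stay/lose-shift, and a group × trial-type split-plot ANOVA
(`mixed_anova()`) whose F statistics come from the classical sequential
decomposition (cross-checked in tests against `aov()` with an explicit
subject error stratum) and whose primary p-values are permutation-based:
group labels shuffled across subjects for the group and interaction
effects, condition labels shuffled within subjects for the trial-type
effect. Win-stay/lose-shift transitions are defined within pair type on
consecutive presentations of that pair; intervening trials of other pairs
do not break the chain (the original conditioning window is not stated —
this is the package's choice). A "win" is a £1 win, or the colour-matching
feedback kind on neutral pairs; undefined rates are reported as missing,
never zero.

## The synthetic cohort and its calibration

`cohort_config()` fixes the study conditions: 39 controls, 30 at-risk, 14
first-episode psychosis (FEP); per-group Q-parameter distributions;
per-ROI, per-group PE-coupling moments set to the published cluster-mean
contrast values (midbrain 24.44/0.66/−55.03, SDs ≈ 50–55; right DLPFC
32.90/36.29/−45.13, SDs ≈ 48–63; striatum null); AR(1) scan noise
(coefficient 0.3, SD 120 in signal units); log-normal reaction times with
pair-type means 1123/1359/1329 ms; truncated-Gaussian symptom scores
(CAARMS totals 15.10 ± 6.75 at-risk, 23.86 ± 6.48 FEP, none for controls,
and zero true correlation with coupling).

Behavioural parameters were calibrated once, by a grid search against the
published group behaviour (75% correct on reward trials, 55% neutral,
win-stay 69%, lose-shift 44%), and then frozen: learning-rate mean 0.20
(FEP 0.18, concentration 12), $\beta$ log-normal with median 2.5 (FEP
about 20% lower), an internal value of 0.2 for the colour-matching neutral
feedback, and a choice-perseveration (stickiness) bonus of 0.33. Two of
these knobs deserve comment. The neutral-feedback value exists only inside
the generative agent — fitting and PE regressors use monetary value — and
captures the empirical fact that participants treat the designated neutral
feedback as weakly reinforcing (their neutral-pair "correct" rate is above
chance). The stickiness term is likewise generator-only: without
perseveration a value-learning agent cannot produce a lose-shift rate
below chance (the published 43.7%). After calibration the cohort means are
approximately 75% / 48% / 57% correct (reward/bivalent/neutral), win-stay
72%, lose-shift 44%: win-stay sits about three points above the published
value because the single-learning-rate softmax family cannot jointly
deliver 75% reward-correct and 69% win-stay; the residual is documented
rather than absorbed by an extra mechanism. The bivalent "correct" rate
has expectation exactly 0.5 by symmetry (the designation is arbitrary), so
the published 52% — itself within sampling error of chance — is not
separately calibrated.

The BOLD forward model (`simulate_bold()`) gives every in-mask voxel a
common task response, adds a PE signal in the coupled ROIs (win events
scaled by the trial's PE), a slow cosine drift with random phase, and
AR(1) Gaussian noise. The per-subject gain is set to the subject's drawn
coupling divided by the subject's own mean-PE difference between bivalent
and reward wins, so the expected contrast equals the drawn coupling — the
published cluster means are targets in arbitrary contrast units, not
assumptions about physical per-cent signal change. If a short session
leaves that difference ill-defined (no wins of one kind, or a difference
below 0.05) the asymptotic value 0.8 is used instead. A `classmean` mode
scales each win event by its regressor-class mean PE, which places the
signal exactly in the design span; the tests use it to verify
machine-precision recovery at zero noise. One coupling value per subject
per ROI is a declared simplification: true voxel-level effect
heterogeneity is unknowable from group summaries.

ROI geometry is parameterised rather than atlas-based (the published
probabilistic midbrain atlas cannot be redistributed): a midbrain
ellipsoid at (0, −14, −10) mm with semi-axes (8, 8, 6) mm standing in for
substantia nigra/VTA, a bilateral striatal box pair, and the right-DLPFC
sphere of radius 10 mm at (50, 30, 28) mm, all on a 48 × 56 × 44 grid at
2 mm — large enough to hold the three regions, small enough for desk-scale
permutation testing.

## What the tests do and do not show

Problem sizes: contingency checks use $10^5$ draws; PE asymptotics use
2000 trials per pair with a 600-trial burn-in; parameter recovery uses 50
agents × 90 trials; the family-wise error calibration uses 200 null
datasets × 500 permutations on a 125-voxel mask with three groups of 10;
group-structure recovery uses 20 full cohort replications with 300
permutations for the ANOVA and 2000 for cluster-mean comparisons.

Under those conditions the pipeline controls the family-wise error rate
and recovers the midbrain ordering (controls > at-risk > FEP) and the
DLPFC pattern (controls ≈ at-risk, both above FEP) in the large majority
of replications. One caveat is intrinsic to the published effect sizes: at
the published moments the midbrain controls-versus-at-risk comparison has
roughly 60% one-tailed power at n = 39/30, so *statistical significance*
of that comparison cannot replicate in 90% of cohorts — only the ordering
can. The replication-rate test records this honestly rather than shrinking
the published SDs.

Passing these tests shows the chain is internally correct and adequately
powered for the simulated signal structure. It does not show robustness to
what the generator leaves out: motion-correlated signal, physiological
noise, spatial autocorrelation of noise, registration error,
between-voxel effect heterogeneity, or model misspecification of real
choice behaviour (e.g. asymmetric learning rates).
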