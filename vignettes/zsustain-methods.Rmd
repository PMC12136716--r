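---
title: "Subtype and stage inference for z-scored regional biomarkers: models and methods"
author: "zsustain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and stage inference for z-scored regional biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cross-sectional case–control neuroimaging studies mix patients at every
point of their disease course. When distinct subpopulations also follow
*different* spatiotemporal courses, a single group-average map hides
both dimensions of heterogeneity. Subtype-and-stage inference (SuStaIn)
addresses this by modelling disease progression as an ordered sequence
of discrete events — a regional biomarker crossing a severity threshold
— and by fitting a mixture of such orderings, so that each patient
receives a subtype (which ordering they follow) and a stage (how far
along it they are), from purely cross-sectional data.

`zsustain` implements this analysis for region-level resting-state fMRI
features (ALFF — the amplitude of low-frequency fluctuations — over 47
bilateral cerebral regions mirroring the AAL-2 parcellation), together
with everything the analysis needs around it: multisite harmonization,
control-referenced covariate adjustment and z-scoring, case–control
feature selection, patient staging, between-subtype clinical
statistics, and region-level meta-analytic term decoding. A synthetic
cohort generator with planted ground truth makes every stage testable
without access to any restricted dataset.

## The z-score event model

Let the biomarker panel contain $B$ regions and severity thresholds
$z \in \{1, 1.5, 2\}$ (control-referenced standard deviations). The
event set is the Cartesian product — with the default 12-region panel,
$N = 36$ events. A subtype is a permutation $S$ of all $N$ events in
which each biomarker's thresholds appear in increasing order, so every
biomarker trajectory is monotone.

A patient at stage $k \in \{0, \dots, N\}$ has expected value for
biomarker $b$ given by piecewise-linear interpolation through the
control points $(0, 0)$, $(\mathrm{pos}(b, z), z)$ for each of $b$'s
events, and $(N, z_{\max})$. Two boundary conventions matter:

* **Stage 0** is a real stage ("no event yet"); patients sitting there
  are labelled *unstaged* downstream.
* **The ceiling wins at stage $N$.** If an event happens to occupy the
  final position, its anchor is absorbed by the $(N, z_{\max})$ anchor;
  the trajectory heads straight to the ceiling. This keeps the
  interpolation single-valued, and it is the convention under which the
  one-event model has stage-1 mean $z_{\max}$.

Observed z-scores are the expected trajectory plus independent Gaussian
noise with sd $\sigma$ per biomarker ($\sigma = 1$ by default — the
data are control-referenced z-scores). Stages carry a uniform prior
over $0..N$ and are marginalized analytically, so a subtype's
likelihood for one patient is a mean of $N + 1$ Gaussian products. The
full model is a $C$-component mixture over subtypes with fractions
$f_c$.

The ceiling $z_{\max} = 3$ (one notch beyond the largest severity
threshold) is a configurable default; nothing in the inference is
sensitive to it as long as it exceeds the largest threshold.

## Fitting

**Sequence optimization** is greedy coordinate ascent: from a random
valid permutation, each event in turn is moved to its
likelihood-maximizing valid position (valid = the window between its
own biomarker's neighbouring threshold events), until a full pass makes
no improvement; the best of `nStarts` restarts (10 by default) wins.
For three or fewer biomarkers at one threshold this provably reaches
the enumerated optimum in our tests.

**Mixtures** are built hierarchically: the $(C-1)$-model's clusters are
each split in two, sequences are fitted to the halves, and the
candidate is refined by EM (E-step: mixture responsibilities; M-step:
fractions = mean responsibility, sequences re-optimized under
responsibility weights) until the relative log-likelihood change drops
below `emTol` ($10^{-6}$).

The split deserves a note. Randomly halving a cluster whose members mix
two *opposite* orderings produces two halves with the same composition;
both halves then refit to the same compromise sequence and EM has no
gradient to separate them. The first candidate split is therefore
discriminative: each member is scored by contrasting its
severity-normalized z-profile against the parent ordering's
early-versus-late biomarker positions, and the cluster is split at the
median score. Members following an opposite ordering land on opposite
sides, and EM then separates the sequences reliably; additional random
halvings remain as fallback candidates. Candidates are screened with a
few EM iterations and only the winner is refined to convergence.

**Uncertainty** comes from a Metropolis chain over sequences: a
proposal picks a subtype and an event uniformly and moves the event to
a uniformly drawn valid position (a symmetric proposal, so acceptance
is $\min(1, e^{\Delta \ell})$). The chain records thinned samples, the
acceptance rate, the maximum-likelihood model visited, and
position-variance matrices (the posterior probability of each event at
each position — the basis of position-variance diagrams).

## Choosing the number of subtypes

Five-fold cross-validation scores each candidate $C$ by CVIC, $-2$
times the summed held-out log-likelihood; the selected $C$ minimizes
CVIC with ties broken toward smaller $C$, and the mean out-of-sample
log-likelihood curve is reported alongside.

The held-out likelihood is **posterior-predictive**: after fitting on
the training folds, the Metropolis chain is run and each test patient's
likelihood is averaged over the thinned sequence samples before taking
logs. This is not a cosmetic choice. Under point-estimate evaluation a
duplicated sequence acts as free model averaging — two noisy copies of
the same ordering predict held-out data a few nats better than either
alone — which systematically drags the argmin toward larger $C$. We
measured exactly this failure on generated cohorts before switching.
Averaging within each candidate removes the loophole: each candidate's
predictive distribution already integrates over its own sequence
uncertainty, so an extra subtype helps only if it captures real
structure. Setting `mcmcIter = 0` in the configuration restores plain
point evaluation for quick experiments.

## Preprocessing

**Harmonization** is parametric empirical-Bayes ComBat, implemented in
the package because downstream code needs the fitted parameters
(per-site location shifts $\gamma^*$, scale factors $\delta^*$,
standardization mean/variance), which wrapper-level tools do not
expose. Per feature, a linear model with site indicators plus preserved
biological covariates (age, sex, education, head-motion FD, diagnosis)
is fitted; standardized residual site effects are shrunk toward
moment-matched normal / inverse-gamma priors by iterated conditional
posterior means (tolerance $10^{-4}$), with the data estimates held
fixed inside the iteration. The adjusted data are re-centred to each
feature's original grand mean, making harmonization exactly
mean-preserving; a single-site cohort passes through unchanged. The
test suite verifies agreement with `sva::ComBat` to $\sim 10^{-7}$ on
planted site effects.

**Covariate adjustment** fits per-feature least squares of feature on
mean-centred covariates using *control subjects only*, and subtracts
the control-fitted prediction from everyone. Fitting on controls keeps
patient pathology out of the nuisance estimates, mirroring the
control-referenced logic of the z-scoring itself. An optional
region-wise column (e.g., regional grey-matter volume) can be appended
per region for sensitivity analyses.

**Z-scoring** subtracts the control mean and divides by the control sd
per biomarker; for reduction-type biomarkers (the default for all 12
panel regions, since only reductions are modelled) the sign is flipped
so abnormality is positive: one control sd *below* the control mean
maps to $+1$. Controls transformed by their own reference have mean 0
and sd 1 by construction, and only patients enter the progression
model.

**Exclusions** follow the cohort rules — complete demographics, age
18–65, mean FD ≤ 0.2 mm and maximum FD ≤ 2 mm, patient HAMD-17 total
≥ 8, then (last) sites retaining at least 10 patients and 10 controls.
Equality retains throughout ("exceeding"/"below" exclude), the
site-size rule runs on the survivors of the other rules, and subjects
are canonically ordered by id so every downstream seed is reproducible.

## Staging, clinical statistics, decoding

Each patient receives mixture responsibilities, a maximum-likelihood
subtype, and a maximum-likelihood stage (ties toward the lowest stage).
Stages map to bins I (stage 1), II (2–3), III (4–5), IV (6–9) and V
(10+); stage-0 patients are "unstaged" and excluded from bin profiles
and stage-trend tests. Bin profiles are mean z per region with a 0.65
display threshold; stage trends are Pearson correlations of a scalar
summary (e.g., whole-brain mean signal) with stage.

Clinical comparisons use HAMD-17 dimensions (core depression = items 1
and 7; anxiety = 9, 10, 11, 15; neurovegetative melancholia = 6, 12),
covariate-adjusted two-sample tests implemented as the group
coefficient of `y ~ group + covariates` (which reduces exactly to the
pooled-variance t without covariates), Pearson chi-squared without
continuity correction, Pearson correlations, and Benjamini–Hochberg
FDR. The pooled-variance and no-continuity-correction choices are
validated by reproducing the published subtype demographic table's age
and chi-squared statistics exactly from its printed summaries;
complete-case analysis per contrast matches that table's varying group
sizes.

Decoding is region-level: a stage bin's contrast map (per-region
pooled t of the bin's patients versus all controls, retaining only
reduced regions, t < 0) is spatially correlated against a panel of term
maps on the same region panel, and terms are ranked by correlation.
Passing the negated map ranks terms by where the reduction is deepest.
The packaged eight-term panel (sensorimotor-like, memory-like,
reward-like, …) is synthetic — labelled loadings plus a fixed jitter —
and is intended for tests and demonstrations; users with access to real
meta-analytic volumes can reduce them to the region panel (mean within
each bilateral region mask) and supply them instead.

## The synthetic cohort generator

`defaultGeneratorConfig()` encodes the planted study architecture: the
12-region panel with thresholds (1, 1.5, 2); subtype 1 ordered PCL →
THA → … → OFCmed with each biomarker's three threshold events
consecutive (the simplest sequence consistent with a banded
position-variance structure); subtype 2 the exact biomarker-order
reversal; mixture fractions 0.68/0.32 (mirroring the 294/138 split);
stages uniform over 0..36 including stage 0; 400 patients and 400
controls across 18 sites; noise sd 1.

Patients' planted abnormality z is the subtype trajectory at the drawn
stage plus noise; controls sit at stage 0. Abnormality maps to a
raw-ALFF-like scale as baseline 1.0 minus z times a control sd of 0.1
(fixed, arbitrary values that make the z-scoring stage non-trivial),
then additive site shifts (sd 0.05), multiplicative site scales
(0.8–1.25) and linear covariate effects are applied; the other 35
bilateral regions are pure noise so feature selection has something to
reject. Clinical scores are bounded HAMD items with a planted
1.5-point subtype-1 effect on the core-depression items (totals ≥ 8
enforced, as the inclusion rule requires), an onset-age–total-HAMD
correlation of 0.17 planted within subtype 1 only, and
demographics/missingness patterned on the published table.

What the generator does *not* emulate: spatial correlation between
regions beyond the planted trajectories, non-Gaussian noise, site-by-
covariate interactions, scanner-specific artefacts, or any voxel-level
structure. Passing recovery tests therefore demonstrates that the
inference machinery is correct under its own assumptions — not that
those assumptions hold in any particular real dataset.

## Numerical choices and problem sizes

* Likelihoods are evaluated in log space with a cached "context"
  (sigma-scaled data, row norms, per-biomarker event indices), making a
  sequence evaluation one matrix product plus a log-sum-exp; the
  brute-force triple-sum oracle in the test suite agrees to $10^{-10}$.
* Tie-breaks: first-encountered optimum in canonical event order;
  equal-CVIC ties go to smaller $C$; equal stage likelihoods go to the
  lowest stage.
* Degenerate inputs error early and name the offender: sites with one
  subject, within-site constant features, zero control sds,
  rank-deficient covariate designs, empty stage bins.
* The test suite and the acceptance script run at deliberately reduced
  problem sizes — the default synthetic cohort (400 patients), the
  `"reduced"` preset (3 restarts, 2 split candidates, 15 EM iterations,
  2×10⁴ MCMC iterations), a 4-biomarker panel for the repeated
  selection-consistency runs, and 2×10⁵ iterations for the exact-
  posterior MCMC check on a two-biomarker toy. These sizes were chosen
  so the whole analysis remains a desk-scale computation while every
  statistical claim stays testable.

## Known limitations

* Stage is discrete with a uniform prior; continuous-time and
  ordinal/mixed-modality variants are out of scope.
* One Metropolis chain per candidate; no parallel tempering. For the
  36-event default panel the chain mixes locally around the ML mode,
  which is sufficient for position-variance diagrams and predictive
  averaging but is not a fully converged global posterior.
* The greedy fitter is a local optimizer; restarts and the
  discriminative split make failures rare on generated data, not
  impossible.
* Voxel-level maps are approximated by 47 bilateral region profiles
  throughout.
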