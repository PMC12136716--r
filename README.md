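# zsustain

Subtype and Stage Inference (SuStaIn) for z-scored regional
neuroimaging biomarkers, in R.

Cross-sectional case–control imaging cohorts mix patients at every
point of their disease course, and distinct subpopulations may follow
*different* courses. `zsustain` implements the z-score event-based
SuStaIn model for region-level resting-state fMRI features (ALFF over
47 bilateral cerebral regions mirroring the AAL-2 parcellation): it
infers, from purely cross-sectional data, a small number of disease
**subtypes** — each an ordering of events in which a regional biomarker
crosses a severity threshold (z = 1, 1.5, 2 relative to controls) — and
assigns every patient a subtype and a **stage** along its ordering.

The package covers the whole analysis, not just the model:

* **Cohort I/O** — TSV/CSV feature + metadata tables, bilateral
  averaging of hemispheric values, the cohort exclusion rules (age
  18–65, mean FD ≤ 0.2 mm, max FD ≤ 2 mm, patient HAMD-17 ≥ 8, sites
  with ≥ 10 patients and ≥ 10 controls), with a per-rule report.
  Cohorts are `SummarizedExperiment`-based S4 objects.
* **Harmonization** — parametric empirical-Bayes ComBat across sites
  (exposing the fitted site location/scale parameters), control-fitted
  covariate residualization (age, sex, education, head motion), and
  control-referenced z-scoring with abnormality positive.
* **Feature selection** — region-wise case–control t-tests (pooled or
  covariate-adjusted), p < 0.05 selection with optional BH-FDR, and
  Jaccard/Spearman stability metrics.
* **The model** — event-set construction, piecewise-linear expected
  trajectories, analytically stage-marginalized Gaussian likelihood,
  greedy maximum-likelihood sequence fitting, hierarchical EM mixture
  subtyping, Metropolis MCMC over orderings with position-variance
  diagrams, and subtype-count selection by five-fold cross-validated
  CVIC computed from the posterior-predictive held-out likelihood.
* **Staging & clinical** — per-patient responsibilities, ML subtype and
  stage, stage bins I–V, bin abnormality profiles (0.65 display
  threshold), stage–severity trends, HAMD dimension construction
  (CD/ANX/NVSM), adjusted group tests, summary-statistics t-tests,
  chi-squared, Pearson correlations and BH-FDR.
* **Decoding** — region-level spatial correlation of stage-bin
  reduction maps against term-map panels (a synthetic labelled panel
  ships for tests and demos).
* **Synthetic cohorts** — a generator with planted orderings, mixture
  fractions, stages, site and covariate effects, and clinical scores,
  so every pipeline stage is testable with no data download.

The model at its core: a subtype is a permutation $S$ of $N$ events
(monotone within biomarker). A patient at stage $k$ has biomarker means
given by linear interpolation through $(0,0)$, each event's
$(\text{position}, z)$ and $(N, z_{\max})$, observed with independent
Gaussian noise $\sigma$; stages have a uniform prior over $0..N$ and
the data likelihood is the mixture
$P(x) = \sum_c f_c \frac{1}{N+1} \sum_k P(x \mid S_c, k)$.

## Worked example

```r
library(zsustain)

sim    <- generateCohort(defaultGeneratorConfig(nPatients = 150L,
                                                nControls = 150L,
                                                nSites = 4L), seed = 7)
cohort <- applyExclusions(sim$cohort)
cohort <- residualizeOnControls(combatAdjust(cohort))
sel    <- selectFeatures(regionwiseGroupTest(cohort))
Z      <- zscoreAgainstControls(cohort)
events <- buildEventSet(defaultBiomarkers(), c(1, 1.5, 2))
model  <- fitSubtypes(Z, 2, events, analysisConfig(preset = "reduced"),
                      seed = 7)
model
```

```
SubtypeModel: 2 subtype(s), 36 events (12 biomarkers x 3 thresholds)
fractions: 0.629 0.371
log-likelihood: -2958.374
  S1: PCL(1) > THA(1) > THA(1.5) > THA(2) > PCL(1.5) > PCL(2) > PreCG(1) > PoCG(1)   ...
  S2: OFCpost(1) > REC(1) > OFCmed(1) > OFCmed(1.5) > OFCmed(2) > OFCpost(1.5) > OFCpost(2) > REC(1.5)   ...
```

The fitted subtype 1 begins with paracentral-lobule and thalamic
events and subtype 2 with orbitofrontal events — the two planted,
opposite orderings — with estimated mixture fractions 0.63/0.37
against a planted 0.68/0.32. Staging and the stage–severity trend:

```r
asg <- assignSubjects(Z, model)
table(subtype = asg$ml_subtype, bin = asg$stage_bin)
staged <- asg$ml_stage > 0
stageTrendCorrelation(wholeBrainMean(cohort)[asg$subject_id][staged],
                      asg$ml_stage[staged])
```

```
       bin
subtype  I II III IV unstaged  V
      1  4 10   3  7        2 69
      2  4  4   3  3        1 40

whole-brain mean vs stage: r = -0.822, p = 3e-37 (n = 147)
```

Whole-brain mean signal declines steeply with assigned stage, as the
generative model implies (the study-scale analogue of the reported
negative stage correlations). `runPipeline()` chains all of the above
(plus MCMC, clinical comparisons and decoding) from a single config
list or YAML file and writes TSV/JSON outputs, a run manifest with
output hashes, and a markdown report.

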