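# The synthetic cohort generator: defaults, reproducibility, planted
# structure and clinical effects.

test_that("the default configuration mirrors the study architecture", {
  cfg <- defaultGeneratorConfig()
  ev <- buildEventSet(cfg$biomarkers, cfg$thresholds)
  expect_equal(nrow(ev), 36L)
  expect_equal(sum(cfg$fractions), 1)
  expect_equal(cfg$fractions, c(0.68, 0.32))
  expect_equal(cfg$nSites, 18L)
  # subtype 2 is the exact biomarker-order reversal of subtype 1
  expect_equal(cfg$subtypeBiomarkerOrder[[2]],
               rev(cfg$subtypeBiomarkerOrder[[1]]))
  # subtype 1: PCL leads, THA early, OFCmed last
  o1 <- cfg$subtypeBiomarkerOrder[[1]]
  expect_equal(o1[1], "PCL")
  expect_equal(o1[2], "THA")
  expect_equal(o1[length(o1)], "OFCmed")
  seqs <- zsustain:::.plantedSequences(cfg)
  for (s in seqs) expect_true(zsustain:::.validSequence(s, ev))
  expect_error(defaultGeneratorConfig(fractions = c(0.5, 0.4)), "sum")
})

test_that("generation is bit-reproducible given config and seed", {
  cfg <- defaultGeneratorConfig(nPatients = 40L, nControls = 40L,
                                nSites = 3L)
  a <- generateCohort(cfg, seed = 9)
  b <- generateCohort(cfg, seed = 9)
  expect_identical(SummarizedExperiment::assay(a$cohort),
                   SummarizedExperiment::assay(b$cohort))
  expect_identical(a$truth$stage, b$truth$stage)
  c <- generateCohort(cfg, seed = 10)
  expect_false(identical(SummarizedExperiment::assay(a$cohort),
                         SummarizedExperiment::assay(c$cohort)))
})

test_that("a noiseless clean cohort round-trips the planted trajectory", {
  cfg <- defaultGeneratorConfig(
    sigma = 1e-12, nPatients = 60L, nControls = 60L, nSites = 1L,
    siteLocationSd = 0, siteScaleRange = c(1, 1),
    covariateEffects = c(age = 0, sex = 0, education = 0, mean_fd = 0))
  sim <- generateCohort(cfg, seed = 11)
  Y <- t(SummarizedExperiment::assay(sim$cohort))
  cd <- as.data.frame(SummarizedExperiment::colData(sim$cohort))
  ev <- sim$truth$events
  pats <- cd$subject_id[cd$group == "patient"]
  for (id in pats[1:10]) {
    st <- sim$truth$subtype[id]; k <- sim$truth$stage[id]
    expZ <- vapply(cfg$biomarkers, function(b)
      unname(expectedTrajectory(sim$truth$sequences[[st]], b, k, ev)),
      numeric(1))
    got <- (cfg$baseline - Y[id, cfg$biomarkers]) / cfg$controlSd
    expect_equal(unname(got), unname(expZ), tolerance = 1e-6)
  }
})

test_that("the stage histogram is uniform at scale", {
  cfg <- defaultGeneratorConfig(nPatients = 2000L, nControls = 10L,
                                nSites = 1L)
  sim <- generateCohort(cfg, seed = 12)
  st <- sim$truth$stage[!is.na(sim$truth$subtype)]
  gof <- chisq.test(tabulate(st + 1L, nbins = 37L),
                    p = rep(1 / 37, 37))
  expect_gt(gof$p.value, 0.01)
})

test_that("site effects injected then harmonized leave small residue", {
  cfg <- defaultGeneratorConfig(nPatients = 150L, nControls = 150L,
                                nSites = 3L)
  sim <- generateCohort(cfg, seed = 13)
  out <- combatAdjust(sim$cohort)
  Y <- SummarizedExperiment::assay(out)
  site <- SummarizedExperiment::colData(out)$site
  resid <- apply(Y, 1L, function(y) diff(range(tapply(y, site, mean))))
  # raw-scale range after adjustment, in control-sd units
  expect_lt(max(resid) / cfg$controlSd, 1)
  expect_lt(mean(resid) / cfg$controlSd, 0.5)
})

test_that("clinical generator plants the CD effect and the onset link", {
  cfg <- defaultGeneratorConfig(nPatients = 400L, nControls = 20L,
                                nSites = 2L)
  hitsCD <- 0L
  for (r in 1:12) {
    sim <- generateCohort(cfg, seed = 130 + r)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$cohort))
    pat <- cd$group == "patient"
    expect_true(all(cd$hamd_total[pat] >= 8))
    dims <- hamdDimensions(cd[pat, paste0("hamd", 1:17)])
    sub <- sim$truth$subtype[cd$subject_id[pat]]
    if (adjustedGroupTest(dims[, "CD"], sub)$p < 0.05) hitsCD <- hitsCD + 1L
  }
  expect_gte(hitsCD, 9L)   # >= ~80% detection of the planted CD effect
  # onset age correlates with total HAMD within subtype 1
  sim <- generateCohort(defaultGeneratorConfig(nPatients = 1500L,
                                               nControls = 20L,
                                               nSites = 2L), seed = 14)
  cd <- as.data.frame(SummarizedExperiment::colData(sim$cohort))
  s1 <- cd$subject_id %in% names(which(sim$truth$subtype == 1))
  r1 <- pearsonCorr(cd$onset_age[s1], cd$hamd_total[s1])$r
  expect_gt(r1, 0.05)
  s2 <- cd$subject_id %in% names(which(sim$truth$subtype == 2))
  r2 <- pearsonCorr(cd$onset_age[s2], cd$hamd_total[s2])$r
  expect_lt(abs(r2), 0.12)
})

test_that("null clinical effects stay null", {
  cfg <- defaultGeneratorConfig(nPatients = 300L, nControls = 20L,
                                nSites = 2L, cdEffect = 0,
                                onsetHamdCorrelation = 0)
  sig <- 0L
  for (r in 1:10) {
    sim <- generateCohort(cfg, seed = 140 + r)
    cd <- as.data.frame(SummarizedExperiment::colData(sim$cohort))
    pat <- cd$group == "patient"
    dims <- hamdDimensions(cd[pat, paste0("hamd", 1:17)])
    sub <- sim$truth$subtype[cd$subject_id[pat]]
    ps <- apply(dims, 2L, function(d) adjustedGroupTest(d, sub)$p)
    sig <- sig + sum(ps < 0.05)
  }
  # 30 null tests at alpha 0.05: expect ~1.5 rejections
  expect_lte(sig, 6L)
})
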