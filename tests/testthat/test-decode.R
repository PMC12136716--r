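# Stage-bin contrast maps and term-map decoding.

makeDecodeCohort <- function(n = 50, planted = character(0),
                             depth = 0.3, seed = 91) {
  set.seed(seed)
  rt <- defaultRegionTable()
  ids <- sprintf("d%03d", seq_len(2 * n))
  grp <- rep(c("patient", "control"), each = n)
  vals <- matrix(rnorm(2 * n * nrow(rt), 1, 0.1), nrow = 2 * n,
                 dimnames = list(ids, rt$abbreviation))
  vals[grp == "patient", planted] <- vals[grp == "patient", planted] - depth
  meta <- data.frame(subject_id = ids, group = grp, site = "A",
                     stringsAsFactors = FALSE)
  list(cohort = alffCohort(vals, meta, rt),
       assignments = data.frame(subject_id = ids[grp == "patient"],
                                ml_subtype = 1L, ml_stage = 2L,
                                stage_bin = "II",
                                stringsAsFactors = FALSE))
}

test_that("patients identical to controls give an all-zero empty map", {
  d <- makeDecodeCohort(n = 20, seed = 92)
  # copy control rows onto patients
  Y <- t(SummarizedExperiment::assay(d$cohort))
  Y[1:20, ] <- Y[21:40, ]
  cd <- as.data.frame(SummarizedExperiment::colData(d$cohort))
  ch <- alffCohort(Y, cd, as.data.frame(
    SummarizedExperiment::rowData(d$cohort)))
  cm <- stagebinContrastMap(ch, d$assignments, 1, "II")
  expect_length(cm, 0)
  expect_equal(unname(attr(cm, "allT")), rep(0, 47))
})

test_that("null bins retain few regions; planted reductions are retained", {
  retainedNull <- vapply(1:20, function(r) {
    d <- makeDecodeCohort(n = 30, planted = character(0), seed = 900 + r)
    length(stagebinContrastMap(d$cohort, d$assignments, 1, "II"))
  }, numeric(1))
  # under the null each region is retained with p ~ 0.5 (sign of t);
  # none should be strongly reduced, and planted regions always are
  d <- makeDecodeCohort(n = 50, planted = c("PreCG", "THA", "OFCmed"),
                        depth = 0.3, seed = 93)
  cm <- stagebinContrastMap(d$cohort, d$assignments, 1, "II")
  expect_true(all(c("PreCG", "THA", "OFCmed") %in% names(cm)))
  expect_true(all(cm[c("PreCG", "THA", "OFCmed")] < -3))
  expect_true(mean(retainedNull) < 47)
  expect_error(stagebinContrastMap(d$cohort, d$assignments, 2, "II"),
               "empty bin")
})

test_that("decoding is exact on proportional maps and null on orthogonal", {
  set.seed(94)
  contrast <- setNames(-abs(rnorm(40, 2, 0.5)),
                       defaultRegionTable()$abbreviation[1:40])
  terms <- cbind(prop = 3 * contrast + 5, noise = rnorm(40))
  rownames(terms) <- names(contrast)
  # orthogonalized column: zero correlation by construction
  x <- scale(contrast)[, 1]
  raw <- rnorm(40)
  terms <- cbind(terms, ortho = raw - mean(raw) -
                   x * sum((raw - mean(raw)) * x) / sum(x^2))
  res <- decodeTerms(contrast, terms)
  expect_equal(res$r[res$term == "prop"], 1, tolerance = 1e-12)
  expect_equal(res$rank[res$term == "prop"], 1L)
  expect_lt(abs(res$r[res$term == "ortho"]), 0.01)
  # affine rescaling of a term map leaves r unchanged
  terms2 <- terms; terms2[, "noise"] <- -2 * terms[, "noise"] + 7
  r1 <- decodeTerms(contrast, terms)
  r2 <- decodeTerms(contrast, terms2)
  expect_equal(abs(r2$r[r2$term == "noise"]),
               abs(r1$r[r1$term == "noise"]), tolerance = 1e-12)
  expect_error(decodeTerms(contrast[1:2], terms), "at least 3")
})

test_that("sensorimotor-like term peaks early for the PCL-led subtype", {
  cfg <- defaultGeneratorConfig(nPatients = 500L, nControls = 250L,
                                nSites = 2L, siteLocationSd = 0,
                                siteScaleRange = c(1, 1),
                                covariateEffects = c(age = 0, sex = 0,
                                                     education = 0,
                                                     mean_fd = 0))
  sim <- generateCohort(cfg, seed = 95)
  truth <- sim$truth
  cd <- as.data.frame(SummarizedExperiment::colData(sim$cohort))
  pat <- cd$subject_id[cd$group == "patient"]
  asg <- data.frame(subject_id = pat,
                    ml_subtype = unname(truth$subtype[pat]),
                    ml_stage = unname(truth$stage[pat]),
                    stage_bin = vapply(truth$stage[pat], stageBinOf,
                                       character(1)),
                    stringsAsFactors = FALSE)
  terms <- defaultTermMaps()
  decoded <- function(subtype, bin) {
    cm <- stagebinContrastMap(sim$cohort, asg, subtype, bin)
    # decode the reduction-depth map so rank 1 = expressed where the
    # reduction is deepest
    decodeTerms(-cm, terms)
  }
  stat <- function(res, term, what) res[[what]][res$term == term]
  s1II <- decoded(1, "II"); s1V <- decoded(1, "V")
  s2II <- decoded(2, "II"); s2V <- decoded(2, "V")
  # early bins: each subtype's leading system dominates, and the two
  # subtypes are exact mirrors of each other
  expect_lt(stat(s1II, "sensorimotor", "rank"),
            stat(s1II, "reward", "rank"))
  expect_lt(stat(s2II, "reward", "rank"),
            stat(s2II, "sensorimotor", "rank"))
  # late bins: the opposite system's association strengthens as its
  # regions join the reduction
  expect_gt(stat(s1V, "reward", "r"), stat(s1II, "reward", "r"))
  expect_gt(stat(s2V, "sensorimotor", "r"),
            stat(s2II, "sensorimotor", "r"))
})
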