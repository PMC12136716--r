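# ComBat harmonization, control-fitted residualization, z-scoring.

# Cohort with a site location shift planted on the FIRST feature only
# (location effects are feature-heterogeneous in real data) and a
# multiplicative site scale applied to every feature (a site-wide
# gain, as a scanner difference would be).
makeSiteCohort <- function(nPerSite = 50, shifts = c(1, 0, -1),
                           scales = rep(1, length(shifts)), nRegions = 6,
                           seed = 11) {
  set.seed(seed)
  rt <- defaultRegionTable()[seq_len(nRegions), ]
  n <- nPerSite * length(shifts)
  ids <- sprintf("h%03d", seq_len(n))
  site <- rep(paste0("site", seq_along(shifts)), each = nPerSite)
  vals <- matrix(rnorm(n * nRegions, 1, 0.2), nrow = n,
                 dimnames = list(ids, rt$abbreviation))
  vals <- (vals - 1) * scales[match(site, unique(site))] + 1
  vals[, 1] <- vals[, 1] + shifts[match(site, unique(site))]
  meta <- data.frame(subject_id = ids,
                     group = rep_len(c("patient", "control"), n),
                     site = site, age = round(runif(n, 20, 60)),
                     sex = sample(c("male", "female"), n, TRUE),
                     education = round(runif(n, 8, 18)),
                     mean_fd = runif(n, 0.02, 0.15),
                     stringsAsFactors = FALSE)
  alffCohort(vals, meta, rt)
}

test_that("single-site input passes through unchanged", {
  ch <- makeTinyCohort(n = 30, sites = "only")
  before <- SummarizedExperiment::assay(ch)
  out <- combatAdjust(ch)
  expect_equal(SummarizedExperiment::assay(out), before, tolerance = 1e-8)
  expect_true(S4Vectors::metadata(out)$combatModel$singleSite)
})

test_that("planted site shifts are removed and scales equalized", {
  ch <- makeSiteCohort(nPerSite = 50, shifts = c(1, 0, -1))
  out <- combatAdjust(ch)
  Y <- SummarizedExperiment::assay(out)
  site <- SummarizedExperiment::colData(out)$site
  for (r in rownames(Y)) {
    mns <- tapply(Y[r, ], site, mean)
    expect_lt(diff(range(mns)), 0.1)
  }
  # two sites differing only by scale x2
  ch2 <- makeSiteCohort(nPerSite = 80, shifts = c(0, 0),
                        scales = c(1, 2), seed = 12)
  out2 <- combatAdjust(ch2)
  Y2 <- SummarizedExperiment::assay(out2)
  site2 <- SummarizedExperiment::colData(out2)$site
  for (r in rownames(Y2)) {
    sds <- tapply(Y2[r, ], site2, sd)
    expect_lt(abs(sds[1] / sds[2] - 1), 0.1)
  }
})

test_that("combat preserves each feature's grand mean", {
  ch <- makeSiteCohort(nPerSite = 30, shifts = c(0.5, -0.2, 0.1))
  before <- rowMeans(SummarizedExperiment::assay(ch))
  after <- rowMeans(SummarizedExperiment::assay(combatAdjust(ch)))
  expect_equal(after, before, tolerance = 1e-6)
})

test_that("combat matches sva::ComBat on planted site effects", {
  skip_if_not_installed("sva")
  ch <- makeSiteCohort(nPerSite = 40, shifts = c(0.8, -0.4),
                       scales = c(1, 1.5), seed = 13)
  cd <- as.data.frame(SummarizedExperiment::colData(ch))
  ours <- SummarizedExperiment::assay(combatAdjust(ch, preserve = NULL))
  ref <- suppressMessages(sva::ComBat(
    dat = SummarizedExperiment::assay(ch), batch = factor(cd$site)))
  # same EB family; agree closely up to the grand-mean re-centring
  ref <- ref + (rowMeans(SummarizedExperiment::assay(ch)) - rowMeans(ref))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("combat rejects degenerate sites", {
  ch <- makeTinyCohort(n = 21, sites = c("A", "B", "C"))
  cd <- as.data.frame(SummarizedExperiment::colData(ch))
  cd$site[cd$subject_id == "P021"] <- "lonely"
  rt <- as.data.frame(SummarizedExperiment::rowData(ch))
  ch2 <- alffCohort(t(SummarizedExperiment::assay(ch)), cd, rt)
  expect_error(combatAdjust(ch2), "fewer than 2")
})

test_that("control-fitted residualization recovers exact linear effects", {
  set.seed(21)
  rt <- defaultRegionTable()[1:2, ]
  n <- 60
  ids <- sprintf("r%03d", seq_len(n))
  age <- runif(n, 20, 60)
  grp <- rep_len(c("control", "patient"), n)
  # feature = 2*age exactly in controls; patients carry +5 pathology
  f1 <- 2 * age + ifelse(grp == "patient", 5, 0)
  vals <- cbind(PreCG = f1, SFG = rnorm(n, 1, 0.1))
  rownames(vals) <- ids
  meta <- data.frame(subject_id = ids, group = grp, site = "A", age = age,
                     sex = "female", education = 12, mean_fd = 0.1,
                     stringsAsFactors = FALSE)
  ch <- alffCohort(vals, meta, rt)
  out <- residualizeOnControls(ch, covariates = "age")
  Y <- SummarizedExperiment::assay(out)
  ctrl <- grp == "control"
  expect_equal(unname(Y["PreCG", ctrl]), rep(0, sum(ctrl)),
               tolerance = 1e-10)
  expect_equal(unname(Y["PreCG", !ctrl]), rep(5, sum(!ctrl)),
               tolerance = 1e-10)
  # idempotence: residualizing twice changes nothing
  out2 <- residualizeOnControls(out, covariates = "age")
  expect_equal(SummarizedExperiment::assay(out2), Y, tolerance = 1e-10)
})

test_that("null covariates give near-centred residuals and null slopes", {
  set.seed(22)
  rt <- defaultRegionTable()[1, , drop = FALSE]
  n <- 500
  ids <- sprintf("n%04d", seq_len(n))
  vals <- matrix(rnorm(n, 3, 1), ncol = 1, dimnames = list(ids, "PreCG"))
  meta <- data.frame(subject_id = ids, group = "control", site = "A",
                     age = runif(n, 20, 60),
                     sex = sample(c("male", "female"), n, TRUE),
                     education = round(runif(n, 8, 18)),
                     mean_fd = runif(n, 0.02, 0.2),
                     stringsAsFactors = FALSE)
  meta$group[1:10] <- "patient"
  ch <- alffCohort(vals, meta, rt)
  out <- residualizeOnControls(ch)
  cm <- S4Vectors::metadata(out)$covariateModel
  # closed-form OLS on the same controls as the oracle
  ctrl <- meta$group[match(colnames(out), meta$subject_id)] == "control"
  X <- cbind(1, scale(cbind(meta$age, as.numeric(meta$sex == "male"),
                            meta$education, meta$mean_fd)[ctrl, ],
                      scale = FALSE))
  beta <- solve(crossprod(X), crossprod(X, vals[ctrl, 1]))
  se <- sqrt(diag(solve(crossprod(X))) *
               sum(lm.fit(X, vals[ctrl, 1])$residuals^2) /
               (sum(ctrl) - ncol(X)))
  expect_equal(unname(cm$coefficients[-1, 1]), unname(beta[-1]),
               tolerance = 1e-8)
  # calibration of the null slopes over replicate draws: |t| > 3 should
  # be rare (not absent) under the null
  exceed <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    y <- rnorm(n, 3, 1)
    tv <- abs(beta2 <- solve(crossprod(X), crossprod(X, y[ctrl]))[-1]) /
      sqrt(diag(solve(crossprod(X)))[-1] *
             sum(lm.fit(X, y[ctrl])$residuals^2) / (sum(ctrl) - ncol(X)))
    exceed <- exceed + sum(tv > 3)
  }
  expect_lte(exceed, 2L)
})

test_that("region-wise extra covariate changes output only when correlated", {
  set.seed(23)
  rt <- defaultRegionTable()[1:2, ]
  n <- 200
  ids <- sprintf("g%03d", seq_len(n))
  gmv <- matrix(rnorm(2 * n, 5, 1), nrow = n,
                dimnames = list(ids, rt$abbreviation))
  vals <- cbind(PreCG = 1 + 0.5 * gmv[, "PreCG"] + rnorm(n, 0, 0.05),
                SFG = rnorm(n, 1, 0.05))
  rownames(vals) <- ids
  meta <- data.frame(subject_id = ids,
                     group = rep_len(c("control", "patient"), n),
                     site = "A", age = runif(n, 20, 60), sex = "male",
                     education = 12, mean_fd = 0.1,
                     stringsAsFactors = FALSE)
  ch <- alffCohort(vals, meta, rt)
  plain <- SummarizedExperiment::assay(
    residualizeOnControls(ch, covariates = "age"))
  withG <- SummarizedExperiment::assay(
    residualizeOnControls(ch, covariates = "age", extraRegionwise = gmv))
  expect_gt(sd(plain["PreCG", ] - withG["PreCG", ]), 0.1)
  expect_lt(sd(plain["SFG", ] - withG["SFG", ]), 0.05)
})

test_that("z-scoring is control-referenced with abnormality positive", {
  set.seed(24)
  rt <- defaultRegionTable()[1:2, ]
  n <- 100
  ids <- sprintf("z%03d", seq_len(n))
  vals <- matrix(rnorm(n * 2, 1, 0.1), nrow = n,
                 dimnames = list(ids, rt$abbreviation))
  grp <- rep_len(c("control", "patient"), n)
  ctrl <- grp == "control"
  m <- mean(vals[ctrl, "PreCG"]); s <- sd(vals[ctrl, "PreCG"])
  vals[!ctrl, "PreCG"][1] <- m            # patient at control mean
  vals[!ctrl, "PreCG"][2] <- m - s        # one sd below
  meta <- data.frame(subject_id = ids, group = grp, site = "A",
                     stringsAsFactors = FALSE)
  ch <- alffCohort(vals, meta, rt)
  Z <- zscoreAgainstControls(ch, biomarkers = c("PreCG", "SFG"),
                             direction = "decrease")
  zm <- zMatrix(Z)
  pid <- ids[!ctrl]
  expect_equal(unname(zm[pid[1], "PreCG"]), 0, tolerance = 1e-10)
  expect_equal(unname(zm[pid[2], "PreCG"]), 1, tolerance = 1e-10)
  # controls through their own reference: mean 0, sd 1
  zc <- zscoreApply(Z, vals[ctrl, ])
  expect_equal(unname(colMeans(zc)), c(0, 0), tolerance = 1e-10)
  expect_equal(unname(apply(zc, 2, sd)), c(1, 1), tolerance = 1e-10)
  # affine map: within-biomarker rank order exactly reversed (decrease)
  expect_equal(order(zm[, "SFG"]),
               rev(order(vals[!ctrl, "SFG"])))
})

test_that("zero control sd is an error naming the biomarker", {
  rt <- defaultRegionTable()[1:2, ]
  vals <- matrix(c(1, 1, 1, 1, 2, 3, 4, 5), nrow = 4,
                 dimnames = list(letters[1:4], rt$abbreviation))
  meta <- data.frame(subject_id = letters[1:4],
                     group = c("control", "control", "patient", "patient"),
                     site = "A", stringsAsFactors = FALSE)
  ch <- alffCohort(vals, meta, rt)
  expect_error(zscoreAgainstControls(ch, biomarkers = c("PreCG", "SFG")),
               "PreCG")
})
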