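# Multisite harmonization, control-referenced residualization and
# abnormality z-scoring.

#' Empirical-Bayes site harmonization (ComBat)
#'
#' Parametric empirical-Bayes location/scale adjustment per feature:
#' a per-feature linear model with site indicators plus preserved
#' biological covariates is fitted, residuals are standardized, per-site
#' location effects are shrunk toward a normal prior and per-site scale
#' factors toward an inverse-gamma prior (moment-matched hyperpriors,
#' iterated conditional posterior means to tolerance 1e-4), the shrunken
#' effects are removed, and covariate effects and the grand mean are
#' restored. With a single site the data are returned unchanged (there
#' is no site effect to remove). Each feature is re-centred to its
#' original grand mean so harmonization is exactly mean-preserving.
#'
#' @param cohort an \linkS4class{AlffCohort} with a \code{site} column.
#' @param preserve colData covariates whose effects are protected from
#'   removal; \code{sex} and \code{group} are converted to 0/1.
#' @return the adjusted cohort; the fitted parameters (per-site
#'   \code{gammaStar} location shifts, \code{deltaStar} scale factors,
#'   covariate coefficients, standardization mean/variance) are stored
#'   in \code{metadata(cohort)$combatModel}.
#' @export
combatAdjust <- function(cohort,
                         preserve = c("age", "sex", "education",
                                      "mean_fd", "group")) {
  Y <- SummarizedExperiment::assay(cohort, "alff")   # features x subjects
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  site <- factor(cd$site)
  nSites <- nlevels(site)
  if (nSites == 1L) {
    S4Vectors::metadata(cohort)$combatModel <-
      list(singleSite = TRUE, sites = levels(site))
    return(cohort)
  }
  ni <- as.integer(table(site))
  if (any(ni < 2L))
    .stopf("site(s) with fewer than 2 subjects: %s",
           paste(levels(site)[ni < 2], collapse = ", "))
  # within-site constant features break the scale estimate
  for (s in levels(site)) {
    v <- apply(Y[, site == s, drop = FALSE], 1L, var)
    if (any(v < 1e-12))
      .stopf("feature(s) constant within site %s: %s", s,
             paste(rownames(Y)[v < 1e-12], collapse = ", "))
  }
  X <- .covariateDesign(cd, preserve)                # n x q (no intercept)
  B <- model.matrix(~ 0 + site)                      # n x I
  D <- cbind(B, X)
  if (qr(D)$rank < ncol(D))
    .stopf("rank-deficient design (collinear covariates or sites)")
  n <- ncol(Y)
  bhat <- solve(crossprod(D), crossprod(D, t(Y)))    # (I+q) x p
  grand <- crossprod(ni / n, bhat[seq_len(nSites), , drop = FALSE])
  standMean <- matrix(grand, nrow = nrow(Y), ncol = n, byrow = FALSE)
  if (ncol(X))
    standMean <- standMean +
      t(X %*% bhat[-seq_len(nSites), , drop = FALSE])
  varPooled <- rowSums((Y - t(D %*% bhat))^2) / n
  Zs <- (Y - standMean) / sqrt(varPooled)
  gammaHat <- t(vapply(levels(site), function(s)
    rowMeans(Zs[, site == s, drop = FALSE]), numeric(nrow(Y))))
  deltaHat <- t(vapply(levels(site), function(s)
    apply(Zs[, site == s, drop = FALSE], 1L, var), numeric(nrow(Y))))
  gammaBar <- rowMeans(gammaHat)
  t2 <- apply(gammaHat, 1L, var)
  aprior <- (2 * apply(deltaHat, 1L, var) + rowMeans(deltaHat)^2) /
    apply(deltaHat, 1L, var)
  bprior <- (rowMeans(deltaHat) * apply(deltaHat, 1L, var) +
               rowMeans(deltaHat)^3) / apply(deltaHat, 1L, var)
  gammaStar <- gammaHat; deltaStar <- deltaHat
  if (nrow(Y) >= 2L) {   # EB shrinkage pools across features
    for (i in seq_len(nSites)) {
      idx <- site == levels(site)[i]
      res <- .itSol(Zs[, idx, drop = FALSE], gammaHat[i, ], deltaHat[i, ],
                    gammaBar[i], t2[i], aprior[i], bprior[i])
      gammaStar[i, ] <- res$g; deltaStar[i, ] <- res$d
    }
  }
  adj <- Zs
  for (i in seq_len(nSites)) {
    idx <- site == levels(site)[i]
    adj[, idx] <- sweep(Zs[, idx, drop = FALSE], 1L, gammaStar[i, ], "-") /
      sqrt(deltaStar[i, ])
  }
  adj <- adj * sqrt(varPooled) + standMean
  adj <- adj + (rowMeans(Y) - rowMeans(adj))   # exact grand-mean restore
  model <- list(singleSite = FALSE, sites = levels(site),
                covariates = colnames(X),
                coefficients = bhat[-seq_len(nSites), , drop = FALSE],
                gammaStar = gammaStar, deltaStar = deltaStar,
                standGrandMean = as.numeric(grand),
                varPooled = varPooled)
  SummarizedExperiment::assay(cohort, "alff") <- adj
  S4Vectors::metadata(cohort)$combatModel <- model
  cohort
}

# Iterated conditional posterior means for one site (Johnson 2007).
# ghat/dhat are the fixed data estimates; only the current posterior
# means (g, d) are updated until the fixpoint.
.itSol <- function(Zsite, ghat, dhat, gbar, t2, a, b, tol = 1e-4) {
  ni <- ncol(Zsite)
  g <- ghat; d <- dhat
  change <- 1
  iter <- 0L
  while (change > tol && iter < 1000L) {
    iter <- iter + 1L
    gnew <- (ni * t2 * ghat + d * gbar) / (ni * t2 + d)
    ss <- rowSums((Zsite - gnew)^2)
    dnew <- (0.5 * ss + b) / (ni / 2 + a - 1)
    change <- max(abs(gnew - g) / abs(g + 1e-12),
                  abs(dnew - d) / abs(d + 1e-12))
    g <- gnew; d <- dnew
  }
  list(g = g, d = d)
}

# Numeric design for nuisance/biological covariates; sex and group are
# 0/1-coded, everything else must already be numeric.
.covariateDesign <- function(cd, covariates) {
  if (!length(covariates))
    return(matrix(numeric(0), nrow = nrow(cd), ncol = 0))
  miss <- setdiff(covariates, colnames(cd))
  if (length(miss))
    .stopf("covariate column(s) missing from metadata: %s",
           paste(miss, collapse = ", "))
  cols <- lapply(covariates, function(v) {
    x <- cd[[v]]
    if (v == "sex") x <- as.numeric(x %in% c("male", "m", "M", 1))
    if (v == "group") x <- as.numeric(x == "patient")
    if (!is.numeric(x)) .stopf("covariate '%s' is not numeric", v)
    if (anyNA(x)) .stopf("covariate '%s' has missing values", v)
    x
  })
  X <- do.call(cbind, cols)
  colnames(X) <- covariates
  X
}

#' Regress nuisance covariates using control-fitted models
#'
#' Per-feature least squares of feature on (mean-centred) covariates is
#' fitted on control subjects only; the control-fitted prediction is
#' subtracted from every subject so patient pathology cannot leak into
#' the nuisance estimates. An optional region-wise extra covariate
#' (e.g., regional grey-matter volume) appends the matching region's
#' column to that region's design.
#'
#' @param cohort an \linkS4class{AlffCohort}.
#' @param covariates colData column names (default age, sex, education,
#'   mean FD).
#' @param extraRegionwise optional subjects x regions matrix aligned
#'   with the cohort (column names = region abbreviations).
#' @return the residualized cohort; the fitted
#'   coefficients are stored in
#'   \code{metadata(cohort)$covariateModel}.
#' @export
residualizeOnControls <- function(cohort,
                                  covariates = c("age", "sex", "education",
                                                 "mean_fd"),
                                  extraRegionwise = NULL) {
  Y <- SummarizedExperiment::assay(cohort, "alff")
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  ctrl <- cd$group == "control"
  if (sum(ctrl) < length(covariates) + 2L)
    .stopf("too few controls to fit %d covariates", length(covariates))
  X <- .covariateDesign(cd, covariates)
  X <- sweep(X, 2L, colMeans(X[ctrl, , drop = FALSE]))   # centre on controls
  Xi <- cbind(`(intercept)` = 1, X)
  if (is.null(extraRegionwise)) {
    if (qr(Xi[ctrl, , drop = FALSE])$rank < ncol(Xi))
      .stopf("rank-deficient covariate matrix")
    beta <- solve(crossprod(Xi[ctrl, , drop = FALSE]),
                  crossprod(Xi[ctrl, , drop = FALSE],
                            t(Y[, ctrl, drop = FALSE])))
    resid <- Y - t(Xi %*% beta)
    coefs <- beta
  } else {
    extraRegionwise <- as.matrix(extraRegionwise)
    resid <- Y
    coefs <- matrix(NA_real_, nrow = ncol(Xi) + 1L, ncol = nrow(Y),
                    dimnames = list(c(colnames(Xi), "regionwise"),
                                    rownames(Y)))
    for (r in rownames(Y)) {
      if (!r %in% colnames(extraRegionwise))
        .stopf("extraRegionwise lacks a column for region %s", r)
      g <- extraRegionwise[, r]
      g <- g - mean(g[ctrl])
      Xr <- cbind(Xi, regionwise = g)
      if (qr(Xr[ctrl, , drop = FALSE])$rank < ncol(Xr))
        .stopf("rank-deficient covariate matrix for region %s", r)
      b <- solve(crossprod(Xr[ctrl, , drop = FALSE]),
                 crossprod(Xr[ctrl, , drop = FALSE], Y[r, ctrl]))
      resid[r, ] <- Y[r, ] - as.numeric(Xr %*% b)
      coefs[, r] <- b
    }
  }
  SummarizedExperiment::assay(cohort, "alff") <- resid
  S4Vectors::metadata(cohort)$covariateModel <-
    list(covariates = covariates, coefficients = coefs,
         regionwise = !is.null(extraRegionwise))
  cohort
}

#' Control-referenced abnormality z-scores
#'
#' For each biomarker, the raw z-score is (value - control mean) /
#' control sd; for a \code{"decrease"}-direction biomarker the sign is
#' flipped so that abnormality is positive (one control sd \emph{below}
#' the control mean maps to +1). Patients only enter the returned
#' matrix; controls define the reference.
#'
#' @param cohort an \linkS4class{AlffCohort}, normally harmonized and
#'   residualized.
#' @param biomarkers region abbreviations to keep (default
#'   \code{\link{defaultBiomarkers}()}).
#' @param direction \code{"decrease"} or \code{"increase"}, scalar or
#'   named per biomarker (default decrease for all).
#' @return a \linkS4class{ZScoreMatrix}.
#' @export
zscoreAgainstControls <- function(cohort,
                                  biomarkers = defaultBiomarkers(),
                                  direction = "decrease") {
  Y <- SummarizedExperiment::assay(cohort, "alff")
  miss <- setdiff(biomarkers, rownames(Y))
  if (length(miss))
    .stopf("cohort lacks biomarker(s): %s", paste(miss, collapse = ", "))
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  ctrl <- cd$group == "control"
  if (sum(ctrl) < 2L) .stopf("at least 2 controls are required")
  if (is.null(names(direction)))
    direction <- setNames(rep_len(direction, length(biomarkers)),
                          biomarkers)
  m <- rowMeans(Y[biomarkers, ctrl, drop = FALSE])
  s <- apply(Y[biomarkers, ctrl, drop = FALSE], 1L, sd)
  if (any(s < 1e-12))
    .stopf("zero control sd for biomarker(s): %s",
           paste(biomarkers[s < 1e-12], collapse = ", "))
  pat <- !ctrl
  Z <- t((Y[biomarkers, pat, drop = FALSE] - m) / s)
  flip <- direction[biomarkers] == "decrease"
  Z[, flip] <- -Z[, flip]
  new("ZScoreMatrix", Z = Z, refMean = m, refSd = s,
      direction = direction[biomarkers])
}

#' Apply a z-score reference to new rows
#'
#' Transforms a subjects x biomarkers matrix with the control reference
#' (and direction flips) of an existing \linkS4class{ZScoreMatrix};
#' controls passed through their own reference have column mean 0 and
#' sd 1.
#'
#' @param zref a \linkS4class{ZScoreMatrix}.
#' @param values subjects x biomarkers matrix covering the reference's
#'   biomarkers.
#' @return transformed matrix on the reference's biomarker panel.
#' @export
zscoreApply <- function(zref, values) {
  b <- colnames(zref@Z)
  miss <- setdiff(b, colnames(values))
  if (length(miss))
    .stopf("values lack biomarker(s): %s", paste(miss, collapse = ", "))
  Z <- sweep(sweep(values[, b, drop = FALSE], 2L, zref@refMean), 2L,
             zref@refSd, "/")
  flip <- zref@direction == "decrease"
  Z[, flip] <- -Z[, flip]
  Z
}
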