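# HAMD dimension construction and between-subtype statistics.

#' Default HAMD-17 dimension map
#'
#' RDoC-style clinical dimensions: core depression (CD) = items 1 and 7;
#' anxiety (ANX) = items 9, 10, 11 and 15; neurovegetative symptoms of
#' melancholia (NVSM) = items 6 and 12.
#'
#' @return named list of integer item numbers.
#' @export
defaultDimensionMap <- function() {
  list(CD = c(1L, 7L), ANX = c(9L, 10L, 11L, 15L), NVSM = c(6L, 12L))
}

#' HAMD dimension scores
#'
#' Each dimension is the sum of its mapped items; a dimension with any
#' missing mapped item is returned as NA with a warning.
#'
#' @param items numeric matrix or data.frame, subjects x 17 HAMD items
#'   (columns \code{hamd1}..\code{hamd17} or plain 1..17).
#' @param map dimension map (default \code{\link{defaultDimensionMap}()}).
#' @return subjects x dimensions numeric matrix.
#' @export
hamdDimensions <- function(items, map = defaultDimensionMap()) {
  items <- as.matrix(items)
  if (ncol(items) != 17L) {
    cn <- paste0("hamd", 1:17)
    if (!all(cn %in% colnames(items)))
      .stopf("items must have 17 columns (hamd1..hamd17)")
    items <- items[, cn, drop = FALSE]
  }
  allItems <- unlist(map)
  if (any(allItems < 1 | allItems > 17))
    .stopf("mapped item numbers must lie in 1..17")
  if (anyDuplicated(allItems))
    .stopf("an item may belong to only one dimension")
  out <- vapply(map, function(ix) rowSums(items[, ix, drop = FALSE]),
                numeric(nrow(items)))
  out <- matrix(out, nrow = nrow(items),
                dimnames = list(rownames(items), names(map)))
  if (anyNA(out))
    .warnf("missing mapped item(s); %d dimension score(s) set to NA",
           sum(is.na(out)))
  out
}

#' Covariate-adjusted two-sample comparison
#'
#' The t statistic and two-sided p of the group coefficient in the
#' linear model \code{y ~ group + covariates}; with no covariates this
#' reduces exactly to the pooled-variance two-sample t-test.
#' Complete-case analysis per contrast.
#'
#' @param y numeric outcome per subject.
#' @param group two-level factor/character.
#' @param covariates optional numeric data.frame/matrix of covariates.
#' @return list with \code{t}, \code{p}, \code{df}, \code{n} and
#'   \code{covariates}.
#' @export
adjustedGroupTest <- function(y, group, covariates = NULL) {
  g <- factor(group)
  if (nlevels(g) != 2L) .stopf("group must have exactly 2 levels")
  dat <- data.frame(y = y, g = g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (min(table(dat$g)) < 2L)
    .stopf("each group needs at least 2 complete-case subjects")
  fml <- if (is.null(covariates)) y ~ g else
    stats::as.formula(paste("y ~ g +", paste(colnames(covariates),
                                             collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) .stopf("collinear covariates")
  sm <- summary(fit)$coefficients
  row <- grep("^g", rownames(sm))[1]
  # sign convention: first factor level minus second
  list(t = -unname(sm[row, "t value"]), p = unname(sm[row, "Pr(>|t|)"]),
       df = fit$df.residual, n = nrow(dat),
       covariates = if (is.null(covariates)) character(0)
                    else colnames(covariates))
}

#' Pooled-variance t-test from summary statistics
#'
#' Student's two-sample t computed from group means, sds and sizes, with
#' a two-sided p on n1 + n2 - 2 df. Useful for published summary tables.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list with \code{t}, \code{p} and \code{df}.
#' @examples
#' summaryTTest(36.065, 11.215, 294, 37.370, 12.982, 138)$t  # -1.071
#' @export
summaryTTest <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) .stopf("both groups need n >= 2")
  if (sd1 <= 0 || sd2 <= 0) .stopf("sds must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Without continuity correction; 1 df.
#'
#' @param counts 2x2 matrix (or 4 counts by row).
#' @return list with \code{chi2} and \code{p}.
#' @export
chiSquared2x2 <- function(counts) {
  m <- matrix(as.numeric(counts), nrow = 2, byrow = is.null(dim(counts)))
  if (any(m < 0)) .stopf("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    .stopf("zero margin in the 2x2 table")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via \code{stats::p.adjust}), validated to
#' lie in [0, 1].
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    .stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pearson correlation with p-value
#'
#' Sample Pearson r with a two-sided p from the t transform on n - 2 df.
#' Complete cases only.
#'
#' @param x,y numeric vectors.
#' @return list with \code{r}, \code{p} and \code{n}.
#' @export
pearsonCorr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) .stopf("need at least 3 complete pairs")
  if (sd(x[ok]) < 1e-12 || sd(y[ok]) < 1e-12)
    .stopf("zero variance")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Between-subtype clinical comparison table
#'
#' Runs covariate-adjusted comparisons of each clinical dimension
#' between two subtypes and BH-adjusts the p-values across dimensions.
#'
#' @param dimensions subjects x dimensions matrix
#'   (\code{\link{hamdDimensions}}).
#' @param subtype per-subject subtype label (two levels used).
#' @param covariates optional data.frame of adjustment covariates.
#' @return data.frame with one row per dimension: \code{t}, \code{p},
#'   \code{p_fdr}, \code{n}.
#' @export
compareSubtypeDimensions <- function(dimensions, subtype,
                                     covariates = NULL) {
  res <- lapply(colnames(dimensions), function(d)
    adjustedGroupTest(dimensions[, d], subtype, covariates))
  out <- data.frame(dimension = colnames(dimensions),
                    t = vapply(res, `[[`, numeric(1), "t"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    n = vapply(res, `[[`, numeric(1), "n"),
                    stringsAsFactors = FALSE)
  out$p_fdr <- benjaminiHochberg(out$p)
  out[, c("dimension", "t", "p", "p_fdr", "n")]
}
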