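# Region-wise case-control testing, feature selection and stability
# metrics for the sensitivity analysis.

#' Region-wise patient-control comparison
#'
#' Without covariates: a pooled-variance (Student) two-sample t-test per
#' region, patients minus controls. With covariates: the t statistic of
#' the group coefficient in the per-region linear model
#' \code{feature ~ group + covariates}. Results follow region-table
#' order.
#'
#' @param cohort an \linkS4class{AlffCohort} containing both groups.
#' @param covariates optional colData covariate names.
#' @return data.frame with columns \code{region}, \code{t}, \code{p},
#'   \code{direction} (\code{"decrease"} when patients < controls) and a
#'   \code{selected} placeholder (filled by
#'   \code{\link{selectFeatures}}).
#' @export
regionwiseGroupTest <- function(cohort, covariates = NULL) {
  Y <- SummarizedExperiment::assay(cohort, "alff")
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  pat <- cd$group == "patient"
  if (length(unique(cd$group)) < 2L)
    .stopf("both groups must be present")
  if (sum(pat) < 2L || sum(!pat) < 2L)
    .stopf("each group needs at least 2 subjects")
  if (is.null(covariates)) {
    res <- t(apply(Y, 1L, function(y) {
      tt <- t.test(y[pat], y[!pat], var.equal = TRUE)
      c(tt$statistic, tt$p.value)
    }))
  } else {
    X <- .covariateDesign(cd, covariates)
    g <- as.numeric(pat)
    res <- t(apply(Y, 1L, function(y) {
      fit <- summary(lm(y ~ g + X))
      fit$coefficients["g", c("t value", "Pr(>|t|)")]
    }))
  }
  data.frame(region = rownames(Y), t = res[, 1], p = res[, 2],
             direction = ifelse(res[, 1] < 0, "decrease", "increase"),
             selected = NA, row.names = NULL, stringsAsFactors = FALSE)
}

#' Select significant regions
#'
#' Regions with (optionally BH-adjusted) p below \code{alpha}, in
#' region-table order. The default is uncorrected p < 0.05.
#'
#' @param results data.frame from \code{\link{regionwiseGroupTest}}.
#' @param alpha significance level.
#' @param correction \code{"none"} or \code{"bh"}.
#' @return character vector of selected region abbreviations.
#' @export
selectFeatures <- function(results, alpha = 0.05,
                           correction = c("none", "bh")) {
  correction <- match.arg(correction)
  if (!nrow(results)) .stopf("empty results")
  p <- results$p
  if (correction == "bh") p <- p.adjust(p, method = "BH")
  results$region[p < alpha]
}

#' Selection stability metrics
#'
#' Jaccard similarity of two selected-region sets and the Spearman rank
#' correlation of two region rankings (computed on the regions common to
#' both rankings; average ranks for ties).
#'
#' @param setA,setB character vectors of selected regions.
#' @param rankA,rankB character vectors ordering regions from most to
#'   least significant (optional; \code{spearman_rho} is NA if absent).
#' @return list with \code{jaccard} and \code{spearman_rho}.
#' @export
stabilityMetrics <- function(setA, setB, rankA = NULL, rankB = NULL) {
  u <- union(setA, setB)
  if (!length(u)) .stopf("empty union of region sets")
  jac <- length(intersect(setA, setB)) / length(u)
  rho <- NA_real_
  if (!is.null(rankA) && !is.null(rankB)) {
    common <- intersect(rankA, rankB)
    if (length(common) >= 2L)
      rho <- cor(match(common, rankA), match(common, rankB),
                 method = "spearman")
  }
  list(jaccard = jac, spearman_rho = rho)
}
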