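#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom stats approx coef cor cor.test dnorm lm lm.fit p.adjust
#'   pchisq pnorm pt quantile rbinom rnorm runif sd setNames t.test var
#'   chisq.test complete.cases model.matrix rlnorm
#' @importFrom utils read.csv read.delim write.csv head
NULL

#' Cohort container for regional biomarker features
#'
#' An \code{AlffCohort} extends
#' \linkS4class{SummarizedExperiment}: the \code{"alff"} assay holds the
#' regions-by-subjects feature matrix, \code{colData} the per-subject
#' metadata (group, site, demographics, motion, clinical scores) and
#' \code{rowData} the bilateral region table.
#'
#' @slot exclusionReport either \code{NULL} or the per-rule exclusion
#'   report attached by \code{\link{applyExclusions}}.
#' @export
setClass("AlffCohort",
  contains = "SummarizedExperiment",
  representation(exclusionReport = "ANY"),
  prototype(exclusionReport = NULL)
)

setValidity("AlffCohort", function(object) {
  msgs <- character()
  if (!"alff" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'alff' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject_id", "group", "site")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    a <- SummarizedExperiment::assay(object, "alff")
    if (anyNA(a)) msgs <- c(msgs, "assay 'alff' contains missing values")
    if (anyDuplicated(cd$subject_id))
      msgs <- c(msgs, "duplicated subject_id in colData")
    if (!all(cd$group %in% c("patient", "control")))
      msgs <- c(msgs, "group must be 'patient' or 'control'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Control-referenced abnormality z-scores
#'
#' Patients-by-biomarkers z-score matrix together with the control
#' reference (mean, sd) and the abnormality direction per biomarker.
#' For \code{direction == "decrease"} the sign is flipped so that
#' abnormality is positive: a value one control sd below the control mean
#' maps to +1.
#'
#' @slot Z numeric matrix, patients x biomarkers.
#' @slot refMean,refSd named numeric, the control reference per biomarker.
#' @slot direction named character, \code{"decrease"} or \code{"increase"}.
#' @export
setClass("ZScoreMatrix",
  representation(Z = "matrix", refMean = "numeric", refSd = "numeric",
                 direction = "character"))

setValidity("ZScoreMatrix", function(object) {
  msgs <- character()
  b <- colnames(object@Z)
  if (is.null(b)) msgs <- c(msgs, "Z must have biomarker column names")
  if (anyNA(object@Z)) msgs <- c(msgs, "Z contains missing values")
  for (slotnm in c("refMean", "refSd", "direction")) {
    v <- slot(object, slotnm)
    if (length(v) != ncol(object@Z) || !identical(names(v), b))
      msgs <- c(msgs, paste0(slotnm, " must be named per biomarker"))
  }
  if (any(object@refSd <= 0)) msgs <- c(msgs, "refSd must be positive")
  if (!all(object@direction %in% c("decrease", "increase")))
    msgs <- c(msgs, "direction must be 'decrease' or 'increase'")
  if (length(msgs)) msgs else TRUE
})

#' Fitted subtype-and-stage model
#'
#' A mixture of event-ordering models: one full event sequence per
#' subtype over the shared event set (biomarker x severity threshold),
#' mixture fractions, the Gaussian noise sd per biomarker and the
#' trajectory ceiling \code{zMax}.
#'
#' @slot events data.frame with columns \code{event}, \code{biomarker},
#'   \code{threshold} in canonical order.
#' @slot sequences list of integer permutations of \code{events$event},
#'   one per subtype; same-biomarker events appear in increasing
#'   threshold order.
#' @slot fractions numeric mixture fractions summing to 1.
#' @slot sigma named numeric noise sd per biomarker.
#' @slot zMax numeric trajectory ceiling.
#' @slot loglik numeric, total log-likelihood at the fitted solution.
#' @export
setClass("SubtypeModel",
  representation(events = "data.frame", sequences = "list",
                 fractions = "numeric", sigma = "numeric", zMax = "numeric",
                 loglik = "numeric"))

setValidity("SubtypeModel", function(object) {
  msgs <- character()
  ev <- object@events
  if (!all(c("event", "biomarker", "threshold") %in% colnames(ev)))
    msgs <- c(msgs, "events needs columns event, biomarker, threshold")
  if (length(object@sequences) != length(object@fractions))
    msgs <- c(msgs, "one mixture fraction per sequence is required")
  if (any(object@fractions <= 0) ||
      abs(sum(object@fractions) - 1) > 1e-9)
    msgs <- c(msgs, "fractions must be positive and sum to 1")
  if (!length(msgs)) {
    for (s in object@sequences) {
      if (!.validSequence(s, ev)) {
        msgs <- c(msgs, paste0("a sequence is not a valid permutation with ",
                               "monotone within-biomarker thresholds"))
        break
      }
    }
    if (object@zMax <= max(ev$threshold))
      msgs <- c(msgs, "zMax must exceed the largest severity threshold")
  }
  if (length(msgs)) msgs else TRUE
})

#' MCMC samples over event orderings
#'
#' @slot samples list (one element per subtype) of integer matrices,
#'   thinned samples x events; each row is a sequence.
#' @slot loglik numeric log-likelihood per thinned sample.
#' @slot acceptanceRate numeric scalar.
#' @slot positionVariance list of events x positions probability matrices
#'   (rows sum to 1).
#' @slot mlModel the maximum-likelihood \linkS4class{SubtypeModel} visited.
#' @export
setClass("McmcSamples",
  representation(samples = "list", loglik = "numeric",
                 acceptanceRate = "numeric", positionVariance = "list",
                 mlModel = "SubtypeModel"))

setValidity("McmcSamples", function(object) {
  for (pv in object@positionVariance) {
    if (any(abs(rowSums(pv) - 1) > 1e-9))
      return("position-variance rows must sum to 1")
  }
  TRUE
})

#' Cross-validated model-selection result
#'
#' @slot table data.frame with one row per candidate subtype count:
#'   \code{C}, \code{cvic}, \code{meanOosLoglik}.
#' @slot selectedC integer, the CVIC-minimizing subtype count
#'   (ties broken toward smaller C).
#' @slot foldLoglik numeric matrix, folds x candidates of held-out
#'   log-likelihoods.
#' @export
setClass("CvResult",
  representation(table = "data.frame", selectedC = "integer",
                 foldLoglik = "matrix"))

setValidity("CvResult", function(object) {
  tab <- object@table
  if (!all(c("C", "cvic", "meanOosLoglik") %in% colnames(tab)))
    return("table needs columns C, cvic, meanOosLoglik")
  best <- min(tab$C[tab$cvic == min(tab$cvic)])
  if (object@selectedC != best)
    return("selectedC must be the smallest CVIC-minimizing C")
  TRUE
})
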