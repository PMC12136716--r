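# Per-patient subtype/stage assignment, stage bins, bin profiles and
# stage-trend tests.

#' Assign each patient a subtype and stage
#'
#' Subtype responsibilities come from the mixture E-step; the
#' maximum-likelihood stage is the argmax over stages of the stage
#' likelihoods under the assigned subtype's sequence (ties broken toward
#' the lowest stage). Stage-0 patients are labelled \code{"unstaged"}.
#'
#' @param Z \linkS4class{ZScoreMatrix} or patients x biomarkers matrix
#'   on the model's biomarker panel.
#' @param model fitted \linkS4class{SubtypeModel}.
#' @return data.frame with \code{subject_id}, one \code{resp_<c>} column
#'   per subtype, \code{ml_subtype}, \code{ml_stage} and
#'   \code{stage_bin}.
#' @export
assignSubjects <- function(Z, model) {
  Zm <- .asZ(Z)
  bios <- unique(model@events$biomarker)
  miss <- setdiff(bios, colnames(Zm))
  if (length(miss))
    .stopf("biomarker panel mismatch; Z lacks: %s",
           paste(miss, collapse = ", "))
  e <- .eStep(Zm, model)
  mlSub <- max.col(e$resp, ties.method = "first")
  mlStage <- integer(nrow(Zm))
  for (c in seq_along(model@sequences)) {
    idx <- which(mlSub == c)
    if (!length(idx)) next
    L <- .stageLogLik(Zm[idx, , drop = FALSE], model@sequences[[c]],
                      model@events, model@sigma, model@zMax)
    mlStage[idx] <- apply(L, 1L, which.max) - 1L  # ties -> lowest stage
  }
  ids <- rownames(Zm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Zm)))
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (c in seq_along(model@sequences))
    out[[paste0("resp_", c)]] <- e$resp[, c]
  out$ml_subtype <- mlSub
  out$ml_stage <- mlStage
  out$stage_bin <- vapply(mlStage, stageBinOf, character(1))
  out
}

#' Stage-bin label of a stage
#'
#' Bins: 0 = \code{"unstaged"}, 1 = I, 2-3 = II, 4-5 = III, 6-9 = IV,
#' 10 and above = V.
#'
#' @param stage non-negative integer stage.
#' @return bin label.
#' @examples
#' stageBinOf(9)   # "IV"
#' stageBinOf(36)  # "V"
#' @export
stageBinOf <- function(stage) {
  if (stage < 0) .stopf("stage must be non-negative")
  if (stage == 0) "unstaged"
  else if (stage == 1) "I"
  else if (stage <= 3) "II"
  else if (stage <= 5) "III"
  else if (stage <= 9) "IV"
  else "V"
}

#' Stage-bin abnormality profile
#'
#' Mean z-score per region over one subtype's members of one stage bin,
#' with the set of regions whose mean exceeds the display threshold
#' (default 0.65).
#'
#' @param Z \linkS4class{ZScoreMatrix} or patients x biomarkers matrix.
#' @param assignments data.frame from \code{\link{assignSubjects}}.
#' @param subtype subtype index.
#' @param bin bin label (I-V).
#' @param threshold display threshold (default 0.65).
#' @return list with \code{bin}, \code{n}, \code{meanZ} (named numeric)
#'   and \code{exceeding} (character).
#' @export
binProfile <- function(Z, assignments, subtype, bin, threshold = 0.65) {
  Zm <- .asZ(Z)
  sel <- assignments$ml_subtype == subtype & assignments$stage_bin == bin
  if (!any(sel))
    .stopf("empty bin %s for subtype %d", bin, subtype)
  meanZ <- colMeans(Zm[sel, , drop = FALSE])
  list(bin = bin, n = sum(sel), meanZ = meanZ,
       exceeding = names(meanZ)[meanZ > threshold])
}

#' Stage-trend correlation
#'
#' Pearson correlation of a per-patient scalar summary (e.g., whole-brain
#' mean signal or a clinical dimension score) with the assigned stage;
#' two-sided p from the t transform with n-2 df.
#'
#' @param values per-patient scalar.
#' @param stages per-patient stage (same length).
#' @return list with \code{r}, \code{p} and \code{n}.
#' @export
stageTrendCorrelation <- function(values, stages) {
  ok <- !is.na(values) & !is.na(stages)
  if (sum(ok) < 3L) .stopf("need at least 3 staged patients")
  if (sd(values[ok]) < 1e-12 || sd(stages[ok]) < 1e-12)
    .stopf("zero variance in values or stages")
  ct <- cor.test(values[ok], stages[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Whole-brain mean signal per subject
#'
#' Unweighted mean over the cohort's bilateral regions of the (typically
#' harmonized, pre-z-scoring) feature values; used for the stage-trend
#' test.
#'
#' @param cohort an \linkS4class{AlffCohort}.
#' @return named numeric, one value per subject.
#' @export
wholeBrainMean <- function(cohort) {
  colMeans(SummarizedExperiment::assay(cohort, "alff"))
}
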