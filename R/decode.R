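# Stage-bin contrast maps and term-map decoding.
#
# Region-level analogue of meta-analytic ("Neurosynth-style") decoding:
# a stage bin's reduced-signal contrast map (per-region t values,
# patients of the bin vs all controls, restricted to reduced regions) is
# spatially correlated against a panel of term maps defined on the same
# region panel. Users with access to real meta-analytic volumes can
# reduce them to the 47-region panel (mean value within each bilateral
# region mask) and supply them as a term map matrix.

#' Synthetic term-map panel
#'
#' Eight labelled term maps on the packaged 47-region panel, each
#' loading on a named region group (sensorimotor-like, memory-like,
#' reward-like, visual-like, attention-like, language-like,
#' introspection-like, salience-like) with a small deterministic jitter.
#' Synthetic stand-ins for meta-analytic volumes, intended for tests and
#' demonstrations.
#'
#' @param regionTable bilateral region table.
#' @return regions x terms numeric matrix (rows in region-table order).
#' @export
defaultTermMaps <- function(regionTable = defaultRegionTable()) {
  loadings <- list(
    sensorimotor = c("PreCG", "PoCG", "PCL", "SMA", "SPG", "ROL"),
    memory       = c("HIP", "PHG", "THA", "PCUN", "MTG"),
    reward       = c("OFCmed", "OFCpost", "OFCant", "REC", "OLF", "CAU"),
    visual       = c("CAL", "CUN", "LING", "SOG", "MOG", "IOG"),
    attention    = c("SPG", "IPG", "MFG", "SMG"),
    language     = c("IFGoperc", "IFGtriang", "STG", "MTG", "ANG"),
    introspection = c("SFGmedial", "ACC", "PCC", "PCUN", "ANG", "SFG"),
    salience     = c("INS", "ACC", "AMYG", "THA"))
  ab <- regionTable$abbreviation
  out <- matrix(0, nrow = length(ab), ncol = length(loadings),
                dimnames = list(ab, names(loadings)))
  for (j in seq_along(loadings))
    out[intersect(loadings[[j]], ab), j] <- 1
  # fixed low-amplitude background so no term map is piecewise constant
  jit <- .withSeed(20240101L, matrix(runif(length(out), 0, 0.15),
                                     nrow = nrow(out)))
  out + jit
}

#' Stage-bin reduced-signal contrast map
#'
#' Per-region pooled-variance two-sample t (the bin's patients vs all
#' controls); only regions with t < 0 (reduced signal in the bin) are
#' retained, mirroring a reduction-masked contrast.
#'
#' @param cohort an \linkS4class{AlffCohort} holding controls and the
#'   assigned patients (harmonized/residualized scale).
#' @param assignments data.frame from \code{\link{assignSubjects}}
#'   (rows matching the cohort's patients by \code{subject_id}).
#' @param subtype subtype index.
#' @param bin stage-bin label.
#' @return named numeric vector of t values over the retained (reduced)
#'   regions; attribute \code{"allT"} carries every region's t.
#' @export
stagebinContrastMap <- function(cohort, assignments, subtype, bin) {
  Y <- SummarizedExperiment::assay(cohort, "alff")
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  ctrl <- cd$subject_id[cd$group == "control"]
  if (!length(ctrl)) .stopf("no controls in cohort")
  members <- assignments$subject_id[assignments$ml_subtype == subtype &
                                      assignments$stage_bin == bin]
  members <- intersect(members, cd$subject_id)
  if (!length(members)) .stopf("empty bin %s for subtype %d", bin, subtype)
  tvals <- apply(Y, 1L, function(y) {
    a <- y[members]; b <- y[ctrl]
    if (sd(a) < 1e-12 && sd(b) < 1e-12 && mean(a) == mean(b)) return(0)
    t.test(a, b, var.equal = TRUE)$statistic
  })
  tvals <- setNames(as.numeric(tvals), rownames(Y))
  keep <- tvals < 0
  structure(tvals[keep], allT = tvals)
}

#' Decode a contrast map against term maps
#'
#' Pearson spatial correlation between the supplied map values and each
#' term map, restricted to the map's regions; terms are ranked by r in
#' decreasing order (rank 1 = largest r). To decode a reduction pattern
#' so that rank 1 means "term expressed where the reduction is deepest",
#' pass the reduction-depth map (the negated t values of
#' \code{\link{stagebinContrastMap}}).
#'
#' @param contrast named numeric vector over regions, e.g., the output
#'   of \code{\link{stagebinContrastMap}} (signed t values) or its
#'   negation (reduction depth).
#' @param terms regions x terms matrix (\code{\link{defaultTermMaps}}).
#' @return data.frame with \code{term}, \code{r} and \code{rank}.
#' @export
decodeTerms <- function(contrast, terms) {
  regions <- names(contrast)
  if (length(regions) < 3L)
    .stopf("need at least 3 retained regions to decode")
  miss <- setdiff(regions, rownames(terms))
  if (length(miss))
    .stopf("term maps lack region(s): %s", paste(miss, collapse = ", "))
  r <- apply(terms[regions, , drop = FALSE], 2L, function(m) {
    if (sd(m) < 1e-12) return(NA_real_)
    cor(contrast, m)
  })
  out <- data.frame(term = colnames(terms), r = as.numeric(r),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$r, ties.method = "min", na.last = "keep")
  out[order(out$rank), , drop = FALSE]
}
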