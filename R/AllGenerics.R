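# Accessor generics and show methods.

#' @rdname AlffCohort-class
#' @param x,object an object.
#' @export
setGeneric("exclusionReport", function(x) standardGeneric("exclusionReport"))
#' @rdname AlffCohort-class
#' @export
setMethod("exclusionReport", "AlffCohort", function(x) x@exclusionReport)

#' Accessors for fitted models
#'
#' @param x a \linkS4class{SubtypeModel}, \linkS4class{McmcSamples},
#'   \linkS4class{CvResult} or \linkS4class{ZScoreMatrix}.
#' @return \code{eventTable}: the canonical event table;
#'   \code{sequences}: list of integer event orderings;
#'   \code{mixtureFractions}: numeric fractions; \code{positionVariance}:
#'   list of events x positions probability matrices; \code{selectedC}:
#'   the chosen subtype count; \code{cvTable}: the per-candidate CVIC
#'   table; \code{zMatrix}: the patients x biomarkers z-score matrix.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname model-accessors
#' @export
setMethod("eventTable", "SubtypeModel", function(x) x@events)

#' @rdname model-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname model-accessors
#' @export
setMethod("sequences", "SubtypeModel", function(x) x@sequences)
#' @rdname model-accessors
#' @export
setMethod("sequences", "McmcSamples", function(x) x@samples)

#' @rdname model-accessors
#' @export
setGeneric("mixtureFractions",
           function(x) standardGeneric("mixtureFractions"))
#' @rdname model-accessors
#' @export
setMethod("mixtureFractions", "SubtypeModel", function(x) x@fractions)

#' @rdname model-accessors
#' @export
setGeneric("positionVariance",
           function(x) standardGeneric("positionVariance"))
#' @rdname model-accessors
#' @export
setMethod("positionVariance", "McmcSamples",
          function(x) x@positionVariance)

#' @rdname model-accessors
#' @export
setGeneric("selectedC", function(x) standardGeneric("selectedC"))
#' @rdname model-accessors
#' @export
setMethod("selectedC", "CvResult", function(x) x@selectedC)

#' @rdname model-accessors
#' @export
setGeneric("cvTable", function(x) standardGeneric("cvTable"))
#' @rdname model-accessors
#' @export
setMethod("cvTable", "CvResult", function(x) x@table)

#' @rdname model-accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))
#' @rdname model-accessors
#' @export
setMethod("zMatrix", "ZScoreMatrix", function(x) x@Z)

setMethod("show", "ZScoreMatrix", function(object) {
  cat(sprintf("ZScoreMatrix: %d patients x %d biomarkers\n",
              nrow(object@Z), ncol(object@Z)))
  cat("biomarkers:", paste(colnames(object@Z), collapse = ", "), "\n")
})

setMethod("show", "SubtypeModel", function(object) {
  C <- length(object@sequences)
  cat(sprintf("SubtypeModel: %d subtype(s), %d events (%d biomarkers x %d thresholds)\n",
              C, nrow(object@events),
              length(unique(object@events$biomarker)),
              length(unique(object@events$threshold))))
  cat("fractions:", paste(sprintf("%.3f", object@fractions), collapse = " "),
      "\n")
  if (length(object@loglik))
    cat(sprintf("log-likelihood: %.3f\n", object@loglik))
  for (c in seq_len(C)) {
    ev <- object@events[object@sequences[[c]], ]
    lab <- paste0(ev$biomarker, "(", ev$threshold, ")")
    cat(sprintf("  S%d: %s\n", c, paste(head(lab, 8), collapse = " > ")),
        if (length(lab) > 8) "  ...\n" else "")
  }
})

setMethod("show", "McmcSamples", function(object) {
  cat(sprintf("McmcSamples: %d subtype(s), %d thinned samples, acceptance %.3f\n",
              length(object@samples), nrow(object@samples[[1]]),
              object@acceptanceRate))
})

setMethod("show", "CvResult", function(object) {
  cat("CvResult (lower CVIC = better):\n")
  print(object@table, row.names = FALSE)
  cat("selected C:", object@selectedC, "\n")
})
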