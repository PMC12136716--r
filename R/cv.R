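# Cross-validated model selection via CVIC.

# Posterior-predictive held-out log-likelihood: per test patient, the
# log of the mean (over thinned MCMC sequence samples) of the mixture
# likelihood. Averaging over the sequence posterior is what makes CVIC
# comparable across subtype counts: a duplicated sequence cannot buy a
# spurious model-averaging gain, because each candidate's predictive
# distribution already integrates over its own sequence uncertainty.
.posteriorPredictiveLoglik <- function(Ztest, samples, fractions,
                                       events, sigma, zMax) {
  ctx <- .llCtx(Ztest, events, sigma, zMax)
  S <- nrow(samples[[1]])
  C <- length(samples)
  n <- nrow(Ztest)
  cache <- new.env(parent = emptyenv())
  acc <- matrix(0, nrow = S, ncol = n)
  for (s in seq_len(S)) {
    lm_ <- vapply(seq_len(C), function(cc) {
      key <- paste(samples[[cc]][s, ], collapse = ".")
      val <- cache[[key]]
      if (is.null(val)) {
        val <- .ctxMarginal(ctx, samples[[cc]][s, ])
        cache[[key]] <- val
      }
      val
    }, numeric(n))
    acc[s, ] <- .rowLogSumExp(sweep(lm_, 2L, log(fractions), "+"))
  }
  sum(.rowLogSumExp(t(acc)) - log(S))
}

#' Select the number of subtypes by cross-validated CVIC
#'
#' Patients are partitioned into \code{folds} random folds (seeded).
#' For each candidate subtype count C, a model is fitted on the
#' training folds, a Metropolis chain is run over its event orderings,
#' and the held-out log-likelihood of the test fold is evaluated under
#' the posterior over sequences (the log mean mixture likelihood across
#' thinned MCMC samples). CVIC(C) is -2 times the summed held-out
#' log-likelihood (lower is better); the selected C minimizes CVIC,
#' ties broken toward smaller C. The mean out-of-sample log-likelihood
#' per candidate is reported alongside. With \code{config$mcmcIter ==
#' 0} the point-estimate model is evaluated instead.
#'
#' @param Z \linkS4class{ZScoreMatrix} or patients x biomarkers matrix.
#' @param maxC largest candidate subtype count.
#' @param events event table from \code{\link{buildEventSet}}.
#' @param folds number of folds (default 5).
#' @param config list from \code{\link{analysisConfig}}.
#' @param seed integer seed for the fold partition and the fits.
#' @param verbose emit progress messages.
#' @return a \linkS4class{CvResult}.
#' @export
crossValidateCvic <- function(Z, maxC, events, folds = 5,
                              config = analysisConfig(),
                              seed = config$seed, verbose = FALSE) {
  Zm <- .asZ(Z)
  n <- nrow(Zm)
  if (folds < 2) .stopf("folds must be >= 2")
  if (n < folds) .stopf("fewer patients than folds")
  foldId <- .withSeed(seed, sample(rep_len(seq_len(folds), n)))
  foldLl <- matrix(NA_real_, nrow = folds, ncol = maxC,
                   dimnames = list(NULL, paste0("C", seq_len(maxC))))
  nIter <- config$mcmcIter
  for (f in seq_len(folds)) {
    train <- Zm[foldId != f, , drop = FALSE]
    test <- Zm[foldId == f, , drop = FALSE]
    for (C in seq_len(maxC)) {
      fit <- fitSubtypes(train, C, events, config,
                         seed = .childSeed(seed, f * 100L + C))
      if (nIter > 0) {
        thin <- max(1L, as.integer((nIter - nIter %/% 10) / 200))
        post <- mcmcPosterior(train, fit, nIter = nIter,
                              seed = .childSeed(seed, f * 100L + C + 50L),
                              thin = thin)
        foldLl[f, C] <- .posteriorPredictiveLoglik(
          test, post@samples, fit@fractions, events, fit@sigma,
          fit@zMax)
      } else {
        foldLl[f, C] <- modelLoglik(test, fit)
      }
      .msg("cv", sprintf("fold %d C=%d heldout loglik %.3f",
                         f, C, foldLl[f, C]), verbose = verbose)
    }
  }
  cvic <- -2 * colSums(foldLl)
  tab <- data.frame(C = seq_len(maxC), cvic = as.numeric(cvic),
                    meanOosLoglik = as.numeric(colMeans(foldLl)))
  sel <- min(tab$C[tab$cvic == min(tab$cvic)])
  new("CvResult", table = tab, selectedC = as.integer(sel),
      foldLoglik = foldLl)
}
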