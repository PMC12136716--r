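# Metropolis sampling of the posterior over event orderings.

#' MCMC posterior over event sequences
#'
#' Metropolis chain on the space of valid sequences (same-biomarker
#' threshold order always preserved): each proposal picks one subtype
#' uniformly, one event uniformly, and moves it to a uniformly drawn
#' valid position; the proposal is symmetric, so acceptance is
#' min(1, exp(delta log-likelihood)). Mixture fractions and sigma are
#' held at their fitted values. Thinned samples, per-sample
#' log-likelihoods, the overall acceptance rate, per-subtype
#' position-variance matrices (posterior probability of each event at
#' each position) and the maximum-likelihood model visited are recorded.
#'
#' @param Z \linkS4class{ZScoreMatrix} or patients x biomarkers matrix.
#' @param init fitted \linkS4class{SubtypeModel} used as the chain start.
#' @param nIter number of iterations (default 1e5).
#' @param seed integer seed.
#' @param thin record every \code{thin}-th iteration (default 10).
#' @param burnin iterations discarded before recording (default
#'   \code{nIter \%/\% 10}).
#' @return a \linkS4class{McmcSamples} object.
#' @export
mcmcPosterior <- function(Z, init, nIter = 1e5, seed = NULL, thin = 10,
                          burnin = nIter %/% 10) {
  if (nIter < 1) .stopf("nIter must be >= 1")
  Zm <- .asZ(Z)
  events <- init@events
  N <- nrow(events)
  C <- length(init@sequences)
  ctx <- .llCtx(Zm, events, init@sigma, init@zMax)
  .withSeed(seed, {
    seqs <- init@sequences
    # cache per-subtype log marginals; total loglik from mixture
    lm_ <- vapply(seqs, function(s) .ctxMarginal(ctx, s),
                  numeric(nrow(Zm)))
    lf <- log(init@fractions)
    curLl <- sum(.rowLogSumExp(sweep(lm_, 2L, lf, "+")))
    nKeep <- max(0L, (nIter - burnin) %/% thin)
    samples <- lapply(seq_len(C), function(i)
      matrix(NA_integer_, nrow = nKeep, ncol = N))
    llKeep <- numeric(nKeep)
    kept <- 0L; accepted <- 0L
    bestLl <- curLl; bestSeqs <- seqs
    us <- sample.int(C, nIter, replace = TRUE)
    evs <- sample.int(N, nIter, replace = TRUE)
    for (it in seq_len(nIter)) {
      u <- us[it]
      ev <- events$event[evs[it]]
      reduced <- seqs[[u]][seqs[[u]] != ev]
      cand <- .validInsertions(reduced, ev, events)
      p <- cand[sample.int(length(cand), 1L)]
      prop <- .insertAt(reduced, ev, p)
      if (!identical(prop, seqs[[u]])) {
        lmProp <- .ctxMarginal(ctx, prop)
        lmNew <- lm_; lmNew[, u] <- lmProp
        llNew <- sum(.rowLogSumExp(sweep(lmNew, 2L, lf, "+")))
        if (log(runif(1)) < llNew - curLl) {
          seqs[[u]] <- prop; lm_ <- lmNew; curLl <- llNew
          accepted <- accepted + 1L
          if (curLl > bestLl) { bestLl <- curLl; bestSeqs <- seqs }
        }
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        for (cIdx in seq_len(C)) samples[[cIdx]][kept, ] <- seqs[[cIdx]]
        llKeep[kept] <- curLl
      }
    }
    pv <- lapply(samples, function(S) {
      m <- matrix(0, nrow = N, ncol = N,
                  dimnames = list(
                    paste0(events$biomarker, "(", events$threshold, ")"),
                    seq_len(N)))
      for (p in seq_len(N)) {
        tab <- tabulate(S[, p], nbins = N)
        m[, p] <- m[, p] + tab
      }
      m / nrow(S)
    })
    ml <- .newModel(events, bestSeqs, init@fractions, init@sigma,
                    init@zMax, loglik = bestLl)
    new("McmcSamples", samples = samples, loglik = llKeep[seq_len(kept)],
        acceptanceRate = accepted / nIter, positionVariance = pv,
        mlModel = ml)
  })
}
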