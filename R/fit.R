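# Maximum-likelihood sequence fitting and hierarchical mixture subtyping.

# One greedy coordinate-ascent pass over events in canonical order:
# move each event to its best valid position (first-encountered optimum
# kept on ties). Returns list(seq, loglik).
.greedyPass <- function(seqVec, ctx, w) {
  cur <- .ctxWeightedLoglik(ctx, seqVec, w)
  for (ev in ctx$events$event) {
    reduced <- seqVec[seqVec != ev]
    cand <- .validInsertions(reduced, ev, ctx$events)
    best <- seqVec; bestLl <- cur
    for (p in cand) {
      s <- .insertAt(reduced, ev, p)
      if (identical(s, seqVec)) next
      ll <- .ctxWeightedLoglik(ctx, s, w)
      if (ll > bestLl + 1e-12) { best <- s; bestLl <- ll }
    }
    seqVec <- best; cur <- bestLl
  }
  list(seq = seqVec, loglik = cur)
}

.greedyFit <- function(init, ctx, w, maxPasses = 100L) {
  cur <- init
  ll <- -Inf
  for (i in seq_len(maxPasses)) {
    res <- .greedyPass(cur, ctx, w)
    if (res$loglik <= ll + 1e-9 && identical(res$seq, cur)) break
    improved <- res$loglik > ll + 1e-9
    cur <- res$seq; ll <- res$loglik
    if (!improved) break
  }
  list(seq = cur, loglik = ll)
}

#' Fit a maximum-likelihood event sequence
#'
#' Greedy coordinate ascent over event orderings: starting from a random
#' valid sequence, every event is repeatedly moved to its
#' log-likelihood-maximizing valid position until a full pass yields no
#' improvement; the best solution over \code{nStarts} random restarts is
#' returned. Optional per-patient weights (mixture responsibilities)
#' weight each patient's log marginal likelihood.
#'
#' @param Z \linkS4class{ZScoreMatrix} or patients x biomarkers matrix.
#' @param events event table from \code{\link{buildEventSet}}.
#' @param sigma noise sd, scalar or named per biomarker.
#' @param zMax trajectory ceiling.
#' @param weights optional non-negative per-patient weights.
#' @param nStarts number of random restarts (default 10).
#' @param seed integer seed; the caller's RNG state is preserved.
#' @param init optional sequence used as one additional warm start.
#' @return integer event sequence (attribute \code{"loglik"} carries the
#'   attained weighted log-likelihood).
#' @export
fitMlSequence <- function(Z, events, sigma = 1, zMax = 3, weights = NULL,
                          nStarts = 10, seed = NULL, init = NULL) {
  Zm <- .asZ(Z)
  if (!nrow(Zm)) .stopf("Z is empty")
  sigma <- .sigmaVec(sigma, events)
  w <- if (is.null(weights)) rep(1, nrow(Zm)) else weights
  if (length(w) != nrow(Zm) || any(w < 0))
    .stopf("weights must be non-negative, one per patient")
  ctx <- .llCtx(Zm, events, sigma, zMax)
  .withSeed(seed, {
    starts <- replicate(nStarts, .randomValidSequence(events),
                        simplify = FALSE)
    if (!is.null(init)) starts <- c(list(init), starts)
    best <- NULL
    for (s0 in starts) {
      res <- .greedyFit(s0, ctx, w)
      if (is.null(best) || res$loglik > best$loglik + 1e-12) best <- res
    }
    structure(best$seq, loglik = best$loglik)
  })
}

# Early-vs-late contrast score of each z-row against a reference
# ordering: positive when abnormality concentrates on the ordering's
# early biomarkers, negative when on its late ones. Severity-normalized
# so stage mostly cancels and subtype membership dominates.
.orderContrastScore <- function(Z, seqVec, events) {
  bios <- unique(events$biomarker)
  pos <- integer(nrow(events)); pos[seqVec] <- seq_len(nrow(events))
  meanPos <- vapply(bios, function(b)
    mean(pos[events$event[events$biomarker == b]]), numeric(1))
  w <- -(meanPos - mean(meanPos))
  as.numeric(Z[, bios, drop = FALSE] %*% w) /
    (rowSums(abs(Z[, bios, drop = FALSE])) + 1e-8)
}

# E-step: responsibilities (n x C) and total log-likelihood.
.eStep <- function(Z, model) {
  lm_ <- sweep(.subtypeLogMarginals(Z, model), 2L,
               log(model@fractions), "+")
  tot <- .rowLogSumExp(lm_)
  list(resp = exp(lm_ - tot), loglik = sum(tot))
}

# Alternating EM refinement of sequences + fractions, warm-starting each
# sequence update from its current value.
.emRefine <- function(Z, model, maxIter, tol, verbose = FALSE) {
  prev <- -Inf
  ctx <- .llCtx(Z, model@events, model@sigma, model@zMax)
  for (it in seq_len(maxIter)) {
    e <- .eStep(Z, model)
    f <- pmax(colMeans(e$resp), 1e-8); f <- f / sum(f)
    seqs <- model@sequences
    for (c in seq_along(seqs)) {
      res <- .greedyFit(seqs[[c]], ctx, e$resp[, c])
      seqs[[c]] <- res$seq
    }
    model <- .newModel(model@events, seqs, f, model@sigma, model@zMax)
    ll <- .eStep(Z, model)$loglik
    .msg("em", sprintf("iter %d loglik %.4f", it, ll), verbose = verbose)
    if (is.finite(prev) && (ll - prev) < tol * abs(prev)) break
    prev <- ll
  }
  model@loglik <- .eStep(Z, model)$loglik
  model
}

#' Fit a C-subtype event-ordering mixture
#'
#' Hierarchical construction: the (C-1)-subtype model is fitted first;
#' each of its clusters is then split (the cluster's hard-assigned
#' patients are randomly halved and a sequence fitted to each half), the
#' resulting candidate C-subtype model is refined by alternating EM
#' (E: mixture responsibilities; M: fractions = mean responsibility and
#' responsibility-weighted sequence re-optimization), and the
#' highest-likelihood candidate over cluster splits is returned.
#'
#' @param Z \linkS4class{ZScoreMatrix} or patients x biomarkers matrix.
#' @param C number of subtypes (>= 1).
#' @param events event table from \code{\link{buildEventSet}}.
#' @param config list from \code{\link{analysisConfig}} supplying
#'   \code{sigma}, \code{zMax}, \code{nStarts}, \code{emMaxIter},
#'   \code{emTol}.
#' @param seed integer seed for restarts and splits.
#' @param verbose emit progress messages.
#' @return a fitted \linkS4class{SubtypeModel}.
#' @export
fitSubtypes <- function(Z, C, events, config = analysisConfig(),
                        seed = config$seed, verbose = FALSE) {
  Zm <- .asZ(Z)
  if (C < 1) .stopf("C must be >= 1")
  if (C > nrow(Zm)) .stopf("C exceeds the number of patients")
  sigma <- .sigmaVec(config$sigma, events)
  .withSeed(seed, .fitSubtypesInner(Zm, C, events, sigma, config, verbose))
}

.fitSubtypesInner <- function(Z, C, events, sigma, config, verbose) {
  zMax <- config$zMax
  s1 <- fitMlSequence(Z, events, sigma, zMax, nStarts = config$nStarts)
  model <- .newModel(events, list(as.integer(s1)), 1, sigma, zMax,
                     loglik = attr(s1, "loglik"))
  .msg("fit", sprintf("C=1 loglik %.3f", model@loglik), verbose = verbose)
  if (C == 1) return(model)
  nSplits <- config$nSplits %||% 3L
  for (cc in 2:C) {
    e <- .eStep(Z, model)
    hard <- max.col(e$resp, ties.method = "first")
    best <- NULL
    for (split in seq_len(cc - 1L)) {
      members <- which(hard == split)
      if (length(members) < 4L) next
      # candidate halvings: the first is a discriminative split — each
      # member is scored by contrasting its severity-normalized
      # z-profile against the parent ordering's early-vs-late biomarker
      # positions, so members following a different ordering land on
      # the other side of the median (purely random halves cannot break
      # this symmetry); the remaining halvings are random. Each half is
      # refitted from random starts, free to diverge from the parent.
      contrast <- .orderContrastScore(Z[members, , drop = FALSE],
                                      model@sequences[[split]], events)
      for (h in seq_len(nSplits)) {
        halves <- if (h == 1L)
          ifelse(rank(contrast, ties.method = "first") >
                   length(members) / 2, 1L, 2L)
        else sample(rep_len(1:2, length(members)))
        sA <- fitMlSequence(Z[members[halves == 1L], , drop = FALSE],
                            events, sigma, zMax, nStarts = 2)
        sB <- fitMlSequence(Z[members[halves == 2L], , drop = FALSE],
                            events, sigma, zMax, nStarts = 2)
        seqs <- c(model@sequences[-split],
                  list(as.integer(sA), as.integer(sB)))
        nGrp <- c(table(factor(hard, levels = seq_len(cc - 1L)))[-split],
                  length(members) / 2, length(members) / 2)
        f <- as.numeric(nGrp) / nrow(Z)
        cand <- .newModel(events, seqs, f / sum(f), sigma, zMax)
        # short EM screen; only the winning candidate is fully refined
        cand <- .emRefine(Z, cand, min(5L, config$emMaxIter),
                          config$emTol, verbose = FALSE)
        if (is.null(best) || cand@loglik > best@loglik) best <- cand
      }
    }
    if (is.null(best))
      .stopf("no cluster large enough to split when growing to C=%d", cc)
    model <- .emRefine(Z, best, config$emMaxIter, config$emTol, verbose)
    .msg("fit", sprintf("C=%d loglik %.3f", cc, model@loglik),
         verbose = verbose)
  }
  model
}
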