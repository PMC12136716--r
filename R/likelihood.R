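# Likelihood of the z-score event model.
#
# Given a sequence S, a patient at stage k has independent Gaussian
# biomarkers centred on the stage-k expected trajectory with sd sigma.
# Patients' stages carry a uniform prior over 0..N (stage 0 = no event),
# marginalized analytically.
#
# The hot path (greedy fitting, EM, MCMC) evaluates thousands of
# sequences against a fixed data matrix, so a likelihood context caches
# everything sequence-independent: the sigma-scaled data, its row norms,
# the normalizing constant and the per-biomarker event index.

# Likelihood context for repeated sequence evaluations.
.llCtx <- function(Z, events, sigma, zMax) {
  bios <- unique(events$biomarker)
  sigma <- .sigmaVec(sigma, events)
  Zs <- sweep(Z[, bios, drop = FALSE], 2L, sigma[bios], "/")
  list(Zs = Zs,
       zss = 0.5 * rowSums(Zs^2),
       cst = -0.5 * length(bios) * log(2 * pi) - sum(log(sigma[bios])),
       n = nrow(Z),
       N = nrow(events),
       bios = bios,
       bioEvents = lapply(bios, function(b)
         events$event[events$biomarker == b]),
       bioThr = lapply(bios, function(b)
         events$threshold[events$biomarker == b] / sigma[b]),
       zMaxScaled = zMax / sigma[bios],
       events = events, sigma = sigma, zMax = zMax)
}

# Sigma-scaled trajectory matrix, (N+1) x B. Anchors: (0, 0), each
# event's (position, threshold), (N, zMax). The zMax anchor always
# holds at stage N; an event whose position collides with N is absorbed
# by it (the trajectory heads straight to the ceiling). Values at
# integer stages come from cumulated per-step slopes.
.ctxTraj <- function(ctx, seqVec) {
  N <- ctx$N
  pos <- integer(N); pos[seqVec] <- seq_len(N)
  out <- matrix(0, nrow = N + 1L, ncol = length(ctx$bios))
  for (j in seq_along(ctx$bios)) {
    p <- pos[ctx$bioEvents[[j]]]        # increasing threshold order
    o <- order(p)
    keep <- p[o] < N
    xs <- c(0L, p[o][keep], N)
    ys <- c(0, ctx$bioThr[[j]][o][keep], ctx$zMaxScaled[j])
    m <- length(xs)
    seg <- xs[-1L] - xs[-m]
    out[, j] <- cumsum(c(0, rep((ys[-1L] - ys[-m]) / seg, seg)))
  }
  out
}

# n x (N+1) per-stage log-likelihood matrix under one sequence.
.ctxStageLL <- function(ctx, seqVec) {
  Ts <- .ctxTraj(ctx, seqVec)
  M <- tcrossprod(ctx$Zs, Ts)
  M <- M - ctx$zss                       # column-major recycle = per row
  M - rep(0.5 * .rowSums(Ts^2, nrow(Ts), ncol(Ts)) - ctx$cst,
          each = ctx$n)
}

# Per-patient log marginal under one sequence (uniform stage prior).
.ctxMarginal <- function(ctx, seqVec) {
  .rowLogSumExp(.ctxStageLL(ctx, seqVec)) - log(ctx$N + 1)
}

# Weighted total: sum_s w_s log P(z_s | S).
.ctxWeightedLoglik <- function(ctx, seqVec, w) {
  sum(w * .ctxMarginal(ctx, seqVec))
}

# --- thin wrappers used by one-off callers ---------------------------

.stageLogLik <- function(Z, seqVec, events, sigma, zMax) {
  .ctxStageLL(.llCtx(Z, events, sigma, zMax), seqVec)
}

.seqLogMarginal <- function(Z, seqVec, events, sigma, zMax) {
  .ctxMarginal(.llCtx(Z, events, sigma, zMax), seqVec)
}

# patients x subtypes matrix of log marginals.
.subtypeLogMarginals <- function(Z, model) {
  ctx <- .llCtx(Z, model@events, model@sigma, model@zMax)
  vapply(model@sequences, function(s) .ctxMarginal(ctx, s),
         numeric(nrow(Z)))
}

.asZ <- function(Z) {
  if (is(Z, "ZScoreMatrix")) Z@Z else as.matrix(Z)
}

# Recycle a scalar sigma to a named per-biomarker vector.
.sigmaVec <- function(sigma, events) {
  bios <- unique(events$biomarker)
  if (is.null(names(sigma)))
    sigma <- setNames(rep_len(sigma, length(bios)), bios)
  if (any(sigma[bios] <= 0) || anyNA(sigma[bios]))
    .stopf("sigma must be positive for every biomarker")
  sigma
}

#' Per-stage likelihood of one patient's z-score profile
#'
#' For each stage k in 0..N, the product over biomarkers of the normal
#' density centred on the stage-k expected trajectory with sd
#' \code{sigma}.
#'
#' @param z named numeric vector of one patient's z-scores (all of the
#'   event set's biomarkers must be present and non-missing).
#' @param sequence valid integer event sequence.
#' @param events event table from \code{\link{buildEventSet}}.
#' @param sigma noise sd, scalar or named per biomarker (default 1).
#' @param zMax trajectory ceiling (default 3).
#' @return numeric vector of length N+1 (stages 0..N).
#' @export
stageLikelihoods <- function(z, sequence, events, sigma = 1, zMax = 3) {
  bios <- unique(events$biomarker)
  if (!all(bios %in% names(z)))
    .stopf("z lacks biomarker(s): %s",
           paste(setdiff(bios, names(z)), collapse = ", "))
  if (anyNA(z[bios]))
    .stopf("missing z value(s); missing biomarkers are not marginalized")
  if (!.validSequence(sequence, events))
    .stopf("not a valid event sequence for this event set")
  Zm <- matrix(z[bios], nrow = 1L, dimnames = list(NULL, bios))
  as.numeric(exp(.stageLogLik(Zm, sequence, events, sigma, zMax)))
}

#' Total log-likelihood of a subtype model
#'
#' Sum over patients of the log mixture marginal
#' \eqn{\log \sum_c f_c (N+1)^{-1} \sum_k P(z | S_c, k)} with a uniform
#' stage prior including stage 0.
#'
#' @param Z a \linkS4class{ZScoreMatrix} or a patients x biomarkers
#'   matrix with biomarker column names.
#' @param model a \linkS4class{SubtypeModel}.
#' @return scalar total log-likelihood.
#' @export
modelLoglik <- function(Z, model) {
  Zm <- .asZ(Z)
  lm_ <- .subtypeLogMarginals(Zm, model)
  sum(.rowLogSumExp(sweep(lm_, 2L, log(model@fractions), "+")))
}

# Construct a SubtypeModel without refitting.
.newModel <- function(events, sequences, fractions, sigma, zMax,
                      loglik = numeric(0)) {
  new("SubtypeModel", events = events, sequences = sequences,
      fractions = fractions, sigma = sigma, zMax = zMax, loglik = loglik)
}
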