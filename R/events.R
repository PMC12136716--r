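# Event set construction and piecewise-linear expected trajectories.
#
# An "event" is one biomarker crossing one severity threshold (z = 1,
# 1.5, 2 by default). A sequence is a permutation of all events in which
# the events of any one biomarker appear in increasing threshold order
# (trajectories are monotone).

#' Build the event set for a biomarker panel
#'
#' Forms the cartesian product of biomarkers and severity thresholds in
#' canonical order: biomarkers in panel order, thresholds increasing
#' within biomarker. With the default 12-region panel and thresholds
#' (1, 1.5, 2) this yields 36 events.
#'
#' @param biomarkers character vector of biomarker abbreviations.
#' @param thresholds strictly increasing positive z-score severity levels.
#' @return data.frame with columns \code{event} (1..N), \code{biomarker},
#'   \code{threshold}.
#' @examples
#' nrow(buildEventSet(defaultBiomarkers(), c(1, 1.5, 2)))  # 36
#' @export
buildEventSet <- function(biomarkers, thresholds = c(1, 1.5, 2)) {
  if (!length(biomarkers) || !length(thresholds))
    .stopf("biomarkers and thresholds must be non-empty")
  if (anyDuplicated(biomarkers))
    .stopf("duplicate biomarker abbreviations: %s",
           paste(unique(biomarkers[duplicated(biomarkers)]), collapse = ", "))
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    .stopf("thresholds must be positive and strictly increasing")
  ev <- data.frame(
    biomarker = rep(biomarkers, each = length(thresholds)),
    threshold = rep(thresholds, times = length(biomarkers)),
    stringsAsFactors = FALSE)
  ev <- cbind(event = seq_len(nrow(ev)), ev)
  ev
}

# TRUE iff seqVec is a permutation of events$event with same-biomarker
# events in increasing threshold order.
.validSequence <- function(seqVec, events) {
  N <- nrow(events)
  if (length(seqVec) != N || !setequal(seqVec, events$event)) return(FALSE)
  thr <- events$threshold[seqVec]
  bio <- events$biomarker[seqVec]
  all(vapply(split(thr, bio), function(v) !is.unsorted(v, strictly = TRUE),
             logical(1)))
}

# Random valid sequence: draw a uniform random interleaving, then assign
# each biomarker's thresholds in increasing order to its drawn slots.
.randomValidSequence <- function(events) {
  N <- nrow(events)
  slots <- sample.int(N)            # slots[i] = position of the i-th event
  seqVec <- integer(N)
  for (b in unique(events$biomarker)) {
    idx <- events$event[events$biomarker == b]   # increasing threshold
    pos <- sort(slots[idx])
    seqVec[pos] <- idx
  }
  seqVec
}

# Trajectory matrix for one sequence: (N+1) x B; row k+1 = expected z of
# every biomarker at stage k (0-based). Control points: (0, 0), (event
# position, its threshold), (N, zMax). The zMax anchor always holds at
# stage N; an event colliding with position N is absorbed by it.
.trajMatrix <- function(seqVec, events, zMax) {
  N <- nrow(events)
  pos <- integer(N); pos[seqVec] <- seq_len(N)   # pos[event id] = position
  bios <- unique(events$biomarker)
  out <- matrix(0, nrow = N + 1L, ncol = length(bios),
                dimnames = list(NULL, bios))
  for (j in seq_along(bios)) {
    idx <- events$event[events$biomarker == bios[j]]
    p <- pos[idx]
    o <- order(p)
    keep <- p[o] < N
    xs <- c(0, p[o][keep], N)
    ys <- c(0, events$threshold[idx][o][keep], zMax)
    out[, j] <- approx(xs, ys, xout = 0:N, method = "linear")$y
  }
  out
}

#' Expected biomarker trajectory value
#'
#' The z-score event model places each biomarker on a piecewise-linear
#' trajectory anchored at (stage 0, z = 0), at each of the biomarker's
#' events (position, threshold), and at (stage N, \code{zMax}). The
#' expected value is monotone nondecreasing in stage.
#'
#' @param sequence integer vector: a valid permutation of the event ids.
#' @param biomarker biomarker abbreviation to query.
#' @param stage integer stage in 0..N (vectorized).
#' @param events event table from \code{\link{buildEventSet}}.
#' @param zMax trajectory ceiling (default 3).
#' @return expected z value(s) at the queried stage(s).
#' @export
expectedTrajectory <- function(sequence, biomarker, stage, events,
                               zMax = 3) {
  N <- nrow(events)
  if (!.validSequence(sequence, events))
    .stopf("not a valid event sequence for this event set")
  if (any(stage < 0 | stage > N))
    .stopf("stage must lie in [0, %d]", N)
  if (!biomarker %in% events$biomarker)
    .stopf("unknown biomarker '%s'", biomarker)
  tm <- .trajMatrix(sequence, events, zMax)
  tm[stage + 1L, biomarker]
}

# All valid insertion positions for event `ev` given the sequence with
# `ev` removed (length N-1): any slot strictly after the biomarker's
# previous-threshold event and at or before its next-threshold event.
.validInsertions <- function(reduced, ev, events) {
  bio <- events$biomarker[ev]; thr <- events$threshold[ev]
  sameBio <- events$event[events$biomarker == bio]
  lowPos <- 0L; highPos <- length(reduced) + 1L
  for (e in sameBio) {
    if (e == ev) next
    p <- match(e, reduced)
    if (events$threshold[e] < thr) lowPos <- max(lowPos, p)
    else highPos <- min(highPos, p)
  }
  seq.int(lowPos + 1L, highPos)
}

.insertAt <- function(reduced, ev, pos) {
  append(reduced, ev, after = pos - 1L)
}
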