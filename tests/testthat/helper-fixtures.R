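# Shared fixtures and independent oracles.

# Small biomarker panels for toy models.
toyEvents <- function(nBio = 2, thresholds = c(1, 1.5, 2)) {
  buildEventSet(paste0("B", seq_len(nBio)), thresholds)
}

# All valid sequences (same-biomarker thresholds increasing) by brute
# force over permutations; only usable for tiny event sets.
enumerateValidSequences <- function(events) {
  N <- nrow(events)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  Filter(function(s) zsustain:::.validSequence(s, events),
         perms(events$event))
}

# Brute-force model log-likelihood: direct triple sum over subtypes,
# stages and per-biomarker normal densities, with no shared code with
# the package's matrix implementation.
bruteLoglik <- function(Z, events, sequences, fractions, sigma, zMax) {
  bios <- unique(events$biomarker)
  if (is.null(names(sigma))) sigma <- setNames(rep(sigma, length(bios)), bios)
  N <- nrow(events)
  total <- 0
  for (s in seq_len(nrow(Z))) {
    mix <- 0
    for (c in seq_along(sequences)) {
      stageSum <- 0
      for (k in 0:N) {
        prod <- 1
        for (b in bios) {
          mu <- unname(expectedTrajectory(sequences[[c]], b, k, events,
                                          zMax))
          prod <- prod * unname(dnorm(Z[s, b], mean = mu, sd = sigma[b]))
        }
        stageSum <- stageSum + prod
      }
      mix <- mix + fractions[c] * stageSum / (N + 1)
    }
    total <- total + log(mix)
  }
  total
}

# Draw patients from a planted single-sequence truth.
simulateFromSequence <- function(seqVec, events, n, sigma = 1, zMax = 3,
                                 stages = NULL) {
  N <- nrow(events)
  bios <- unique(events$biomarker)
  if (is.null(stages)) stages <- sample(0:N, n, replace = TRUE)
  Tm <- t(vapply(stages, function(k)
    vapply(bios, function(b)
      expectedTrajectory(seqVec, b, k, events, zMax), numeric(1)),
    numeric(length(bios))))
  Z <- Tm + matrix(rnorm(n * length(bios), 0, sigma), nrow = n)
  colnames(Z) <- bios
  list(Z = Z, stages = stages)
}

# Kendall tau between two sequences' event positions.
seqKendall <- function(a, b) {
  pa <- integer(length(a)); pa[a] <- seq_along(a)
  pb <- integer(length(b)); pb[b] <- seq_along(b)
  cor(pa, pb, method = "kendall")
}

# Small in-memory cohort for io/harmonization tests.
makeTinyCohort <- function(n = 40, nRegions = 4, seed = 7,
                           sites = c("A", "B")) {
  set.seed(seed)
  rt <- defaultRegionTable()[seq_len(nRegions), ]
  ids <- sprintf("P%03d", seq_len(n))
  vals <- matrix(rnorm(n * nRegions, 1, 0.1), nrow = n,
                 dimnames = list(ids, rt$abbreviation))
  meta <- data.frame(
    subject_id = ids,
    group = rep(c("patient", "control"), length.out = n),
    site = rep(rep(sites, each = 2), length.out = n),
    age = round(runif(n, 20, 60)),
    sex = sample(c("male", "female"), n, TRUE),
    education = round(runif(n, 6, 18)),
    mean_fd = runif(n, 0.02, 0.15),
    max_fd = runif(n, 0.2, 1.2),
    hamd_total = ifelse(rep(c(TRUE, FALSE), length.out = n),
                        sample(8:30, n, TRUE), NA),
    stringsAsFactors = FALSE)
  alffCohort(vals, meta, rt)
}
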