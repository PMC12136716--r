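# Event sets, sequence validity, expected trajectories and the
# likelihood against brute-force oracles.

test_that("event set is the ordered cartesian product", {
  ev <- buildEventSet(defaultBiomarkers(), c(1, 1.5, 2))
  expect_equal(nrow(ev), 36L)
  expect_equal(nrow(buildEventSet("A", 1)), 1L)
  expect_equal(nrow(buildEventSet(c("A", "B"), c(1, 2))), 4L)
  # canonical order: biomarker-major, threshold increasing
  expect_equal(ev$biomarker[1:3], rep("PreCG", 3))
  expect_equal(ev$threshold[1:3], c(1, 1.5, 2))
  expect_error(buildEventSet(c("A", "A"), 1), "duplicate")
  expect_error(buildEventSet("A", c(2, 1)), "strictly increasing")
})

test_that("sequence validity enforces monotone within-biomarker order", {
  ev <- toyEvents(2, c(1, 2))     # events 1,2 = B1; 3,4 = B2
  expect_true(zsustain:::.validSequence(c(1L, 3L, 2L, 4L), ev))
  expect_false(zsustain:::.validSequence(c(2L, 1L, 3L, 4L), ev))
  expect_false(zsustain:::.validSequence(c(1L, 2L, 3L), ev))
  # random sequences are always valid
  set.seed(41)
  ev36 <- buildEventSet(defaultBiomarkers(), c(1, 1.5, 2))
  for (i in 1:20)
    expect_true(zsustain:::.validSequence(
      zsustain:::.randomValidSequence(ev36), ev36))
})

test_that("expected trajectory interpolates its control points", {
  ev <- buildEventSet(c("A", "B"), c(1, 1.5))   # N = 4
  s <- c(1L, 2L, 3L, 4L)     # A(1)@1 A(1.5)@2 B(1)@3 B(1.5)@4
  expect_equal(unname(expectedTrajectory(s, "A", 0, ev)), 0)
  expect_equal(unname(expectedTrajectory(s, "A", 1, ev)), 1)
  expect_equal(unname(expectedTrajectory(s, "A", 2, ev)), 1.5)
  expect_equal(unname(expectedTrajectory(s, "B", 3, ev)), 1)
  # the ceiling is reached at stage N, absorbing a colliding event
  expect_equal(unname(expectedTrajectory(s, "A", 4, ev)), 3)
  expect_equal(unname(expectedTrajectory(s, "B", 4, ev)), 3)
  # interpolation between anchors at positions 2 and 6 -> 1.25 at stage 4
  ev4 <- buildEventSet(c("A", "B", "C", "D"), c(1, 1.5))   # N = 8
  s4 <- c(3L, 1L, 4L, 5L, 6L, 2L, 7L, 8L)
  expect_equal(unname(expectedTrajectory(s4, "A", 4, ev4)), 1.25)
  # monotone nondecreasing in stage for random sequences
  set.seed(42)
  for (i in 1:10) {
    sq <- zsustain:::.randomValidSequence(ev4)
    for (b in c("A", "B", "C", "D")) {
      tr <- expectedTrajectory(sq, b, 0:8, ev4)
      expect_true(all(diff(tr) >= -1e-12))
    }
  }
  expect_error(expectedTrajectory(s4, "A", 9, ev4), "stage")
})

test_that("stage likelihoods are normal density products", {
  # 1 biomarker, 1 threshold, N = 1, zMax = 2
  ev <- buildEventSet("A", 1)
  z <- c(A = 0)
  L <- stageLikelihoods(z, 1L, ev, sigma = 1, zMax = 2)
  expect_equal(L, c(dnorm(0, 0, 1), dnorm(0, 2, 1)), tolerance = 1e-12)
  # profile exactly on the stage-k trajectory maximizes stage k
  ev2 <- toyEvents(2, c(1, 2))
  s <- c(1L, 3L, 2L, 4L)
  for (k in 0:4) {
    zk <- vapply(c("B1", "B2"), function(b)
      unname(expectedTrajectory(s, b, k, ev2)), numeric(1))
    expect_equal(which.max(stageLikelihoods(zk, s, ev2)) - 1L, k)
  }
  # flatness in the large-sigma limit
  Lf <- stageLikelihoods(c(B1 = 0.3, B2 = 0.1), s, ev2, sigma = 100)
  expect_lt(max(Lf) / min(Lf), 1.01)
  expect_error(stageLikelihoods(c(B1 = 1), s, ev2), "lacks")
  expect_error(stageLikelihoods(c(B1 = 1, B2 = NA), s, ev2), "missing")
})

test_that("model log-likelihood equals brute-force enumeration (N <= 4)", {
  set.seed(43)
  configs <- list(
    list(ev = buildEventSet("A", 1), C = 1),
    list(ev = buildEventSet(c("A", "B"), 1), C = 2),
    list(ev = buildEventSet(c("A", "B"), c(1, 2)), C = 2),
    list(ev = buildEventSet(c("A", "B", "C", "D"), 1), C = 2))
  for (cf in configs) {
    ev <- cf$ev
    bios <- unique(ev$biomarker)
    seqs <- lapply(seq_len(cf$C), function(i)
      zsustain:::.randomValidSequence(ev))
    f <- if (cf$C == 1) 1 else c(0.6, 0.4)
    Z <- matrix(rnorm(3 * length(bios), 0.5, 1), nrow = 3,
                dimnames = list(NULL, bios))
    model <- zsustain:::.newModel(ev, seqs, f,
                                  setNames(rep(1, length(bios)), bios),
                                  zMax = 3)
    expect_equal(modelLoglik(Z, model),
                 bruteLoglik(Z, ev, seqs, f, 1, 3), tolerance = 1e-10)
  }
})

test_that("degenerate mixtures and duplicated patients behave additively", {
  set.seed(44)
  ev <- toyEvents(2, c(1, 2))
  s <- c(1L, 3L, 2L, 4L)
  Z <- matrix(rnorm(6, 0.5, 1), nrow = 3,
              dimnames = list(NULL, c("B1", "B2")))
  m1 <- zsustain:::.newModel(ev, list(s), 1, c(B1 = 1, B2 = 1), 3)
  # C=1 equals the single-sequence marginal
  expect_equal(modelLoglik(Z, m1),
               sum(zsustain:::.seqLogMarginal(Z, s, ev,
                                              c(B1 = 1, B2 = 1), 3)),
               tolerance = 1e-12)
  # duplicating every patient doubles the log-likelihood
  expect_equal(modelLoglik(rbind(Z, Z), m1), 2 * modelLoglik(Z, m1),
               tolerance = 1e-10)
})
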