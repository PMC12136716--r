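# Synthetic cohort generator with planted ground truth.
#
# Emits cohorts with the exact statistical structure the analysis
# assumes: two patient subpopulations following opposite event orderings
# over the 12-region panel, uniform stages over 0..36, Gaussian
# biomarker noise, additive/multiplicative site effects across 18 sites,
# linear covariate effects, and HAMD item scores with a planted subtype
# effect on the core-depression items.

#' Default generator configuration
#'
#' Two subtypes over the 12-region panel with thresholds (1, 1.5, 2) —
#' 36 events. Subtype 1's ordering starts with the paracentral lobule's
#' events, the thalamus's events follow early, and the medial
#' orbitofrontal cortex's events come last; subtype 2 is the exact
#' biomarker-order reversal. Within a biomarker the three threshold
#' events are consecutive. Mixture fractions 0.68/0.32, stages uniform
#' on 0..36, 18 sites, noise sd 1.
#'
#' @param ... named overrides of individual fields.
#' @return a list of class \code{"zsGeneratorConfig"}.
#' @export
defaultGeneratorConfig <- function(...) {
  bio1 <- c("PCL", "THA", "PoCG", "PreCG", "SMA", "SPG",
            "SFG", "SFGmedial", "OLF", "REC", "OFCpost", "OFCmed")
  cfg <- list(
    biomarkers = defaultBiomarkers(),
    thresholds = c(1, 1.5, 2),
    zMax = 3,
    sigma = 1,
    # subtype orderings given as biomarker orders; each biomarker's
    # threshold events are planted consecutively
    subtypeBiomarkerOrder = list(bio1, rev(bio1)),
    fractions = c(0.68, 0.32),
    stageDistribution = "uniform",   # uniform over 0..N including stage 0
    nPatients = 400L,
    nControls = 400L,
    nSites = 18L,
    siteLocationSd = 0.05,           # raw-scale additive site shift sd
    siteScaleRange = c(0.8, 1.25),   # multiplicative site scale
    baseline = 1.0,                  # raw-scale regional mean
    controlSd = 0.1,                 # raw-scale control sd per region
    covariateEffects = c(age = -0.0010, sex = 0.02, education = 0.0015,
                         mean_fd = -0.10),
    cdEffect = 1.5,                  # planted subtype-1 core-depression
                                     # effect, HAMD points
    onsetHamdCorrelation = 0.17,     # planted within subtype 1 only
    seed = 42L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    .stopf("unknown generator field(s): %s",
           paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  # a custom panel without explicit orderings: first-to-last and its
  # exact reversal, mirroring the default architecture
  if ("biomarkers" %in% names(dots) &&
      !"subtypeBiomarkerOrder" %in% names(dots))
    cfg$subtypeBiomarkerOrder <- list(cfg$biomarkers,
                                      rev(cfg$biomarkers))
  if (abs(sum(cfg$fractions) - 1) > 1e-9)
    .stopf("fractions must sum to 1")
  if (length(cfg$subtypeBiomarkerOrder) != length(cfg$fractions))
    .stopf("one biomarker order per subtype is required")
  for (o in cfg$subtypeBiomarkerOrder)
    if (!setequal(o, cfg$biomarkers))
      .stopf("each subtype ordering must permute the biomarker panel")
  structure(cfg, class = "zsGeneratorConfig")
}

# Planted event sequences (integer, over buildEventSet's canonical ids):
# each biomarker's thresholds consecutive, biomarkers in config order.
.plantedSequences <- function(cfg) {
  ev <- buildEventSet(cfg$biomarkers, cfg$thresholds)
  lapply(cfg$subtypeBiomarkerOrder, function(ord)
    unlist(lapply(ord, function(b) ev$event[ev$biomarker == b])))
}

#' Generate a synthetic cohort
#'
#' Each patient draws a subtype (by mixture fraction) and a stage
#' (uniform over 0..N); the planted abnormality z is the subtype
#' trajectory at that stage plus Gaussian noise. Controls sit at stage
#' 0. Abnormality is mapped to a raw feature scale (baseline minus
#' z times the control sd — reductions), then additive/multiplicative
#' site effects and linear covariate effects are applied, for the panel
#' regions and for the remaining 35 bilateral regions (pure noise).
#' Complete subject metadata is emitted.
#'
#' @param config list from \code{\link{defaultGeneratorConfig}}.
#' @param seed integer seed (bit-reproducible output).
#' @param regionTable bilateral region table.
#' @return list with \code{cohort} (an \linkS4class{AlffCohort} over all
#'   47 regions) and \code{truth} (planted per-patient subtype/stage,
#'   site effects, sequences, fractions, covariate effects).
#' @export
generateCohort <- function(config = defaultGeneratorConfig(),
                           seed = config$seed,
                           regionTable = defaultRegionTable()) {
  cfg <- config
  ev <- buildEventSet(cfg$biomarkers, cfg$thresholds)
  N <- nrow(ev)
  seqs <- .plantedSequences(cfg)
  .withSeed(seed, {
    nP <- cfg$nPatients; nC <- cfg$nControls; n <- nP + nC
    ids <- sprintf("S%04d", seq_len(n))
    group <- c(rep("patient", nP), rep("control", nC))
    subtype <- c(sample.int(length(cfg$fractions), nP, replace = TRUE,
                            prob = cfg$fractions), rep(NA_integer_, nC))
    stage <- c(sample.int(N + 1L, nP, replace = TRUE) - 1L,
               rep(0L, nC))
    site <- paste0("site", sample.int(cfg$nSites, n, replace = TRUE))
    age <- pmin(65, pmax(18, round(rnorm(n, 36, 12), 1)))
    sex <- sample(c("female", "male"), n, replace = TRUE,
                  prob = c(0.62, 0.38))
    education <- pmin(22, pmax(3, round(rnorm(n, 12, 3))))
    meanFd <- round(runif(n, 0.02, 0.18), 4)
    maxFd <- round(runif(n, 0.2, 1.5), 3)
    # planted abnormality z for the 12 panel regions
    Zplant <- matrix(0, nrow = n, ncol = length(cfg$biomarkers),
                     dimnames = list(ids, cfg$biomarkers))
    for (c in seq_along(seqs)) {
      idx <- which(!is.na(subtype) & subtype == c)
      if (!length(idx)) next
      Tm <- .trajMatrix(seqs[[c]], ev, cfg$zMax)
      Zplant[idx, ] <- Tm[stage[idx] + 1L, , drop = FALSE]
    }
    Zplant <- Zplant + matrix(rnorm(n * ncol(Zplant), 0, cfg$sigma),
                              nrow = n)
    # raw scale over all 47 regions; non-panel regions are pure noise
    ab <- regionTable$abbreviation
    raw <- matrix(cfg$baseline +
                    rnorm(n * length(ab), 0, cfg$sigma) * cfg$controlSd,
                  nrow = n, dimnames = list(ids, ab))
    raw[, cfg$biomarkers] <- cfg$baseline - Zplant * cfg$controlSd
    # site and covariate effects
    siteLoc <- setNames(rnorm(cfg$nSites, 0, cfg$siteLocationSd),
                        paste0("site", seq_len(cfg$nSites)))
    siteScale <- setNames(runif(cfg$nSites, cfg$siteScaleRange[1],
                                cfg$siteScaleRange[2]),
                          paste0("site", seq_len(cfg$nSites)))
    raw <- cfg$baseline + (raw - cfg$baseline) * siteScale[site] +
      siteLoc[site]
    be <- cfg$covariateEffects
    covShift <- be["age"] * (age - 36) +
      be["sex"] * (sex == "male") +
      be["education"] * (education - 12) +
      be["mean_fd"] * (meanFd - 0.1)
    raw <- raw + covShift * cfg$controlSd / 0.1   # scale-free planting
    meta <- data.frame(subject_id = ids, group = group, site = site,
                       age = age, sex = sex, education = education,
                       mean_fd = meanFd, max_fd = maxFd,
                       stringsAsFactors = FALSE)
    truth <- list(subtype = setNames(subtype, ids),
                  stage = setNames(stage, ids),
                  site = setNames(site, ids),
                  siteLocation = siteLoc, siteScale = siteScale,
                  sequences = seqs, events = ev,
                  fractions = cfg$fractions,
                  covariateEffects = be, config = cfg)
    clin <- generateClinical(truth, cfg, seed = .childSeed(seed, 1L))
    meta <- cbind(meta, clin[match(ids, clin$subject_id),
                             setdiff(colnames(clin), "subject_id")])
    cohort <- suppressWarnings(alffCohort(raw, meta, regionTable))
    list(cohort = cohort, truth = truth)
  })
}

#' Generate clinical scores for a planted cohort
#'
#' HAMD-17 items from bounded integer distributions with a planted
#' additive subtype-1 effect on the core-depression items (1 and 7),
#' patient totals forced to >= 8, onset age correlated with the total
#' HAMD score within subtype 1 only (target correlation
#' \code{onsetHamdCorrelation}), plus illness duration and
#' episode/medication status with Table-1-like missingness. Controls
#' get missing clinical fields.
#'
#' @param truth ground-truth list from \code{\link{generateCohort}}.
#' @param config the generator configuration.
#' @param seed integer seed.
#' @return data.frame keyed by \code{subject_id} with \code{hamd1}..
#'   \code{hamd17}, \code{hamd_total}, \code{onset_age},
#'   \code{duration}, \code{episode}, \code{medication}.
#' @export
generateClinical <- function(truth, config, seed) {
  ids <- names(truth$subtype)
  n <- length(ids)
  pat <- !is.na(truth$subtype)
  .withSeed(seed, {
    # item maxima follow the instrument: items 4-6, 12-14, 16-17 are
    # 0-2, the rest 0-4
    itemMax <- c(4, 4, 4, 2, 2, 2, 4, 4, 4, 4, 4, 2, 2, 2, 4, 2, 2)
    items <- matrix(NA_integer_, nrow = n, ncol = 17,
                    dimnames = list(ids, paste0("hamd", 1:17)))
    sev <- runif(sum(pat), 0.35, 0.75)   # per-patient overall severity
    for (j in 1:17)
      items[pat, j] <- rbinom(sum(pat), itemMax[j], sev)
    # planted subtype-1 core-depression effect, split over items 1 and 7
    s1 <- pat & truth$subtype == 1L
    for (j in c(1L, 7L)) {
      bump <- rbinom(sum(s1), 2, config$cdEffect / 4)
      items[s1, j] <- pmin(itemMax[j], items[s1, j] + bump)
    }
    tot <- rowSums(items)
    # enforce the inclusion criterion HAMD >= 8 by lifting light cases
    low <- which(pat & tot < 8)
    for (i in low) {
      while (sum(items[i, ]) < 8) {
        j <- sample.int(17, 1L)
        if (items[i, j] < itemMax[j]) items[i, j] <- items[i, j] + 1L
      }
    }
    tot <- rowSums(items)
    onset <- rep(NA_real_, n)
    dur <- rep(NA_real_, n)
    # onset age correlated with total HAMD within subtype 1 only
    rho <- config$onsetHamdCorrelation
    z <- scale(tot[s1])[, 1]
    onset[s1] <- round(pmin(60, pmax(12,
      28 + 9 * (rho * z + sqrt(1 - rho^2) * rnorm(sum(s1))))), 1)
    s2 <- pat & !s1
    onset[s2] <- round(pmin(60, pmax(12, rnorm(sum(s2), 29, 9))), 1)
    dur[pat] <- round(pmin(360, rlnorm(sum(pat), log(24), 0.9)), 1)
    episode <- rep(NA_character_, n)
    medication <- rep(NA_character_, n)
    known <- pat & runif(n) < 0.65       # Table-1-like missingness
    episode[known] <- sample(c("first", "recurrent"), sum(known),
                             replace = TRUE, prob = c(0.75, 0.25))
    medication[known] <- sample(c("used", "not_used"), sum(known),
                                replace = TRUE)
    out <- data.frame(subject_id = ids, items, stringsAsFactors = FALSE)
    out$hamd_total <- ifelse(pat, tot, NA_integer_)
    out[!pat, paste0("hamd", 1:17)] <- NA_integer_
    out$onset_age <- onset
    out$duration <- dur
    out$episode <- episode
    out$medication <- medication
    out
  })
}
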