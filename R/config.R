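# Analysis configuration.

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: exclusion-rule
#' thresholds, severity z-levels, the trajectory ceiling, noise sd,
#' fitting/MCMC settings, fold count and seed. The \code{"reduced"}
#' preset lowers the restart, EM and MCMC budgets for quick exploratory
#' runs at small problem sizes.
#'
#' @param preset \code{"default"} or \code{"reduced"}.
#' @param ... named overrides of individual fields.
#' @return a list of class \code{"zsAnalysisConfig"}.
#' @examples
#' cfg <- analysisConfig(preset = "reduced", folds = 5)
#' @export
analysisConfig <- function(preset = c("default", "reduced"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    ageRange = c(18, 65),      # years, inclusive
    maxMeanFd = 0.2,           # mm; exceeding excludes
    maxMaxFd = 2,              # mm; exceeding excludes
    minHamd = 8,               # patients below 8 excluded
    minSiteSize = 10,          # per group, per site
    zThresholds = c(1, 1.5, 2),
    zMax = 3,
    sigma = 1,
    nStarts = 10,
    nSplits = 3,
    emMaxIter = 50,
    emTol = 1e-6,
    mcmcIter = 1e5,
    mcmcThin = 10,
    folds = 5,
    displayThreshold = 0.65,   # stage-bin profile display cut
    seed = 42,
    preset = preset)
  if (preset == "reduced") {
    cfg$nStarts <- 3
    cfg$nSplits <- 2
    cfg$emMaxIter <- 15
    cfg$mcmcIter <- 2e4
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    .stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validateConfig(cfg)
  structure(cfg, class = "zsAnalysisConfig")
}

.validateConfig <- function(cfg) {
  z <- cfg$zThresholds
  if (any(z <= 0) || is.unsorted(z, strictly = TRUE))
    .stopf("zThresholds must be positive and strictly increasing")
  if (cfg$zMax <= max(z))
    .stopf("zMax must exceed the largest severity threshold")
  if (cfg$folds < 2) .stopf("folds must be >= 2")
  invisible(cfg)
}
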