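# End-to-end orchestration with a reproducible run manifest.

#' Serialize a fitted model to JSON
#'
#' Sequences are written as ordered biomarker/threshold pairs, with the
#' mixture fractions, sigma and zMax echoed.
#'
#' @param model a \linkS4class{SubtypeModel}.
#' @param path output file path.
#' @export
writeModelJson <- function(model, path) {
  obj <- list(
    subtypes = lapply(seq_along(model@sequences), function(c) {
      ev <- model@events[model@sequences[[c]], ]
      list(fraction = model@fractions[c],
           sequence = lapply(seq_len(nrow(ev)), function(i)
             list(biomarker = ev$biomarker[i],
                  threshold = ev$threshold[i])))
    }),
    sigma = as.list(model@sigma),
    zMax = model@zMax,
    loglik = if (length(model@loglik)) model@loglik else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model back from JSON
#'
#' @param path JSON file written by \code{\link{writeModelJson}}.
#' @param events optional event table; reconstructed from the file when
#'   absent.
#' @return a \linkS4class{SubtypeModel}.
#' @export
readModelJson <- function(path, events = NULL) {
  obj <- jsonlite::read_json(path)
  seq1 <- obj$subtypes[[1]]$sequence
  bios <- unique(vapply(seq1, `[[`, character(1), "biomarker"))
  thrs <- sort(unique(vapply(seq1, `[[`, numeric(1), "threshold")))
  if (is.null(events)) events <- buildEventSet(bios, thrs)
  key <- paste(events$biomarker, events$threshold)
  seqs <- lapply(obj$subtypes, function(s)
    match(vapply(s$sequence, function(e)
      paste(e$biomarker, e$threshold), character(1)), key))
  f <- vapply(obj$subtypes, `[[`, numeric(1), "fraction")
  .newModel(events, seqs, f / sum(f),
            setNames(unlist(obj$sigma), names(obj$sigma)), obj$zMax,
            loglik = if (is.null(obj$loglik)) numeric(0) else obj$loglik)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> validate/exclude -> harmonize ->
#' residualize -> select -> fit (or cross-validate) -> stage ->
#' clinical -> decode, writing TSV/JSON outputs plus a markdown report
#' and returning a manifest (config echo, package version, seeds,
#' per-output md5 hashes). Deterministic given the seed.
#'
#' @param config either a YAML file path or a named list; recognised
#'   fields: \code{seed}, \code{outDir}, \code{simulate} (logical or a
#'   list of generator overrides), \code{featurePath}/\code{metadataPath}
#'   (when \code{simulate} is FALSE), \code{maxSubtypes},
#'   \code{nSubtypes} (skip CV when given), \code{folds},
#'   \code{mcmcIter} (0 disables MCMC), \code{preset}, and
#'   \code{stages} (character vector disabling defaults when absent).
#' @param verbose emit stage-tagged progress messages.
#' @return the manifest list (invisibly, with the result objects in
#'   \code{$results}).
#' @export
runPipeline <- function(config = list(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 42L)
  outDir <- config$outDir %||% tempfile("zsustain_run_")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  acfg <- analysisConfig(preset = config$preset %||% "default",
                         seed = seed)
  if (!is.null(config$folds)) acfg$folds <- config$folds
  if (!is.null(config$mcmcIter)) acfg$mcmcIter <- config$mcmcIter
  t0 <- Sys.time()
  manifest <- list(package = "zsustain",
                   version = as.character(utils::packageVersion("zsustain")),
                   seed = seed, config = config, stages = character(0),
                   hashes = list(), timings = list())
  results <- list()
  mark <- function(stage, t) {
    manifest$stages <<- c(manifest$stages, stage)
    manifest$timings[[stage]] <<- round(as.numeric(Sys.time() - t,
                                                   units = "secs"), 2)
    .msg(stage, "done", verbose = verbose)
  }
  # --- simulate / load -----------------------------------------------
  ts <- Sys.time()
  if (isTRUE(config$simulate) || is.list(config$simulate) ||
      is.null(config$featurePath)) {
    gcfg <- do.call(defaultGeneratorConfig,
                    if (is.list(config$simulate)) config$simulate
                    else list())
    sim <- generateCohort(gcfg, seed = seed)
    cohort <- sim$cohort
    results$truth <- sim$truth
    mark("simulate", ts)
  } else {
    cohort <- readCohortTables(config$featurePath, config$metadataPath)
    mark("load", ts)
  }
  # --- validate / exclusions -----------------------------------------
  ts <- Sys.time()
  cohort <- applyExclusions(cohort, acfg)
  excl <- exclusionReport(cohort)
  write.csv(excl, file.path(outDir, "exclusion_report.csv"),
            row.names = FALSE)
  results$exclusionReport <- excl
  mark("validate", ts)
  # --- harmonize + residualize ---------------------------------------
  ts <- Sys.time()
  cohort <- combatAdjust(cohort)
  cohort <- residualizeOnControls(cohort)
  results$harmonized <- cohort
  mark("harmonize", ts)
  # --- feature selection ---------------------------------------------
  ts <- Sys.time()
  tests <- regionwiseGroupTest(cohort)
  selected <- selectFeatures(tests, alpha = 0.05)
  selected <- selected[tests$direction[match(selected,
                                             tests$region)] == "decrease"]
  if (length(selected) < 2L) selected <- defaultBiomarkers()
  tests$selected <- tests$region %in% selected
  write.csv(tests, file.path(outDir, "region_tests.csv"),
            row.names = FALSE)
  results$regionTests <- tests
  results$selected <- selected
  mark("select", ts)
  # --- z-scores -------------------------------------------------------
  ts <- Sys.time()
  Z <- zscoreAgainstControls(cohort, biomarkers = selected)
  results$Z <- Z
  mark("zscore", ts)
  # --- fit / cross-validate ------------------------------------------
  events <- buildEventSet(selected, acfg$zThresholds)
  ts <- Sys.time()
  if (is.null(config$nSubtypes)) {
    cv <- crossValidateCvic(Z, maxC = config$maxSubtypes %||% 2L,
                            events = events, folds = acfg$folds,
                            config = acfg, seed = seed,
                            verbose = verbose)
    results$cv <- cv
    C <- selectedC(cv)
    write.csv(cvTable(cv), file.path(outDir, "cv_table.csv"),
              row.names = FALSE)
  } else C <- as.integer(config$nSubtypes)
  model <- fitSubtypes(Z, C, events, acfg, seed = seed,
                       verbose = verbose)
  if (acfg$mcmcIter > 0) {
    post <- mcmcPosterior(Z, model, nIter = acfg$mcmcIter,
                          seed = .childSeed(seed, 7L),
                          thin = acfg$mcmcThin)
    model <- post@mlModel
    results$mcmc <- post
  }
  results$model <- model
  writeModelJson(model, file.path(outDir, "model.json"))
  mark("fit", ts)
  # --- staging --------------------------------------------------------
  ts <- Sys.time()
  assignments <- assignSubjects(Z, model)
  write.csv(assignments, file.path(outDir, "assignments.csv"),
            row.names = FALSE)
  results$assignments <- assignments
  mark("stage", ts)
  # --- clinical -------------------------------------------------------
  ts <- Sys.time()
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  patMeta <- cd[match(assignments$subject_id, cd$subject_id), ]
  itemCols <- paste0("hamd", 1:17)
  clinical <- NULL
  twoGroups <- length(unique(assignments$ml_subtype)) == 2 &&
    min(table(assignments$ml_subtype)) >= 3
  if (all(itemCols %in% colnames(patMeta)) && twoGroups) {
    dims <- suppressWarnings(hamdDimensions(patMeta[, itemCols]))
    clinical <- compareSubtypeDimensions(
      dims, assignments$ml_subtype,
      covariates = data.frame(age = patMeta$age,
                              sex = as.numeric(patMeta$sex == "male"),
                              education = patMeta$education))
    write.csv(clinical, file.path(outDir, "clinical_dimensions.csv"),
              row.names = FALSE)
  }
  results$clinical <- clinical
  mark("clinical", ts)
  # --- decode ---------------------------------------------------------
  ts <- Sys.time()
  terms <- defaultTermMaps()
  decoded <- list()
  for (st in seq_along(model@sequences)) {
    for (bin in c("I", "II", "III", "IV", "V")) {
      ok <- any(assignments$ml_subtype == st &
                  assignments$stage_bin == bin)
      if (!ok) next
      cm <- tryCatch(stagebinContrastMap(cohort, assignments, st, bin),
                     error = function(e) NULL)
      if (is.null(cm) || length(cm) < 3L) next
      decoded[[paste0("S", st, "_", bin)]] <- decodeTerms(-cm, terms)
    }
  }
  results$decoding <- decoded
  mark("decode", ts)
  # --- report + manifest ---------------------------------------------
  .writeReport(file.path(outDir, "report.md"), results, model)
  outs <- list.files(outDir, full.names = TRUE)
  manifest$hashes <- as.list(tools::md5sum(outs))
  names(manifest$hashes) <- basename(outs)
  manifest$elapsed <- round(as.numeric(Sys.time() - t0,
                                       units = "secs"), 2)
  manifest$results <- results
  jsonlite::write_json(manifest[setdiff(names(manifest), "results")],
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest$outDir <- outDir
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeReport <- function(path, results, model) {
  lines <- c("# zsustain run report", "")
  if (!is.null(results$exclusionReport)) {
    lines <- c(lines, "## Exclusions", "",
               utils::capture.output(print(results$exclusionReport)), "")
  }
  lines <- c(lines, "## Model", "",
             utils::capture.output(show(model)), "")
  if (!is.null(results$mcmc)) {
    lines <- c(lines, "## Position-variance (subtype 1, first 6 events)",
               "",
               utils::capture.output(
                 print(round(positionVariance(results$mcmc)[[1]][1:6,
                             1:min(10, ncol(positionVariance(
                               results$mcmc)[[1]]))], 3))), "")
  }
  if (!is.null(results$clinical)) {
    lines <- c(lines, "## Clinical dimensions", "",
               utils::capture.output(print(results$clinical)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
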