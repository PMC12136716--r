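# Cohort I/O: region table, table reading/validation, bilateral
# averaging, exclusion rules.

#' The packaged bilateral region table
#'
#' 47 bilateral cerebral regions mirroring the AAL-2 cerebral
#' parcellation: one row per region with its name, abbreviation, left and
#' right atlas integer labels and a coarse network tag (SMN, DMN, LIM or
#' other).
#'
#' @param path optional path to a user TSV with the same columns.
#' @return data.frame with columns \code{region_id}, \code{name},
#'   \code{abbreviation}, \code{left_label}, \code{right_label},
#'   \code{network}.
#' @export
defaultRegionTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "regions_bilateral.tsv",
                        package = "zsustain", mustWork = TRUE)
  rt <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "name", "abbreviation", "left_label",
            "right_label", "network")
  miss <- setdiff(need, colnames(rt))
  if (length(miss))
    .stopf("region table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(rt$abbreviation))
    .stopf("region abbreviations must be unique")
  if (anyDuplicated(c(rt$left_label, rt$right_label)))
    .stopf("left/right atlas labels must be distinct across regions")
  rt
}

#' The default 12-region biomarker panel
#'
#' The case-control-different regions used as the progression model's
#' biomarkers: precentral gyrus, dorsolateral superior frontal gyrus,
#' supplementary motor area, olfactory cortex, medial superior frontal
#' gyrus, gyrus rectus, medial and posterior orbitofrontal cortex,
#' postcentral gyrus, superior parietal gyrus, paracentral lobule and
#' thalamus.
#'
#' @return character vector of 12 region abbreviations.
#' @export
defaultBiomarkers <- function() {
  c("PreCG", "SFG", "SMA", "OLF", "SFGmedial", "REC",
    "OFCmed", "OFCpost", "PoCG", "SPG", "PCL", "THA")
}

.readTable <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  else read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

.metadataColumns <- c(
  "subject_id", "group", "site", "age", "sex", "education", "mean_fd",
  "max_fd", "hamd_total", "onset_age", "duration", "episode", "medication")

#' Construct a cohort from in-memory tables
#'
#' @param values subjects x regions numeric matrix (column names =
#'   region abbreviations, row names = subject ids).
#' @param metadata data.frame of per-subject metadata keyed by
#'   \code{subject_id}; must include \code{group} and \code{site}.
#' @param regionTable bilateral region table
#'   (default \code{\link{defaultRegionTable}()}).
#' @return an \linkS4class{AlffCohort} (regions x subjects internally),
#'   subjects sorted lexicographically by id.
#' @export
alffCohort <- function(values, metadata, regionTable = defaultRegionTable()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    .stopf("values must carry subject ids as row names")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicated subject_id in feature table: %s",
           paste(unique(rownames(values)[duplicated(rownames(values))]),
                 collapse = ", "))
  if (anyDuplicated(metadata$subject_id))
    .stopf("duplicated subject_id in metadata: %s",
           paste(unique(metadata$subject_id[duplicated(metadata$subject_id)]),
                 collapse = ", "))
  unknown <- setdiff(colnames(values), regionTable$abbreviation)
  if (length(unknown))
    .stopf("unknown region label(s) in feature table: %s",
           paste(unknown, collapse = ", "))
  if (!is.numeric(values))
    .stopf("non-numeric feature cells in feature table")
  common <- sort(intersect(rownames(values), metadata$subject_id))
  dropped <- setdiff(union(rownames(values), metadata$subject_id), common)
  if (length(dropped))
    .warnf("dropping %d subject(s) absent from one of the tables: %s",
           length(dropped), paste(head(dropped, 5), collapse = ", "))
  if (!length(common)) .stopf("no subjects shared by the two tables")
  values <- values[common, , drop = FALSE]
  metadata <- metadata[match(common, metadata$subject_id), , drop = FALSE]
  if (anyNA(values)) .stopf("feature table contains missing values")
  # hamd_total must equal the item sum when both are present
  itemCols <- paste0("hamd", 1:17)
  if (all(itemCols %in% colnames(metadata)) &&
      "hamd_total" %in% colnames(metadata)) {
    items <- as.matrix(metadata[, itemCols])
    ok <- is.na(metadata$hamd_total) | apply(items, 1L, anyNA) |
      abs(rowSums(items) - metadata$hamd_total) < 1e-8
    if (!all(ok))
      .stopf("hamd_total disagrees with the item sum for: %s",
             paste(metadata$subject_id[!ok], collapse = ", "))
  }
  keepRegions <- regionTable$abbreviation[
    regionTable$abbreviation %in% colnames(values)]
  values <- values[, keepRegions, drop = FALSE]
  rd <- regionTable[match(keepRegions, regionTable$abbreviation), ,
                    drop = FALSE]
  cd <- S4Vectors::DataFrame(metadata, row.names = metadata$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(alff = t(values)), colData = cd,
    rowData = S4Vectors::DataFrame(rd, row.names = rd$abbreviation))
  new("AlffCohort", se)
}

#' Read and validate cohort tables from disk
#'
#' Features: TSV/CSV with a header of region abbreviations and a first
#' column \code{subject_id}. Metadata: TSV/CSV with the subject-record
#' columns (missing values as empty cells or "NA"). Subjects present in
#' both tables are retained (a dropped subject is warned about);
#' subjects are ordered lexicographically by id so downstream seeding is
#' reproducible.
#'
#' @param featurePath,metadataPath file paths.
#' @param regionTable bilateral region table.
#' @return an \linkS4class{AlffCohort}.
#' @export
readCohortTables <- function(featurePath, metadataPath,
                             regionTable = defaultRegionTable()) {
  feat <- .readTable(featurePath)
  meta <- .readTable(metadataPath)
  if (!"subject_id" %in% colnames(feat))
    .stopf("feature table lacks a subject_id column")
  if (!"subject_id" %in% colnames(meta))
    .stopf("metadata table lacks a subject_id column")
  vals <- feat[, setdiff(colnames(feat), "subject_id"), drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    .stopf("non-numeric feature column(s): %s",
           paste(colnames(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- as.character(feat$subject_id)
  meta$subject_id <- as.character(meta$subject_id)
  alffCohort(m, meta, regionTable)
}

#' Average left and right hemisphere columns into bilateral regions
#'
#' Each bilateral region's value is the arithmetic mean of its left and
#' right hemisphere columns. Hemisphere columns may be named by atlas
#' integer label (\code{left_label}/\code{right_label} of the region
#' table) or as \code{<abbreviation>_L} / \code{<abbreviation>_R}.
#'
#' @param values subjects x unilateral-region numeric matrix.
#' @param regionTable bilateral region table.
#' @return subjects x bilateral-regions matrix, columns named by
#'   abbreviation in region-table order.
#' @export
bilateralAverage <- function(values, regionTable = defaultRegionTable()) {
  values <- as.matrix(values)
  cn <- colnames(values)
  out <- matrix(NA_real_, nrow = nrow(values), ncol = nrow(regionTable),
                dimnames = list(rownames(values), regionTable$abbreviation))
  for (i in seq_len(nrow(regionTable))) {
    ab <- regionTable$abbreviation[i]
    lcol <- which(cn %in% c(as.character(regionTable$left_label[i]),
                            paste0(ab, "_L")))
    rcol <- which(cn %in% c(as.character(regionTable$right_label[i]),
                            paste0(ab, "_R")))
    if (length(lcol) != 1L || length(rcol) != 1L)
      .stopf("missing or ambiguous hemisphere column for region %s", ab)
    out[, i] <- (values[, lcol] + values[, rcol]) / 2
  }
  out
}

#' Apply the cohort exclusion rules
#'
#' Rules, in application order: complete demographics (group, site, age,
#' sex, education present); age within 18-65 inclusive; head motion
#' (mean FD <= 0.2 mm and max FD <= 2 mm; equality retains); patients'
#' HAMD-17 total >= 8; and finally sites retaining at least 10 patients
#' and 10 controls. A per-rule exclusion report (counts in application
#' order) is attached to the returned cohort.
#'
#' @param cohort an \linkS4class{AlffCohort}.
#' @param config list from \code{\link{analysisConfig}}.
#' @return the filtered cohort; retrieve the report with
#'   \code{\link{exclusionReport}}.
#' @export
applyExclusions <- function(cohort, config = analysisConfig()) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  keep <- rep(TRUE, nrow(cd))
  report <- data.frame(rule = character(0), excluded = integer(0),
                       remaining = integer(0))
  note <- function(rule, drop) {
    keep <<- keep & !drop
    report <<- rbind(report, data.frame(rule = rule,
                                        excluded = sum(drop & !is.na(drop)),
                                        remaining = sum(keep)))
  }
  demo <- c("group", "site", "age", "sex", "education")
  miss <- setdiff(demo, colnames(cd))
  if (length(miss))
    .stopf("metadata lacks demographic column(s): %s",
           paste(miss, collapse = ", "))
  note("demographics", keep & !complete.cases(cd[, demo]))
  note("age", keep & (cd$age < config$ageRange[1] |
                        cd$age > config$ageRange[2]))
  for (f in c("mean_fd", "max_fd")) if (!f %in% colnames(cd))
    .stopf("motion rule enabled but column '%s' missing", f)
  note("motion", keep & (cd$mean_fd > config$maxMeanFd |
                           cd$max_fd > config$maxMaxFd))
  if (!"hamd_total" %in% colnames(cd))
    .stopf("HAMD rule enabled but column 'hamd_total' missing")
  pat <- cd$group == "patient"
  if (any(keep & pat & is.na(cd$hamd_total)))
    .stopf("HAMD rule enabled but hamd_total missing for patient(s): %s",
           paste(cd$subject_id[keep & pat & is.na(cd$hamd_total)],
                 collapse = ", "))
  note("hamd", keep & pat & cd$hamd_total < config$minHamd)
  # site-size rule applied last, on the survivors of the other rules
  tab <- table(factor(cd$site[keep]),
               factor(cd$group[keep], levels = c("control", "patient")))
  okSites <- rownames(tab)[
    tab[, "patient"] >= config$minSiteSize &
      tab[, "control"] >= config$minSiteSize]
  note("site_size", keep & !(cd$site %in% okSites))
  out <- cohort[, keep]
  out@exclusionReport <- report
  out
}
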