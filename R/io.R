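## File formats: NIfTI-1 volumes (via RNifti), TSV cohort tables, YAML
## configuration and JSON reports.

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti that normalize errors into format errors
#' naming the offending file. \code{readVolume} accepts \code{.nii} and
#' \code{.nii.gz}; a write-then-read round trip preserves the data array
#' and grid metadata.
#'
#' @param path file path.
#' @return \code{readVolume}: a numeric array (an RNifti image, carrying
#'   grid metadata); \code{writeVolume}: the path, invisibly.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tryCatch(RNifti::readNifti(path),
           error = function(e)
             stop("malformed NIfTI file '", path, "': ",
                  conditionMessage(e), call. = FALSE))
}

#' @rdname readVolume
#' @param volume numeric array (3D map or 4D series) to write.
#' @export
writeVolume <- function(volume, path) {
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

.cohortSchema <- function() {
  list(
    required = c("subject", "group", "age", "sex", "ssri_snri",
                 "mean_fd_baseline"),
    numeric = c("age", "mean_fd_baseline", "mean_fd_followup",
                "interval_months", "soms_cd_baseline", "soms_cd_followup",
                "phq15_baseline", "phq15_followup", "bdi_baseline",
                "bdi_followup", "stai_baseline", "stai_followup",
                "pcl5_baseline", "ctq_abuse", "ctq_neglect"),
    binary = c("sex", "ssri_snri", "fnd_seizure"),
    symptom = c("soms_cd_baseline", "soms_cd_followup", "phq15_baseline",
                "phq15_followup", "bdi_baseline", "bdi_followup",
                "stai_baseline", "stai_followup", "pcl5_baseline",
                "ctq_abuse", "ctq_neglect"),
    cgi = c("much improved", "improved", "unchanged", "worse",
            "much worse")
  )
}

#' Read / write the cohort table
#'
#' The cohort table is a TSV with one row per subject. Required columns:
#' \code{subject}, \code{group} (FND or HC), \code{age}, \code{sex}
#' (female = 1), \code{ssri_snri}, \code{mean_fd_baseline}; recognized
#' further columns are the session FD and interval, the questionnaire
#' totals at baseline/follow-up (SOMS:CD, PHQ-15, BDI-II, STAI-total;
#' baseline-only PCL-5 and CTQ subscales), \code{fnd_seizure},
#' \code{cgi_i} and \code{has_followup_scan}. Schema violations (unknown
#' CGI category, non-binary indicator, HC rows carrying symptom or CGI
#' fields) are reported with their row numbers. Missing follow-up fields
#' mark lost-to-follow-up rows and are allowed.
#'
#' @param path TSV file path.
#' @return \code{readCohortTable}: a validated data.frame.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  validateCohortTable(df)
  df
}

#' @rdname readCohortTable
#' @param table a cohort data.frame.
#' @export
writeCohortTable <- function(table, path) {
  validateCohortTable(table)
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readCohortTable
#' @export
validateCohortTable <- function(table) {
  sc <- .cohortSchema()
  missingCols <- setdiff(sc$required, names(table))
  if (length(missingCols))
    stop("cohort table missing required column(s): ",
         paste(missingCols, collapse = ", "))
  badGroup <- which(!table$group %in% c("FND", "HC"))
  if (length(badGroup))
    stop("unknown group in row(s) ", paste(badGroup, collapse = ", "),
         " (must be FND or HC)")
  for (b in intersect(sc$binary, names(table))) {
    bad <- which(!(is.na(table[[b]]) | table[[b]] %in% c(0, 1)))
    if (length(bad))
      stop("column '", b, "' must be 0/1; bad row(s): ",
           paste(bad, collapse = ", "))
  }
  if ("cgi_i" %in% names(table)) {
    bad <- which(!(is.na(table$cgi_i) | table$cgi_i %in% sc$cgi))
    if (length(bad))
      stop("unknown CGI-I category in row(s) ",
           paste(bad, collapse = ", "))
  }
  hc <- table$group == "HC"
  for (s in intersect(c(sc$symptom, "cgi_i"), names(table))) {
    bad <- which(hc & !is.na(table[[s]]))
    if (length(bad))
      stop("HC row(s) ", paste(bad, collapse = ", "),
           " must not carry symptom/CGI field '", s, "'")
  }
  invisible(TRUE)
}

#' Export a synthetic cohort to disk
#'
#' Writes each session as a 4D NIfTI volume (time last), the masks and
#' label volume as 3D NIfTI, the covariate table as TSV, the simulation
#' config as YAML and the truth record as JSON, into \code{dir}.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- cohort@space
  writeVolume(array(as.numeric(sp@greyMask), sp@dims),
              file.path(dir, "grey_mask.nii.gz"))
  writeVolume(array(as.numeric(sp@isoMask), sp@dims),
              file.path(dir, "iso_mask.nii.gz"))
  writeVolume(array(as.numeric(sp@labels), sp@dims),
              file.path(dir, "network_labels.nii.gz"))
  gv <- which(sp@greyMask)
  for (id in names(cohort@scans)) {
    for (ses in names(cohort@scans[[id]])) {
      ts <- cohort@scans[[id]][[ses]]
      vol4d <- array(0, c(sp@dims, nrow(ts)))
      for (t in seq_len(nrow(ts))) {
        v3 <- array(0, sp@dims); v3[gv] <- ts[t, ]
        vol4d[, , , t] <- v3
      }
      writeVolume(vol4d, file.path(dir, paste0(id, "_", ses, ".nii.gz")))
    }
  }
  writeCohortTable(cohort@covariates, file.path(dir, "cohort.tsv"))
  yaml::write_yaml(configAsList(cohort@config),
                   file.path(dir, "simulation_config.yaml"))
  jsonlite::write_json(
    list(boost = as.list(cohort@truth$boost),
         delta = as.list(cohort@truth$delta),
         effectRegion = cohort@truth$effectRegion,
         targetNetwork = cohort@truth$targetNetwork),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read / write pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return \code{readPipelineConfig}: a named list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname readPipelineConfig
#' @param config a named list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
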