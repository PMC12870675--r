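## End-to-end pipeline driver: simulate (or load) -> metrics -> GLM ->
## cluster correction -> seed post-hoc -> cohort stats -> HC
## contextualization, with all artifacts written under an output
## directory and a machine-readable JSON report.

.pipelineDefaults <- function() {
  list(
    analysis = list(outcome = "soms_cd", analysis = "baseline_predictor",
                    metric = "integration"),
    inference = list(z_thresh = 1.96, alpha = 0.05, n_iter = 1000L,
                     connectivity = 26L, seed = 1L),
    posthoc = list(seed_analysis = TRUE, n_iter = 500L, top_k = 3L),
    screening = list(wd_outlier_sd = 3)
  )
}

.mergeConfig <- function(config) {
  def <- .pipelineDefaults()
  for (blk in names(def)) {
    if (is.null(config[[blk]])) config[[blk]] <- def[[blk]]
    else for (k in names(def[[blk]]))
      if (is.null(config[[blk]][[k]])) config[[blk]][[k]] <- def[[blk]][[k]]
  }
  config
}

.validatePipelineConfig <- function(config) {
  an <- config$analysis
  if (!an$outcome %in% c("soms_cd", "phq15"))
    stop("config error [analysis]: outcome must be soms_cd or phq15")
  if (!an$analysis %in% c("baseline_predictor", "longitudinal_change",
                          "both"))
    stop("config error [analysis]: unknown analysis '", an$analysis, "'")
  if (!an$metric %in% c("weighted_degree", "integration", "segregation"))
    stop("config error [analysis]: unknown metric '", an$metric, "'")
  if (is.null(config$synthetic) && is.null(config$inputs))
    stop("config error [inputs]: either a synthetic block or an inputs ",
         "block is required")
  if (!is.null(config$inputs)) {
    need <- c("grey_mask", "iso_mask", "labels", "cohort_table")
    for (p in need)
      if (is.null(config$inputs[[p]]) || !file.exists(config$inputs[[p]]))
        stop("config error [inputs]: missing path '", p, "'")
  }
  invisible(TRUE)
}

#' Assemble a PhantomSpace from mask and label volumes
#'
#' Wraps externally supplied grey-matter, isocortical and network-label
#' volumes (as arrays or NIfTI paths) into the package's coordinate-frame
#' object. Labels are consumed as given.
#'
#' @param grey,iso numeric/logical 3D arrays or NIfTI paths.
#' @param labels integer 3D array or NIfTI path (0 outside the isocortex).
#' @return a \code{\linkS4class{PhantomSpace}}.
#' @export
spaceFromVolumes <- function(grey, iso, labels) {
  loadVol <- function(x) if (is.character(x)) readVolume(x) else x
  grey <- loadVol(grey); iso <- loadVol(iso); labels <- loadVol(labels)
  g <- array(grey > 0, dim(grey))
  i <- array(iso > 0, dim(iso))
  l <- array(as.integer(round(labels)), dim(labels))
  new("PhantomSpace", dims = as.integer(dim(g)), greyMask = g,
      isoMask = i, labels = l, nNetworks = max(l), seed = NA_integer_)
}

## Per-subject metric maps for one session's time series.
.sessionMetricMap <- function(ts, space, metric, subject, timepoint) {
  if (metric == "weighted_degree") {
    fc <- computeFCMatrix(ts, voxels = which(space@greyMask),
                          scope = "grey", dims = space@dims)
    weightedDegreeMap(fc, subject = subject, timepoint = timepoint)
  } else {
    gv <- which(space@greyMask)
    isoCols <- match(which(space@isoMask), gv)
    fc <- computeFCMatrix(ts[, isoCols, drop = FALSE],
                          voxels = which(space@isoMask),
                          scope = "isocortical", dims = space@dims)
    if (metric == "integration")
      integrationMap(fc, space, subject = subject, timepoint = timepoint)
    else
      segregationMap(fc, space, subject = subject, timepoint = timepoint)
  }
}

.analysisCovariates <- function(tab, outcome, longitudinal) {
  baseCol <- paste0(outcome, "_baseline")
  fd <- if (longitudinal)
    rowMeans(cbind(tab$mean_fd_baseline, tab$mean_fd_followup),
             na.rm = TRUE)
  else tab$mean_fd_baseline
  data.frame(age = tab$age, sex = tab$sex, ssri_snri = tab$ssri_snri,
             mean_fd = fd, interval = tab$interval_months,
             baseline_score = tab[[baseCol]])
}

.runOneAnalysis <- function(cohort, space, metricName, outcome, kind,
                            inference, log) {
  tab <- cohort@covariates
  fnd <- tab[tab$group == "FND", ]
  longitudinal <- kind == "longitudinal_change"
  if (longitudinal) fnd <- fnd[fnd$has_followup_scan, ]

  log("stage ", kind, ": computing ", metricName, " maps for ",
      nrow(fnd), " subjects")
  maps <- vector("list", nrow(fnd))
  for (i in seq_len(nrow(fnd))) {
    id <- fnd$subject[i]
    base <- .sessionMetricMap(cohort@scans[[id]]$baseline, space,
                              metricName, id, "baseline")
    maps[[i]] <- if (longitudinal) {
      fu <- .sessionMetricMap(cohort@scans[[id]]$followup, space,
                              metricName, id, "followup")
      metricChangeMap(fu, base)
    } else base
  }

  outcomeChange <- changeScore(fnd[[paste0(outcome, "_followup")]],
                               fnd[[paste0(outcome, "_baseline")]])
  covs <- .analysisCovariates(fnd, outcome, longitudinal)
  fit <- fitBrainBehaviorGLM(maps, outcomeChange, covs,
                             outcomeName = paste0("delta_", outcome),
                             term = metricName)
  fw <- estimateMapSmoothness(fit)
  mask <- if (metricName == "weighted_degree") space@greyMask else
    space@isoMask
  null <- clusterNullDistribution(mask, fwhm = fw,
                                  zThresh = inference$z_thresh,
                                  nIter = inference$n_iter,
                                  alpha = inference$alpha,
                                  connectivity = inference$connectivity,
                                  seed = inference$seed)
  clusters <- applyClusterCorrection(fit, null)
  log("stage ", kind, ": ", nrow(clusters@table),
      " surviving cluster(s), extent threshold ",
      null@extentThreshold)
  list(maps = maps, subjects = fnd$subject, outcomeChange = outcomeChange,
       covariates = covs, fit = fit, fwhm = fw, null = null,
       clusters = clusters)
}

.runSeedPosthoc <- function(res, cohort, space, posthoc, inference,
                            timepoints, log) {
  sig <- which(res$clusters@sigMask)
  counts <- suppressWarnings(assignClusterVoxelsToNetworks(sig, space))
  top <- suppressWarnings(selectTopNetworks(counts, posthoc$top_k))
  out <- list(voxel_counts = as.list(counts), top_networks = top,
              seeds = list())
  tab <- cohort@covariates
  rows <- match(res$subjects, tab$subject)
  covs <- data.frame(age = tab$age[rows], sex = tab$sex[rows],
                     ssri_snri = tab$ssri_snri[rows],
                     mean_fd = tab$mean_fd_baseline[rows])
  for (net in top) {
    seedVox <- sig[space@labels[sig] == net]
    seedRes <- list(network = net, n_seed_voxels = length(seedVox))
    perTP <- list()
    for (tp in timepoints) {
      zmaps <- lapply(res$subjects, function(id)
        seedToVoxelZMap(cohort@scans[[id]][[tp]], seedVox, space,
                        subject = id, timepoint = tp))
      grp <- groupSeedGLM(zmaps, covs, space@isoMask,
                          zThresh = inference$z_thresh,
                          nIter = posthoc$n_iter,
                          alpha = inference$alpha,
                          connectivity = inference$connectivity,
                          seed = inference$seed)
      cnt <- countBetweenNetworkConnections(
        which(grp$clusters@sigMask), space, net, timepoint = tp)
      perTP[[tp]] <- list(counts = cnt, clusters = grp$clusters@table)
    }
    seedRes$connection_counts <- lapply(perTP, `[[`, "counts")
    if (length(timepoints) == 2L) {
      cmp <- compareTimepointConnectionCounts(
        perTP[[1]]$counts, perTP[[2]]$counts, space)
      seedRes$timepoint_comparison <- cmp
    }
    out$seeds[[as.character(net)]] <- seedRes
    log("seed network ", net, ": ", length(seedVox), " seed voxels")
  }
  out
}

.cohortStatsBlock <- function(tab) {
  fnd <- tab[tab$group == "FND", ]
  cgiCounts <- vapply(.cohortSchema()$cgi,
                      function(cat) sum(fnd$cgi_i == cat, na.rm = TRUE),
                      1L)
  tests <- list(
    soms_cd = pairedTest(fnd$soms_cd_baseline, fnd$soms_cd_followup,
                         "wilcoxon"),
    phq15 = pairedTest(fnd$phq15_baseline, fnd$phq15_followup, "t"),
    bdi = pairedTest(fnd$bdi_baseline, fnd$bdi_followup, "wilcoxon"),
    stai = pairedTest(fnd$stai_baseline, fnd$stai_followup, "t"))
  fdr <- bhFDR(vapply(tests, `[[`, 1, "p"))
  okFD <- !is.na(fnd$mean_fd_followup)
  fdTest <- if (sum(okFD) >= 5)
    pairedTest(fnd$mean_fd_baseline[okFD], fnd$mean_fd_followup[okFD],
               "t") else NULL
  list(cgi_counts = as.list(cgiCounts),
       cgi_summary = as.list(summarizeCGI(cgiCounts)),
       paired_tests = tests,
       fdr_adjusted_p = as.list(setNames(fdr$adjusted, names(tests))),
       fd_paired_t = fdTest)
}

#' Run the full analysis pipeline
#'
#' Executes the configured analysis end to end and writes all artifacts
#' (z maps and significance masks as NIfTI, cluster and count tables as
#' TSV, a JSON report, a plain-text log) into the output directory.
#' Re-running with the same configuration and seeds reproduces all
#' numeric outputs.
#'
#' The configuration is a nested list (typically from a YAML file):
#' \itemize{
#'   \item \code{output_dir}: where artifacts are written.
#'   \item \code{synthetic}: parameters for \code{\link{makePhantomSpace}}
#'     (\code{dims}, \code{n_networks}, \code{space_seed}) plus any
#'     \code{\link{simulationConfig}} fields -- or instead
#'   \item \code{inputs}: paths to \code{grey_mask}, \code{iso_mask},
#'     \code{labels}, \code{cohort_table} and a \code{scan_dir} holding
#'     \code{<subject>_<session>.nii[.gz]} 4D volumes.
#'   \item \code{analysis}: \code{outcome} (soms_cd | phq15),
#'     \code{analysis} (baseline_predictor | longitudinal_change | both),
#'     \code{metric} (weighted_degree | integration | segregation).
#'   \item \code{inference}: \code{z_thresh}, \code{alpha}, \code{n_iter},
#'     \code{connectivity}, \code{seed}.
#'   \item \code{posthoc}: \code{seed_analysis}, \code{n_iter},
#'     \code{top_k}.
#' }
#'
#' @param config nested configuration list, or a path to a YAML file.
#' @return (invisibly) the report, a nested list mirroring the JSON
#'   written to \code{output_dir/report.json}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- .mergeConfig(config)
  .validatePipelineConfig(config)
  outDir <- config$output_dir
  if (is.null(outDir)) stop("config error [output]: output_dir required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "pipeline.log")
  cat("", file = logPath)
  t0 <- proc.time()[3]
  log <- function(...) {
    line <- paste0(sprintf("[%7.1fs] ", proc.time()[3] - t0), ...)
    cat(line, "\n", file = logPath, append = TRUE, sep = "")
    message(line)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs ----
  cohort <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      space <- makePhantomSpace(
        dims = if (is.null(syn$dims)) c(12L, 12L, 10L) else syn$dims,
        nNetworks = if (is.null(syn$n_networks)) 7L else syn$n_networks,
        seed = if (is.null(syn$space_seed)) 1L else syn$space_seed)
      scArgs <- syn[setdiff(names(syn),
                            c("dims", "n_networks", "space_seed"))]
      simCfg <- do.call(simulationConfig, c(list(space = space), scArgs))
      log("simulating cohort: ", simCfg@nFND, " FND / ", simCfg@nHC,
          " HC on a ", paste(space@dims, collapse = "x"), " phantom")
      simulateLongitudinalCohort(space, simCfg)
    } else {
      inp <- config$inputs
      space <- spaceFromVolumes(inp$grey_mask, inp$iso_mask, inp$labels)
      tab <- readCohortTable(inp$cohort_table)
      scans <- list()
      gv <- which(space@greyMask)
      for (i in seq_len(nrow(tab))) {
        id <- tab$subject[i]
        scans[[id]] <- list()
        for (ses in c("baseline", "followup")) {
          f <- file.path(inp$scan_dir, paste0(id, "_", ses, ".nii.gz"))
          if (!file.exists(f))
            f <- file.path(inp$scan_dir, paste0(id, "_", ses, ".nii"))
          if (file.exists(f)) {
            v <- readVolume(f)
            d <- dim(v)
            ts <- t(matrix(v, prod(d[1:3]), d[4])[gv, , drop = FALSE])
            scans[[id]][[ses]] <- ts
          }
        }
      }
      cfg <- simulationConfig(space, nFND = sum(tab$group == "FND"),
                              nFollowup = sum(tab$has_followup_scan %in%
                                                TRUE),
                              nHC = sum(tab$group == "HC"))
      new("SyntheticCohort", space = space, config = cfg, scans = scans,
          covariates = tab, truth = list())
    }
  })
  space <- cohort@space
  report <- list(
    package_version = as.character(packageVersion("voxconn")),
    config = config,
    config_hash = .configHash(config))

  ## ---- weighted-degree outlier screen ----
  screening <- stage("screening", {
    fndIds <- cohort@covariates$subject[cohort@covariates$group == "FND"]
    meanWD <- vapply(fndIds, function(id) {
      fc <- computeFCMatrix(cohort@scans[[id]]$baseline,
                            voxels = which(space@greyMask),
                            scope = "grey", dims = space@dims)
      mean(mapValues(weightedDegreeMap(fc, subject = id)))
    }, numeric(1))
    excluded <- flagOutlierSubjects(meanWD,
                                    config$screening$wd_outlier_sd)
    list(mean_weighted_degree = as.list(meanWD), excluded = excluded)
  })
  if (length(screening$excluded)) {
    log("WARN: excluding weighted-degree outlier(s): ",
        paste(screening$excluded, collapse = ", "))
    keep <- !cohort@covariates$subject %in% screening$excluded
    cohort@covariates <- cohort@covariates[keep, ]
    cohort@scans <- cohort@scans[cohort@covariates$subject]
  }
  report$screening <- screening

  ## ---- primary analyses ----
  kinds <- if (config$analysis$analysis == "both")
    c("baseline_predictor", "longitudinal_change") else
      config$analysis$analysis
  results <- list()
  for (kind in kinds) {
    res <- stage(kind, .runOneAnalysis(
      cohort, space, config$analysis$metric, config$analysis$outcome,
      kind, config$inference, log))
    results[[kind]] <- res
    writeVolume(asVolume(res$fit), file.path(outDir,
                                             paste0(kind, "_zmap.nii.gz")))
    writeVolume(array(as.numeric(res$clusters@sigMask), space@dims),
                file.path(outDir, paste0(kind, "_sigmask.nii.gz")))
    write.table(res$clusters@table,
                file.path(outDir, paste0(kind, "_clusters.tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    blk <- list(n_subjects = length(res$subjects),
                residual_df = res$fit@df,
                fwhm = res$fwhm,
                extent_threshold = res$null@extentThreshold,
                degenerate_null = res$null@degenerate,
                clusters = res$clusters@table)
    if (nrow(res$clusters@table)) {
      cm <- clusterMeanValues(res$clusters, res$maps)
      sp <- spearmanAssoc(res$outcomeChange, rowMeans(cm))
      blk$spearman_vs_outcome <- sp
    }
    report$analyses[[kind]] <- blk

    if (isTRUE(config$posthoc$seed_analysis) &&
        config$analysis$metric == "integration" &&
        nrow(res$clusters@table)) {
      tps <- if (kind == "longitudinal_change")
        c("baseline", "followup") else "baseline"
      report$analyses[[kind]]$seed_posthoc <- stage(
        paste0(kind, "_seed_posthoc"),
        .runSeedPosthoc(res, cohort, space, config$posthoc,
                        config$inference, tps, log))
    }
  }

  ## ---- cohort statistics ----
  report$cohort_stats <- stage("cohort_stats",
                               .cohortStatsBlock(cohort@covariates))

  ## ---- HC contextualization (needs both analyses) ----
  if (length(kinds) == 2L) {
    report$hc_contextualization <- stage("hc_contextualization", {
      ov <- overlapMask(results[[1]]$clusters@sigMask,
                        results[[2]]$clusters@sigMask)
      if (!any(ov)) {
        log("no overlap voxels between baseline and longitudinal masks")
        list(n_overlap_voxels = 0L)
      } else {
        ovIdx <- which(ov)
        meanOver <- function(ts) {
          mp <- .sessionMetricMap(ts, space, config$analysis$metric,
                                  "", "baseline")
          mean(mp@values[match(ovIdx, mp@voxels)], na.rm = TRUE)
        }
        tab <- cohort@covariates
        lng <- tab[tab$group == "FND" & tab$has_followup_scan, ]
        fndBase <- vapply(lng$subject, function(id)
          meanOver(cohort@scans[[id]]$baseline), numeric(1))
        fndFU <- vapply(lng$subject, function(id)
          meanOver(cohort@scans[[id]]$followup), numeric(1))
        hcIds <- tab$subject[tab$group == "HC"]
        hcVals <- vapply(hcIds, function(id)
          meanOver(cohort@scans[[id]]$baseline), numeric(1))
        oc <- changeScore(
          lng[[paste0(config$analysis$outcome, "_followup")]],
          lng[[paste0(config$analysis$outcome, "_baseline")]])
        strata <- stratifyExtremes(oc, 0.2, ids = lng$subject)
        tests <- hcContextualize(fndBase, fndFU, hcVals, strata)
        write.table(tests, file.path(outDir, "hc_contextualization.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
        list(n_overlap_voxels = length(ovIdx), strata = strata,
             tests = tests)
      }
    })
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", force = TRUE)
  log("pipeline complete; report written to ",
      file.path(outDir, "report.json"))
  invisible(report)
}

## hash of the analysis-relevant configuration (output location excluded,
## so the same analysis re-run elsewhere carries the same hash)
.configHash <- function(config) {
  config$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
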