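#' Configure a synthetic longitudinal cohort
#'
#' Builds a validated \code{\linkS4class{SimulationConfig}}. Defaults
#' emulate the study design the generator stands in for: 32 FND subjects
#' of whom 28 complete a second imaging session, 50 healthy controls, a
#' 28:4 female:male ratio and 13/32 SSRI/SNRI use. The generative model is
#' a latent-factor block covariance -- one factor per network plus a shared
#' global factor plus independent voxel noise -- whose within- and
#' between-network correlation targets are \code{withinR} and
#' \code{betweenR}. Subjects carry a baseline coupling boost (SD
#' \code{boostSD}) that loads the effect-region voxels onto the target
#' network's factor, and an independent longitudinal boost change (SD
#' \code{deltaSD}); symptom change is generated as
#' \deqn{\Delta = b_0 (-boost) + b_1 (-\Delta boost) + \sigma \epsilon}
#' so that higher baseline integration, and integration decreases over
#' time, map to more negative (improved) change scores. With the default
#' slopes and a baseline-only effect (\code{longitudinalEffectSize = 0})
#' the planted boost-outcome correlation is
#' \eqn{12 \times 0.15 / \sqrt{(12 \times 0.15)^2 + 2.4^2} = 0.6}.
#'
#' @param space a \code{\linkS4class{PhantomSpace}}; supplies the default
#'   effect region (a ball inside network 3, the "salience-like" block).
#' @param nFND,nFollowup,nHC cohort sizes.
#' @param nTimepoints samples per session (>= 20).
#' @param withinR,betweenR correlation targets, \code{0 <= betweenR <=
#'   withinR < 1}.
#' @param effectRegion integer linear voxel indices of the planted region;
#'   must lie inside the isocortical mask.
#' @param targetNetwork network the region's boost couples into.
#' @param baselineEffectSize,longitudinalEffectSize slopes of the
#'   change-score model (score units per unit boost).
#' @param boostSD,deltaSD,noiseSD spread of boosts, boost changes and
#'   change-score noise.
#' @param femaleProb,ssriProb covariate sampling rates.
#' @param seed master RNG seed; per-subject streams are derived from it by
#'   fixed offsets so adding subjects never perturbs earlier ones.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(space,
                             nFND = 32L, nFollowup = 28L, nHC = 50L,
                             nTimepoints = 150L,
                             withinR = 0.5, betweenR = 0.1,
                             effectRegion = defaultEffectRegion(space),
                             targetNetwork = 1L,
                             baselineEffectSize = 12,
                             longitudinalEffectSize = 12,
                             boostSD = 0.15, deltaSD = 0.15, noiseSD = 2.4,
                             femaleProb = 28 / 32, ssriProb = 13 / 32,
                             seed = 1L) {
  stopifnot(is(space, "PhantomSpace"))
  effectRegion <- as.integer(effectRegion)
  if (length(effectRegion) && !all(space@isoMask[effectRegion]))
    stop("effectRegion must lie inside the isocortical mask")
  cfg <- new("SimulationConfig",
    nFND = as.integer(nFND), nFollowup = as.integer(nFollowup),
    nHC = as.integer(nHC), nTimepoints = as.integer(nTimepoints),
    withinR = withinR, betweenR = betweenR,
    effectRegion = effectRegion, targetNetwork = as.integer(targetNetwork),
    baselineEffectSize = baselineEffectSize,
    longitudinalEffectSize = longitudinalEffectSize,
    boostSD = boostSD, deltaSD = deltaSD, noiseSD = noiseSD,
    femaleProb = femaleProb, ssriProb = ssriProb,
    seed = as.integer(seed))
  validObject(cfg)
  cfg
}

#' Simulate one subject's resting-state time series
#'
#' Draws a timepoints-by-grey-voxels matrix from the latent-factor block
#' covariance model: voxel \eqn{v} in network \eqn{k} follows
#' \deqn{x_{vt} = \sqrt{a_g}\, g_t + \sqrt{a_w}\, f_{kt} +
#'   c\, f_{k^* t}\,[v \in R] + \sqrt{1 - r_w}\, e_{vt}}
#' with \eqn{a_g = r_b} (between-network target) and
#' \eqn{a_w = r_w - r_b}, so the expected voxel-pair Pearson correlation is
#' \eqn{r_w} within a network and \eqn{r_b} across networks. Grey-matter
#' voxels outside the isocortex share their own extra latent factor.
#' The region boost \eqn{c} adds cross-network loading onto the target
#' network's factor for effect-region voxels only, raising their expected
#' between-network correlation monotonically in \eqn{c}.
#'
#' @param space a \code{\linkS4class{PhantomSpace}}.
#' @param withinR,betweenR correlation targets, \code{0 <= betweenR <=
#'   withinR < 1}; anything else is a parameterization error (the implied
#'   covariance would not be positive definite).
#' @param regionBoost numeric cross-network loading for the effect region.
#' @param effectRegion integer linear voxel indices receiving the boost.
#' @param targetNetwork network whose factor the boost loads onto.
#' @param nTimepoints number of samples (>= 20).
#' @param seed integer RNG seed.
#' @return numeric matrix, \code{nTimepoints} rows by one column per
#'   grey-matter voxel (column order = \code{greyVoxels(space)}).
#' @export
simulateSubjectTimeseries <- function(space, withinR, betweenR,
                                      regionBoost = 0,
                                      effectRegion = integer(0),
                                      targetNetwork = 1L,
                                      nTimepoints = 150L, seed = 1L) {
  stopifnot(is(space, "PhantomSpace"))
  if (withinR >= 1 || withinR < 0 || betweenR < 0 || betweenR > withinR)
    stop("parameterization error: need 0 <= betweenR <= withinR < 1")
  nTimepoints <- as.integer(nTimepoints)
  if (nTimepoints < 20L) stop("nTimepoints must be >= 20")

  gv <- which(space@greyMask)
  V <- length(gv)
  K <- space@nNetworks
  lab <- space@labels[gv]
  lab[lab == 0L] <- K + 1L  # deep grey voxels share their own factor

  ag <- betweenR
  aw <- withinR - betweenR
  nz <- 1 - withinR

  set.seed(as.integer(seed))
  ## latent factors are orthonormalized in-sample (exactly uncorrelated,
  ## zero mean, unit variance): realized factor covariance then matches
  ## its target instead of fluctuating at O(1/sqrt(T)), emulating fully
  ## nuisance-regressed (preprocessed) resting-state data and keeping
  ## subject-level global connectivity shifts out of the generative model
  raw <- matrix(rnorm(nTimepoints * (K + 2L)), nTimepoints, K + 2L)
  raw <- scale(raw, center = TRUE, scale = FALSE)
  fac <- qr.Q(qr(raw)) * sqrt(nTimepoints - 1)
  g <- fac[, 1L]
  f <- fac[, -1L, drop = FALSE]
  ## voxel noise is projected off the factor subspace for the same
  ## reason: chance noise-factor correlations otherwise induce shared
  ## connectivity shifts across all voxels of a subject
  e <- matrix(rnorm(nTimepoints * V), nTimepoints, V)
  e <- e - fac %*% (crossprod(fac, e) / (nTimepoints - 1))
  x <- sqrt(nz) * e
  x <- x + sqrt(ag) * g + sqrt(aw) * f[, lab]
  if (regionBoost != 0 && length(effectRegion)) {
    cols <- match(as.integer(effectRegion), gv)
    if (anyNA(cols)) stop("effectRegion contains non-grey voxels")
    x[, cols] <- x[, cols] + regionBoost * f[, targetNetwork]
  }
  colnames(x) <- NULL
  x
}

## Binary covariates are assigned deterministically from the subject
## index by a Kronecker (low-discrepancy) sequence, so every block of
## subjects carries the configured rate exactly (28F:4M, 13/32 SSRI at
## the defaults) and no finite cohort degenerates to a constant column.
.rateAssign <- function(i, p) as.integer((i * p) %% 1 < p)

## Per-subject covariate draws (FND). Magnitudes follow the clinical
## characteristics the generator emulates; see the methods vignette.
.drawFNDCovariates <- function(cfg, i) {
  list(
    age = min(80, max(18, rnorm(1, 42.4, 13.3))),
    sex = .rateAssign(i, cfg@femaleProb),
    ssri = .rateAssign(i, cfg@ssriProb),
    seizure = .rateAssign(i, 10 / 32),
    fd_base = rgamma(1, shape = 3.17, scale = 0.023),
    fd_fu = rgamma(1, shape = 5.64, scale = 0.0135),
    interval = min(9, max(5, rnorm(1, 6.8, 0.8))),
    soms = round(rgamma(1, shape = 1.1, scale = 6)),
    phq = round(rgamma(1, shape = 4.29, scale = 2.75)),
    bdi = round(rgamma(1, shape = 1.8, scale = 8.5)),
    stai = round(max(20, rnorm(1, 82.5, 23.2))),
    pcl = round(rgamma(1, shape = 1.71, scale = 13.7)),
    ctq_abuse = round(15 + rgamma(1, shape = 1.18, scale = 13.5)),
    ctq_neglect = round(10 + rgamma(1, shape = 1.86, scale = 6.24))
  )
}

.cgiFromChange <- function(delta) {
  if (delta <= -6) "much improved"
  else if (delta <= -1) "improved"
  else if (delta < 1) "unchanged"
  else if (delta < 6) "worse"
  else "much worse"
}

#' Simulate a longitudinal FND + HC cohort
#'
#' Generates scans, covariates and ground truth for one synthetic study.
#' FND subjects carry a baseline coupling boost and (for longitudinal
#' subjects) an independent boost change; healthy controls have a single
#' session with no boost. Core-symptom (SOMS:CD) change scores are
#' generated from the planted boosts via the model described in
#' \code{\link{simulationConfig}}, rounded into the questionnaire totals;
#' all remaining questionnaire totals, demographics and nuisance
#' covariates are drawn independently at realistic magnitudes.
#'
#' @param space a \code{\linkS4class{PhantomSpace}}.
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @export
simulateLongitudinalCohort <- function(space, config) {
  stopifnot(is(space, "PhantomSpace"), is(config, "SimulationConfig"))
  validObject(config)
  if (length(config@effectRegion) && !all(space@isoMask[config@effectRegion]))
    stop("effectRegion must lie inside the isocortical mask")

  scans <- list()
  rows <- list()
  boosts <- numeric(0)
  deltas <- numeric(0)

  for (i in seq_len(config@nFND)) {
    id <- sprintf("FND_%02d", i)
    set.seed(.subjectSeed(config@seed, i, salt = 0L))
    cv <- .drawFNDCovariates(config, i)
    boost <- rnorm(1, 0, config@boostSD)
    delta <- rnorm(1, 0, config@deltaSD)
    eps <- rnorm(1)
    hasFU <- i <= config@nFollowup
    somsChange <- config@baselineEffectSize * (-boost) +
      (if (hasFU) config@longitudinalEffectSize * (-delta) else 0) +
      config@noiseSD * eps
    ## outcome totals are NOT floored at zero: change scores are the
    ## generated quantity, and flooring would distort planted effects
    somsFU <- round(cv$soms + somsChange)
    phqFU <- round(cv$phq + rnorm(1, 0, 2.5))
    bdiFU <- max(0, round(cv$bdi + rnorm(1, -3.2, 6)))
    staiFU <- round(max(20, cv$stai + rnorm(1, -5.2, 10)))

    ses <- list(baseline = simulateSubjectTimeseries(
      space, config@withinR, config@betweenR,
      regionBoost = boost, effectRegion = config@effectRegion,
      targetNetwork = config@targetNetwork,
      nTimepoints = config@nTimepoints,
      seed = .subjectSeed(config@seed, i, salt = 1L)))
    if (hasFU)
      ses$followup <- simulateSubjectTimeseries(
        space, config@withinR, config@betweenR,
        regionBoost = boost + delta, effectRegion = config@effectRegion,
        targetNetwork = config@targetNetwork,
        nTimepoints = config@nTimepoints,
        seed = .subjectSeed(config@seed, i, salt = 2L))
    scans[[id]] <- ses
    boosts[id] <- boost
    deltas[id] <- if (hasFU) delta else NA_real_

    rows[[id]] <- data.frame(
      subject = id, group = "FND",
      age = cv$age, sex = cv$sex, ssri_snri = cv$ssri,
      fnd_seizure = cv$seizure,
      mean_fd_baseline = cv$fd_base,
      mean_fd_followup = if (hasFU) cv$fd_fu else NA_real_,
      interval_months = cv$interval,
      soms_cd_baseline = cv$soms, soms_cd_followup = somsFU,
      phq15_baseline = cv$phq, phq15_followup = phqFU,
      bdi_baseline = cv$bdi, bdi_followup = bdiFU,
      stai_baseline = cv$stai, stai_followup = staiFU,
      pcl5_baseline = cv$pcl,
      ctq_abuse = cv$ctq_abuse, ctq_neglect = cv$ctq_neglect,
      cgi_i = .cgiFromChange(somsFU - cv$soms),
      has_followup_scan = hasFU,
      stringsAsFactors = FALSE)
  }

  for (i in seq_len(config@nHC)) {
    id <- sprintf("HC_%02d", i)
    set.seed(.subjectSeed(config@seed, 100000L + i, salt = 0L))
    age <- min(75, max(18, rnorm(1, 38.7, 10.5)))
    sex <- .rateAssign(i, 43 / 50)
    fd <- rgamma(1, shape = 4, scale = 0.015)
    scans[[id]] <- list(baseline = simulateSubjectTimeseries(
      space, config@withinR, config@betweenR,
      regionBoost = 0, effectRegion = config@effectRegion,
      targetNetwork = config@targetNetwork,
      nTimepoints = config@nTimepoints,
      seed = .subjectSeed(config@seed, 100000L + i, salt = 1L)))
    rows[[id]] <- data.frame(
      subject = id, group = "HC",
      age = age, sex = sex, ssri_snri = NA_integer_,
      fnd_seizure = NA_integer_,
      mean_fd_baseline = fd, mean_fd_followup = NA_real_,
      interval_months = NA_real_,
      soms_cd_baseline = NA_real_, soms_cd_followup = NA_real_,
      phq15_baseline = NA_real_, phq15_followup = NA_real_,
      bdi_baseline = NA_real_, bdi_followup = NA_real_,
      stai_baseline = NA_real_, stai_followup = NA_real_,
      pcl5_baseline = NA_real_,
      ctq_abuse = NA_real_, ctq_neglect = NA_real_,
      cgi_i = NA_character_,
      has_followup_scan = FALSE,
      stringsAsFactors = FALSE)
  }

  cov <- do.call(rbind, rows)
  rownames(cov) <- NULL
  new("SyntheticCohort", space = space, config = config, scans = scans,
      covariates = cov,
      truth = list(boost = boosts, delta = deltas,
                   effectRegion = config@effectRegion,
                   targetNetwork = config@targetNetwork))
}

#' Simulate a null cohort
#'
#' Identical to \code{\link{simulateLongitudinalCohort}} but with both
#' brain-behavior effect sizes and all planted boosts forced to zero, for
#' type-I-error calibration of the downstream pipeline.
#'
#' @inheritParams simulateLongitudinalCohort
#' @return a \code{\linkS4class{SyntheticCohort}} whose truth record shows
#'   zero boosts.
#' @export
simulateNullCohort <- function(space, config) {
  stopifnot(is(config, "SimulationConfig"))
  cfg <- config
  cfg@baselineEffectSize <- 0
  cfg@longitudinalEffectSize <- 0
  cfg@boostSD <- 0
  cfg@deltaSD <- 0
  simulateLongitudinalCohort(space, cfg)
}

#' Serialize / deserialize a SimulationConfig
#'
#' \code{configAsList} flattens a config into a plain named list (suitable
#' for YAML); \code{configFromList} rebuilds and validates it. A round
#' trip is lossless.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return \code{configAsList}: a named list; \code{configFromList}: a
#'   \code{\linkS4class{SimulationConfig}}.
#' @export
configAsList <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  sn <- slotNames(config)
  out <- lapply(sn, function(s) slot(config, s))
  names(out) <- sn
  out
}

#' @rdname configAsList
#' @param x a named list as produced by \code{configAsList}.
#' @export
configFromList <- function(x) {
  intSlots <- c("nFND", "nFollowup", "nHC", "nTimepoints", "effectRegion",
                "targetNetwork", "seed")
  args <- x
  for (s in intSlots) if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
  if (is.null(args$effectRegion)) args$effectRegion <- integer(0)
  cfg <- do.call(new, c(list(Class = "SimulationConfig"), args))
  validObject(cfg)
  cfg
}
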