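## S4 class definitions and validity. Accessor generics live in AllGenerics.R.

#' PhantomSpace: the coordinate frame of all maps
#'
#' A 3D voxel grid carrying a grey-matter mask, an isocortical mask (a
#' subset of grey matter) and an integer network-label volume. Labels are 0
#' outside the isocortical mask and take values \code{1..K} inside, with
#' each network forming one spatially contiguous block so that planted
#' effect regions are connected.
#'
#' @slot dims integer(3), voxels per axis.
#' @slot greyMask logical array of dimension \code{dims}.
#' @slot isoMask logical array, subset of \code{greyMask}.
#' @slot labels integer array; 0 outside \code{isoMask}, \code{1..K} inside.
#' @slot nNetworks integer, number of networks K.
#' @slot seed integer seed the space was grown from.
#'
#' @seealso \code{\link{makePhantomSpace}}
#' @export
setClass("PhantomSpace",
  representation(
    dims = "integer",
    greyMask = "array",
    isoMask = "array",
    labels = "array",
    nNetworks = "integer",
    seed = "integer"
  )
)

setValidity("PhantomSpace", function(object) {
  msg <- character(0)
  d <- object@dims
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "dims must be a positive integer triple")
  if (!identical(dim(object@greyMask), d) ||
      !identical(dim(object@isoMask), d) ||
      !identical(dim(object@labels), d))
    msg <- c(msg, "mask/label arrays must all share dims")
  if (any(object@isoMask & !object@greyMask))
    msg <- c(msg, "isoMask must be a subset of greyMask")
  if (any(object@labels[!object@isoMask] != 0L))
    msg <- c(msg, "labels must be 0 outside isoMask")
  if (any(object@labels[object@isoMask] < 1L) ||
      any(object@labels[object@isoMask] > object@nNetworks))
    msg <- c(msg, "labels inside isoMask must lie in 1..nNetworks")
  tab <- tabulate(object@labels[object@isoMask], object@nNetworks)
  if (any(tab == 0L))
    msg <- c(msg, "every network label must have at least one voxel")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic longitudinal cohort
#'
#' Holds the full description of a simulated study: cohort sizes, session
#' structure, correlation targets of the block-covariance generative model,
#' the planted effect region with its cross-network coupling boosts, the
#' symptom-change generating slopes, and the master seed. Defaults mirror
#' the study design the generator emulates: 32 FND subjects (28 with two
#' imaging sessions), 50 healthy controls, a 28F:4M sex ratio and 13/32
#' SSRI/SNRI use.
#'
#' @slot nFND integer, number of FND subjects.
#' @slot nFollowup integer, FND subjects with a second imaging session.
#' @slot nHC integer, healthy controls (one session each).
#' @slot nTimepoints integer, samples per session.
#' @slot withinR numeric in [0,1), target within-network correlation.
#' @slot betweenR numeric in [0, withinR], target between-network correlation.
#' @slot effectRegion integer vector of linear voxel indices (the
#'   "insula-like" planted region, inside the isocortical mask).
#' @slot targetNetwork integer, the network the effect region couples into.
#' @slot baselineEffectSize numeric slope linking the (negated) baseline
#'   coupling boost to the symptom-change score.
#' @slot longitudinalEffectSize numeric slope for the (negated) boost change.
#' @slot boostSD numeric, SD of the per-subject baseline coupling boost.
#' @slot deltaSD numeric, SD of the per-subject longitudinal boost change.
#' @slot noiseSD numeric, SD of the Gaussian noise on change scores.
#' @slot femaleProb numeric, probability a subject is female.
#' @slot ssriProb numeric, probability of SSRI/SNRI use.
#' @slot seed integer master seed.
#'
#' @seealso \code{\link{simulationConfig}}
#' @export
setClass("SimulationConfig",
  representation(
    nFND = "integer",
    nFollowup = "integer",
    nHC = "integer",
    nTimepoints = "integer",
    withinR = "numeric",
    betweenR = "numeric",
    effectRegion = "integer",
    targetNetwork = "integer",
    baselineEffectSize = "numeric",
    longitudinalEffectSize = "numeric",
    boostSD = "numeric",
    deltaSD = "numeric",
    noiseSD = "numeric",
    femaleProb = "numeric",
    ssriProb = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (object@nFND < 1L) msg <- c(msg, "nFND must be >= 1")
  if (object@nFollowup > object@nFND)
    msg <- c(msg, "nFollowup cannot exceed nFND")
  if (object@nHC < 0L) msg <- c(msg, "nHC must be >= 0")
  if (object@nTimepoints < 20L) msg <- c(msg, "nTimepoints must be >= 20")
  if (object@withinR < 0 || object@withinR >= 1)
    msg <- c(msg, "withinR must lie in [0, 1)")
  if (object@betweenR < 0 || object@betweenR > object@withinR)
    msg <- c(msg, "betweenR must lie in [0, withinR]")
  if (any(c(object@boostSD, object@deltaSD, object@noiseSD) < 0))
    msg <- c(msg, "boostSD, deltaSD and noiseSD must be nonnegative")
  if (object@femaleProb < 0 || object@femaleProb > 1 ||
      object@ssriProb < 0 || object@ssriProb > 1)
    msg <- c(msg, "femaleProb and ssriProb must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: a simulated longitudinal study
#'
#' Container for the scans, covariate table and ground truth of one
#' simulated cohort. \code{scans} is a list with one element per subject,
#' each a list of session matrices (timepoints x grey voxels) named
#' \code{baseline} and (for longitudinal FND subjects) \code{followup}.
#' \code{truth} records the planted per-subject coupling boosts and the
#' effect region, sufficient to score recovery.
#'
#' @slot space the \code{\linkS4class{PhantomSpace}} the scans live in.
#' @slot config the \code{\linkS4class{SimulationConfig}} used.
#' @slot scans named list of per-subject session matrices.
#' @slot covariates data.frame, one row per subject (cohort table schema).
#' @slot truth list with elements \code{boost}, \code{delta},
#'   \code{effectRegion}, \code{targetNetwork}.
#' @export
setClass("SyntheticCohort",
  representation(
    space = "PhantomSpace",
    config = "SimulationConfig",
    scans = "list",
    covariates = "data.frame",
    truth = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character(0)
  if (length(object@scans) != nrow(object@covariates))
    msg <- c(msg, "one scans entry per covariate row required")
  grp <- object@covariates$group
  nses <- vapply(object@scans, length, 1L)
  if (any(nses[grp == "HC"] != 1L))
    msg <- c(msg, "HC subjects must have exactly one session")
  if (any(nses[grp == "FND"] < 1L | nses[grp == "FND"] > 2L))
    msg <- c(msg, "FND subjects must have one or two sessions")
  if (length(msg)) msg else TRUE
})

#' ConnectivityMatrix: symmetric nonnegative voxel-by-voxel weights
#'
#' Pearson correlation weights between voxel time series with negative
#' values removed (set to zero) and a zero diagonal; \code{voxels} ties the
#' rows to linear indices of the originating grid, and \code{scope} records
#' whether the matrix spans all grey matter or the isocortex only.
#'
#' @slot weights numeric matrix, symmetric, in [0,1], zero diagonal.
#' @slot voxels integer vector of linear voxel indices (row order).
#' @slot scope character, \code{"grey"} or \code{"isocortical"}.
#' @slot dims integer(3) grid dimensions the voxel indices refer to.
#' @export
setClass("ConnectivityMatrix",
  representation(
    weights = "matrix",
    voxels = "integer",
    scope = "character",
    dims = "integer"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character(0)
  w <- object@weights
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (nrow(w) != length(object@voxels))
    msg <- c(msg, "voxels must match matrix order")
  if (any(abs(diag(w)) > 0)) msg <- c(msg, "diagonal must be zero")
  if (any(w < 0) || any(w > 1 + 1e-12))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (max(abs(w - t(w))) > 1e-12) msg <- c(msg, "weights must be symmetric")
  if (!object@scope %in% c("grey", "isocortical"))
    msg <- c(msg, "scope must be 'grey' or 'isocortical'")
  if (length(msg)) msg else TRUE
})

#' MetricMap: one scalar per masked voxel for one metric and timepoint
#'
#' @slot metric character, one of \code{"weighted_degree"},
#'   \code{"integration"}, \code{"segregation"} or \code{"seed_fisher_z"}.
#' @slot values numeric, one value per voxel in \code{voxels}.
#' @slot voxels integer linear indices into the grid.
#' @slot dims integer(3) grid dimensions.
#' @slot subject character subject identifier.
#' @slot timepoint character, \code{"baseline"}, \code{"followup"} or
#'   \code{"change"}.
#' @export
setClass("MetricMap",
  representation(
    metric = "character",
    values = "numeric",
    voxels = "integer",
    dims = "integer",
    subject = "character",
    timepoint = "character"
  )
)

setValidity("MetricMap", function(object) {
  msg <- character(0)
  if (length(object@values) != length(object@voxels))
    msg <- c(msg, "values and voxels must have equal length")
  if (!object@timepoint %in% c("baseline", "followup", "change"))
    msg <- c(msg, "timepoint must be baseline/followup/change")
  if (object@timepoint != "change" && object@metric != "seed_fisher_z" &&
      any(object@values < -1e-9, na.rm = TRUE))
    msg <- c(msg, "baseline/followup metric values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' GLMResult: per-voxel coefficient and z maps for the term of interest
#'
#' @slot beta numeric, coefficient of the term of interest per voxel.
#' @slot tstat numeric, its t statistic per voxel.
#' @slot z numeric, tail-matched z statistic (capped at +/- 8.2).
#' @slot df integer residual degrees of freedom.
#' @slot residuals numeric matrix (subjects x voxels) of model residuals.
#' @slot voxels,dims grid bookkeeping as in \code{\linkS4class{MetricMap}}.
#' @slot outcome character, outcome name.
#' @slot term character, name of the tested term.
#' @slot design character, one-line description of the design.
#' @slot flags integer per voxel: 0 ok, 1 zero-variance (z forced to 0),
#'   2 capped (numerically perfect fit).
#' @export
setClass("GLMResult",
  representation(
    beta = "numeric",
    tstat = "numeric",
    z = "numeric",
    df = "integer",
    residuals = "matrix",
    voxels = "integer",
    dims = "integer",
    outcome = "character",
    term = "character",
    design = "character",
    flags = "integer"
  )
)

setValidity("GLMResult", function(object) {
  msg <- character(0)
  nv <- length(object@voxels)
  if (length(object@beta) != nv || length(object@z) != nv ||
      length(object@tstat) != nv || length(object@flags) != nv)
    msg <- c(msg, "per-voxel slots must match voxels length")
  if (object@df < 1L) msg <- c(msg, "residual df must be positive")
  if (length(msg)) msg else TRUE
})

#' ClusterNull: Monte-Carlo null distribution of maximum cluster extent
#'
#' @slot zThresh numeric cluster-forming voxel threshold (two-sided |z|).
#' @slot fwhm numeric(3) per-axis smoothness (voxels) of simulated fields.
#' @slot nIter integer number of Monte-Carlo iterations.
#' @slot alpha numeric family-wise error target.
#' @slot maxExtents integer sampled maximum cluster extents.
#' @slot extentThreshold integer smallest extent controlling FWE at alpha.
#' @slot degenerate logical, TRUE when no simulated field ever crossed the
#'   voxel threshold (any observed cluster then "survives" vacuously).
#' @slot connectivity integer, 6, 18 or 26.
#' @slot seed integer seed of the simulation.
#' @export
setClass("ClusterNull",
  representation(
    zThresh = "numeric",
    fwhm = "numeric",
    nIter = "integer",
    alpha = "numeric",
    maxExtents = "integer",
    extentThreshold = "integer",
    degenerate = "logical",
    connectivity = "integer",
    seed = "integer"
  )
)

setValidity("ClusterNull", function(object) {
  msg <- character(0)
  if (object@nIter < 100L) msg <- c(msg, "nIter must be >= 100")
  if (object@zThresh <= 0) msg <- c(msg, "zThresh must be positive")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: surviving clusters after extent correction
#'
#' @slot table data.frame with one row per surviving cluster: id, extent,
#'   peak absolute z, 0-based peak coordinate, sign.
#' @slot sigMask logical array marking surviving voxels.
#' @slot clusterLabels integer array, 0 background, cluster id elsewhere.
#' @slot zThresh,extentThreshold thresholds used.
#' @export
setClass("ClusterResult",
  representation(
    table = "data.frame",
    sigMask = "array",
    clusterLabels = "array",
    zThresh = "numeric",
    extentThreshold = "integer"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "PhantomSpace", function(object) {
  cat("PhantomSpace", paste(object@dims, collapse = " x "),
      "|", sum(object@greyMask), "grey voxels,",
      sum(object@isoMask), "isocortical,",
      object@nNetworks, "networks\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nFND, "FND (", object@nFollowup,
      "longitudinal ),", object@nHC, "HC,", object@nTimepoints,
      "timepoints/session\n")
  cat("  correlation targets: within", object@withinR,
      "between", object@betweenR, "\n")
  cat("  effect region:", length(object@effectRegion), "voxels ->",
      "network", object@targetNetwork,
      "| slopes", object@baselineEffectSize, "/",
      object@longitudinalEffectSize, "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", sum(object@covariates$group == "FND"), "FND +",
      sum(object@covariates$group == "HC"), "HC subjects,",
      sum(vapply(object@scans, length, 1L)), "sessions\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix (", object@scope, "): ",
      nrow(object@weights), " x ", ncol(object@weights),
      ", mean weight ", signif(mean(object@weights), 3), "\n", sep = "")
})

setMethod("show", "MetricMap", function(object) {
  cat("MetricMap", object@metric, "[", object@timepoint, "]",
      "subject", object@subject, ":", length(object@values), "voxels,",
      "range", paste(signif(range(object@values), 4), collapse = " .. "),
      "\n")
})

setMethod("show", "GLMResult", function(object) {
  cat("GLMResult for", object@outcome, "~", object@term, "+ covariates |",
      length(object@voxels), "voxels, df =", object@df, "\n")
  cat("  |z| range:",
      paste(signif(range(abs(object@z)), 4), collapse = " .. "), "\n")
})

setMethod("show", "ClusterNull", function(object) {
  cat("ClusterNull: |z| >", object@zThresh, ",", object@nIter,
      "iterations, fwhm", paste(signif(object@fwhm, 3), collapse = "/"),
      "-> extent threshold", object@extentThreshold, "voxels",
      if (object@degenerate) "(degenerate)" else "", "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", nrow(object@table), "surviving cluster(s),",
      sum(object@sigMask), "significant voxels\n")
  if (nrow(object@table)) print(object@table)
})
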