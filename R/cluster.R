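#' Monte-Carlo null distribution of maximum cluster extent
#'
#' Simulates the family-wise null of cluster sizes: per iteration a white
#' Gaussian field is generated on the bounding grid, smoothed to the
#' requested per-axis FWHM (no smoothing at or below 1 voxel, the
#' intrinsic lattice smoothness), re-standardized within the mask so the
#' voxel threshold keeps its nominal two-sided rate, thresholded at
#' \code{|z| > zThresh}, and the maximum connected-component extent over
#' positive and negative excursions is recorded. The extent threshold is
#' the smallest cluster size whose empirical exceedance probability among
#' the sampled maxima is at most \code{alpha}; observed clusters at least
#' that large are declared significant. When no simulated field ever
#' crosses the voxel threshold the null is degenerate (flagged): any
#' nonempty observed cluster then survives vacuously.
#'
#' @param mask logical 3D array defining the analysis mask.
#' @param fwhm per-axis smoothness in voxels (scalar recycled to 3).
#' @param zThresh positive voxel-forming threshold (two-sided).
#' @param nIter number of Monte-Carlo iterations (>= 100).
#' @param alpha family-wise error target.
#' @param connectivity 6, 18 or 26 (volumetric corner adjacency default).
#' @param seed integer RNG seed.
#' @return a \code{\linkS4class{ClusterNull}}.
#' @export
clusterNullDistribution <- function(mask, fwhm = 1, zThresh = 1.96,
                                    nIter = 10000L, alpha = 0.05,
                                    connectivity = 26L, seed = 1L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  if (zThresh <= 0) stop("zThresh must be positive")
  nIter <- as.integer(nIter)
  if (nIter < 100L) stop("nIter must be >= 100")
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  connectivity <- as.integer(connectivity)
  dims <- dim(mask)
  maskIdx <- which(mask)
  if (!length(maskIdx)) stop("empty mask")
  smoothNeeded <- any(fwhm > 1)
  kernFwhm <- ifelse(fwhm > 1, fwhm, 0)

  set.seed(as.integer(seed))
  maxExt <- integer(nIter)
  for (it in seq_len(nIter)) {
    field <- array(rnorm(prod(dims)), dims)
    if (smoothNeeded) field <- .smoothVolume(field, kernFwhm)
    v <- field[maskIdx]
    v <- (v - mean(v)) / sd(v)
    maxExt[it] <- max(
      .maxComponentSize(maskIdx[v > zThresh], dims, connectivity),
      .maxComponentSize(maskIdx[v < -zThresh], dims, connectivity))
  }

  degenerate <- all(maxExt == 0L)
  ## smallest extent with empirical tail probability <= alpha
  k <- 1L
  while (mean(maxExt >= k) > alpha) k <- k + 1L

  new("ClusterNull", zThresh = zThresh, fwhm = fwhm, nIter = nIter,
      alpha = alpha, maxExtents = maxExt, extentThreshold = as.integer(k),
      degenerate = degenerate, connectivity = connectivity,
      seed = as.integer(seed))
}

.maxComponentSize <- function(idx, dims, connectivity) {
  if (!length(idx)) return(0L)
  memb <- .components3d(idx, dims, connectivity)
  max(tabulate(memb))
}

#' Apply cluster-extent correction to a z map
#'
#' Labels connected components of \code{|z| > zThresh} (positive and
#' negative excursions separately), removes those smaller than the null's
#' extent threshold, and reports the survivors.
#'
#' @param z a \code{\linkS4class{GLMResult}} or a numeric vector of
#'   per-voxel z values.
#' @param null a \code{\linkS4class{ClusterNull}} computed at the same
#'   voxel threshold.
#' @param voxels,dims voxel bookkeeping when \code{z} is a bare vector.
#' @return a \code{\linkS4class{ClusterResult}}; its table has one row per
#'   surviving cluster with extent, peak |z|, 0-based peak coordinate and
#'   sign.
#' @export
applyClusterCorrection <- function(z, null, voxels = NULL, dims = NULL) {
  stopifnot(is(null, "ClusterNull"))
  if (is(z, "GLMResult")) {
    voxels <- z@voxels; dims <- z@dims; z <- z@z
  }
  stopifnot(!is.null(voxels), !is.null(dims))
  dims <- as.integer(dims)
  if (length(z) != length(voxels)) stop("z and voxels must align")

  labs <- array(0L, dims)
  rows <- list()
  cid <- 0L
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) which(z > null@zThresh) else which(z < -null@zThresh)
    if (!length(sel)) next
    idx <- as.integer(voxels[sel])
    memb <- .components3d(idx, dims, null@connectivity)
    for (m in seq_len(max(memb))) {
      part <- memb == m
      ext <- sum(part)
      if (ext < null@extentThreshold) next
      cid <- cid + 1L
      labs[idx[part]] <- cid
      zz <- z[sel][part]
      pk <- which.max(abs(zz))
      rows[[cid]] <- data.frame(
        id = cid, extent = ext, peak_z = zz[pk],
        peak_x = arrayInd(idx[part][pk], dims)[1] - 1L,
        peak_y = arrayInd(idx[part][pk], dims)[2] - 1L,
        peak_z_coord = arrayInd(idx[part][pk], dims)[3] - 1L,
        sign = sgn)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), extent = integer(0), peak_z = numeric(0),
               peak_x = integer(0), peak_y = integer(0),
               peak_z_coord = integer(0), sign = numeric(0))
  new("ClusterResult", table = tab, sigMask = labs > 0L,
      clusterLabels = labs, zThresh = null@zThresh,
      extentThreshold = null@extentThreshold)
}

#' Per-cluster mean metric values
#'
#' For each surviving cluster, the mean metric value per subject across
#' the cluster's voxels -- the quantity plotted against symptom change in
#' cluster scatterplots and fed to healthy-control comparisons.
#'
#' @param clusters a \code{\linkS4class{ClusterResult}}.
#' @param metricMaps list of per-subject \code{\linkS4class{MetricMap}}s.
#' @return numeric matrix, subjects x clusters.
#' @export
clusterMeanValues <- function(clusters, metricMaps) {
  stopifnot(is(clusters, "ClusterResult"))
  M <- .stackMaps(metricMaps)
  vox <- if (is.matrix(metricMaps)) seq_len(ncol(M)) else
    metricMaps[[1]]@voxels
  ids <- sort(unique(clusters@clusterLabels[clusters@clusterLabels > 0L]))
  out <- matrix(NA_real_, nrow(M), length(ids),
                dimnames = list(rownames(M), paste0("cluster_", ids)))
  for (j in seq_along(ids)) {
    cvox <- which(clusters@clusterLabels == ids[j])
    cols <- match(cvox, vox)
    cols <- cols[!is.na(cols)]
    out[, j] <- rowMeans(M[, cols, drop = FALSE])
  }
  out
}

#' Post-hoc covariate sensitivity re-fits
#'
#' Re-fits the voxel-wise GLM with each extra covariate set appended to
#' the base nuisance design, re-estimates residual smoothness, re-runs
#' the Monte-Carlo cluster correction, and reports for each primary
#' cluster whether at least one surviving voxel overlaps it ("held").
#' The one-voxel overlap rule is the weakest reading of robustness;
#' stricter overlap fractions can be requested.
#'
#' @param metricMaps,outcome,covariates as in
#'   \code{\link{fitBrainBehaviorGLM}}.
#' @param extraSets named list of data.frames (one per sensitivity
#'   adjustment), each with one row per subject; an empty data.frame
#'   reproduces the primary model.
#' @param clusters primary-model \code{\linkS4class{ClusterResult}}.
#' @param mask logical array for the null simulation.
#' @param nIter,alpha,connectivity,seed null-simulation settings.
#' @param minOverlap minimum fraction of a primary cluster's voxels that
#'   must survive for it to count as held (default any single voxel).
#' @return data.frame with one row per (cluster, extra set): extent of
#'   overlap and a logical \code{held}.
#' @export
posthocCovariateSensitivity <- function(metricMaps, outcome, covariates,
                                        extraSets, clusters, mask,
                                        nIter = 1000L, alpha = 0.05,
                                        connectivity = 26L, seed = 1L,
                                        minOverlap = 0) {
  stopifnot(is(clusters, "ClusterResult"), is.list(extraSets))
  primIds <- clusters@table$id
  out <- list()
  for (setName in names(extraSets)) {
    extra <- extraSets[[setName]]
    cov2 <- if (is.null(extra) || ncol(as.data.frame(extra)) == 0L)
      covariates else cbind(covariates, extra)
    fit <- fitBrainBehaviorGLM(metricMaps, outcome, cov2)
    fw <- estimateMapSmoothness(fit)
    null <- clusterNullDistribution(mask, fwhm = fw,
                                    zThresh = clusters@zThresh,
                                    nIter = nIter, alpha = alpha,
                                    connectivity = connectivity,
                                    seed = seed)
    corr <- applyClusterCorrection(fit, null)
    for (cidx in seq_along(primIds)) {
      cvox <- which(clusters@clusterLabels == primIds[cidx])
      ov <- sum(corr@sigMask[cvox])
      out[[length(out) + 1L]] <- data.frame(
        cluster = primIds[cidx], set = setName, overlap_voxels = ov,
        cluster_extent = length(cvox),
        held = ov > max(0, minOverlap * length(cvox)) |
          (minOverlap == 0 & ov >= 1L))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
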