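## Post-hoc seed-based characterization of significant integration voxels:
## which networks do they sit in, and which networks do they connect to?

#' Assign significant voxels to networks
#'
#' Histogram of network labels over the voxels of a significance mask.
#' Significant voxels outside the labeled isocortex are excluded with a
#' warning.
#'
#' @param sigMask logical 3D array (or integer vector of linear voxel
#'   indices) of significant voxels.
#' @param space a \code{\linkS4class{PhantomSpace}}.
#' @return named integer vector of length K (networks \code{1..K}); counts
#'   sum to the number of labeled significant voxels.
#' @export
assignClusterVoxelsToNetworks <- function(sigMask, space) {
  stopifnot(is(space, "PhantomSpace"))
  idx <- if (is.array(sigMask)) which(sigMask) else as.integer(sigMask)
  lab <- space@labels[idx]
  if (any(lab == 0L)) {
    warning(sum(lab == 0L),
            " significant voxel(s) outside the isocortical mask excluded")
    lab <- lab[lab > 0L]
  }
  counts <- tabulate(lab, space@nNetworks)
  names(counts) <- as.character(seq_len(space@nNetworks))
  counts
}

#' Select the networks with the most significant voxels
#'
#' Orders networks by descending voxel count, breaking ties by ascending
#' network index; networks with zero count are never selected. Warns when
#' fewer than \code{k} networks have any significant voxels.
#'
#' @param counts named integer vector of per-network voxel counts.
#' @param k number of networks to select (default 3).
#' @return integer vector of network ids, length at most \code{k}.
#' @export
selectTopNetworks <- function(counts, k = 3L) {
  if (k < 1L) stop("k must be >= 1")
  ids <- as.integer(names(counts))
  if (anyNA(ids)) ids <- seq_along(counts)
  nz <- counts > 0L
  if (sum(nz) < k)
    warning("only ", sum(nz), " network(s) contain significant voxels")
  ord <- order(-counts[nz], ids[nz])
  head(ids[nz][ord], k)
}

#' Seed-to-voxel Fisher-z connectivity map
#'
#' Averages the time series across the seed's member voxels, correlates
#' the average with every isocortical voxel's series, and applies the
#' variance-stabilizing Fisher transform \eqn{z = \mathrm{atanh}(r)} with
#' \eqn{r} clipped to \eqn{\pm(1 - 10^{-7})} first so perfectly
#' correlated voxels (the seed members themselves) stay finite. A
#' zero-variance seed average yields a map of NA values with a warning.
#'
#' @param timeseries numeric matrix, timepoints x grey voxels (column
#'   order = \code{greyVoxels(space)}).
#' @param seedVoxels integer linear voxel indices of the seed members.
#' @param space a \code{\linkS4class{PhantomSpace}}.
#' @param subject,timepoint bookkeeping carried into the map.
#' @return a \code{\linkS4class{MetricMap}} with metric
#'   \code{"seed_fisher_z"} over the isocortical voxels.
#' @export
seedToVoxelZMap <- function(timeseries, seedVoxels, space, subject = "",
                            timepoint = "baseline") {
  stopifnot(is(space, "PhantomSpace"))
  gv <- which(space@greyMask)
  cols <- match(as.integer(seedVoxels), gv)
  if (anyNA(cols)) stop("seed voxels must be present in the time series")
  if (!length(cols)) stop("seed must be nonempty")
  seedAvg <- rowMeans(timeseries[, cols, drop = FALSE])
  isoIdx <- which(space@isoMask)
  isoCols <- match(isoIdx, gv)
  if (sd(seedAvg) == 0) {
    warning("zero-variance seed average; map flagged undefined")
    vals <- rep(NA_real_, length(isoIdx))
  } else {
    r <- drop(cor(seedAvg, timeseries[, isoCols, drop = FALSE]))
    r[!is.finite(r)] <- 0
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    vals <- atanh(r)
  }
  new("MetricMap", metric = "seed_fisher_z", values = vals,
      voxels = as.integer(isoIdx), dims = space@dims, subject = subject,
      timepoint = timepoint)
}

#' Group-level seed connectivity GLM versus zero
#'
#' Tests, per isocortical voxel, whether subject-level Fisher-z seed
#' connectivity differs from zero while adjusting for covariates
#' (typically age, sex, SSRI/SNRI use and mean framewise displacement).
#' Covariates are mean-centered so the tested intercept is the adjusted
#' group mean; the intercept t is converted to z and the same Monte-Carlo
#' cluster-extent correction as the primary analyses is applied at the
#' smoothness of the model residuals.
#'
#' @param zMaps list of per-subject \code{\linkS4class{MetricMap}}s (or a
#'   subjects-by-voxels matrix of Fisher-z values).
#' @param covariates data.frame of nuisance covariates.
#' @param mask logical array for the null simulation (the isocortical
#'   mask).
#' @param zThresh,nIter,alpha,connectivity,seed inference settings.
#' @return list with elements \code{glm} (\code{\linkS4class{GLMResult}}
#'   for the intercept), \code{null} (\code{\linkS4class{ClusterNull}})
#'   and \code{clusters} (\code{\linkS4class{ClusterResult}}).
#' @export
groupSeedGLM <- function(zMaps, covariates, mask, zThresh = 1.96,
                         nIter = 10000L, alpha = 0.05,
                         connectivity = 26L, seed = 1L) {
  Y <- .stackMaps(zMaps)  # n x V
  n <- nrow(Y)
  Z <- .buildNuisance(covariates)
  ## all covariates centered; column 1 is the intercept of interest
  p <- ncol(Z)
  df <- n - p
  if (df < 1L) stop("non-positive residual df")
  qrZ <- qr(Z)
  beta <- qr.coef(qrZ, Y)
  fitted <- Z %*% beta
  resid <- Y - fitted
  sigma2 <- colSums(resid^2) / df
  xtxInv11 <- chol2inv(chol(crossprod(Z)))[1L, 1L]
  se <- sqrt(sigma2 * xtxInv11)
  tstat <- beta[1L, ] / se
  flags <- integer(ncol(Y))
  zeroVar <- !is.finite(tstat) & beta[1L, ] == 0
  z <- tToZ(tstat, df)
  capped <- !is.finite(z) | abs(z) > .Z_CAP
  z[capped] <- sign(tstat[capped]) * .Z_CAP
  flags[capped] <- 2L
  z[zeroVar] <- 0
  flags[zeroVar] <- 1L

  if (is.matrix(zMaps)) {
    vox <- seq_len(ncol(Y)); dims <- c(ncol(Y), 1L, 1L)
  } else {
    vox <- zMaps[[1]]@voxels; dims <- zMaps[[1]]@dims
  }
  glm <- new("GLMResult", beta = beta[1L, ], tstat = tstat, z = z,
             df = as.integer(df), residuals = resid,
             voxels = as.integer(vox), dims = as.integer(dims),
             outcome = "seed_fisher_z", term = "(intercept)",
             design = paste("seed_fisher_z ~ 1 +",
                            paste(colnames(Z)[-1L], collapse = " + ")),
             flags = flags)
  fw <- tryCatch(estimateMapSmoothness(glm), error = function(e) c(1, 1, 1))
  null <- clusterNullDistribution(mask, fwhm = fw, zThresh = zThresh,
                                  nIter = nIter, alpha = alpha,
                                  connectivity = connectivity, seed = seed)
  clusters <- applyClusterCorrection(glm, null)
  list(glm = glm, null = null, clusters = clusters)
}

#' Count significant between-network connections of a seed
#'
#' Counts significant voxels per target network, excluding the seed's own
#' network (within-network links are not integration).
#'
#' @param sigMask logical array or integer vector of significant voxel
#'   indices (from the group seed map).
#' @param space a \code{\linkS4class{PhantomSpace}}.
#' @param seedNetwork integer id of the seed's network.
#' @param timepoint label carried into the result.
#' @return data.frame with columns \code{network} and \code{count} (one
#'   row per non-seed network) plus attributes \code{seedNetwork} and
#'   \code{timepoint}.
#' @export
countBetweenNetworkConnections <- function(sigMask, space, seedNetwork,
                                           timepoint = "baseline") {
  counts <- suppressWarnings(
    assignClusterVoxelsToNetworks(sigMask, space))
  seedNetwork <- as.integer(seedNetwork)
  keep <- setdiff(seq_len(space@nNetworks), seedNetwork)
  out <- data.frame(network = keep, count = as.integer(counts[keep]))
  attr(out, "seedNetwork") <- seedNetwork
  attr(out, "timepoint") <- timepoint
  out
}

#' Compare baseline and follow-up between-network connection counts
#'
#' Converts per-network significant-voxel counts at the two timepoints
#' into percentages of each target network's isocortical size, and flags
#' networks whose connectivity decreased at follow-up.
#'
#' @param base,follow data.frames from
#'   \code{\link{countBetweenNetworkConnections}} with the same seed
#'   network.
#' @param space a \code{\linkS4class{PhantomSpace}} (supplies network
#'   sizes as percent denominators).
#' @return data.frame with per-network baseline/follow-up percentages,
#'   their delta (percentage points) and a \code{decreased} flag.
#' @export
compareTimepointConnectionCounts <- function(base, follow, space) {
  sb <- attr(base, "seedNetwork"); sf <- attr(follow, "seedNetwork")
  if (!identical(sb, sf))
    stop("mismatched seed networks: ", sb, " vs ", sf)
  stopifnot(identical(base$network, follow$network))
  sizes <- tabulate(space@labels[space@isoMask], space@nNetworks)
  denom <- sizes[base$network]
  bp <- 100 * base$count / denom
  fp <- 100 * follow$count / denom
  data.frame(network = base$network,
             network_size = denom,
             baseline_count = base$count, followup_count = follow$count,
             baseline_pct = bp, followup_pct = fp,
             delta_pct = fp - bp,
             decreased = fp < bp)
}
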