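#' Voxel-wise functional connectivity matrix
#'
#' Computes pairwise Pearson correlations between voxel time series, zeroes
#' the diagonal and removes negative correlations (set to 0, not
#' absolute-valued), yielding the symmetric nonnegative weight matrix all
#' graph metrics are built from. A zero-variance voxel has undefined
#' correlations; its row and column are set to 0 with a warning so the map
#' geometry stays stable.
#'
#' @param timeseries numeric matrix, timepoints x voxels (>= 3 timepoints).
#' @param voxels integer linear indices tying columns to grid coordinates;
#'   defaults to \code{1..ncol}.
#' @param scope \code{"grey"} (whole grey matter) or \code{"isocortical"}.
#' @param dims integer(3) grid dimensions; defaults to a flat
#'   \code{c(ncol, 1, 1)} grid for standalone matrices.
#' @return a \code{\linkS4class{ConnectivityMatrix}}.
#' @examples
#' ts <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
#' connWeights(computeFCMatrix(ts))  # r = -1 removed -> all zero
#' @export
computeFCMatrix <- function(timeseries,
                            voxels = seq_len(ncol(timeseries)),
                            scope = c("grey", "isocortical"),
                            dims = NULL) {
  scope <- match.arg(scope)
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3L)
    stop("at least 3 timepoints are required")
  if (!length(voxels)) stop("voxel index must be nonempty")
  voxels <- as.integer(voxels)
  if (is.null(dims)) dims <- c(length(voxels), 1L, 1L)
  dims <- as.integer(dims)

  sds <- apply(timeseries, 2L, sd)
  flat <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(timeseries))
  if (any(flat)) {
    warning(sum(flat), " zero-variance voxel(s): correlations undefined, ",
            "row/column set to 0")
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  r[is.na(r)] <- 0
  r[r < 0] <- 0
  diag(r) <- 0
  r <- (r + t(r)) / 2  # exact symmetry against float asymmetries
  dimnames(r) <- NULL
  new("ConnectivityMatrix", weights = r, voxels = voxels, scope = scope,
      dims = dims)
}

#' Extract the isocortical submatrix of a grey-matter connectivity matrix
#'
#' For Pearson weights the isocortical-only matrix equals the submatrix of
#' the whole-grey matrix restricted to isocortical voxels, so a submatrix
#' view is used rather than recomputing correlations.
#'
#' @param fc a \code{\linkS4class{ConnectivityMatrix}} with scope
#'   \code{"grey"}.
#' @param space the \code{\linkS4class{PhantomSpace}} (or any object with
#'   an isocortical mask) defining which voxels are isocortical.
#' @return a \code{\linkS4class{ConnectivityMatrix}} with scope
#'   \code{"isocortical"}.
#' @export
isocorticalSubmatrix <- function(fc, space) {
  stopifnot(is(fc, "ConnectivityMatrix"), is(space, "PhantomSpace"))
  keep <- which(space@isoMask[fc@voxels])
  new("ConnectivityMatrix", weights = fc@weights[keep, keep, drop = FALSE],
      voxels = fc@voxels[keep], scope = "isocortical", dims = fc@dims)
}

#' Weighted-degree map
#'
#' Per-voxel sum of positive connection weights over the whole grey-matter
#' matrix (the diagonal is excluded: self-correlation is not a
#' connection). High values mark voxels strongly connected to the rest of
#' the brain.
#'
#' @param fc a \code{\linkS4class{ConnectivityMatrix}} with scope
#'   \code{"grey"}; any other scope is a usage error.
#' @param subject,timepoint bookkeeping carried into the map.
#' @return a \code{\linkS4class{MetricMap}}.
#' @export
weightedDegreeMap <- function(fc, subject = "", timepoint = "baseline") {
  stopifnot(is(fc, "ConnectivityMatrix"))
  if (fc@scope != "grey")
    stop("weighted-degree is defined on the whole grey-matter matrix")
  new("MetricMap", metric = "weighted_degree",
      values = rowSums(fc@weights), voxels = fc@voxels, dims = fc@dims,
      subject = subject, timepoint = timepoint)
}

.labelsFor <- function(fc, labels) {
  if (is(labels, "PhantomSpace")) labels <- networkLabels(labels)[fc@voxels]
  labels <- as.integer(labels)
  if (length(labels) != length(fc@voxels))
    stop("labels must align with the matrix voxels")
  if (any(labels < 1L))
    stop("every matrix voxel must carry a network label (1..K)")
  labels
}

#' Integration map (between-network connectivity)
#'
#' Per-voxel sum of positive weights to voxels carrying a \emph{different}
#' network label, computed on the isocortical-only matrix.
#'
#' @param fc a \code{\linkS4class{ConnectivityMatrix}} with scope
#'   \code{"isocortical"}.
#' @param labels integer network label per matrix voxel, or a
#'   \code{\linkS4class{PhantomSpace}} to take labels from.
#' @param subject,timepoint bookkeeping carried into the map.
#' @return a \code{\linkS4class{MetricMap}}.
#' @export
integrationMap <- function(fc, labels, subject = "",
                           timepoint = "baseline") {
  stopifnot(is(fc, "ConnectivityMatrix"))
  if (fc@scope != "isocortical")
    stop("integration is defined on the isocortical-only matrix")
  lab <- .labelsFor(fc, labels)
  tot <- rowSums(fc@weights)
  within <- .withinNetworkSums(fc@weights, lab)
  new("MetricMap", metric = "integration", values = tot - within,
      voxels = fc@voxels, dims = fc@dims, subject = subject,
      timepoint = timepoint)
}

#' Segregation map (within-network connectivity)
#'
#' Per-voxel sum of positive weights to voxels carrying the \emph{same}
#' network label (diagonal excluded), on the isocortical-only matrix.
#' Together with \code{\link{integrationMap}} it partitions the row sum:
#' integration + segregation equals the total isocortical connectivity of
#' every voxel.
#'
#' @inheritParams integrationMap
#' @return a \code{\linkS4class{MetricMap}}.
#' @export
segregationMap <- function(fc, labels, subject = "",
                           timepoint = "baseline") {
  stopifnot(is(fc, "ConnectivityMatrix"))
  if (fc@scope != "isocortical")
    stop("segregation is defined on the isocortical-only matrix")
  lab <- .labelsFor(fc, labels)
  new("MetricMap", metric = "segregation",
      values = .withinNetworkSums(fc@weights, lab),
      voxels = fc@voxels, dims = fc@dims, subject = subject,
      timepoint = timepoint)
}

## rowSums restricted to same-label columns, one group at a time
.withinNetworkSums <- function(w, lab) {
  out <- numeric(nrow(w))
  for (k in unique(lab)) {
    cols <- lab == k
    out[cols] <- rowSums(w[cols, cols, drop = FALSE])
  }
  out
}

#' Longitudinal change map
#'
#' Voxel-wise follow-up minus baseline for one metric and subject. Metric
#' names and voxel sets must match; the result carries timepoint
#' \code{"change"} and may be negative.
#'
#' @param followup,baseline \code{\linkS4class{MetricMap}}s of the same
#'   metric, subject and voxel set.
#' @return a \code{\linkS4class{MetricMap}} with timepoint \code{"change"}.
#' @export
metricChangeMap <- function(followup, baseline) {
  stopifnot(is(followup, "MetricMap"), is(baseline, "MetricMap"))
  if (followup@metric != baseline@metric)
    stop("metric mismatch: ", followup@metric, " vs ", baseline@metric)
  if (!identical(followup@voxels, baseline@voxels) ||
      !identical(followup@dims, baseline@dims))
    stop("mask mismatch between follow-up and baseline maps")
  if (nzchar(followup@subject) && nzchar(baseline@subject) &&
      followup@subject != baseline@subject)
    stop("subject mismatch: ", followup@subject, " vs ", baseline@subject)
  new("MetricMap", metric = followup@metric,
      values = followup@values - baseline@values,
      voxels = followup@voxels, dims = followup@dims,
      subject = followup@subject, timepoint = "change")
}

#' Flag outlier subjects by mean weighted-degree
#'
#' Screens the cohort for subjects whose grey-matter-mean weighted-degree
#' is extreme relative to the rest of the cohort. Each subject is compared
#' against the leave-one-out mean and SD of the remaining subjects (a
#' jackknifed z score), so a single gross outlier cannot mask itself by
#' inflating the pooled SD. Subjects deviating by more than \code{kSD}
#' leave-one-out standard deviations are flagged; with zero remaining
#' spread a subject is flagged only if it actually deviates.
#'
#' @param meanWD named numeric vector of per-subject grey-matter-mean
#'   weighted-degree (>= 3 subjects).
#' @param kSD positive deviation threshold in SD units (default 3).
#' @return character vector of flagged subject names (indices if unnamed).
#' @export
flagOutlierSubjects <- function(meanWD, kSD = 3) {
  if (length(meanWD) < 3L) stop("at least 3 subjects are required")
  if (kSD <= 0) stop("kSD must be positive")
  nm <- names(meanWD)
  if (is.null(nm)) nm <- as.character(seq_along(meanWD))
  flagged <- vapply(seq_along(meanWD), function(i) {
    rest <- meanWD[-i]
    dev <- abs(meanWD[i] - mean(rest))
    s <- sd(rest)
    if (s == 0) dev > 0 else dev > kSD * s
  }, logical(1))
  nm[flagged]
}
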