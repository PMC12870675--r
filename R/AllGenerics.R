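## Accessor generics. Slot access outside the package goes through these.

#' Accessors for voxconn S4 objects
#'
#' Small accessor family for the package's data containers: grid
#' dimensions, masks, voxel index lists, network labels and metric values.
#'
#' @param x a voxconn S4 object.
#' @return The requested component; see the individual class pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spaceDims", function(x) standardGeneric("spaceDims"))

#' @rdname accessors
#' @export
setGeneric("greyMask", function(x) standardGeneric("greyMask"))

#' @rdname accessors
#' @export
setGeneric("isoMask", function(x) standardGeneric("isoMask"))

#' @rdname accessors
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' @rdname accessors
#' @export
setGeneric("nNetworks", function(x) standardGeneric("nNetworks"))

#' @rdname accessors
#' @export
setGeneric("greyVoxels", function(x) standardGeneric("greyVoxels"))

#' @rdname accessors
#' @export
setGeneric("isoVoxels", function(x) standardGeneric("isoVoxels"))

#' @rdname accessors
#' @export
setGeneric("connWeights", function(x) standardGeneric("connWeights"))

#' @rdname accessors
#' @export
setGeneric("connScope", function(x) standardGeneric("connScope"))

#' @rdname accessors
#' @export
setGeneric("mapVoxels", function(x) standardGeneric("mapVoxels"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname accessors
#' @export
setGeneric("mapTimepoint", function(x) standardGeneric("mapTimepoint"))

#' @rdname accessors
#' @export
setGeneric("zMap", function(x) standardGeneric("zMap"))

#' @rdname accessors
#' @export
setGeneric("glmResiduals", function(x) standardGeneric("glmResiduals"))

#' @rdname accessors
#' @export
setGeneric("residualDF", function(x) standardGeneric("residualDF"))

#' @rdname accessors
#' @export
setGeneric("extentThreshold", function(x) standardGeneric("extentThreshold"))

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname accessors
#' @export
setGeneric("cohortCovariates", function(x) standardGeneric("cohortCovariates"))

#' @rdname accessors
#' @export
setGeneric("cohortScans", function(x) standardGeneric("cohortScans"))

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' Materialize a per-voxel vector as a 3D volume
#'
#' Fills a numeric array of the object's grid dimensions with the
#' per-voxel values, \code{NA} outside the object's voxel set.
#'
#' @param x a \code{\linkS4class{MetricMap}} or \code{\linkS4class{GLMResult}}
#'   (for a \code{GLMResult} the z map is materialized).
#' @return numeric 3D array.
#' @export
setGeneric("asVolume", function(x) standardGeneric("asVolume"))

## ---- methods ------------------------------------------------------------

#' @rdname accessors
setMethod("spaceDims", "PhantomSpace", function(x) x@dims)
#' @rdname accessors
setMethod("greyMask", "PhantomSpace", function(x) x@greyMask)
#' @rdname accessors
setMethod("isoMask", "PhantomSpace", function(x) x@isoMask)
#' @rdname accessors
setMethod("networkLabels", "PhantomSpace", function(x) x@labels)
#' @rdname accessors
setMethod("nNetworks", "PhantomSpace", function(x) x@nNetworks)
#' @rdname accessors
setMethod("greyVoxels", "PhantomSpace", function(x) which(x@greyMask))
#' @rdname accessors
setMethod("isoVoxels", "PhantomSpace", function(x) which(x@isoMask))

#' @rdname accessors
setMethod("connWeights", "ConnectivityMatrix", function(x) x@weights)
#' @rdname accessors
setMethod("connScope", "ConnectivityMatrix", function(x) x@scope)
#' @rdname accessors
setMethod("mapVoxels", "ConnectivityMatrix", function(x) x@voxels)

#' @rdname accessors
setMethod("mapVoxels", "MetricMap", function(x) x@voxels)
#' @rdname accessors
setMethod("mapValues", "MetricMap", function(x) x@values)
#' @rdname accessors
setMethod("metricName", "MetricMap", function(x) x@metric)
#' @rdname accessors
setMethod("mapTimepoint", "MetricMap", function(x) x@timepoint)

#' @rdname accessors
setMethod("mapVoxels", "GLMResult", function(x) x@voxels)
#' @rdname accessors
setMethod("zMap", "GLMResult", function(x) x@z)
#' @rdname accessors
setMethod("glmResiduals", "GLMResult", function(x) x@residuals)
#' @rdname accessors
setMethod("residualDF", "GLMResult", function(x) x@df)

#' @rdname accessors
setMethod("extentThreshold", "ClusterNull", function(x) x@extentThreshold)
#' @rdname accessors
setMethod("clusterTable", "ClusterResult", function(x) x@table)
#' @rdname accessors
setMethod("significanceMask", "ClusterResult", function(x) x@sigMask)

#' @rdname accessors
setMethod("cohortCovariates", "SyntheticCohort", function(x) x@covariates)
#' @rdname accessors
setMethod("cohortScans", "SyntheticCohort", function(x) x@scans)
#' @rdname accessors
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

setMethod("asVolume", "MetricMap", function(x) {
  vol <- array(NA_real_, x@dims)
  vol[x@voxels] <- x@values
  vol
})

setMethod("asVolume", "GLMResult", function(x) {
  vol <- array(NA_real_, x@dims)
  vol[x@voxels] <- x@z
  vol
})
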