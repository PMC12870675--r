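#' Construct a phantom brain space
#'
#' Builds a small 3D grid carrying the three structures every analysis in
#' the package needs: a grey-matter mask (an ellipsoid inscribed in the
#' grid), an isocortical mask (grey matter minus a central "deep
#' structures" core), and a contiguous K-network label volume emulating a
#' seven-network cortical parcellation. Networks are grown by multi-source
#' breadth-first search from K seed voxels placed by farthest-point
#' sampling, so every network is one spatially connected block.
#'
#' @param dims integer(3), voxels per axis; each must be at least 4.
#' @param nNetworks integer in 2..7, number of networks K.
#' @param seed integer RNG seed; the construction is deterministic given
#'   \code{dims}, \code{nNetworks} and \code{seed}.
#' @return a \code{\linkS4class{PhantomSpace}}.
#' @examples
#' sp <- makePhantomSpace(c(12, 12, 10), nNetworks = 7, seed = 1)
#' sp
#' @export
makePhantomSpace <- function(dims, nNetworks = 7L, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 4L))
    stop("dims must be an integer triple with every axis >= 4")
  nNetworks <- as.integer(nNetworks)
  if (nNetworks < 2L || nNetworks > 7L)
    stop("nNetworks must lie in 2..7")

  ctr <- (dims + 1) / 2
  rad <- dims / 2 - 0.25
  co <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- ((co[, 1] - ctr[1]) / rad[1])^2 + ((co[, 2] - ctr[2]) / rad[2])^2 +
        ((co[, 3] - ctr[3]) / rad[3])^2
  grey <- array(d2 <= 1, dims)

  ## deep-structure core excluded from the isocortex
  coreR <- min(dims) / 4.5
  core <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
          (co[, 3] - ctr[3])^2 <= coreR^2
  iso <- grey & !array(core, dims)

  isoIdx <- which(iso)
  if (length(isoIdx) < nNetworks * 8L)
    stop("grid too small to host ", nNetworks,
         " contiguous network blocks (", length(isoIdx),
         " isocortical voxels)")

  set.seed(as.integer(seed))
  isoCo <- arrayInd(isoIdx, dims)
  seeds <- sample.int(length(isoIdx), 1L)
  mind <- colSums((t(isoCo) - isoCo[seeds[1L], ])^2)
  while (length(seeds) < nNetworks) {
    nxt <- which.max(mind)  # ties -> first index, deterministic
    seeds <- c(seeds, nxt)
    mind <- pmin(mind, colSums((t(isoCo) - isoCo[nxt, ])^2))
  }

  ## multi-source BFS over the 6-neighborhood; ties to the lower label
  labels <- array(0L, dims)
  labels[isoIdx[seeds]] <- seq_len(nNetworks)
  off <- .neighborOffsets(6L)
  frontier <- isoIdx[seeds]
  while (length(frontier)) {
    fco <- arrayInd(frontier, dims)
    cand <- integer(0); candLab <- integer(0)
    for (r in seq_len(nrow(off))) {
      nx <- fco[, 1] + off[r, 1]; ny <- fco[, 2] + off[r, 2]
      nz <- fco[, 3] + off[r, 3]
      ok <- nx >= 1L & nx <= dims[1] & ny >= 1L & ny <= dims[2] &
            nz >= 1L & nz <= dims[3]
      lin <- (nz[ok] - 1L) * dims[1] * dims[2] + (ny[ok] - 1L) * dims[1] +
             nx[ok]
      open <- iso[lin] & labels[lin] == 0L
      cand <- c(cand, lin[open])
      candLab <- c(candLab, labels[frontier[ok]][open])
    }
    if (!length(cand)) break
    ord <- order(cand, candLab)
    first <- !duplicated(cand[ord])
    newIdx <- cand[ord][first]
    labels[newIdx] <- candLab[ord][first]
    frontier <- newIdx
  }
  ## voxels unreachable from any seed (isolated islands of the iso mask)
  ## are dropped from the isocortex but kept in grey matter
  orphan <- iso & labels == 0L
  if (any(orphan)) iso[orphan] <- FALSE

  new("PhantomSpace", dims = dims, greyMask = grey, isoMask = iso,
      labels = labels, nNetworks = nNetworks, seed = as.integer(seed))
}

#' Default planted effect region
#'
#' Picks a compact, contiguous ball of isocortical voxels inside one
#' network of a phantom space, to serve as the planted "insula-like"
#' region of a simulation. The ball is grown around the voxel closest to
#' the network's centroid.
#'
#' @param space a \code{\linkS4class{PhantomSpace}}.
#' @param network integer network label to host the region.
#' @param radius numeric ball radius in voxels.
#' @return integer vector of linear voxel indices.
#' @export
defaultEffectRegion <- function(space, network = 3L, radius = 2) {
  stopifnot(is(space, "PhantomSpace"))
  network <- as.integer(network)
  if (network < 1L || network > space@nNetworks)
    stop("network must lie in 1..", space@nNetworks)
  idx <- which(space@labels == network)
  co <- arrayInd(idx, space@dims)
  ctr <- co[which.min(colSums((t(co) - colMeans(co))^2)), ]
  d2 <- colSums((t(co) - ctr)^2)
  reg <- idx[d2 <= radius^2]
  memb <- .components3d(reg, space@dims, 26L)
  ## keep the component containing the centroid voxel
  keep <- memb[match(idx[which.min(d2)], reg)]
  reg[memb == keep]
}
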