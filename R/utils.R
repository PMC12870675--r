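## Internal lattice helpers: neighbor structure, connected components,
## separable Gaussian smoothing. Shared by the cluster machinery and the
## phantom builder.

.neighborOffsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(g != 0) > 0L, , drop = FALSE]
  keep <- switch(as.character(connectivity),
    "6"  = rowSums(abs(g)) == 1L,
    "18" = rowSums(abs(g)) <= 2L,
    "26" = rep(TRUE, nrow(g)),
    stop("connectivity must be 6, 18 or 26")
  )
  g[keep, , drop = FALSE]
}

## Connected components over a set of voxels (linear indices) on a 3D grid.
## Returns an integer membership vector aligned with `idx` (component ids
## numbered from 1). Uses an igraph over the half-space neighbor offsets.
.components3d <- function(idx, dims, connectivity = 26L) {
  nv <- length(idx)
  if (nv == 0L) return(integer(0))
  if (nv == 1L) return(1L)
  lookup <- array(0L, dims)
  lookup[idx] <- seq_len(nv)
  co <- arrayInd(idx, dims)
  off <- .neighborOffsets(connectivity)
  ## half space: keep one of each +/- pair
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
             (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(off))) {
    nx <- co[, 1] + off[r, 1]
    ny <- co[, 2] + off[r, 2]
    nz <- co[, 3] + off[r, 3]
    ok <- nx >= 1L & nx <= dims[1] & ny >= 1L & ny <= dims[2] &
          nz >= 1L & nz <= dims[3]
    if (!any(ok)) next
    lin <- (nz[ok] - 1L) * dims[1] * dims[2] + (ny[ok] - 1L) * dims[1] + nx[ok]
    j <- lookup[lin]
    hit <- j > 0L
    if (any(hit)) {
      from <- c(from, which(ok)[hit])
      to <- c(to, j[hit])
    }
  }
  if (!length(from)) return(seq_len(nv))
  g <- igraph::make_graph(rbind(from, to), n = nv, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

## Separable Gaussian smoothing of a 3D array, with edge renormalization so
## a constant field stays constant. fwhm is per-axis, in voxels; axes with
## fwhm <= 0 are left untouched.
.gaussianKernel1d <- function(fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

.smoothAxis <- function(vol, axis, kern) {
  if (length(kern) == 1L) return(vol)
  d <- dim(vol)
  n <- d[axis]
  r <- (length(kern) - 1L) / 2L
  ## banded smoothing matrix with zero padding
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1L & j <= n
    S[i, j[ok]] <- kern[ok]
  }
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  m <- matrix(v, nrow = n)
  sm <- S %*% m
  out <- array(sm, dim = d[perm])
  aperm(out, order(perm))
}

.smoothVolume <- function(vol, fwhm) {
  fwhm <- rep_len(fwhm, 3L)
  sm <- vol
  norm <- array(1, dim(vol))
  for (a in 1:3) {
    if (fwhm[a] > 0) {
      k <- .gaussianKernel1d(fwhm[a])
      sm <- .smoothAxis(sm, a, k)
      norm <- .smoothAxis(norm, a, k)
    }
  }
  sm / norm
}

## Derive a per-subject RNG seed from a master seed without letting stream
## choices of one subject perturb another; kept well below 2^31.
.subjectSeed <- function(master, index, salt = 0L) {
  as.integer((as.numeric(master) * 1009 + index * 7919 + salt * 104729) %%
               2147483629)
}

.isWholeNumber <- function(x) {
  is.numeric(x) && length(x) >= 1L && all(abs(x - round(x)) < 1e-8)
}
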