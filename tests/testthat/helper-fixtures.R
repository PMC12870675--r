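# Shared fixtures and independent test-side oracles. Everything here is
# deliberately naive (double loops, direct formulas) so it cannot share a
# bug with the vectorized package code.

tinySpace <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makePhantomSpace(c(8, 8, 6), 4, seed = 1)
    cache
  }
})

midSpace <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makePhantomSpace(c(12, 12, 10), 7, seed = 1)
    cache
  }
})

# random symmetric nonnegative weight matrix with zero diagonal
randomWeights <- function(v, seed) {
  set.seed(seed)
  w <- matrix(runif(v * v), v, v)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

fcFromWeights <- function(w, scope = "isocortical") {
  methods::new("ConnectivityMatrix", weights = w,
               voxels = seq_len(nrow(w)), scope = scope,
               dims = c(nrow(w), 1L, 1L))
}

# naive double-loop metric oracles
oracleWeightedDegree <- function(w) {
  v <- nrow(w)
  out <- numeric(v)
  for (i in seq_len(v)) for (j in seq_len(v))
    if (i != j) out[i] <- out[i] + w[i, j]
  out
}

oracleIntegration <- function(w, lab) {
  v <- nrow(w)
  out <- numeric(v)
  for (i in seq_len(v)) for (j in seq_len(v))
    if (i != j && lab[i] != lab[j]) out[i] <- out[i] + w[i, j]
  out
}

oracleSegregation <- function(w, lab) {
  v <- nrow(w)
  out <- numeric(v)
  for (i in seq_len(v)) for (j in seq_len(v))
    if (i != j && lab[i] == lab[j]) out[i] <- out[i] + w[i, j]
  out
}

# explicit normal-equations OLS oracle: returns t statistic of column k
oracleOlsT <- function(X, y, k) {
  xtxi <- solve(t(X) %*% X)
  beta <- xtxi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  drop(beta[k] / sqrt(s2 * xtxi[k, k]))
}

# independent separable Gaussian smoothing (loop-based, zero padded)
oracleSmooth <- function(vol, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(vol)
  for (axis in 1:3) {
    out <- array(0, d)
    norm <- array(0, d)
    for (s in seq_along(k)) {
      sh <- s - r - 1L
      idx <- seq_len(d[axis]) + sh
      ok <- idx >= 1 & idx <= d[axis]
      src <- switch(axis,
        vol[idx[ok], , , drop = FALSE],
        vol[, idx[ok], , drop = FALSE],
        vol[, , idx[ok], drop = FALSE])
      if (axis == 1) { out[ok, , ] <- out[ok, , ] + k[s] * src
        norm[ok, , ] <- norm[ok, , ] + k[s] }
      if (axis == 2) { out[, ok, ] <- out[, ok, ] + k[s] * src
        norm[, ok, ] <- norm[, ok, ] + k[s] }
      if (axis == 3) { out[, , ok] <- out[, , ok] + k[s] * src
        norm[, , ok] <- norm[, , ok] + k[s] }
    }
    vol <- out / norm
  }
  vol
}

# independent BFS connectivity check over linear indices
oracleIsConnected <- function(idx, dims, conn = 6L) {
  if (length(idx) <= 1L) return(TRUE)
  co <- arrayInd(idx, dims)
  seen <- c(1L)
  frontier <- c(1L)
  while (length(frontier)) {
    nxt <- integer(0)
    for (f in frontier) {
      dx <- abs(co[, 1] - co[f, 1]); dy <- abs(co[, 2] - co[f, 2])
      dz <- abs(co[, 3] - co[f, 3])
      nb <- if (conn == 6L) which(dx + dy + dz == 1L)
            else which(pmax(dx, dy, dz) == 1L)
      nb <- setdiff(nb, seen)
      seen <- c(seen, nb)
      nxt <- c(nxt, nb)
    }
    frontier <- nxt
  }
  length(seen) == length(idx)
}

# one-step 26-neighborhood dilation of a voxel index set
dilate26 <- function(idx, dims) {
  co <- arrayInd(idx, dims)
  unique(unlist(lapply(seq_along(idx), function(i) {
    g <- expand.grid(x = co[i, 1] + (-1:1), y = co[i, 2] + (-1:1),
                     z = co[i, 3] + (-1:1))
    ok <- g$x >= 1 & g$x <= dims[1] & g$y >= 1 & g$y <= dims[2] &
          g$z >= 1 & g$z <= dims[3]
    (g$z[ok] - 1) * dims[1] * dims[2] + (g$y[ok] - 1) * dims[1] + g$x[ok]
  })))
}

# per-subject integration maps for the FND rows of a cohort, at one session
cohortIntegrationMaps <- function(cohort, session = "baseline",
                                  subjects = NULL) {
  sp <- cohort@space
  gv <- greyVoxels(sp)
  isoCols <- match(isoVoxels(sp), gv)
  if (is.null(subjects)) {
    tab <- cohortCovariates(cohort)
    subjects <- tab$subject[tab$group == "FND"]
  }
  lapply(subjects, function(id) {
    ts <- cohortScans(cohort)[[id]][[session]]
    fc <- computeFCMatrix(ts[, isoCols, drop = FALSE],
                          voxels = isoVoxels(sp),
                          scope = "isocortical", dims = spaceDims(sp))
    integrationMap(fc, sp, subject = id, timepoint = session)
  })
}

primaryCovariates <- function(tab, outcome = "soms_cd") {
  data.frame(age = tab$age, sex = tab$sex, ssri_snri = tab$ssri_snri,
             mean_fd = tab$mean_fd_baseline,
             interval = tab$interval_months,
             baseline_score = tab[[paste0(outcome, "_baseline")]])
}
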