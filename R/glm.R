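## Mass-univariate brain-behavior GLMs. The metric term's t statistic is
## obtained by the Frisch-Waugh partialling identity: outcome and metric
## are both residualized on the nuisance design, and the simple slope of
## the residualized pair carries the identical t (and hence z) as the full
## multiple regression -- which also makes the statistic symmetric under
## exchanging the roles of outcome and metric.

.Z_CAP <- 8.2

#' Convert a Student-t statistic to a z statistic
#'
#' Tail-probability matching: \code{z} is the standard-normal quantile of
#' the t cumulative probability at \code{t} with \code{df} degrees of
#' freedom, computed on the log scale so extreme statistics do not
#' underflow. Sign-preserving and monotone in \code{t}; non-finite input
#' propagates as NA.
#'
#' @param t numeric vector of t statistics.
#' @param df degrees of freedom (>= 1), scalar or vector.
#' @return numeric vector of z statistics.
#' @examples
#' tToZ(0, 5)            # 0
#' tToZ(1.7, 1e6)        # ~1.7
#' @export
tToZ <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  z <- rep(NA_real_, length(t))
  ok <- is.finite(t)
  if (any(ok)) {
    lt <- pt(-abs(t[ok]), df = if (length(df) == 1L) df else df[ok],
             log.p = TRUE)
    z[ok] <- -sign(t[ok]) * qnorm(lt, log.p = TRUE)
    z[ok][t[ok] == 0] <- 0
  }
  z
}

.stackMaps <- function(metricMaps) {
  if (is.matrix(metricMaps)) return(metricMaps)
  stopifnot(length(metricMaps) >= 1L, is(metricMaps[[1]], "MetricMap"))
  vox <- metricMaps[[1]]@voxels
  for (m in metricMaps)
    if (!identical(m@voxels, vox))
      stop("all metric maps must share the same voxel set")
  t(vapply(metricMaps, function(m) m@values,
           numeric(length(vox))))  # subjects x voxels
}

.buildNuisance <- function(covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) == 0L) stop("covariates must be nonempty")
  if (any(!complete.cases(covariates)))
    stop("missing covariate values in rows ",
         paste(which(!complete.cases(covariates)), collapse = ", "))
  Z <- matrix(1, nrow(covariates), 1L, dimnames = list(NULL, "(intercept)"))
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.logical(v)) v <- as.numeric(v)
    if (!is.numeric(v)) stop("covariate '", nm, "' must be numeric")
    isBinary <- all(v %in% c(0, 1))
    Z <- cbind(Z, if (isBinary) v else v - mean(v))
    colnames(Z)[ncol(Z)] <- nm
  }
  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) {
    bad <- colnames(Z)[qrZ$pivot[(qrZ$rank + 1L):ncol(Z)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Z
}

## Residualize columns of Y on Z via the QR of Z.
.residualize <- function(Z, Y) {
  Y - Z %*% qr.coef(qr(Z), Y)
}

#' Fit per-voxel brain-behavior GLMs
#'
#' At each voxel fits \code{outcome ~ metric + covariates} by least
#' squares and reports the metric term's coefficient, t statistic and
#' tail-matched z statistic, with per-subject residual maps retained for
#' spatial smoothness estimation. Continuous covariates are mean-centered
#' (binary indicators left as coded); the intercept is always included.
#' Voxels whose (residualized) metric has no cross-subject variance get
#' z = 0 with flag 1; numerically perfect fits are capped at |z| = 8.2
#' with flag 2.
#'
#' By the partialling identity the metric-term t is unchanged when the
#' roles of outcome and metric are exchanged (with the same covariates),
#' so the modeled direction -- symptom change as outcome, voxel metric as
#' predictor -- is a labeling convention, not an inferential choice.
#'
#' @param metricMaps list of per-subject \code{\linkS4class{MetricMap}}s
#'   on a common voxel set (or a subjects-by-voxels matrix).
#' @param outcome numeric vector, one value per subject (e.g. a symptom
#'   change score).
#' @param covariates data.frame of nuisance covariates, one row per
#'   subject; typically age, sex, SSRI/SNRI use, mean framewise
#'   displacement, inter-session interval and the baseline symptom score.
#' @param outcomeName,term labels stored in the result.
#' @param minSubjects minimum cohort size (default 10).
#' @return a \code{\linkS4class{GLMResult}}.
#' @export
fitBrainBehaviorGLM <- function(metricMaps, outcome, covariates,
                                outcomeName = "outcome",
                                term = "metric", minSubjects = 10L) {
  M <- .stackMaps(metricMaps)   # n x V
  n <- nrow(M)
  if (length(outcome) != n)
    stop("outcome length must equal the number of subjects")
  if (n < minSubjects)
    stop("at least ", minSubjects, " subjects are required")
  Z <- .buildNuisance(covariates)
  p <- ncol(Z) + 1L
  df <- n - p
  if (df < 1L) stop("non-positive residual df: n = ", n, ", design = ", p)

  ry <- drop(.residualize(Z, matrix(outcome, ncol = 1L)))
  rm_ <- .residualize(Z, M)
  ssm <- colSums(rm_^2)
  ssy <- sum(ry^2)

  flags <- integer(ncol(M))
  zeroVar <- ssm <= 1e-10 * n
  flags[zeroVar] <- 1L

  beta <- numeric(ncol(M))
  tstat <- numeric(ncol(M))
  ok <- !zeroVar
  beta[ok] <- colSums(rm_[, ok, drop = FALSE] * ry) / ssm[ok]
  rss <- pmax(0, ssy - beta^2 * ssm)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / ssm)
  tstat[ok] <- (beta / se)[ok]
  ## perfect fits (rss -> 0): se 0 with nonzero slope -> signed infinity;
  ## a zero slope with zero residual (fully absorbed outcome) -> t = 0
  bad <- ok & !is.finite(tstat)
  tstat[bad & abs(beta) > 0] <- sign(beta[bad & abs(beta) > 0]) * Inf
  tstat[bad & beta == 0] <- 0

  z <- tToZ(tstat, df)
  capped <- ok & (!is.finite(z) | abs(z) > .Z_CAP)
  z[capped] <- sign(tstat[capped]) * .Z_CAP
  flags[capped] <- 2L
  z[zeroVar] <- 0
  tstat[zeroVar] <- 0

  resid <- ry - sweep(rm_, 2L, beta, `*`)

  if (is.matrix(metricMaps)) {
    vox <- seq_len(ncol(M))
    dims <- c(ncol(M), 1L, 1L)
  } else {
    vox <- metricMaps[[1]]@voxels
    dims <- metricMaps[[1]]@dims
  }
  new("GLMResult", beta = beta, tstat = tstat, z = z, df = as.integer(df),
      residuals = resid, voxels = as.integer(vox), dims = as.integer(dims),
      outcome = outcomeName, term = term,
      design = paste0(outcomeName, " ~ ", term, " + ",
                      paste(colnames(Z)[-1L], collapse = " + ")),
      flags = flags)
}

#' Estimate spatial smoothness from residual maps
#'
#' Classical gradient-variance estimator: along each axis, for the
#' in-mask neighbor pairs, \deqn{FWHM_a = \sqrt{-2 \ln 2 / \ln(1 -
#' \mathrm{var}(\partial_a e) / (2\, \mathrm{var}(e)))}} averaged over
#' residual maps and floored at 1 voxel (a white-noise field has
#' \eqn{\mathrm{var}(\partial e) \approx 2 \mathrm{var}(e)} and so floors
#' out). Residual maps with zero variance contribute nothing; if every
#' map is constant, estimation fails.
#'
#' @param residuals a \code{\linkS4class{GLMResult}} (its residual maps
#'   are used) or a numeric matrix, maps x voxels.
#' @param voxels,dims voxel bookkeeping when a bare matrix is given.
#' @return numeric(3) per-axis FWHM in voxels.
#' @export
estimateMapSmoothness <- function(residuals, voxels = NULL, dims = NULL) {
  if (is(residuals, "GLMResult")) {
    voxels <- residuals@voxels
    dims <- residuals@dims
    residuals <- residuals@residuals
  }
  stopifnot(is.matrix(residuals), !is.null(voxels), !is.null(dims))
  if (nrow(residuals) < 2L)
    stop("at least 2 residual maps are required")
  dims <- as.integer(dims)

  inMask <- array(FALSE, dims)
  inMask[voxels] <- TRUE
  colOf <- array(NA_integer_, dims)
  colOf[voxels] <- seq_along(voxels)
  co <- arrayInd(as.integer(voxels), dims)
  pairs <- vector("list", 3L)
  for (a in 1:3) {
    nb <- co
    nb[, a] <- nb[, a] + 1L
    ok <- nb[, a] <= dims[a]
    lin <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
           (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    hit <- inMask[lin]
    pairs[[a]] <- cbind(which(ok)[hit], colOf[lin[hit]])
  }
  if (all(vapply(pairs, nrow, 1L) == 0L))
    stop("mask has no neighboring voxel pairs; smoothness undefined")

  fwhmCap <- max(dims)
  perMap <- matrix(NA_real_, nrow(residuals), 3L)
  for (m in seq_len(nrow(residuals))) {
    e <- residuals[m, ]
    ve <- var(e)
    if (!is.finite(ve) || ve == 0) next
    for (a in 1:3) {
      pr <- pairs[[a]]
      if (nrow(pr) < 2L) next
      vd <- var(e[pr[, 1]] - e[pr[, 2]])
      rho <- vd / (2 * ve)
      perMap[m, a] <-
        if (rho >= 1) 1
        else if (rho <= 0) fwhmCap
        else min(fwhmCap, sqrt(-2 * log(2) / log(1 - rho)))
    }
  }
  est <- colMeans(perMap, na.rm = TRUE)
  if (all(!is.finite(est)))
    stop("all residual maps constant; smoothness estimation failed")
  est[!is.finite(est)] <- 1
  pmax(1, est)
}
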