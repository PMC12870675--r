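## Clinical characterization and healthy-control contextualization:
## change scores, CGI-I summaries, paired and two-sample nonparametric
## tests, FDR, extreme-responder stratification and overlap-voxel
## comparisons. Results are returned as plain lists with a common shape
## (test, statistic, df, p, n, flag) so they serialize directly to JSON.

.testResult <- function(test, statistic, p, n, df = NA_real_,
                        flag = NA_character_) {
  list(test = test, statistic = as.numeric(statistic), df = df,
       p = as.numeric(p), n = as.integer(n), flag = flag)
}

#' Symptom change score
#'
#' Follow-up minus baseline questionnaire totals; lower totals are
#' better, so negative change means improvement. Rows with a missing
#' total get \code{NA} and are excluded from change analyses downstream.
#'
#' @param follow,base numeric vectors of questionnaire totals.
#' @return numeric vector of signed change scores.
#' @export
changeScore <- function(follow, base) {
  if (length(follow) != length(base))
    stop("follow and base must have equal length")
  follow - base
}

#' Summarize CGI-I categories
#'
#' Aggregates the five-category patient-reported improvement scale into
#' improved (much improved + improved), unchanged, and worsened (worse +
#' much worse), as percentages of the total. Improved and unchanged are
#' rounded half-up to one decimal; worsened is reported as the
#' complement to 100.0, so the three categories always total exactly
#' 100\% as in clinical reporting (e.g. 19/32, 10/32, 3/32 print as
#' 59.4 / 31.3 / 9.3).
#'
#' @param counts numeric vector of length 5, category counts in the order
#'   much improved, improved, unchanged, worse, much worse.
#' @return named numeric vector \code{c(improved, unchanged, worsened)} in
#'   percent.
#' @examples
#' summarizeCGI(c(5, 14, 10, 3, 0))  # 59.4 / 31.3 / 9.3
#' @export
summarizeCGI <- function(counts) {
  if (length(counts) != 5L || any(counts < 0))
    stop("counts must be 5 nonnegative category counts")
  counts <- unname(counts)
  total <- sum(counts)
  if (total == 0) stop("total count must be positive")
  roundHalfUp <- function(x) floor(x * 10 + 0.5) / 10
  improved <- roundHalfUp(100 * (counts[1] + counts[2]) / total)
  unchanged <- roundHalfUp(100 * counts[3] / total)
  c(improved = improved, unchanged = unchanged,
    worsened = roundHalfUp(100 - improved - unchanged))
}

## Signed-rank z with zeros dropped, midranks and no continuity
## correction (so a signed z statistic is reported).
.wilcoxonSignedRank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(.testResult("wilcoxon_signed_rank", 0, 1, 0,
                       flag = "all differences zero"))
  r <- rank(abs(d))
  wPlus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0)
    return(.testResult("wilcoxon_signed_rank", 0, 1, n,
                       flag = "degenerate"))
  z <- (wPlus - mu) / sqrt(sig2)
  .testResult("wilcoxon_signed_rank", z, 2 * pnorm(-abs(z)), n)
}

#' Paired pre-post tests
#'
#' Two-sided paired tests between baseline and follow-up measurements.
#' \itemize{
#'   \item \code{"wilcoxon"}: signed-rank with zero differences dropped,
#'     midranks for ties and the normal approximation, reported as a
#'     signed z (no continuity correction).
#'   \item \code{"t"}: paired Student t with df = n - 1; zero-variance
#'     differences are flagged and the statistic capped.
#'   \item \code{"mcnemar"}: paired binary data; exact binomial on the
#'     discordant pairs when they number fewer than 25, chi-square
#'     otherwise.
#' }
#'
#' @param base,follow paired numeric (or 0/1 for McNemar) vectors.
#' @param method one of \code{"wilcoxon"}, \code{"t"}, \code{"mcnemar"}.
#' @return a test-result list: test, statistic, df, p, n, flag.
#' @export
pairedTest <- function(base, follow, method = c("wilcoxon", "t",
                                                "mcnemar")) {
  method <- match.arg(method)
  ok <- complete.cases(base, follow)
  base <- base[ok]; follow <- follow[ok]
  n <- length(base)
  if (method == "mcnemar") {
    if (!all(c(base, follow) %in% c(0, 1)))
      stop("mcnemar requires paired binary 0/1 data")
    b <- sum(base == 0 & follow == 1)
    c_ <- sum(base == 1 & follow == 0)
    disc <- b + c_
    if (disc == 0)
      return(.testResult("mcnemar", 0, 1, n, flag = "no discordant pairs"))
    if (disc < 25) {
      p <- binom.test(b, disc, 0.5)$p.value
      return(.testResult("mcnemar", b, p, n, flag = "exact binomial"))
    }
    stat <- (b - c_)^2 / disc
    return(.testResult("mcnemar", stat, pchisq(stat, 1, lower.tail = FALSE),
                       n, df = 1))
  }
  if (n < 5L) stop("at least 5 pairs are required")
  d <- follow - base
  if (method == "wilcoxon") return(.wilcoxonSignedRank(d))
  ## paired t
  if (sd(d) == 0) {
    if (all(d == 0))
      return(.testResult("paired_t", 0, 1, n, df = n - 1,
                         flag = "all differences zero"))
    return(.testResult("paired_t", sign(mean(d)) * .Z_CAP, 0, n,
                       df = n - 1, flag = "zero-variance differences"))
  }
  tt <- t.test(follow, base, paired = TRUE)
  .testResult("paired_t", unname(tt$statistic), tt$p.value, n,
              df = unname(tt$parameter))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank tie
#' handling; U is reported for the first sample. For small untied
#' samples (both sizes < 50, no ties) the exact two-sided p value is
#' used; otherwise the normal approximation with tie correction.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return a test-result list; \code{statistic} is \eqn{U_a}.
#' @export
mannWhitneyU <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (!na || !nb) stop("both samples must be nonempty")
  r <- rank(c(a, b))
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  mu <- na * nb / 2
  hasTies <- anyDuplicated(c(a, b)) > 0L
  if (!hasTies && na < 50 && nb < 50) {
    p <- if (ua > mu)
      2 * stats::pwilcox(ua - 1, na, nb, lower.tail = FALSE)
    else 2 * stats::pwilcox(ua, na, nb)
    return(.testResult("mann_whitney_u", ua, min(1, p), n,
                       flag = "exact"))
  }
  ties <- table(r)
  sig2 <- na * nb / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0)
    return(.testResult("mann_whitney_u", ua, 1, n, flag = "degenerate"))
  z <- (ua - mu) / sqrt(sig2)
  .testResult("mann_whitney_u", ua, 2 * pnorm(-abs(z)), n)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p values (monotone non-decreasing in rank) and
#' rejection flags at level \code{q}.
#'
#' @param p numeric vector of p values in [0, 1].
#' @param q FDR level in (0, 1).
#' @return list with \code{adjusted} and logical \code{rejected}.
#' @export
bhFDR <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Stratify extreme responders
#'
#' Splits off the k most-improved (most negative change scores) and k
#' most-worsened subjects, with \eqn{k = \max(1, \lfloor n \cdot
#' fraction \rfloor)}; at the default fraction 0.2 a 28-subject cohort
#' yields k = 5. Ties at the stratum boundary are broken by subject
#' order, with a warning.
#'
#' @param change numeric change scores (negative = improvement).
#' @param fraction stratum fraction in (0, 0.5].
#' @param ids subject identifiers (defaults to indices).
#' @return list with \code{improved} and \code{worsened} id vectors,
#'   disjoint and both of length k.
#' @export
stratifyExtremes <- function(change, fraction = 0.2, ids = NULL) {
  n <- length(change)
  if (n < 2L) stop("at least 2 subjects are required")
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]")
  if (is.null(ids)) ids <- seq_len(n)
  k <- max(1L, as.integer(floor(n * fraction)))
  ord <- order(change, seq_len(n))  # stable: ties by subject order
  lo <- ord[seq_len(k)]
  hi <- ord[seq.int(n, n - k + 1L)]
  bnd <- sort(change)
  if ((k < n && bnd[k] == bnd[k + 1L]) ||
      (k < n && bnd[n - k + 1L] == bnd[n - k]))
    warning("ties at a stratum boundary broken by subject order")
  list(improved = ids[lo], worsened = ids[hi], k = k)
}

#' Overlap of two significance masks
#'
#' Voxel-wise AND of the baseline-predictor and longitudinal-change
#' significance masks: the voxels that emerged in both analyses.
#'
#' @param a,b logical arrays on the same grid.
#' @return logical array.
#' @export
overlapMask <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch between masks")
  a & b
}

#' Contextualize overlap-voxel values against healthy controls
#'
#' Mann-Whitney U tests of per-subject mean metric values (over the
#' overlap voxels) for the full FND cohort and the extreme-improvement /
#' extreme-worsening strata, each versus healthy controls, at baseline
#' and follow-up -- six cells. Empty strata are flagged not-computed.
#'
#' @param fndBase,fndFollow named numeric vectors of per-FND-subject mean
#'   values at the two timepoints.
#' @param hcValues numeric vector of healthy-control mean values
#'   (nonempty).
#' @param strata list with \code{improved} and \code{worsened} id
#'   vectors, as from \code{\link{stratifyExtremes}}.
#' @return data.frame with one row per (group, timepoint) cell: U, p, n
#'   of the FND side, and a flag.
#' @export
hcContextualize <- function(fndBase, fndFollow, hcValues, strata) {
  if (!length(hcValues)) stop("HC sample must be nonempty")
  groups <- list(full = names(fndBase),
                 top_improved = strata$improved,
                 bottom_worsened = strata$worsened)
  out <- list()
  for (g in names(groups)) {
    for (tp in c("baseline", "followup")) {
      vals <- if (tp == "baseline") fndBase else fndFollow
      sel <- vals[names(vals) %in% groups[[g]]]
      sel <- sel[!is.na(sel)]
      if (!length(sel)) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, timepoint = tp, U = NA_real_, p = NA_real_,
          n_fnd = 0L, n_hc = length(hcValues), flag = "not computed")
        next
      }
      tr <- mannWhitneyU(sel, hcValues)
      out[[length(out) + 1L]] <- data.frame(
        group = g, timepoint = tp, U = tr$statistic, p = tr$p,
        n_fnd = length(sel), n_hc = length(hcValues),
        flag = if (is.na(tr$flag)) "" else tr$flag)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation
#'
#' Rho on midranks with the two-sided t-approximation p value (the
#' statistic reported alongside cluster scatterplots).
#'
#' @param x,y numeric vectors, n >= 4.
#' @return a test-result list with \code{statistic} = rho.
#' @export
spearmanAssoc <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("at least 4 complete pairs are required")
  if (sd(x) == 0 || sd(y) == 0)
    return(.testResult("spearman", NA_real_, NA_real_, n,
                       flag = "zero-variance input"))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1)
    return(.testResult("spearman", rho, 0, n, df = n - 2,
                       flag = "perfect monotone"))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  .testResult("spearman", rho, 2 * pt(-abs(tt), n - 2), n, df = n - 2)
}
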