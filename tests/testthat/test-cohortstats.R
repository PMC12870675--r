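test_that("change scores are signed follow-up minus baseline", {
  expect_equal(changeScore(7, 10), -3)
  expect_equal(changeScore(5, 5), 0)
  expect_true(is.na(changeScore(NA, 5)))
  expect_error(changeScore(1:3, 1:2), "equal length")
})

test_that("CGI-I summaries aggregate and round as printed", {
  expect_equal(summarizeCGI(c(5, 14, 10, 3, 0)),
               c(improved = 59.4, unchanged = 31.3, worsened = 9.3))
  expect_equal(summarizeCGI(c(0, 0, 32, 0, 0)),
               c(improved = 0, unchanged = 100, worsened = 0))
  expect_error(summarizeCGI(c(0, 0, 0, 0, 0)), "positive")
  expect_error(summarizeCGI(c(1, 2, 3)), "5")
  # percentages always sum to ~100
  set.seed(2)
  for (i in 1:20) {
    cts <- rmultinom(1, sample(10:60, 1), runif(5))[, 1]
    expect_lt(abs(sum(summarizeCGI(cts)) - 100), 0.15)
  }
})

test_that("signed-rank z matches the base-R normal approximation", {
  base <- c(10, 12, 9, 15, 8, 11)
  fol <- c(8, 13, 6, 9, 9, 5)
  res <- pairedTest(base, fol, "wilcoxon")
  ref <- suppressWarnings(
    wilcox.test(fol, base, paired = TRUE, exact = FALSE,
                correct = FALSE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(res$statistic), -qnorm(res$p / 2), tolerance = 1e-10)
  d <- fol - base
  expect_equal(sign(res$statistic),
               sign(sum(rank(abs(d))[d > 0]) -
                      length(d) * (length(d) + 1) / 4))

  # zero differences flagged degenerate
  same <- pairedTest(1:6, 1:6, "wilcoxon")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_match(same$flag, "zero")
})

test_that("paired t handles regular and degenerate differences", {
  base <- c(3, 5, 2, 8, 6, 4)
  fol <- c(4, 4, 5, 9, 5, 7)
  res <- pairedTest(base, fol, "t")
  d <- fol - base
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(6)),
               tolerance = 1e-12)
  expect_equal(res$df, 5)

  cap <- pairedTest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6), "t")
  expect_equal(cap$statistic, 8.2)
  expect_equal(cap$p, 0)
  expect_match(cap$flag, "zero-variance")
  expect_error(pairedTest(1:3, 3:1, "t"), "5 pairs")
})

test_that("mcnemar uses the exact binomial path for few discordants", {
  base <- c(1, 1, 1, 0, 0, 0, 0, 1, 0, 1)
  fol <- c(1, 0, 0, 1, 0, 0, 1, 1, 0, 0)
  res <- pairedTest(base, fol, "mcnemar")
  # discordant pairs: b = 0->1 (2), c = 1->0 (3)
  expect_equal(res$p, binom.test(2, 5, 0.5)$p.value)
  expect_match(res$flag, "exact")
  nod <- pairedTest(c(0, 1, 0), c(0, 1, 0), "mcnemar")
  expect_equal(nod$p, 1)
})

test_that("Mann-Whitney U matches brute-force enumeration", {
  expect_equal(mannWhitneyU(c(1, 2), c(3, 4))$statistic, 0)
  # identical multisets -> U = n_a n_b / 2
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)

  set.seed(7)
  a <- round(rnorm(5, 0, 5), 3); b <- round(rnorm(5, 1, 5), 3)
  res <- mannWhitneyU(a, b)
  # oracle: enumerate all C(10,5) labelings of the pooled sample
  pool <- c(a, b)
  uOf <- function(ix) sum(rank(pool)[ix]) - 5 * 6 / 2
  combos <- combn(10, 5)
  us <- apply(combos, 2, uOf)
  uObs <- uOf(1:5)
  mu <- 5 * 5 / 2
  pExact <- mean(abs(us - mu) >= abs(uObs - mu))
  expect_equal(res$statistic, uObs)
  expect_equal(res$p, pExact, tolerance = 1e-10)

  # with ties, the tie-corrected normal approximation matches base R
  a2 <- c(1, 2, 2, 3, 5, 7); b2 <- c(2, 3, 3, 6, 6, 8, 9)
  res2 <- mannWhitneyU(a2, b2)
  ref <- suppressWarnings(wilcox.test(a2, b2, exact = FALSE,
                                      correct = FALSE))
  expect_equal(res2$statistic, unname(ref$statistic))
  expect_equal(res2$p, ref$p.value, tolerance = 1e-10)
})

test_that("BH-FDR follows the step-up rule", {
  res <- bhFDR(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(res$rejected, c(TRUE, TRUE, TRUE, FALSE))
  # hand-derived adjusted values: p_(i) * m / i, monotonized
  expect_equal(res$adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_true(bhFDR(0.01, 0.05)$rejected)
  expect_false(any(bhFDR(rep(1, 4), 0.05)$rejected))
  p <- runif(10)
  expect_true(all(bhFDR(p)$adjusted >= p))
  expect_error(bhFDR(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("extreme-responder strata are floor-sized and disjoint", {
  set.seed(3)
  ch28 <- rnorm(28)
  s <- stratifyExtremes(ch28, 0.2)
  expect_equal(s$k, 5L)
  expect_length(s$improved, 5L)
  expect_length(s$worsened, 5L)
  expect_length(intersect(s$improved, s$worsened), 0L)
  expect_true(all(ch28[s$improved] <= sort(ch28)[5]))
  expect_true(all(ch28[s$worsened] >= sort(ch28)[24]))

  s10 <- stratifyExtremes(c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4), 0.2,
                          ids = letters[1:10])
  expect_equal(s10$improved, c("a", "b"))
  expect_equal(s10$worsened, c("j", "i"))

  expect_warning(tie <- stratifyExtremes(rep(0, 10), 0.2), "ties")
  expect_equal(tie$improved, 1:2)
  expect_error(stratifyExtremes(rnorm(10), 0.6), "0.5")
  expect_error(stratifyExtremes(1, 0.2), "2 subjects")
})

test_that("mask overlap is a voxel-wise intersection", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  b <- array(c(FALSE, TRUE, TRUE, FALSE), c(2, 2, 1))
  ov <- overlapMask(a, b)
  expect_equal(sum(ov), 1L)
  expect_lte(sum(ov), min(sum(a), sum(b)))
  expect_equal(overlapMask(a, a), a)
  expect_equal(sum(overlapMask(a, !a)), 0L)
  expect_error(overlapMask(a, array(TRUE, c(2, 1, 2))), "grid mismatch")
})

test_that("HC contextualization separates planted strata", {
  set.seed(21)
  nF <- 25; nH <- 50
  ids <- sprintf("F%02d", 1:nF)
  change <- rnorm(nF)
  strata <- stratifyExtremes(change, 0.2, ids = ids)
  hc <- rnorm(nH)

  # null: FND drawn from the HC distribution
  fb <- setNames(rnorm(nF), ids)
  ff <- setNames(rnorm(nF), ids)
  tabNull <- hcContextualize(fb, ff, hc, strata)
  expect_equal(nrow(tabNull), 6L)
  expect_lte(sum(tabNull$p < 0.05, na.rm = TRUE), 1L)

  # top stratum shifted +3 SD at baseline only
  fb2 <- fb
  fb2[strata$improved] <- fb2[strata$improved] + 3
  tabShift <- hcContextualize(fb2, ff, hc, strata)
  pick <- function(g, tp)
    tabShift[tabShift$group == g & tabShift$timepoint == tp, ]
  expect_lt(pick("top_improved", "baseline")$p, 0.01)
  expect_gt(pick("top_improved", "followup")$p, 0.05)

  expect_error(hcContextualize(fb, ff, numeric(0), strata), "nonempty")

  # empty stratum flagged, not an error
  strata0 <- list(improved = character(0), worsened = strata$worsened)
  tab0 <- hcContextualize(fb, ff, hc, strata0)
  expect_true(any(tab0$flag == "not computed"))
})

test_that("Spearman association matches the rank-Pearson construction", {
  x <- c(2, 7, 1, 9, 4, 6)
  y <- c(5, 8, 2, 12, 3, 10)
  res <- spearmanAssoc(x, y)
  expect_equal(res$statistic, cor(rank(x), rank(y)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = FALSE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)

  expect_equal(spearmanAssoc(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearmanAssoc(1:8, -(1:8)^3)$statistic, -1)
  expect_match(spearmanAssoc(rep(1, 5), rnorm(5))$flag, "zero-variance")
  expect_error(spearmanAssoc(1:3, 1:3), "4 complete")
})

test_that("tests are invariant to subject order", {
  set.seed(5)
  a <- rnorm(12); b <- rnorm(15)
  perm <- sample(12)
  expect_equal(mannWhitneyU(a, b)[c("statistic", "p")],
               mannWhitneyU(a[perm], b[sample(15)])[c("statistic", "p")])
  x <- rnorm(10); y <- rnorm(10)
  p10 <- sample(10)
  expect_equal(spearmanAssoc(x, y)[c("statistic", "p")],
               spearmanAssoc(x[p10], y[p10])[c("statistic", "p")])
  expect_equal(pairedTest(x, y, "wilcoxon")[c("statistic", "p")],
               pairedTest(x[p10], y[p10], "wilcoxon")[c("statistic", "p")])
})
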