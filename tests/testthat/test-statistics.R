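# Group summaries, t tests, Spearman correlation, ICC, cohort report.

test_that("group summaries give mean and SEM with degenerate-n handling", {
  tab <- data.frame(group = c("a", "a", "a", "b", "c", "c"),
                    m = c(1, 2, 3, 5, 4, 4))
  s <- summarizeGroups(tab, "m")
  expect_equal(s$mean[s$group == "a"], 2)
  expect_equal(s$sem[s$group == "a"], 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$sem[s$group == "b"], 0)       # n = 1: undefined -> 0 + flag
  expect_true(s$sem_undefined[s$group == "b"])
  expect_equal(s$sem[s$group == "c"], 0)       # all equal
  expect_false(s$sem_undefined[s$group == "c"])
  expect_error(summarizeGroups(tab, "missing"), class = "fqValidationError")
})

test_that("pooled t test matches the hand formula; degenerate cases flagged", {
  r <- twoSampleT(c(1, 2, 3), c(2, 3, 4), "pooled")
  expect_equal(r$statistic, -sqrt(3 / 2), tolerance = 1e-12)  # = -1.2247
  expect_equal(r$df, 4)
  expect_equal(r$p.value, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-12)

  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  deg <- twoSampleT(c(1, 1), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 0)
  expect_equal(twoSampleT(c(2, 2), c(2, 2))$p.value, 1)

  expect_error(twoSampleT(1, c(1, 2)), class = "fqValidationError")
})

test_that("pooled equals Welch for equal variances and sizes; both match formulas", {
  set.seed(42)
  a <- rnorm(8); b <- a + 0.3          # identical spread, equal n
  p <- twoSampleT(a, b, "pooled"); w <- twoSampleT(a, b, "welch")
  expect_equal(p$statistic, w$statistic, tolerance = 1e-12)
  expect_equal(p$p.value, w$p.value, tolerance = 1e-12)

  x <- rnorm(9); y <- rnorm(14, 1, 2)
  r <- twoSampleT(x, y, "pooled")
  sp2 <- (8 * var(x) + 13 * var(y)) / 21
  tHand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 9 + 1 / 14))
  expect_equal(r$statistic, tHand, tolerance = 1e-12)
  expect_equal(r$p.value, 2 * pt(-abs(tHand), 21), tolerance = 1e-12)
})

test_that("Spearman rho handles monotone data and ties by average ranks", {
  x <- c(3, 8, 1, 9, 4)
  expect_equal(spearmanCor(x, exp(x))$estimate, 1)
  expect_equal(spearmanCor(x, -x^3)$estimate, -1)

  xt <- c(1, 2, 2, 4); yt <- c(1, 3, 2, 4)
  r <- spearmanCor(xt, yt)
  # brute-force average-rank formula
  rk <- function(v) {
    sapply(v, function(a) sum(v < a) + (1 + sum(v == a)) / 2)
  }
  rx <- rk(xt); ry <- rk(yt)
  rHand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(r$estimate, rHand, tolerance = 1e-12)
  expect_equal(r$estimate,
               suppressWarnings(cor(xt, yt, method = "spearman")),
               tolerance = 1e-12)

  expect_error(spearmanCor(c(1, 1, 1), c(1, 2, 3)),
               class = "fqValidationError")
  expect_error(spearmanCor(c(1, 2), c(1, 2)), class = "fqValidationError")
})

test_that("Spearman permutation p is exact for small n and coherent with large-n", {
  set.seed(7)
  x <- rnorm(7); y <- rnorm(7)          # no ties: AS89 exact is the oracle
  ours <- spearmanCor(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)

  # symmetry and monotone-transform invariance
  expect_equal(spearmanCor(x, y)$p.value, spearmanCor(y, x)$p.value)
  expect_equal(spearmanCor(exp(x), y)$estimate, ours$estimate)

  # with ties the permutation p is still a valid probability and agrees in
  # direction with the t approximation
  xt <- c(1, 2, 2, 3, 4, 5, 5, 6); yt <- c(2, 1, 3, 3, 5, 4, 6, 6)
  pp <- spearmanCor(xt, yt)
  expect_true(pp$p.value >= 0 && pp$p.value <= 1)
  tstat <- pp$estimate * sqrt((pp$n - 2) / (1 - pp$estimate^2))
  pt2 <- 2 * pt(-abs(tstat), pp$n - 2)
  expect_equal(pp$p.value < 0.5, pt2 < 0.5)

  # large-n branch uses the t approximation
  set.seed(8)
  xl <- rnorm(20); yl <- xl + rnorm(20)
  rl <- spearmanCor(xl, yl)
  expect_equal(rl$method, "t approximation")
  tl <- rl$estimate * sqrt(18 / (1 - rl$estimate^2))
  expect_equal(rl$p.value, 2 * pt(-abs(tl), 18), tolerance = 1e-12)
})

test_that("ICC matches an explicit ANOVA decomposition and aov()", {
  m <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  r <- iccTwoWay(m)
  # hand ANOVA: explicit sums
  grand <- mean(m)
  ssS <- 3 * sum((rowMeans(m) - grand)^2)
  ssR <- 3 * sum((colMeans(m) - grand)^2)
  ssE <- sum((m - grand)^2) - ssS - ssR
  msS <- ssS / 2; msE <- ssE / 4
  expect_equal(r$icc, (msS - msE) / (msS + 2 * msE), tolerance = 1e-12)
  expect_equal(r$icc, 1)   # raters differ by constant offsets only

  set.seed(3)
  m2 <- matrix(rnorm(24, rep(1:6, 4)), 6, 4)
  r2 <- iccTwoWay(m2)
  long <- data.frame(score = as.vector(m2),
                     subject = factor(rep(1:6, 4)),
                     rater = factor(rep(1:4, each = 6)))
  msTab <- summary(aov(score ~ subject + rater, long))[[1]]
  msSubA <- msTab["subject", "Mean Sq"]; msErrA <- msTab["Residuals", "Mean Sq"]
  expect_equal(unname(r2$meanSquares["subjects"]), msSubA, tolerance = 1e-10)
  expect_equal(unname(r2$meanSquares["error"]), msErrA, tolerance = 1e-10)
  expect_equal(r2$icc, (msSubA - msErrA) / (msSubA + 3 * msErrA),
               tolerance = 1e-10)
})

test_that("ICC is offset-invariant, flags negatives, and agreement differs", {
  set.seed(5)
  m <- matrix(rnorm(15, rep(1:5, 3)), 5, 3)
  off <- sweep(m, 2, c(0, 1.5, -2), "+")
  expect_equal(iccTwoWay(off)$icc, iccTwoWay(m)$icc, tolerance = 1e-12)
  # absolute agreement charges the rater offsets
  expect_lt(iccTwoWay(off, "agreement")$icc, iccTwoWay(off)$icc)

  neg <- rbind(c(1, 5), c(5, 1), c(1, 5))   # crossed: no subject consistency
  rn <- iccTwoWay(neg)
  expect_true(rn$negative)
  expect_lt(rn$icc, 0)

  expect_error(iccTwoWay(rbind(c(1, NA), c(2, 3))),
               class = "fqValidationError")
  expect_error(iccTwoWay(matrix(1:3, 3, 1)), class = "fqValidationError")
})

test_that("cohort report wires components together", {
  tab <- data.frame(
    slide_id = sprintf("s%d", 1:9), patient_id = sprintf("s%d", 1:9),
    group = rep(c("g1", "g2", "g3"), each = 3),
    mean_tissue_density = c(0.8, 0.82, 0.85, 0.6, 0.63, 0.61, 0.4, 0.42, 0.38),
    fibrosis_score_pct = c(70, 75, 72, 40, 45, 42, 10, 12, 9))
  lung <- data.frame(patient_id = sprintf("s%d", 1:9),
                     FVC = c(40, 38, 35, 60, 58, 66, 85, 80, 88))
  ash <- cbind(r1 = c(6, 5, 7, 4, 3, 4, 1, 2, 1),
               r2 = c(7, 5, 6, 4, 4, 5, 2, 2, 1),
               r3 = c(6, 6, 7, 5, 3, 4, 1, 1, 2))
  rep <- runCohortStats(tab, lungFunction = lung, ashcroft = ash)
  expect_equal(nrow(rep$tTests), 2 * 3)      # 2 metrics x 3 group pairs
  expect_true(all(rep$correlations$rho < 0)) # inverse coupling recovered
  expect_s3_class(rep$icc, "fqICCResult")
  expect_gt(rep$icc$icc, 0.75)               # "good" reliability regime
  expect_equal(rep$nTests, 6L + 2L + 1L)

  one <- runCohortStats(tab[tab$group == "g1", ], lungFunction = lung)
  expect_null(one$tTests)
  expect_match(paste(one$notes, collapse = " "), "t tests skipped")
  expect_false(is.null(one$correlations))

  dir <- file.path(tempdir(), "statsout")
  paths <- writeStatsReport(rep, dir)
  expect_true(file.exists(file.path(dir, "t_tests.csv")))
  expect_true(file.exists(file.path(dir, "report.txt")))
})
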