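# Validation statistics: group summaries, two-sample t tests, Spearman
# correlation with exact small-sample permutation p, and two-way ANOVA
# intraclass correlation for inter-rater reliability of Ashcroft scores.

#' Per-group mean, SEM and n for one metric
#'
#' SEM = sample SD / sqrt(n). Groups of size 1 have undefined SEM; it is
#' reported as 0 with \code{sem_undefined = TRUE}.
#'
#' @param table data.frame with a \code{group} column (cohort table).
#' @param metric name of the numeric column to summarize.
#' @param groupCol name of the grouping column (default \code{"group"}).
#' @return data.frame with columns group, n, mean, sem, sem_undefined,
#'   in the order groups first appear.
#' @export
summarizeGroups <- function(table, metric, groupCol = "group") {
  if (!metric %in% names(table))
    .stopValidation(sprintf("metric '%s' not found", metric))
  if (!groupCol %in% names(table))
    .stopValidation(sprintf("group column '%s' not found", groupCol))
  groups <- unique(as.character(table[[groupCol]]))
  rows <- lapply(groups, function(g) {
    v <- table[[metric]][table[[groupCol]] == g]
    v <- v[!is.na(v)]
    if (!length(v))
      .stopValidation(sprintf("group '%s' has no values for %s", g, metric))
    n <- length(v)
    data.frame(group = g, n = n, mean = mean(v),
               sem = if (n > 1) sd(v) / sqrt(n) else 0,
               sem_undefined = n == 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample two-tailed t test
#'
#' \code{variant = "pooled"} is the classic Student test with
#' \code{df = n_a + n_b - 2}; \code{"welch"} uses the Welch-Satterthwaite
#' approximation. When both groups have zero variance the statistic
#' degenerates: equal means give t = 0, p = 1; unequal means give
#' t = +/-Inf, p = 0, with \code{degenerate = TRUE}.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return List of class \code{"fqTestResult"}: statistic, df, p.value,
#'   means, sems, n, variant, degenerate.
#' @export
twoSampleT <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    .stopValidation("both groups need at least 2 values")
  degenerate <- var(a) == 0 && var(b) == 0
  if (degenerate) {
    if (mean(a) == mean(b)) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
    df <- length(a) + length(b) - 2
  } else {
    tt <- stats::t.test(a, b, var.equal = variant == "pooled",
                        alternative = "two.sided")
    stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(
    statistic = stat, df = df, p.value = p,
    means = c(a = mean(a), b = mean(b)),
    sems = c(a = sd(a) / sqrt(length(a)), b = sd(b) / sqrt(length(b))),
    n = c(a = length(a), b = length(b)),
    variant = variant, degenerate = degenerate),
    class = "fqTestResult")
}

#' @export
print.fqTestResult <- function(x, ...) {
  cat(sprintf("Two-sample t test (%s): t = %.4g, df = %.4g, p = %.4g%s\n",
              x$variant, x$statistic, x$df, x$p.value,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  cat(sprintf("  a: %.4g +/- %.4g (n = %d);  b: %.4g +/- %.4g (n = %d)\n",
              x$means["a"], x$sems["a"], x$n["a"],
              x$means["b"], x$sems["b"], x$n["b"]))
  invisible(x)
}

.avgRank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with exact small-sample p value
#'
#' rho is the Pearson correlation of average ranks (ties receive average
#' ranks). The two-tailed p value is computed by exhaustive permutation of
#' one variable's ranks for n <= 9 (valid with ties), and by the
#' t-distribution approximation \code{t = r sqrt((n-2)/(1-r^2))} for
#' larger n.
#'
#' @param x,y paired numeric vectors; rows with missing values are
#'   dropped pairwise.
#' @return List of class \code{"fqCorrelationResult"}: estimate (rho), n,
#'   p.value, method.
#' @export
spearmanCor <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) .stopValidation("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    .stopValidation("Spearman rho undefined: constant input")
  rx <- .avgRank(x); ry <- .avgRank(y)
  r <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- .permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    # correlation of rxc with every permutation of ryc
    permuted <- matrix(ryc[perms], nrow(perms), n)
    rAll <- (permuted %*% rxc) / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rAll) >= abs(r) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  structure(list(estimate = r, n = n, p.value = min(p, 1), method = method),
            class = "fqCorrelationResult")
}

#' @export
print.fqCorrelationResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d), two-tailed p = %.4g [%s]\n",
              x$estimate, x$n, x$p.value, x$method))
  invisible(x)
}

#' Intraclass correlation from two-way ANOVA without replication
#'
#' Decomposes a complete subjects x raters score matrix by two-factor
#' ANOVA without replication and returns the single-rater consistency ICC
#' (Shrout-Fleiss ICC(3,1)):
#' \deqn{ICC = (MS_S - MS_E) / (MS_S + (k-1) MS_E)}
#' where \eqn{MS_S} is the between-subjects and \eqn{MS_E} the residual
#' mean square. \code{type = "agreement"} gives the absolute-agreement form
#' ICC(2,1), which also charges systematic rater differences. Negative
#' estimates are reported as computed, flagged with \code{negative = TRUE}.
#'
#' @param scores numeric matrix, subjects in rows, raters in columns,
#'   no missing cells.
#' @param type \code{"consistency"} (default) or \code{"agreement"}.
#' @return List of class \code{"fqICCResult"}: icc, type, meanSquares
#'   (subjects, raters, error), n, k, negative.
#' @export
iccTwoWay <- function(scores, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  scores <- as.matrix(scores)
  if (any(is.na(scores)))
    .stopValidation("score matrix must be complete (no missing cells)")
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L)
    .stopValidation("need >= 2 subjects and >= 2 raters")
  grand <- mean(scores)
  rm <- rowMeans(scores); cm <- colMeans(scores)
  ssS <- k * sum((rm - grand)^2)
  ssR <- n * sum((cm - grand)^2)
  ssT <- sum((scores - grand)^2)
  ssE <- ssT - ssS - ssR
  msS <- ssS / (n - 1)
  msR <- ssR / (k - 1)
  msE <- max(ssE / ((n - 1) * (k - 1)), 0)   # guard tiny negative rounding
  icc <- if (type == "consistency") {
    (msS - msE) / (msS + (k - 1) * msE)
  } else {
    (msS - msE) / (msS + (k - 1) * msE + k * (msR - msE) / n)
  }
  structure(list(icc = icc, type = type,
                 meanSquares = c(subjects = msS, raters = msR, error = msE),
                 n = n, k = k, negative = icc < 0),
            class = "fqICCResult")
}

#' @export
print.fqICCResult <- function(x, ...) {
  band <- if (is.nan(x$icc)) "undefined"
    else if (x$icc >= 0.9) "excellent"
    else if (x$icc >= 0.75) "good"
    else if (x$icc >= 0.5) "moderate" else "poor"
  cat(sprintf("ICC(%s, single rater) = %.3f [%s reliability]; n = %d subjects, k = %d raters\n",
              x$type, x$icc, band, x$n, x$k))
  cat(sprintf("  MS subjects = %.4g, MS raters = %.4g, MS error = %.4g\n",
              x$meanSquares["subjects"], x$meanSquares["raters"],
              x$meanSquares["error"]))
  invisible(x)
}

#' Read a cohort table from CSV
#'
#' One row per section; must contain \code{slide_id} and \code{group}
#' columns, typically produced by \code{\link{runQuantify}} or
#' \code{\link{generateCohort}}.
#'
#' @param path cohort CSV path.
#' @return data.frame.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) .stopIO(sprintf("file not found: %s", path))
  tab <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("slide_id", "group"))
    if (!col %in% names(tab))
      .stopValidation(sprintf("cohort table lacks required column '%s'", col))
  if (any(is.na(tab$group)))
    .stopValidation("cohort table has missing group labels")
  if ("ashcroft" %in% names(tab) &&
      any(tab$ashcroft < 0 | tab$ashcroft > 8, na.rm = TRUE))
    .stopValidation("Ashcroft scores must lie in [0, 8]")
  tab
}

#' Run the cohort validation statistics
#'
#' For each metric: per-group mean ± SEM, all pairwise two-sample t tests;
#' Spearman correlation of mean tissue density and fibrosis score against
#' every lung-function column; and, when an Ashcroft score matrix with
#' >= 2 rater columns is supplied, the two-way ANOVA ICC of inter-rater
#' reliability. p < 0.05 is flagged significant; ICC in [0.75, 0.90) is
#' labelled "good" reliability. No multiple-testing correction is applied;
#' the report carries the number of tests performed.
#'
#' @param table cohort data.frame (one row per section) with a
#'   \code{group} column and metric columns.
#' @param metrics metric columns to analyze; defaults to the standard
#'   morphometry columns present in \code{table}.
#' @param lungFunction optional data.frame with \code{patient_id} and
#'   percent-predicted columns (FVC/FEV1/TLC/DLCO); joined to \code{table}
#'   by \code{patient_id}.
#' @param ashcroft optional numeric matrix or data.frame of Ashcroft
#'   scores, sections x raters.
#' @param tTestVariant \code{"pooled"} (default, Student) or
#'   \code{"welch"}.
#' @return List of class \code{"fqStatsReport"}: groupSummaries, tTests,
#'   correlations, icc, nTests, notes.
#' @export
runCohortStats <- function(table, metrics = NULL, lungFunction = NULL,
                           ashcroft = NULL,
                           tTestVariant = c("pooled", "welch")) {
  tTestVariant <- match.arg(tTestVariant)
  if (!"group" %in% names(table))
    .stopValidation("cohort table lacks a 'group' column")
  if (is.null(metrics)) {
    std <- c("mean_tissue_density", "fibrosis_score_pct", "collagen_pct",
             "mucus_pct", "cd68_pct")
    metrics <- std[std %in% names(table) &
                     vapply(std, function(m)
                       m %in% names(table) && any(!is.na(table[[m]])),
                       logical(1))]
  }
  if (!length(metrics)) .stopValidation("no metric columns to analyze")
  groups <- unique(as.character(table$group))
  notes <- character(0)
  nTests <- 0L

  summaries <- do.call(rbind, lapply(metrics, function(m)
    cbind(metric = m, summarizeGroups(table, m))))

  tTests <- NULL
  if (length(groups) >= 2L) {
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    rows <- list()
    for (m in metrics) for (pr in pairs) {
      a <- table[[m]][table$group == pr[1]]
      b <- table[[m]][table$group == pr[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) next
      tt <- twoSampleT(a, b, tTestVariant)
      nTests <- nTests + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group_a = pr[1], group_b = pr[2],
        t = tt$statistic, df = tt$df, p = tt$p.value,
        significant = tt$p.value < 0.05, stringsAsFactors = FALSE)
    }
    tTests <- if (length(rows)) do.call(rbind, rows) else NULL
  } else {
    notes <- c(notes, "single group: t tests skipped")
  }

  correlations <- NULL
  if (!is.null(lungFunction)) {
    joined <- merge(table, lungFunction, by = "patient_id")
    lfCols <- setdiff(names(lungFunction), "patient_id")
    corMetrics <- intersect(c("mean_tissue_density", "fibrosis_score_pct"),
                            metrics)
    rows <- list()
    for (m in corMetrics) for (lf in lfCols) {
      ok <- complete.cases(joined[[m]], joined[[lf]])
      if (sum(ok) < 3L) next
      ct <- spearmanCor(joined[[m]][ok], joined[[lf]][ok])
      nTests <- nTests + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, lung_function = lf, rho = ct$estimate, n = ct$n,
        p = ct$p.value, significant = ct$p.value < 0.05,
        stringsAsFactors = FALSE)
    }
    correlations <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  icc <- NULL
  if (!is.null(ashcroft)) {
    am <- as.matrix(ashcroft)
    if (ncol(am) >= 2L) {
      icc <- iccTwoWay(am)
      nTests <- nTests + 1L
    } else {
      notes <- c(notes, "fewer than 2 rater columns: ICC skipped")
    }
  }

  structure(list(groupSummaries = summaries, tTests = tTests,
                 correlations = correlations, icc = icc,
                 nTests = nTests, notes = notes),
            class = "fqStatsReport")
}

#' @export
print.fqStatsReport <- function(x, ...) {
  cat("Cohort validation statistics\n")
  cat("== Group summaries (mean +/- SEM) ==\n")
  print(x$groupSummaries, row.names = FALSE)
  if (!is.null(x$tTests)) {
    cat("== Pairwise t tests ==\n"); print(x$tTests, row.names = FALSE)
  }
  if (!is.null(x$correlations)) {
    cat("== Spearman correlations vs lung function ==\n")
    print(x$correlations, row.names = FALSE)
  }
  if (!is.null(x$icc)) { cat("== Inter-rater ICC ==\n"); print(x$icc) }
  cat(sprintf("%d tests performed; no multiple-testing correction applied\n",
              x$nTests))
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

#' Write a stats report to CSV files and a plain-text summary
#'
#' @param report an \code{"fqStatsReport"} from
#'   \code{\link{runCohortStats}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeStatsReport <- function(report, dir) {
  stopifnot(inherits(report, "fqStatsReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  w(report$groupSummaries, "group_summaries.csv")
  if (!is.null(report$tTests)) w(report$tTests, "t_tests.csv")
  if (!is.null(report$correlations)) w(report$correlations,
                                       "correlations.csv")
  if (!is.null(report$icc))
    w(data.frame(icc = report$icc$icc, type = report$icc$type,
                 ms_subjects = report$icc$meanSquares["subjects"],
                 ms_raters = report$icc$meanSquares["raters"],
                 ms_error = report$icc$meanSquares["error"],
                 n_subjects = report$icc$n, k_raters = report$icc$k),
      "icc.csv")
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink())
  print(report)
  paths <- c(paths, txt)
  invisible(paths)
}
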