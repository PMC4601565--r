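#' Correlation between before- and after-selection metric vectors
#'
#' Sample Pearson correlation between a metric vector measured before feature
#' selection (`a`) and the corresponding vector after selection (`p`), one
#' entry per dataset. Used to quantify how closely the reduced-feature
#' classifier tracks the full-feature one across benchmarks.
#'
#' @param a,p numeric vectors of equal length `k >= 3`.
#' @return The correlation, in `[-1, 1]`.
#' @export
metric_correlation <- function(a, p) {
  a <- as.numeric(a); p <- as.numeric(p)
  if (length(a) != length(p)) stop("metric vectors differ in length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 paired metrics", call. = FALSE)
  if (anyNA(a) || anyNA(p)) stop("metric vectors contain missing values", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(p) == 0) {
    stop("correlation undefined: a metric vector has zero variance", call. = FALSE)
  }
  stats::cor(a, p)
}

#' Evans strength category of a correlation
#'
#' Bins the magnitude of a correlation coefficient into the five Evans
#' strength categories: 0.00-0.19 very weak, 0.20-0.39 weak, 0.40-0.59
#' moderate, 0.60-0.79 strong, 0.80-1.00 very strong. A boundary value starts
#' its own bin (0.80 is "very strong"). The sign is ignored.
#'
#' @param r correlation in `[-1, 1]`.
#' @return One of `"very weak"`, `"weak"`, `"moderate"`, `"strong"`,
#'   `"very strong"`.
#' @examples
#' evans_category(0.914)  # "very strong"
#' @export
evans_category <- function(r) {
  r <- abs(as.numeric(r))
  if (is.na(r) || r > 1) stop("correlation magnitude must be <= 1", call. = FALSE)
  labels <- c("very weak", "weak", "moderate", "strong", "very strong")
  labels[findInterval(r, c(0, 0.2, 0.4, 0.6, 0.8))]
}

#' Two-sided Student-t critical value
#'
#' @param df degrees of freedom (`>= 1`).
#' @param alpha two-sided significance level in `(0, 1)`.
#' @return The critical value `t*` such that `P(|T| > t*) = alpha`.
#' @examples
#' critical_value(4, 0.05)  # 2.7764
#' @export
critical_value <- function(df, alpha) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  stats::qt(1 - alpha / 2, df = df)
}

#' Paired t-test between metric vectors
#'
#' Tests whether the classifier performs differently before feature selection
#' (`a`) and after (`p`), using the paired statistic on `d = a - p`:
#' `t = sum(d) / sqrt((k * sum(d^2) - sum(d)^2) / (k - 1))`, `df = k - 1`.
#' The null hypothesis of no difference is accepted at a level when
#' `|t|` does not exceed the two-sided critical value. When every difference
#' is zero the statistic is 0 and `degenerate` is flagged (zero variance);
#' identical nonzero differences give an infinite statistic, also flagged.
#'
#' @param a,p numeric vectors of equal length `k >= 2` (`a` before selection,
#'   `p` after).
#' @param alpha significance levels for the accept/reject decisions.
#' @return An object of class `mfss_ttest`: `t_stat`, `df`, `critical_values`
#'   (named by alpha), `decision` (`"accept"`/`"reject"` of the no-difference
#'   null, named by alpha), `r_ap` and `evans_label` (`NA` when `k < 3` or a
#'   vector is constant), and `degenerate`.
#' @export
paired_t <- function(a, p, alpha = c(0.05, 0.01)) {
  a <- as.numeric(a); p <- as.numeric(p)
  if (length(a) != length(p)) stop("metric vectors differ in length", call. = FALSE)
  k <- length(a)
  if (k < 2L) stop("need at least 2 paired observations", call. = FALSE)
  if (anyNA(a) || anyNA(p)) stop("metric vectors contain missing values", call. = FALSE)
  d <- a - p
  denom2 <- (k * sum(d^2) - sum(d)^2) / (k - 1)
  degenerate <- denom2 <= 0
  t_stat <- if (degenerate) {
    if (all(d == 0)) 0 else sign(sum(d)) * Inf
  } else {
    sum(d) / sqrt(denom2)
  }
  df <- k - 1L
  crit <- stats::setNames(critical_value(df, alpha), paste0("alpha_", alpha))
  decision <- stats::setNames(ifelse(abs(t_stat) <= crit, "accept", "reject"),
                              names(crit))
  r_ap <- tryCatch(metric_correlation(a, p), error = function(e) NA_real_)
  structure(list(t_stat = t_stat, df = df, critical_values = crit,
                 decision = decision, r_ap = r_ap,
                 evans_label = if (is.na(r_ap)) NA_character_ else evans_category(r_ap),
                 degenerate = degenerate),
            class = "mfss_ttest")
}

#' @export
print.mfss_ttest <- function(x, ...) {
  cat(sprintf("paired t-test: t = %.3f (df = %d)%s\n", x$t_stat, x$df,
              if (x$degenerate) " [degenerate variance]" else ""))
  for (i in seq_along(x$critical_values)) {
    cat(sprintf("  %s: critical %.4f -> %s H0\n", names(x$critical_values)[i],
                x$critical_values[i], x$decision[i]))
  }
  if (!is.na(x$r_ap)) {
    cat(sprintf("  r_ap = %.3f (%s)\n", x$r_ap, x$evans_label))
  }
  invisible(x)
}

#' Validate a BFS/MFSS metric table
#'
#' Full statistical validation of a long-format metric table (the shape
#' produced by [compare_bfs_mfss()] across several datasets, or transcribed
#' from published results): for every (classifier, metric) pair it correlates
#' the per-dataset BFS and MFSS vectors, assigns the Evans strength label, and
#' runs the paired t-test with accept/reject decisions.
#'
#' @param metrics data frame with columns `dataset`, `classifier`, `condition`
#'   (values `BFS`/`MFSS`) and one numeric column per metric.
#' @param metric_cols metric columns to validate; defaults to all numeric
#'   columns present.
#' @param alpha significance levels.
#' @return Data frame with one row per (classifier, metric): `r_ap`,
#'   `evans_label`, `t_stat`, `df`, and a decision column per level.
#' @export
validate_metric_table <- function(metrics,
                                  metric_cols = NULL,
                                  alpha = c(0.05, 0.01)) {
  req <- c("dataset", "classifier", "condition")
  if (!all(req %in% names(metrics))) {
    stop("metric table needs columns dataset, classifier, condition", call. = FALSE)
  }
  if (!all(metrics$condition %in% c("BFS", "MFSS"))) {
    stop("condition must be 'BFS' or 'MFSS'", call. = FALSE)
  }
  if (is.null(metric_cols)) {
    metric_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  }
  if (!length(metric_cols)) stop("no numeric metric columns found", call. = FALSE)
  classifiers <- unique(metrics$classifier)
  rows <- list()
  for (cl in classifiers) {
    sub <- metrics[metrics$classifier == cl, , drop = FALSE]
    bfs <- sub[sub$condition == "BFS", , drop = FALSE]
    mf <- sub[sub$condition == "MFSS", , drop = FALSE]
    ord <- match(bfs$dataset, mf$dataset)
    if (anyNA(ord) || nrow(bfs) != nrow(mf)) {
      stop(sprintf("classifier '%s': BFS and MFSS dataset sets differ", cl),
           call. = FALSE)
    }
    mf <- mf[ord, , drop = FALSE]
    for (mc in metric_cols) {
      tt <- paired_t(bfs[[mc]], mf[[mc]], alpha = alpha)
      row <- data.frame(classifier = cl, metric = mc,
                        r_ap = tt$r_ap,
                        evans_label = tt$evans_label,
                        t_stat = tt$t_stat, df = tt$df,
                        stringsAsFactors = FALSE)
      for (i in seq_along(alpha)) {
        row[[paste0("decision_alpha_", alpha[i])]] <- tt$decision[[i]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled benchmark metric tables
#'
#' Published evaluation metrics for five benchmark multidimensional datasets
#' (thyroid, solar flare, scene, music, yeast) under four classifiers (J48,
#' Naive Bayes, SVM, IBk), before (BFS) and after (MFSS) feature selection:
#' Hamming score, exact match, Hamming loss and zero-one loss per run. These
#' are the inputs to the statistical-validation examples.
#'
#' @return Long-format data frame with columns `dataset`, `classifier`,
#'   `condition`, `hamming_score`, `exact_match`, `hamming_loss`,
#'   `zero_one_loss`.
#' @export
benchmark_metrics <- function() {
  path <- system.file("extdata", "benchmark_metrics.tsv", package = "mfss",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Bundled benchmark feature counts
#'
#' Post-load feature counts of the five benchmark datasets together with the
#' number of features the `s = round(log2(l))` rule selects.
#'
#' @return Data frame with columns `dataset`, `n_features`,
#'   `n_selected`.
#' @export
benchmark_feature_counts <- function() {
  path <- system.file("extdata", "benchmark_feature_counts.tsv",
                      package = "mfss", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
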