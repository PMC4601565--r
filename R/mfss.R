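#' Feature-class Pearson correlation matrix
#'
#' Computes, for every (feature, class-variable) pair, the sample Pearson
#' correlation between the feature column and the numerically encoded class
#' column (binary classes as \{0,1\}; multi-valued nominal classes as integer
#' codes in declared-domain order). Pairs involving a zero-variance column are
#' set to 0 by convention ("no association"), which keeps constant features at
#' the bottom of any ranking.
#'
#' @param x an [mddataset] with no missing values and `n >= 3`.
#' @param absolute if `TRUE`, return absolute correlations (an extension for
#'   sign-agnostic ranking; the default ranks signed correlations).
#' @return An object of class `mfss_correlation`: list with `values` (the
#'   `l x m` correlation matrix) and `n_used` (observations per entry).
#' @export
feature_class_correlation <- function(x, absolute = FALSE) {
  stopifnot(inherits(x, "mddataset"))
  validate_mddataset(x, require_complete = TRUE)
  n <- nrow(x$features)
  if (n < 3L) stop("correlation degenerate for n < 3", call. = FALSE)
  enc <- encode_targets(x)
  fsd <- apply(x$features, 2, stats::sd)
  csd <- apply(enc, 2, stats::sd)
  vals <- suppressWarnings(stats::cor(x$features, enc))
  vals[fsd == 0, ] <- 0
  vals[, csd == 0] <- 0
  if (absolute) vals <- abs(vals)
  dimnames(vals) <- list(x$feature_names, x$class_names)
  structure(list(values = vals, n_used = n, absolute = absolute),
            class = "mfss_correlation")
}

#' @export
print.mfss_correlation <- function(x, ...) {
  cat(sprintf("feature-class correlation matrix (%d x %d), n = %d%s\n",
              nrow(x$values), ncol(x$values), x$n_used,
              if (isTRUE(x$absolute)) ", absolute" else ""))
  print(round(x$values, 3))
  invisible(x)
}

#' Per-class rank weights
#'
#' For each class variable, the feature with the largest correlation receives
#' weight `l`, the next largest `l - 1`, down to weight 1 for the smallest.
#' Ties are broken deterministically: the feature with the smaller original
#' index receives the larger weight. Each weight column is thus a permutation
#' of `1..l` and sums to `l(l+1)/2`.
#'
#' @param corr an [feature_class_correlation()] result.
#' @return An `l x m` integer matrix of class `mfss_rank_weights`.
#' @export
rank_weights <- function(corr) {
  stopifnot(inherits(corr, "mfss_correlation"))
  r <- corr$values
  l <- nrow(r)
  w <- matrix(0L, l, ncol(r), dimnames = dimnames(r))
  for (i in seq_len(ncol(r))) {
    ord <- order(-r[, i], seq_len(l))  # descending r, ties to the lower index
    w[ord, i] <- seq.int(l, 1L)
  }
  class(w) <- c("mfss_rank_weights", class(w))
  w
}

#' Overall feature weights
#'
#' Aggregates the per-class correlations into one weight per feature: the
#' rank-weighted average
#' `w_j = sum_i w_ji * r_ji / sum_i w_ji`.
#' Each overall weight is a convex combination of the feature's per-class
#' correlations, so it lies between their minimum and maximum (and in
#' \[-1, 1\]). With a single class variable the aggregation is the identity.
#'
#' @param corr an [feature_class_correlation()] result.
#' @param weights the matching [rank_weights()] matrix.
#' @return Named numeric vector of length `l`.
#' @export
overall_weights <- function(corr, weights) {
  stopifnot(inherits(corr, "mfss_correlation"))
  if (!all(dim(weights) == dim(corr$values))) {
    stop("correlation and rank-weight shapes differ", call. = FALSE)
  }
  w <- rowSums(unclass(weights) * corr$values) / rowSums(unclass(weights))
  names(w) <- rownames(corr$values)
  w
}

#' Selected-subset size
#'
#' The selection threshold `s = log2(l)` rounded to the nearest integer (halves
#' round up), clamped to `1..l`. For the five benchmark feature counts 28, 10,
#' 294, 71 and 103 this yields 5, 3, 8, 6 and 7 selected features (between 3%
#' and 30% of the features).
#'
#' @param l number of features, `l >= 2`.
#' @return Integer subset size.
#' @examples
#' subset_size(294)  # 8
#' @export
subset_size <- function(l) {
  l <- as.integer(l)
  if (is.na(l) || l < 2L) stop("subset_size requires l >= 2", call. = FALSE)
  s <- as.integer(floor(log2(l) + 0.5))  # round half up
  max(1L, min(l, s))
}

#' Multidimensional feature subset selection (MFSS)
#'
#' Runs the full filter pipeline: feature-class correlations, per-class rank
#' weights, overall-weight aggregation, ranking by descending overall weight
#' (ties to the lower feature index), and selection of the top
#' `s = round(log2(l))` features. The result is a single feature subset shared
#' by all class variables.
#'
#' @param x an [mddataset] (complete; run [impute_missing()] first if needed).
#' @param s optional override of the subset size (1..l).
#' @param absolute rank by absolute correlation instead of signed correlation.
#' @return An object of class `mfss_selection`: `ranking` (feature indices in
#'   rank order), `s`, `selected` (the first `s` indices), `overall_weights`,
#'   `correlation`, `rank_weights` and `feature_names`.
#' @examples
#' sp <- synthetic_spec(n = 200, l = 16, m = 2,
#'                      informative = data.frame(feature = 1:4,
#'                                               class = c(1, 1, 2, 2),
#'                                               effect = 5),
#'                      seed = 7)
#' sel <- mfss(generate_synthetic(sp))
#' sel$selected
#' @export
mfss <- function(x, s = NULL, absolute = FALSE) {
  stopifnot(inherits(x, "mddataset"))
  l <- ncol(x$features)
  corr <- feature_class_correlation(x, absolute = absolute)
  rw <- rank_weights(corr)
  ow <- overall_weights(corr, rw)
  ranking <- order(-ow, seq_along(ow))
  if (is.null(s)) {
    s <- subset_size(l)
  } else {
    s <- as.integer(s)
    if (is.na(s) || s < 1L || s > l) stop("s must lie in 1..l", call. = FALSE)
  }
  structure(
    list(ranking = ranking, s = s, selected = ranking[seq_len(s)],
         overall_weights = ow, correlation = corr, rank_weights = rw,
         feature_names = x$feature_names, absolute = absolute),
    class = "mfss_selection"
  )
}

#' @export
print.mfss_selection <- function(x, ...) {
  l <- length(x$ranking)
  cat(sprintf("MFSS selection: %d of %d features%s\n", x$s, l,
              if (isTRUE(x$absolute)) " (absolute correlations)" else ""))
  sel <- x$selected
  cat("  selected:",
      paste(sprintf("%s (w=%.3f)", x$feature_names[sel],
                    x$overall_weights[sel]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mfss_selection <- function(x, ...) {
  l <- length(x$ranking)
  rank_pos <- integer(l)
  rank_pos[x$ranking] <- seq_len(l)
  df <- data.frame(
    feature = x$feature_names,
    overall_weight = unname(x$overall_weights),
    stringsAsFactors = FALSE
  )
  corr <- x$correlation$values
  for (i in seq_len(ncol(corr))) {
    df[[paste0("r_", colnames(corr)[i])]] <- unname(corr[, i])
  }
  df$rank <- rank_pos
  df$selected <- rank_pos <= x$s
  df[order(df$rank), , drop = FALSE]
}
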