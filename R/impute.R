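#' Impute missing values
#'
#' Deterministic completion of an [mddataset]: instances with any missing class
#' value are dropped first, then every remaining gap in a feature column is
#' replaced by the mean of that column's observed values. (Nominal features
#' are already integer-encoded at read time, so the mean rule applies
#' uniformly; a mode rule for encoded nominals is available via
#' `nominal_features`.) The operation is idempotent and the result contains no
#' missing entries.
#'
#' @param x an [mddataset].
#' @param nominal_features optional character vector of feature names to
#'   complete with the per-column mode (smallest value on ties) instead of the
#'   mean.
#' @return A complete [mddataset].
#' @export
impute_missing <- function(x, nominal_features = character(0)) {
  stopifnot(inherits(x, "mddataset"))
  keep <- !Reduce(`|`, lapply(x$targets, is.na))
  if (sum(keep) < 3L) {
    stop("fewer than 3 instances remain after dropping rows with missing class values",
         call. = FALSE)
  }
  feats <- x$features[keep, , drop = FALSE]
  targs <- x$targets[keep, , drop = FALSE]
  for (j in seq_len(ncol(feats))) {
    col <- feats[, j]
    if (!anyNA(col)) next
    obs <- col[!is.na(col)]
    if (length(obs) == 0L) {
      stop(sprintf("feature '%s' has no observed values; cannot impute",
                   colnames(feats)[j]), call. = FALSE)
    }
    fill <- if (colnames(feats)[j] %in% nominal_features) {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])  # which.max: first (smallest) mode
    } else {
      mean(obs)
    }
    col[is.na(col)] <- fill
    feats[, j] <- col
  }
  out <- mddataset(feats, targs, class_domains = x$class_domains)
  validate_mddataset(out, require_complete = TRUE)
  out
}
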