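#' Multidimensional dataset
#'
#' Container for a dataset in which every instance carries several class
#' variables ("multidimensional" data, generalizing binary multi-label data).
#' Features are held as an `n x l` numeric matrix; the `m` class variables are
#' held as factors whose level sets are the declared class domains.
#'
#' @param features numeric matrix (or coercible data frame) with `n` rows and
#'   `l >= 2` columns. Column names become feature names; unnamed columns are
#'   named `f1 ... fl`.
#' @param targets data frame (or matrix) with `n` rows and `m >= 1` columns of
#'   class values. Columns are converted to factors.
#' @param class_domains optional named list giving, per class variable, the
#'   ordered vector of admissible values. Defaults to the observed levels.
#'   Every domain must have cardinality at least 2.
#' @return An object of class `mddataset` with elements `features`, `targets`,
#'   `feature_names`, `class_names` and `class_domains`.
#' @examples
#' d <- mddataset(matrix(rnorm(20), 10, 2), data.frame(c1 = rep(c("a", "b"), 5)))
#' dim_mdd(d)
#' @export
mddataset <- function(features, targets, class_domains = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    names(targets) <- paste0("c", seq_len(ncol(targets)))
  }
  if (!is.null(class_domains)) {
    if (length(class_domains) != ncol(targets)) {
      stop("class_domains must have one entry per class variable", call. = FALSE)
    }
    if (is.null(names(class_domains))) names(class_domains) <- names(targets)
    targets[] <- Map(function(col, dom) {
      col <- as.character(col)
      bad <- !is.na(col) & !(col %in% as.character(dom))
      if (any(bad)) {
        stop(sprintf("class value '%s' outside its declared domain", col[which(bad)[1L]]),
             call. = FALSE)
      }
      factor(col, levels = as.character(dom))
    }, targets, class_domains)
  } else {
    targets[] <- lapply(targets, function(col) {
      if (is.factor(col)) col else factor(as.character(col), levels = unique(sort(as.character(col))))
    })
  }
  x <- structure(
    list(
      features = features,
      targets = targets,
      feature_names = colnames(features),
      class_names = names(targets),
      class_domains = lapply(targets, levels)
    ),
    class = "mddataset"
  )
  validate_mddataset(x)
  x
}

validate_mddataset <- function(x, require_complete = FALSE) {
  n <- nrow(x$features)
  l <- ncol(x$features)
  m <- ncol(x$targets)
  if (nrow(x$targets) != n) stop("feature and target row counts differ", call. = FALSE)
  if (l < 2L) stop("need at least 2 features (l >= 2)", call. = FALSE)
  if (m < 1L) stop("need at least 1 class variable (m >= 1)", call. = FALSE)
  if (n < 3L) stop("need at least 3 instances (n >= 3)", call. = FALSE)
  card <- vapply(x$class_domains, length, integer(1))
  if (any(card < 2L)) {
    stop(sprintf("class variable '%s' has a domain of cardinality < 2",
                 x$class_names[which(card < 2L)[1L]]), call. = FALSE)
  }
  if (require_complete && (anyNA(x$features) || anyNA(x$targets))) {
    stop("dataset contains missing values; run impute_missing() first", call. = FALSE)
  }
  invisible(x)
}

#' Dataset dimensions
#'
#' @param x an [mddataset].
#' @return Named integer vector `c(n, l, m)`: instances, features, class
#'   variables.
#' @export
dim_mdd <- function(x) {
  stopifnot(inherits(x, "mddataset"))
  c(n = nrow(x$features), l = ncol(x$features), m = ncol(x$targets))
}

#' @export
print.mddataset <- function(x, ...) {
  d <- dim_mdd(x)
  cat(sprintf("mddataset: %d instances, %d features, %d class variables\n",
              d["n"], d["l"], d["m"]))
  card <- vapply(x$class_domains, length, integer(1))
  cat("  classes:", paste(sprintf("%s(K=%d)", x$class_names, card), collapse = ", "), "\n")
  miss <- sum(is.na(x$features)) + sum(vapply(x$targets, function(t) sum(is.na(t)), integer(1)))
  if (miss > 0) cat("  missing entries:", miss, "\n")
  invisible(x)
}

# Numeric encoding of the class matrix for correlation work: binary domains map
# to {0,1}, larger domains to integer codes 0..K-1 in declared-domain order.
encode_targets <- function(x) {
  stopifnot(inherits(x, "mddataset"))
  enc <- vapply(x$targets, function(col) as.integer(col) - 1L, integer(nrow(x$targets)))
  enc <- matrix(as.double(enc), nrow = nrow(x$targets),
                dimnames = list(NULL, x$class_names))
  enc
}

# Subset instances and/or features, preserving domains.
subset_mdd <- function(x, rows = NULL, features = NULL) {
  stopifnot(inherits(x, "mddataset"))
  f <- x$features
  t <- x$targets
  if (!is.null(rows)) {
    f <- f[rows, , drop = FALSE]
    t <- t[rows, , drop = FALSE]
  }
  if (!is.null(features)) f <- f[, features, drop = FALSE]
  mddataset(f, t, class_domains = x$class_domains)
}
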