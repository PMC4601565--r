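#' Fit a problem-transformation multidimensional classifier
#'
#' Trains one independent single-target predictor per class variable (the
#' problem-transformation construction: a single-dimensional multiclass
#' classifier applied to each class variable) and bundles them into a
#' multi-predictor whose output is an `n x m` matrix of predicted classes.
#'
#' @param x an [mddataset] with no missing values.
#' @param trainer a trainer function (see [trainers]).
#' @param seed seed forwarded to the trainer.
#' @return An object of class `md_classifier`.
#' @export
fit_multidimensional <- function(x, trainer, seed = 0L) {
  stopifnot(inherits(x, "mddataset"))
  validate_mddataset(x, require_complete = TRUE)
  predictors <- lapply(x$class_names, function(cn) {
    tryCatch(
      trainer(x$features, x$targets[[cn]], seed = seed),
      error = function(e) {
        stop(sprintf("trainer failed on class variable '%s': %s",
                     cn, conditionMessage(e)), call. = FALSE)
      }
    )
  })
  names(predictors) <- x$class_names
  structure(list(predictors = predictors, class_names = x$class_names,
                 feature_names = x$feature_names),
            class = "md_classifier")
}

#' @param object an `md_classifier`.
#' @param newdata numeric feature matrix (columns matching the training
#'   features) or an [mddataset].
#' @param ... unused.
#' @rdname fit_multidimensional
#' @export
predict.md_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "mddataset")) newdata <- newdata$features
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata))) {
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  out <- as.data.frame(lapply(object$predictors, function(p) p(newdata)))
  names(out) <- object$class_names
  out
}

#' Evaluation protocol descriptor
#'
#' @param type `"cv"` (k-fold cross-validation; each instance is predicted by
#'   the model trained without its fold, and metrics are computed on the pooled
#'   out-of-fold predictions) or `"holdout"` (single split).
#' @param folds number of folds for `"cv"`.
#' @param holdout_fraction test fraction for `"holdout"`.
#' @param seed seed controlling fold assignment / the split.
#' @return An object of class `eval_protocol`.
#' @export
eval_protocol <- function(type = c("cv", "holdout"), folds = 10L,
                          holdout_fraction = 0.3, seed = 1L) {
  type <- match.arg(type)
  if (type == "cv" && folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (type == "holdout" && (holdout_fraction <= 0 || holdout_fraction >= 1)) {
    stop("holdout_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(type = type, folds = as.integer(folds),
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "eval_protocol")
}

protocol_splits <- function(protocol, n) {
  with_seed(protocol$seed, {
    if (protocol$type == "cv") {
      fold <- sample(rep_len(seq_len(protocol$folds), n))
      lapply(seq_len(protocol$folds), function(k) {
        list(train = which(fold != k), test = which(fold == k))
      })
    } else {
      test <- sort(sample.int(n, size = max(1L, round(protocol$holdout_fraction * n))))
      list(list(train = setdiff(seq_len(n), test), test = test))
    }
  })
}

#' Benchmark classifiers before and after MFSS
#'
#' Runs the before-feature-selection (BFS) versus MFSS comparison: for every
#' trainer and every train/test split of the protocol, a multidimensional
#' classifier is fitted twice -- once on all `l` features and once on only the
#' `s` MFSS-selected features -- and evaluated on the held-out instances.
#' The feature subset is recomputed from the *training* portion of each split
#' only (no selection leakage into the test instances) and is by construction
#' identical for every trainer within a split, reflecting the single shared
#' subset that the filter produces.
#'
#' @param x an [mddataset] with no missing values.
#' @param trainers named list of trainer functions, e.g. from
#'   [trainer_registry()].
#' @param protocol an [eval_protocol()].
#' @param s optional subset-size override forwarded to [mfss()].
#' @param absolute forwarded to [mfss()].
#' @return An object of class `mfss_benchmark`: `metrics` (data frame with one
#'   row per classifier x condition), `selection` (the full-data selection, for
#'   reference), `protocol`, and `fold_selections` (selected index sets per
#'   split).
#' @export
compare_bfs_mfss <- function(x, trainers, protocol = eval_protocol(), s = NULL,
                             absolute = FALSE) {
  stopifnot(inherits(x, "mddataset"), inherits(protocol, "eval_protocol"))
  validate_mddataset(x, require_complete = TRUE)
  if (is.null(names(trainers)) || any(!nzchar(names(trainers)))) {
    stop("trainers must be a named list", call. = FALSE)
  }
  n <- nrow(x$features)
  splits <- protocol_splits(protocol, n)
  for (sp in splits) {
    if (length(sp$train) < 2L) stop("protocol leaves < 2 training instances", call. = FALSE)
  }
  truth <- x$targets
  fold_selections <- vector("list", length(splits))
  # per trainer & condition: out-of-fold prediction containers
  pred_bfs <- lapply(trainers, function(tr) truth)
  pred_mfss <- lapply(trainers, function(tr) truth)
  tested <- logical(n)

  for (k in seq_along(splits)) {
    tr_idx <- splits[[k]]$train
    te_idx <- splits[[k]]$test
    train <- subset_mdd(x, rows = tr_idx)
    sel <- mfss(train, s = s, absolute = absolute)
    fold_selections[[k]] <- sel$selected
    test_feats <- x$features[te_idx, , drop = FALSE]
    for (nm in names(trainers)) {
      fit_full <- fit_multidimensional(train, trainers[[nm]], seed = protocol$seed)
      pred_bfs[[nm]][te_idx, ] <- predict(fit_full, test_feats)
      train_sel <- subset_mdd(train, features = sel$selected)
      fit_sel <- fit_multidimensional(train_sel, trainers[[nm]], seed = protocol$seed)
      pred_mfss[[nm]][te_idx, ] <- predict(fit_sel, test_feats[, sel$selected, drop = FALSE])
    }
    tested[te_idx] <- TRUE
  }

  rows <- list()
  for (nm in names(trainers)) {
    for (cond in c("BFS", "MFSS")) {
      pr <- if (cond == "BFS") pred_bfs[[nm]] else pred_mfss[[nm]]
      ms <- metric_set(truth[tested, , drop = FALSE], pr[tested, , drop = FALSE])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(classifier = nm, condition = cond, stringsAsFactors = FALSE), ms)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  structure(list(metrics = metrics,
                 selection = mfss(x, s = s, absolute = absolute),
                 protocol = protocol,
                 fold_selections = fold_selections),
            class = "mfss_benchmark")
}

#' @export
print.mfss_benchmark <- function(x, ...) {
  cat(sprintf("BFS vs MFSS benchmark (%s, seed %d)\n",
              if (x$protocol$type == "cv") sprintf("%d-fold CV", x$protocol$folds)
              else sprintf("%.0f%% holdout", 100 * x$protocol$holdout_fraction),
              x$protocol$seed))
  print(x$metrics, digits = 3)
  invisible(x)
}
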