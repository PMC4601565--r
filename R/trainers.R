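#' Built-in single-target trainers
#'
#' The benchmarking harness is classifier-agnostic: a *trainer* is any function
#' `function(x, y, seed)` taking a numeric feature matrix and a factor class
#' column and returning a *predictor*, a function mapping a feature matrix to a
#' factor of predicted classes whose levels equal the training levels. Training
#' must be deterministic given `seed`. Heavyweight learners (decision trees,
#' SVMs, ...) plug in through the same contract; the bundled trainers are
#' deliberately simple, deterministic baselines:
#'
#' * `trainer_majority()` — always predicts the modal training class (first
#'   level on ties).
#' * `trainer_centroid()` — nearest class centroid in Euclidean distance (ties
#'   to the earlier domain value).
#' * `trainer_knn(k)` — k-nearest-neighbour vote (default `k = 1`); distance
#'   ties resolved by the smaller training index, vote ties by the earlier
#'   domain value.
#' * `trainer_gaussian_nb()` — Gaussian naive Bayes with a small variance
#'   floor.
#'
#' @param k neighbourhood size for `trainer_knn`.
#' @param var_floor minimum per-class feature variance for
#'   `trainer_gaussian_nb`.
#' @return A trainer function.
#' @name trainers
NULL

#' @rdname trainers
#' @export
trainer_majority <- function() {
  function(x, y, seed = 0L) {
    tab <- table(y)
    lab <- names(tab)[which.max(tab)]
    lev <- levels(y)
    function(newx) factor(rep(lab, nrow(as.matrix(newx))), levels = lev)
  }
}

#' @rdname trainers
#' @export
trainer_centroid <- function() {
  function(x, y, seed = 0L) {
    x <- as.matrix(x)
    lev <- levels(y)
    present <- lev[lev %in% unique(as.character(y))]
    cent <- t(vapply(present, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                     double(ncol(x))))
    function(newx) {
      newx <- as.matrix(newx)
      d2 <- outer(rowSums(newx^2), rowSums(cent^2), "+") - 2 * newx %*% t(cent)
      factor(present[max.col(-d2, ties.method = "first")], levels = lev)
    }
  }
}

#' @rdname trainers
#' @export
trainer_knn <- function(k = 1L) {
  force(k)
  function(x, y, seed = 0L) {
    x <- as.matrix(x)
    lev <- levels(y)
    function(newx) {
      newx <- as.matrix(newx)
      d2 <- outer(rowSums(newx^2), rowSums(x^2), "+") - 2 * newx %*% t(x)
      kk <- min(k, nrow(x))
      pred <- apply(d2, 1, function(row) {
        nb <- order(row, seq_along(row))[seq_len(kk)]
        votes <- table(factor(as.character(y[nb]), levels = lev))
        lev[which.max(votes)]
      })
      factor(pred, levels = lev)
    }
  }
}

#' @rdname trainers
#' @export
trainer_gaussian_nb <- function(var_floor = 1e-9) {
  force(var_floor)
  function(x, y, seed = 0L) {
    x <- as.matrix(x)
    lev <- levels(y)
    present <- lev[lev %in% unique(as.character(y))]
    prior <- vapply(present, function(cl) mean(y == cl), double(1))
    mu <- lapply(present, function(cl) colMeans(x[y == cl, , drop = FALSE]))
    v <- lapply(present, function(cl) {
      s <- apply(x[y == cl, , drop = FALSE], 2, stats::var)
      s[is.na(s) | s < var_floor] <- var_floor
      s
    })
    function(newx) {
      newx <- as.matrix(newx)
      ll <- vapply(seq_along(present), function(ci) {
        log(prior[ci]) + rowSums(
          -0.5 * log(2 * pi * rep(1, nrow(newx)) %o% v[[ci]]) -
            0.5 * sweep(newx, 2, mu[[ci]])^2 / (rep(1, nrow(newx)) %o% v[[ci]])
        )
      }, double(nrow(newx)))
      ll <- matrix(ll, nrow = nrow(newx))
      factor(present[max.col(ll, ties.method = "first")], levels = lev)
    }
  }
}

#' Trainer registry
#'
#' Resolves trainer names (as used in configuration files and on the command
#' line) to trainer factories.
#'
#' @param names character vector of trainer names; any of `"majority"`,
#'   `"centroid"`, `"knn"`, `"gaussian_nb"`.
#' @return Named list of trainer functions.
#' @export
trainer_registry <- function(names = c("majority", "centroid")) {
  known <- list(
    majority = trainer_majority,
    centroid = trainer_centroid,
    knn = trainer_knn,
    gaussian_nb = trainer_gaussian_nb
  )
  bad <- setdiff(names, names(known))
  if (length(bad)) {
    stop(sprintf("unknown trainer(s): %s (known: %s)",
                 paste(bad, collapse = ", "),
                 paste(names(known), collapse = ", ")), call. = FALSE)
  }
  stats::setNames(lapply(names, function(nm) known[[nm]]()), names)
}
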