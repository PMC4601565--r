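#' Specification for a synthetic multidimensional dataset
#'
#' Describes a planted-structure generative model that mimics the shape of the
#' binary multi-label benchmarks (several balanced binary class variables, a
#' small set of class-associated features, the rest independent noise).
#'
#' Each class variable is an exactly balanced binary label. An informative
#' feature planted on class `i` with effect size `e` is drawn as
#' `e * z + Normal(0, noise_sd)` where `z` is the +/-1 (sign) encoding of the
#' class; its population correlation with the class is therefore
#' `e / sqrt(e^2 + noise_sd^2)`. Non-planted features are pure
#' `Normal(0, noise_sd)` noise.
#'
#' @param n instances (n >= 3).
#' @param l features (l >= 2).
#' @param m class variables (m >= 1).
#' @param informative data frame with columns `feature` (index in `1..l`),
#'   `class` (index in `1..m`) and `effect` (> 0); at most one planting per
#'   feature. May be empty (pure-noise dataset).
#' @param noise_sd standard deviation of the Gaussian noise (> 0).
#' @param seed integer seed; identical specs generate identical datasets.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n, l, m, informative = NULL, noise_sd = 1, seed = 1L) {
  if (is.null(informative)) {
    informative <- data.frame(feature = integer(0), class = integer(0),
                              effect = numeric(0))
  }
  informative <- as.data.frame(informative)
  stopifnot(all(c("feature", "class", "effect") %in% names(informative)))
  n <- as.integer(n); l <- as.integer(l); m <- as.integer(m)
  if (n < 3L || l < 2L || m < 1L) stop("need n >= 3, l >= 2, m >= 1", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (nrow(informative)) {
    if (any(informative$feature < 1L | informative$feature > l)) {
      stop("informative feature index out of range 1..l", call. = FALSE)
    }
    if (any(informative$class < 1L | informative$class > m)) {
      stop("informative class index out of range 1..m", call. = FALSE)
    }
    if (anyDuplicated(informative$feature)) {
      stop("at most one planting per feature", call. = FALSE)
    }
    if (any(informative$effect <= 0)) stop("effect sizes must be > 0", call. = FALSE)
  }
  structure(list(n = n, l = l, m = m, informative = informative,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic multidimensional dataset
#'
#' @param spec a [synthetic_spec].
#' @return An [mddataset] with feature names `f1..fl` and class names `c1..cm`.
#' @examples
#' sp <- synthetic_spec(n = 100, l = 10, m = 2,
#'                      informative = data.frame(feature = 1:2, class = c(1, 2),
#'                                               effect = 5),
#'                      seed = 42)
#' d <- generate_synthetic(sp)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n; l <- spec$l; m <- spec$m
    # exactly balanced binary classes, independently permuted
    cls <- matrix(0L, n, m)
    for (i in seq_len(m)) cls[, i] <- sample(rep_len(0:1, n))
    feats <- matrix(stats::rnorm(n * l, sd = spec$noise_sd), n, l)
    if (nrow(spec$informative)) {
      for (k in seq_len(nrow(spec$informative))) {
        j <- spec$informative$feature[k]
        i <- spec$informative$class[k]
        e <- spec$informative$effect[k]
        feats[, j] <- feats[, j] + e * (2 * cls[, i] - 1)
      }
    }
    colnames(feats) <- paste0("f", seq_len(l))
    targets <- as.data.frame(lapply(seq_len(m), function(i) factor(cls[, i], levels = 0:1)))
    names(targets) <- paste0("c", seq_len(m))
    mddataset(feats, targets, class_domains = rep(list(c("0", "1")), m))
  })
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
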