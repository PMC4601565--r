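test_that("feature_class_correlation matches the raw-sum oracle and conventions", {
  # hand-built degenerate and perfect cases
  feats <- cbind(f1 = c(0, 1, 0, 1), f2 = c(1, 2, 3, 4),
                 f3 = c(5, 5, 5, 5), f4 = c(4, 3, 2, 1))
  targs <- data.frame(c1 = factor(c("0", "1", "0", "1"), levels = c("0", "1")),
                      c2 = factor(c("1", "1", "0", "0"), levels = c("0", "1")))
  d <- mddataset(feats, targs)
  r <- feature_class_correlation(d)$values
  expect_equal(r["f1", "c1"], 1)                     # feature equals encoding
  expect_equal(unname(r["f3", ]), c(0, 0))           # zero variance -> 0
  expect_equal(r["f2", "c2"], cor(1:4, c(1, 1, 0, 0)))  # sign follows encoding
  expect_equal(cor(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)

  # random blocks agree with the raw-sum formulation to 1e-12
  d6 <- random_mdd(6, 3, 2, seed = 8)
  r6 <- feature_class_correlation(d6)$values
  enc <- sapply(d6$targets, function(t) as.integer(t) - 1)
  for (j in 1:3) for (i in 1:2) {
    expect_equal(r6[j, i], pearson_raw_sums(d6$features[, j], enc[, i]),
                 tolerance = 1e-12)
  }
})

test_that("raw-sum and centered correlation agree to 1e-10 over random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    if (sd(y) == 0) next
    expect_equal(cor(x, y), pearson_raw_sums(x, y), tolerance = 1e-10)
  }
})

test_that("rank_weights assigns l..1 per class with the index tie-break", {
  mk <- function(vals) {
    structure(list(values = matrix(vals, ncol = 1), n_used = 10, absolute = FALSE),
              class = "mfss_correlation")
  }
  expect_equal(as.vector(rank_weights(mk(c(0.2, 0.9, 0.5)))), c(1L, 3L, 2L))
  expect_equal(as.vector(rank_weights(mk(c(0.5, 0.5)))), c(2L, 1L))
  # property: every column is a permutation of 1..l summing to l(l+1)/2
  for (seed in 1:20) {
    d <- random_mdd(12, sample(2:15, 1), sample(1:4, 1), seed = seed)
    w <- rank_weights(feature_class_correlation(d))
    l <- nrow(w)
    for (i in seq_len(ncol(w))) {
      expect_setequal(w[, i], seq_len(l))
      expect_equal(sum(w[, i]), l * (l + 1) / 2)
    }
  }
})

test_that("overall_weights is the rank-weighted convex combination", {
  corr <- structure(list(values = matrix(c(0.9, 0.4), 1, 2), n_used = 5,
                         absolute = FALSE), class = "mfss_correlation")
  w <- matrix(c(3L, 2L), 1, 2)
  expect_equal(unname(overall_weights(corr, w)), (3 * 0.9 + 2 * 0.4) / 5)  # 0.7

  # m = 1 collapse: aggregation is the identity
  d1 <- random_mdd(30, 5, 1, seed = 3)
  c1 <- feature_class_correlation(d1)
  expect_equal(unname(overall_weights(c1, rank_weights(c1))),
               unname(c1$values[, 1]))

  # equal rank weights across classes -> plain mean of the correlations
  cm <- structure(list(values = matrix(c(0.1, 0.8, 0.5, 0.2), 2, 2), n_used = 9,
                       absolute = FALSE), class = "mfss_correlation")
  eq <- matrix(c(2L, 1L, 2L, 1L), 2, 2)
  expect_equal(unname(overall_weights(cm, eq)), rowMeans(cm$values))

  # convex-combination bound on random instances
  for (seed in 1:10) {
    d <- random_mdd(25, 8, 3, seed = seed)
    co <- feature_class_correlation(d)
    ow <- overall_weights(co, rank_weights(co))
    expect_true(all(ow >= apply(co$values, 1, min) - 1e-12))
    expect_true(all(ow <= apply(co$values, 1, max) + 1e-12))
    expect_true(all(abs(ow) <= 1))
  }
})

test_that("subset_size rounds log2(l) half-up and reproduces the benchmark counts", {
  expect_equal(subset_size(28), 5L)
  expect_equal(subset_size(10), 3L)
  expect_equal(subset_size(294), 8L)
  expect_equal(subset_size(71), 6L)
  expect_equal(subset_size(103), 7L)
  expect_equal(subset_size(2), 1L)
  expect_equal(subset_size(3), 2L)   # log2(3) = 1.585 rounds up
  expect_error(subset_size(1), "l >= 2")
})

test_that("mfss recovers planted features and collapses correctly for m = 1", {
  sp <- planted_spec(seed = 123)
  sel <- mfss(generate_synthetic(sp))
  expect_equal(sel$s, subset_size(50))
  expect_setequal(sel$selected, sp$informative$feature)
  expect_equal(sel$selected, sel$ranking[seq_len(sel$s)])

  d1 <- random_mdd(40, 7, 1, seed = 17)
  sel1 <- mfss(d1)
  r1 <- feature_class_correlation(d1)$values[, 1]
  expect_equal(sel1$ranking, order(-r1, seq_along(r1)))
})

test_that("selection is invariant to feature scaling and class order", {
  d <- generate_synthetic(planted_spec(seed = 7, n = 200, l = 20, m = 4))
  sel <- mfss(d)
  # positive affine transform of feature columns leaves everything unchanged
  set.seed(99)
  d2 <- d
  d2$features <- sweep(sweep(d$features, 2, runif(20, 0.5, 3), "*"),
                       2, rnorm(20), "+")
  sel2 <- mfss(d2)
  expect_equal(sel2$correlation$values, sel$correlation$values, tolerance = 1e-12)
  expect_identical(sel2$ranking, sel$ranking)
  expect_identical(sel2$selected, sel$selected)
  # permuting the class variables permutes columns only; the subset is shared
  perm <- c(3, 1, 4, 2)
  d3 <- mddataset(d$features, d$targets[perm],
                  class_domains = d$class_domains[perm])
  expect_setequal(mfss(d3)$selected, sel$selected)
})

test_that("subset-size override, absolute mode and the report surface work", {
  d <- generate_synthetic(planted_spec(seed = 2, n = 100, l = 10, m = 3))
  expect_equal(mfss(d, s = 4)$s, 4L)
  expect_error(mfss(d, s = 11), "1..l")
  df <- as.data.frame(mfss(d))
  expect_equal(nrow(df), 10)
  expect_equal(sum(df$selected), subset_size(10))
  expect_equal(df$rank, 1:10)
  expect_true(all(diff(df$overall_weight) <= 1e-12))
  # absolute mode ranks a strongly negative correlate highly
  set.seed(21)
  targs <- data.frame(c1 = factor(rep(c("0", "1"), 6), levels = c("0", "1")))
  dneg <- mddataset(cbind(f1 = as.numeric(targs$c1 == "1") * -2 + rnorm(12, sd = 0.01),
                          f2 = rnorm(12), f3 = rnorm(12)), targs)
  expect_false(1 %in% mfss(dneg, s = 1)$selected)
  expect_true(1 %in% mfss(dneg, s = 1, absolute = TRUE)$selected)
})
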