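test_that("mddataset enforces its invariants", {
  f <- matrix(rnorm(12), 4, 3)
  t <- data.frame(c1 = c("a", "b", "a", "b"))
  d <- mddataset(f, t)
  expect_s3_class(d, "mddataset")
  expect_equal(unname(dim_mdd(d)), c(4L, 3L, 1L))
  expect_error(mddataset(f[1:2, ], t[1:2, , drop = FALSE]), "n >= 3")
  expect_error(mddataset(f[, 1, drop = FALSE], t), "l >= 2")
  expect_error(mddataset(f, t[, 0, drop = FALSE]), "m >= 1")
  expect_error(mddataset(f, data.frame(c1 = rep("a", 4))), "cardinality")
  expect_error(mddataset(f, t, class_domains = list(c1 = c("a", "c"))), "domain")
})

test_that("ARFF fixtures parse identically under both label dialects", {
  p1 <- withr::local_tempfile(fileext = ".arff")
  write_arff_fixture(p1, "relation")
  d1 <- read_mdd_arff(p1)
  expect_equal(unname(dim_mdd(d1)), c(5L, 3L, 2L))
  expect_equal(d1$class_names, c("L1", "L2"))
  expect_equal(d1$class_domains$L2, c("no", "yes"))
  expect_equal(unname(d1$features[, "f1"]), c(1.5, 2.5, 0.5, 3.5, 2.0))

  p2 <- withr::local_tempfile(fileext = ".arff")
  xml <- withr::local_tempfile(fileext = ".xml")
  write_arff_fixture(p2, "xml", xml_path = xml)
  d2 <- read_mdd_arff(p2, labels = xml)
  expect_equal(d2$features, d1$features)
  expect_identical(d2$targets, d1$targets)

  # explicit count and explicit names match the relation-token result too
  p3 <- withr::local_tempfile(fileext = ".arff")
  write_arff_fixture(p3, "none")
  expect_identical(read_mdd_arff(p3, labels = 2)$targets, d1$targets)
  expect_identical(read_mdd_arff(p3, labels = c("L1", "L2"))$targets, d1$targets)
  # negative count picks trailing attributes instead
  d4 <- read_mdd_arff(p3, labels = -1)
  expect_equal(d4$class_names, "f3")
})

test_that("ARFF errors name the offending line or attribute", {
  p <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation 'x: -C 1'", "@attribute a {0,1}",
               "@attribute b numeric", "@data", "0,1", "0"), p)
  expect_error(read_mdd_arff(p), "line 6")
  writeLines(c("@relation 'x: -C 1'", "@attribute a {0,1}",
               "@attribute b string", "@data", "0,hello"), p)
  expect_error(read_mdd_arff(p), "unsupported attribute type")
  writeLines(c("@relation x", "@attribute a {0,1}",
               "@attribute b numeric", "@data", "0,1"), p)
  expect_error(read_mdd_arff(p, labels = "zzz"), "unknown attribute")
  expect_error(read_mdd_arff(p), "no class attributes")
})

test_that("write/read ARFF round-trip preserves values, names and domains", {
  d <- generate_synthetic(synthetic_spec(20, 4, 2, seed = 5))
  p <- withr::local_tempfile(fileext = ".arff")
  xml <- withr::local_tempfile(fileext = ".xml")
  write_mdd_arff(d, p, xml_labels = xml)
  for (back in list(read_mdd_arff(p), read_mdd_arff(p, labels = xml))) {
    expect_equal(back$features, d$features)
    expect_identical(back$targets, d$targets)
    expect_identical(back$class_domains, d$class_domains)
  }
  # nominal feature columns are integer-encoded in declaration order
  p2 <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation 'x: -C 1'", "@attribute y {0,1}",
               "@attribute col {low,mid,high}", "@attribute f numeric",
               "@data", "0,low,1", "1,high,2", "0,mid,3"), p2)
  d2 <- read_mdd_arff(p2)
  expect_equal(unname(d2$features[, "col"]), c(0, 2, 1))
})

test_that("the hand-rolled parser agrees with an independent ARFF reader", {
  # comment-free fixture: the reference reader rejects inline % comments
  p <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation 'toy: -C 2'",
               "@attribute L1 {0,1}", "@attribute L2 {no,yes}",
               "@attribute f1 numeric", "@attribute f2 real",
               "@attribute f3 integer",
               "@data",
               "0,no,1.5,2,3", "1,yes,2.5,1,4", "0,no,0.5,3,5",
               "1,yes,3.5,0,6", "1,no,2.0,2,7"), p)
  py <- sprintf(
    "from scipy.io import arff; import sys; d, m = arff.loadarff('%s')\nfor row in d: print(','.join(str(v, 'utf-8') if isinstance(v, bytes) else repr(float(v)) for v in row))",
    p)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  oracle <- do.call(rbind, strsplit(out, ","))
  d <- read_mdd_arff(p)
  expect_equal(matrix(as.numeric(oracle[, 3:5]), ncol = 3), unname(d$features))
  expect_equal(oracle[, 1], as.character(d$targets$L1))
  expect_equal(oracle[, 2], as.character(d$targets$L2))
})

test_that("read_mdd_table splits features from declared target columns", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("f1,f2,c1", "1,4,a", "2,3,b", "3,2,a", "4,1,b"), p)
  d <- read_mdd_table(p, "c1")
  expect_equal(unname(dim_mdd(d)), c(4L, 2L, 1L))
  expect_equal(d$class_domains$c1, c("a", "b"))
  expect_error(read_mdd_table(p, character(0)), "m >= 1")
  expect_error(read_mdd_table(p, c("c1", "nope")), "nope")
  # 4-row toy table: correlation matches hand Pearson computation
  r <- feature_class_correlation(d)$values
  enc <- c(0, 1, 0, 1)
  expect_equal(unname(r[, 1]),
               c(cor(c(1, 2, 3, 4), enc), cor(c(4, 3, 2, 1), enc)),
               tolerance = 1e-12)
})

test_that("impute_missing applies mean/mode fills, drops class-missing rows, and is idempotent", {
  feats <- cbind(f1 = c(1, NA, 3, 10, 20, 30, 1, 2, 3, 4),
                 f2 = c(2, 2, NA, 2, 4, 4, 4, 1, 1, 1))
  targs <- data.frame(c1 = factor(c("a", "b", "a", "b", NA, "a", "b", "a", NA, "b"),
                                  levels = c("a", "b")))
  d <- mddataset(feats, targs, class_domains = list(c1 = c("a", "b")))
  out <- impute_missing(d)
  expect_equal(unname(dim_mdd(out)["n"]), 8L)        # 2 of 10 rows dropped
  expect_false(anyNA(out$features))
  # [1, ?, 3, ...] -> gap replaced by the mean of observed values
  obs <- feats[-c(5, 9), "f1"]
  expect_equal(unname(out$features[2, "f1"]), mean(obs, na.rm = TRUE))
  # mode fill for declared-nominal encoded features
  out2 <- impute_missing(d, nominal_features = "f2")
  expect_equal(unname(out2$features[3, "f2"]), 2)
  # identity on complete data, idempotent in general
  expect_equal(impute_missing(out), out)
  full <- generate_synthetic(synthetic_spec(10, 3, 1, seed = 2))
  expect_equal(impute_missing(full), full)
  # all-missing feature is an error naming the feature
  feats2 <- feats; feats2[, "f2"] <- NA
  d2 <- mddataset(feats2, targs, class_domains = list(c1 = c("a", "b")))
  expect_error(impute_missing(d2), "f2")
})

test_that("generate_synthetic is seed-deterministic with the planted structure", {
  sp <- synthetic_spec(200, 8, 2,
                       informative = data.frame(feature = c(1, 2), class = c(1, 2),
                                                effect = 5),
                       noise_sd = 1, seed = 99)
  d1 <- generate_synthetic(sp)
  d2 <- generate_synthetic(sp)
  expect_identical(d1$features, d2$features)
  expect_identical(d1$targets, d2$targets)
  # balanced binary classes
  expect_true(all(vapply(d1$targets, function(t) sum(t == "1"), numeric(1)) == 100))
  # planted features dominate every noise feature's correlation
  r <- abs(feature_class_correlation(d1)$values)
  expect_gt(min(r[1, 1], r[2, 2]), max(r[3:8, ]))
  # null structure: with nothing planted all |r| stay below 3/sqrt(n)
  d0 <- generate_synthetic(synthetic_spec(500, 10, 2, seed = 4))
  r0 <- abs(feature_class_correlation(d0)$values)
  expect_lt(max(r0), 3 / sqrt(500))
  # invalid specs
  expect_error(synthetic_spec(100, 4, 1,
                              informative = data.frame(feature = 9, class = 1, effect = 1)),
               "out of range")
  expect_error(synthetic_spec(100, 4, 1,
                              informative = data.frame(feature = 1, class = 1, effect = 0)),
               "> 0")
})

test_that("planted-pair correlation converges to effect/sqrt(effect^2 + sd^2)", {
  e <- 2; sd <- 1.5
  sp <- synthetic_spec(1e4, 3, 1,
                       informative = data.frame(feature = 1, class = 1, effect = e),
                       noise_sd = sd, seed = 31)
  r <- feature_class_correlation(generate_synthetic(sp))$values[1, 1]
  expect_equal(r, e / sqrt(e^2 + sd^2), tolerance = 0.05)
})
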