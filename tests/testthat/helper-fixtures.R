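# Shared fixtures and independent oracles, built in code at test time.

# Eq.-style raw-sum Pearson correlation: the independent oracle for the
# centered/cov implementation used by the package.
pearson_raw_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# small dense multi-label ARFF fixture: 5 instances, 3 numeric features,
# 2 binary labels; `dialect` controls how the labels are declared.
write_arff_fixture <- function(path, dialect = c("relation", "xml", "none"),
                               xml_path = NULL) {
  dialect <- match.arg(dialect)
  relation <- switch(dialect,
    relation = "@relation 'toy: -C 2'",
    "@relation toy")
  lines <- c(
    relation,
    "",
    "@attribute L1 {0,1}",
    "@attribute L2 {no,yes}",
    "@attribute f1 numeric",
    "@attribute f2 real",
    "@attribute f3 integer",
    "",
    "@data",
    "0,no,1.5,2,3",
    "1,yes,2.5,1,4   % trailing comment",
    "0,no,0.5,3,5",
    "1,yes,3.5,0,6",
    "1,no,2.0,2,7"
  )
  writeLines(lines, path)
  if (dialect == "xml") {
    writeLines(c(
      "<labels xmlns=\"http://mulan.sourceforge.net/labels\">",
      "  <label name=\"L1\"/>",
      "  <label name=\"L2\"/>",
      "</labels>"
    ), xml_path)
  }
  invisible(path)
}

# random complete dataset with nominal class variables of cardinality K
random_mdd <- function(n, l, m, K = 2, seed = 1) {
  set.seed(seed)
  feats <- matrix(rnorm(n * l), n, l, dimnames = list(NULL, paste0("f", 1:l)))
  targs <- as.data.frame(lapply(seq_len(m), function(i) {
    factor(sample(letters[1:K], n, replace = TRUE), levels = letters[1:K])
  }))
  names(targs) <- paste0("c", seq_len(m))
  mddataset(feats, targs, class_domains = rep(list(letters[1:K]), m))
}

# planted-recovery design used across tests: one informative feature per class
planted_spec <- function(seed, n = 500, l = 50, m = 6, effect = 5, noise_sd = 1) {
  s <- subset_size(l)
  stopifnot(m >= s)
  synthetic_spec(n = n, l = l, m = m,
                 informative = data.frame(feature = seq_len(s),
                                          class = seq_len(s),
                                          effect = effect),
                 noise_sd = noise_sd, seed = seed)
}

# frozen reference statistics for the bundled benchmark metric tables
reference_validation <- function() {
  data.frame(
    classifier = rep(c("J48", "NaiveBayes", "SVM", "IBk"), each = 2),
    metric = rep(c("hamming_score", "exact_match"), 4),
    r = c(0.914, 0.943, 0.867, 0.908, 0.801, 0.853, 0.859, 0.878),
    t = c(0.675, 1.111, 0.376, 0.166, 1.549, 1.577, 1.239, 1.110),
    stringsAsFactors = FALSE
  )
}
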