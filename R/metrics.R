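#' Multi-label evaluation metrics
#'
#' Cell-wise and instance-wise agreement measures between a true and a
#' predicted `n x m` class matrix. The Hamming metrics are defined over class
#' variables of any cardinality (fraction of disagreeing cells), which reduces
#' to the usual multi-label definition for binary labels. Two identities hold
#' on every input: `hamming_score + hamming_loss = 1` and
#' `exact_match + zero_one_loss = 1`.
#'
#' @param true,pred matrices or data frames of identical shape holding class
#'   values (factors, characters or numbers; compared after character
#'   conversion).
#' @return A fraction in `[0, 1]`.
#' @name ml_metrics
NULL

as_label_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(as.data.frame(lapply(x, as.character)))
  if (!is.matrix(x)) x <- as.matrix(x)
  matrix(as.character(x), nrow = nrow(x), ncol = ncol(x))
}

check_label_shapes <- function(true, pred) {
  true <- as_label_matrix(true)
  pred <- as_label_matrix(pred)
  if (!all(dim(true) == dim(pred))) {
    stop(sprintf("shape mismatch: true is %dx%d, pred is %dx%d",
                 nrow(true), ncol(true), nrow(pred), ncol(pred)), call. = FALSE)
  }
  if (nrow(true) == 0L) stop("empty label matrices", call. = FALSE)
  list(true = true, pred = pred)
}

#' @rdname ml_metrics
#' @export
hamming_loss <- function(true, pred) {
  z <- check_label_shapes(true, pred)
  mean(z$true != z$pred)
}

#' @rdname ml_metrics
#' @export
hamming_score <- function(true, pred) 1 - hamming_loss(true, pred)

#' @rdname ml_metrics
#' @export
exact_match <- function(true, pred) {
  z <- check_label_shapes(true, pred)
  mean(rowSums(z$true != z$pred) == 0L)
}

#' @rdname ml_metrics
#' @export
zero_one_loss <- function(true, pred) 1 - exact_match(true, pred)

#' Example-based precision, recall and F1
#'
#' Instance-averaged precision/recall/F1 for binary label matrices. For an
#' instance, precision is the fraction of predicted labels that are true and
#' recall the fraction of true labels that are predicted. An instance with both
#' the true and the predicted label set empty contributes 1 to all three
#' measures; an empty predicted (resp. true) set against a non-empty
#' counterpart contributes 0 to precision (resp. recall); F1 is 0 when
#' precision + recall is 0.
#'
#' @param true,pred binary (0/1 or logical) matrices of equal shape.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
example_prf <- function(true, pred) {
  true <- as.matrix(true); pred <- as.matrix(pred)
  if (!all(dim(true) == dim(pred))) stop("shape mismatch", call. = FALSE)
  ok <- function(m) all(m %in% c(0, 1, TRUE, FALSE))
  if (!ok(true) || !ok(pred)) {
    stop("example_prf requires binary (0/1) label matrices", call. = FALSE)
  }
  true <- matrix(as.numeric(true), nrow(true)); pred <- matrix(as.numeric(pred), nrow(pred))
  inter <- rowSums(true * pred)
  nt <- rowSums(true); np <- rowSums(pred)
  p <- ifelse(np > 0, inter / np, as.numeric(nt == 0))
  r <- ifelse(nt > 0, inter / nt, as.numeric(np == 0))
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  f[nt == 0 & np == 0] <- 1
  c(precision = mean(p), recall = mean(r), f1 = mean(f))
}

#' Full metric set for one prediction
#'
#' @param true,pred class matrices as for [hamming_loss()].
#' @param binary_prf also compute example-based precision/recall/F1 (requires
#'   binary labels); defaults to `TRUE` when all values are 0/1.
#' @return A one-row data frame with columns `hamming_score`, `hamming_loss`,
#'   `exact_match`, `zero_one_loss` and, when available, `precision`,
#'   `recall`, `f1`.
#' @export
metric_set <- function(true, pred, binary_prf = NULL) {
  z <- check_label_shapes(true, pred)
  hl <- mean(z$true != z$pred)
  em <- mean(rowSums(z$true != z$pred) == 0L)
  out <- data.frame(hamming_score = 1 - hl, hamming_loss = hl,
                    exact_match = em, zero_one_loss = 1 - em)
  if (is.null(binary_prf)) {
    binary_prf <- all(z$true %in% c("0", "1")) && all(z$pred %in% c("0", "1"))
  }
  if (isTRUE(binary_prf)) {
    prf <- example_prf(matrix(as.numeric(z$true), nrow(z$true)),
                       matrix(as.numeric(z$pred), nrow(z$pred)))
    out$precision <- prf[["precision"]]
    out$recall <- prf[["recall"]]
    out$f1 <- prf[["f1"]]
  }
  out
}
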