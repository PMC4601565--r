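#' Read a delimited table as a multidimensional dataset
#'
#' Reads a CSV/TSV file with a header row and splits its columns into features
#' and class variables. Every column not named in `target_columns` becomes a
#' feature; non-numeric feature columns are integer-encoded (codes `0..K-1` in
#' order of first appearance). Class domains are inferred from the observed
#' values, sorted.
#'
#' @param path path to the delimited file.
#' @param target_columns character vector (length >= 1) of class-variable
#'   column names.
#' @param sep field separator; by default inferred from the file extension
#'   (`.tsv`/`.tab` -> tab, otherwise comma).
#' @param na_strings values interpreted as missing.
#' @return An [mddataset].
#' @export
read_mdd_table <- function(path, target_columns,
                           sep = NULL,
                           na_strings = c("", "?", "NA")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (length(target_columns) < 1L) {
    stop("target_columns must name at least one class variable (m >= 1)", call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = na_strings, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(target_columns, names(df))
  if (length(missing)) {
    stop(sprintf("target column(s) not present: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  feat_cols <- setdiff(names(df), target_columns)
  features <- vapply(df[feat_cols], function(col) {
    if (is.numeric(col)) as.double(col)
    else as.double(as.integer(factor(col, levels = unique(col[!is.na(col)]))) - 1L)
  }, double(nrow(df)))
  features <- matrix(features, nrow = nrow(df), dimnames = list(NULL, feat_cols))
  mddataset(features, df[target_columns])
}

#' Write the selection report
#'
#' Tab-separated report with one row per feature: name, overall weight,
#' per-class correlations, rank position and the selected flag.
#'
#' @param sel an [mfss] selection result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(sel, path) {
  stopifnot(inherits(sel, "mfss_selection"))
  df <- as.data.frame(sel)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
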