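#' Read a multi-label ARFF file
#'
#' Parses the dense ARFF dialects commonly used for multi-label and
#' multidimensional benchmarks. The class (label) attributes may be declared in
#' either of the two circulating conventions:
#' * a `-C m` token inside the relation name (`@relation 'flags: -C 3'`);
#'   positive `m` marks the first `m` attributes as class variables, negative
#'   `m` the last `|m|`;
#' * an accompanying XML label list (`<labels><label name="..."/></labels>`)
#'   naming the class attributes.
#'
#' Numeric attributes pass through unchanged. Nominal feature attributes are
#' integer-encoded (codes `0..K-1` in declaration order) so that all features
#' are numeric; nominal class attributes keep their declared domains. `?`
#' entries become missing values.
#'
#' @param path path to the ARFF file.
#' @param labels label specification, one of: `NULL` (use the `-C` token in the
#'   relation name, or a `<path>.xml` file next to `path` if present), an
#'   integer count (sign as for `-C`), a character vector of attribute names,
#'   or the path to an XML label list.
#' @return An [mddataset].
#' @seealso [write_mdd_arff()] for the inverse operation.
#' @export
read_mdd_arff <- function(path, labels = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- parse_arff(path)
  label_names <- resolve_label_spec(labels, raw, path)
  if (length(label_names) == 0L) {
    stop("no class attributes identified: supply `labels` or a -C relation token",
         call. = FALSE)
  }
  is_label <- raw$names %in% label_names
  feat_idx <- which(!is_label)
  lab_idx <- match(label_names, raw$names)

  features <- do.call(cbind, lapply(feat_idx, function(j) encode_arff_column(raw, j)))
  colnames(features) <- raw$names[feat_idx]
  targets <- as.data.frame(raw$data[lab_idx], optional = TRUE)
  names(targets) <- raw$names[lab_idx]
  domains <- lapply(lab_idx, function(j) {
    if (is.null(raw$domains[[j]])) {
      # numeric class attribute: domain inferred from observed values
      as.character(sort(unique(stats::na.omit(raw$data[[j]]))))
    } else raw$domains[[j]]
  })
  names(domains) <- raw$names[lab_idx]
  mddataset(features, targets, class_domains = domains)
}

#' Write a multi-label ARFF file
#'
#' Emits a dense ARFF file with the class attributes first and a `-C m` token
#' in the relation name, so [read_mdd_arff()] round-trips without extra
#' configuration. Missing entries are written as `?`.
#'
#' @param x an [mddataset].
#' @param path output path.
#' @param relation relation name stem (the `-C m` token is appended).
#' @param xml_labels optional path for an XML label list mirroring the `-C`
#'   declaration (the Mulan convention); written only when non-`NULL`.
#' @return `path`, invisibly.
#' @export
write_mdd_arff <- function(x, path, relation = "mdd", xml_labels = NULL) {
  stopifnot(inherits(x, "mddataset"))
  m <- length(x$class_names)
  header <- c(
    sprintf("@relation '%s: -C %d'", relation, m),
    "",
    vapply(seq_len(m), function(i) {
      sprintf("@attribute %s {%s}", quote_arff(x$class_names[i]),
              paste(quote_arff(x$class_domains[[i]]), collapse = ","))
    }, character(1)),
    vapply(x$feature_names, function(f) {
      sprintf("@attribute %s numeric", quote_arff(f))
    }, character(1)),
    "",
    "@data"
  )
  tcells <- vapply(x$targets, function(col) {
    v <- quote_arff(as.character(col))
    v[is.na(col)] <- "?"
    v
  }, character(nrow(x$features)))
  tcells <- matrix(tcells, nrow = nrow(x$features))
  fcells <- apply(x$features, 2, function(col) {
    v <- format_arff_num(col)
    v[is.na(col)] <- "?"
    v
  })
  fcells <- matrix(fcells, nrow = nrow(x$features))
  rows <- apply(cbind(tcells, fcells), 1, paste, collapse = ",")
  writeLines(c(header, rows), path)
  if (!is.null(xml_labels)) {
    doc <- xml2::xml_new_root("labels",
                              xmlns = "http://mulan.sourceforge.net/labels")
    for (nm in x$class_names) {
      xml2::xml_add_child(doc, "label", name = nm)
    }
    xml2::write_xml(doc, xml_labels)
  }
  invisible(path)
}

format_arff_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) return("?")
    if (!is.finite(z)) stop("non-finite feature value cannot be written", call. = FALSE)
    # full precision round-trip
    format(z, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

quote_arff <- function(s) {
  needs <- grepl("[ ,{}'\"%]", s)
  s[needs] <- sprintf("'%s'", gsub("'", "\\\\'", s[needs]))
  s
}

# ---- parser -----------------------------------------------------------------

parse_arff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  relation <- NULL
  att_names <- character(0)
  att_types <- character(0)     # "numeric" or "nominal"
  att_domains <- list()
  data_rows <- list()
  in_data <- FALSE
  n_att <- 0L

  for (ln in seq_along(lines)) {
    line <- trim_arff(lines[ln])
    if (!nzchar(line)) next
    if (!in_data) {
      low <- tolower(line)
      if (startsWith(low, "@relation")) {
        relation <- trimws(sub("^@relation", "", line, ignore.case = TRUE))
        relation <- unquote_arff(relation)
      } else if (startsWith(low, "@attribute")) {
        spec <- trimws(sub("^@attribute", "", line, ignore.case = TRUE))
        att <- parse_attribute(spec, ln)
        n_att <- n_att + 1L
        att_names[n_att] <- att$name
        att_types[n_att] <- att$type
        att_domains[n_att] <- list(att$domain)  # keep NULL slots for numeric
      } else if (startsWith(low, "@data")) {
        if (n_att == 0L) stop(sprintf("ARFF parse error at line %d: @data before any @attribute", ln),
                              call. = FALSE)
        in_data <- TRUE
      } else {
        stop(sprintf("ARFF parse error at line %d: unrecognized declaration '%s'",
                     ln, substr(line, 1, 40)), call. = FALSE)
      }
    } else {
      if (startsWith(line, "{")) {
        stop(sprintf("ARFF parse error at line %d: sparse data rows are not supported", ln),
             call. = FALSE)
      }
      vals <- split_csv_arff(line, ln)
      if (length(vals) != n_att) {
        stop(sprintf("ARFF parse error at line %d: %d values for %d attributes",
                     ln, length(vals), n_att), call. = FALSE)
      }
      data_rows[[length(data_rows) + 1L]] <- vals
    }
  }
  if (is.null(relation)) stop("ARFF parse error: missing @relation declaration", call. = FALSE)
  if (!in_data) stop("ARFF parse error: missing @data section", call. = FALSE)

  cells <- matrix("", nrow = length(data_rows), ncol = n_att)
  for (i in seq_along(data_rows)) cells[i, ] <- data_rows[[i]]
  cols <- vector("list", n_att)
  for (j in seq_len(n_att)) {
    v <- cells[, j]
    v[v == "?"] <- NA_character_
    if (att_types[j] == "numeric") {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop(sprintf("ARFF parse error: non-numeric value '%s' in numeric attribute '%s'",
                     v[bad[1L]], att_names[j]), call. = FALSE)
      }
      cols[[j]] <- num
    } else {
      bad <- which(!is.na(v) & !(v %in% att_domains[[j]]))
      if (length(bad)) {
        stop(sprintf("ARFF parse error: value '%s' outside the domain of attribute '%s'",
                     v[bad[1L]], att_names[j]), call. = FALSE)
      }
      cols[[j]] <- factor(v, levels = att_domains[[j]])
    }
  }
  list(relation = relation, names = att_names, types = att_types,
       domains = att_domains, data = cols)
}

parse_attribute <- function(spec, ln) {
  if (startsWith(spec, "'") || startsWith(spec, "\"")) {
    q <- substr(spec, 1, 1)
    end <- regexpr(paste0("(?<!\\\\)", q), substr(spec, 2, nchar(spec)), perl = TRUE)
    if (end < 0) stop(sprintf("ARFF parse error at line %d: unterminated quote", ln), call. = FALSE)
    name <- unquote_arff(substr(spec, 1, end + 1L))
    rest <- trimws(substr(spec, end + 2L, nchar(spec)))
  } else {
    sp <- regexpr("[ \t]", spec)
    if (sp < 0) stop(sprintf("ARFF parse error at line %d: attribute without a type", ln), call. = FALSE)
    name <- substr(spec, 1, sp - 1L)
    rest <- trimws(substr(spec, sp + 1L, nchar(spec)))
  }
  low <- tolower(rest)
  if (low %in% c("numeric", "real", "integer")) {
    list(name = name, type = "numeric", domain = NULL)
  } else if (startsWith(rest, "{")) {
    if (!endsWith(rest, "}")) {
      stop(sprintf("ARFF parse error at line %d: unterminated nominal domain", ln), call. = FALSE)
    }
    inner <- substr(rest, 2, nchar(rest) - 1L)
    dom <- split_csv_arff(inner, ln)
    if (length(dom) < 1L) {
      stop(sprintf("ARFF parse error at line %d: empty nominal domain", ln), call. = FALSE)
    }
    list(name = name, type = "nominal", domain = dom)
  } else {
    stop(sprintf("ARFF parse error at line %d: unsupported attribute type '%s'", ln, rest),
         call. = FALSE)
  }
}

# split a comma-separated ARFF payload, honouring single/double quotes
split_csv_arff <- function(line, ln) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  out <- character(0)
  buf <- character(0)
  quote <- ""
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (nzchar(quote)) {
      if (ch == "\\" && i < length(chars) && chars[i + 1L] == quote) {
        buf <- c(buf, quote); i <- i + 1L
      } else if (ch == quote) {
        quote <- ""
      } else buf <- c(buf, ch)
    } else if (ch == "'" || ch == "\"") {
      quote <- ch
    } else if (ch == ",") {
      out <- c(out, trimws(paste(buf, collapse = "")))
      buf <- character(0)
    } else buf <- c(buf, ch)
    i <- i + 1L
  }
  if (nzchar(quote)) stop(sprintf("ARFF parse error at line %d: unterminated quote", ln), call. = FALSE)
  c(out, trimws(paste(buf, collapse = "")))
}

trim_arff <- function(line) {
  # strip unquoted % comments
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  quote <- ""
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (nzchar(quote)) {
      if (ch == quote) quote <- ""
    } else if (ch == "'" || ch == "\"") {
      quote <- ch
    } else if (ch == "%") {
      return(trimws(paste(chars[seq_len(i - 1L)], collapse = "")))
    }
  }
  trimws(line)
}

unquote_arff <- function(s) {
  s <- trimws(s)
  if (nchar(s) >= 2 && substr(s, 1, 1) %in% c("'", "\"") &&
      substr(s, nchar(s), nchar(s)) == substr(s, 1, 1)) {
    q <- substr(s, 1, 1)
    s <- substr(s, 2, nchar(s) - 1L)
    s <- gsub(paste0("\\\\", q), q, s)
  }
  s
}

resolve_label_spec <- function(labels, raw, path) {
  if (is.null(labels)) {
    cm <- relation_label_count(raw$relation)
    if (!is.na(cm)) return(count_to_names(cm, raw$names))
    xml <- paste0(tools::file_path_sans_ext(path), ".xml")
    if (file.exists(xml)) return(read_label_xml(xml, raw$names))
    return(character(0))
  }
  if (is.numeric(labels) && length(labels) == 1L) {
    return(count_to_names(as.integer(labels), raw$names))
  }
  if (is.character(labels) && length(labels) == 1L &&
      grepl("\\.xml$", labels, ignore.case = TRUE)) {
    return(read_label_xml(labels, raw$names))
  }
  if (is.character(labels)) {
    missing <- setdiff(labels, raw$names)
    if (length(missing)) {
      stop(sprintf("label specification names unknown attribute(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    return(labels)
  }
  stop("unsupported `labels` specification", call. = FALSE)
}

relation_label_count <- function(relation) {
  m <- regmatches(relation, regexec("-[Cc][ \t]+(-?[0-9]+)", relation))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

count_to_names <- function(cm, att_names) {
  n_att <- length(att_names)
  if (cm == 0L || abs(cm) >= n_att) {
    stop(sprintf("label count %d invalid for %d attributes", cm, n_att), call. = FALSE)
  }
  if (cm > 0L) att_names[seq_len(cm)] else att_names[seq(n_att + cm + 1L, n_att)]
}

read_label_xml <- function(xml_path, att_names) {
  if (!file.exists(xml_path)) stop(sprintf("label list not found: %s", xml_path), call. = FALSE)
  doc <- xml2::read_xml(xml_path)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='label']")
  nm <- xml2::xml_attr(nodes, "name")
  nm <- nm[!is.na(nm)]
  missing <- setdiff(nm, att_names)
  if (length(missing)) {
    stop(sprintf("label list names unknown attribute(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  nm
}

encode_arff_column <- function(raw, j) {
  if (raw$types[j] == "numeric") raw$data[[j]]
  else as.double(as.integer(raw$data[[j]]) - 1L)
}
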