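#' Read an abundance matrix and its sample design table
#'
#' The matrix TSV has a header row of sample ids and a first column of
#' feature ids; the design TSV has columns `sample_id`, `zt`, `condition`,
#' `replicate` and optionally `regime` (defaulted to "LD"). Validation is
#' strict: duplicate feature or sample ids, sample-id mismatches between the
#' two files, non-numeric or negative abundances, and zeitgeber times
#' outside [0, 24) are all errors naming the offending entry. Missing
#' abundances are empty cells (read as NA), never zeros. Matrix columns are
#' reordered to the design row order.
#'
#' @param matrix_path path to the abundance TSV.
#' @param design_path path to the design TSV.
#' @return list with `matrix` (numeric feature x sample matrix) and
#'   `design` (data frame).
#' @export
read_matrix <- function(matrix_path, design_path) {
  raw <- utils::read.delim(matrix_path,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  feat <- as.character(raw[[1]])
  if (anyDuplicated(feat)) {
    stop(
      "duplicate feature ids: ",
      paste(unique(feat[duplicated(feat)]), collapse = ", ")
    )
  }
  vals <- raw[, -1, drop = FALSE]
  if (anyDuplicated(names(vals))) {
    stop(
      "duplicate sample ids in matrix: ",
      paste(unique(names(vals)[duplicated(names(vals))]), collapse = ", ")
    )
  }
  for (cn in names(vals)) {
    v <- vals[[cn]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & v != "" & is.na(conv)
      if (any(bad)) {
        stop(
          "non-numeric abundance in sample ", cn, ", feature ",
          feat[which(bad)[1]], ": '", v[which(bad)[1]], "'"
        )
      }
      vals[[cn]] <- conv
    }
  }
  M <- as.matrix(vals)
  rownames(M) <- feat
  neg <- which(!is.na(M) & M < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(
      "negative abundance for feature ", feat[neg[1, 1]],
      " in sample ", colnames(M)[neg[1, 2]]
    )
  }
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  if ("zt" %in% names(design)) design$zt <- as.numeric(design$zt)
  req <- c("sample_id", "zt", "condition", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss) > 0) {
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!"regime" %in% names(design)) design$regime <- "LD"
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id)) {
    stop(
      "duplicate sample ids in design: ",
      paste(unique(design$sample_id[duplicated(design$sample_id)]),
        collapse = ", "
      )
    )
  }
  if (any(!is.finite(design$zt)) || any(design$zt < 0 | design$zt >= 24)) {
    stop(
      "zt outside [0, 24) for sample(s): ",
      paste(design$sample_id[!is.finite(design$zt) |
        design$zt < 0 | design$zt >= 24], collapse = ", ")
    )
  }
  not_in_mat <- setdiff(design$sample_id, colnames(M))
  if (length(not_in_mat) > 0) {
    stop(
      "design sample id(s) absent from the matrix: ",
      paste(not_in_mat, collapse = ", ")
    )
  }
  not_in_design <- setdiff(colnames(M), design$sample_id)
  if (length(not_in_design) > 0) {
    stop(
      "matrix sample id(s) absent from the design: ",
      paste(not_in_design, collapse = ", ")
    )
  }
  list(matrix = M[, design$sample_id, drop = FALSE], design = design)
}

#' Write an abundance matrix and design table as TSV
#'
#' Numeric values are written at full (17 significant digit) precision so
#' that write followed by [read_matrix()] restores bit-identical values.
#' Missing abundances become empty cells.
#'
#' @param mat numeric feature x sample matrix with dimnames.
#' @param design matching sample design table.
#' @param matrix_path,design_path output paths.
#' @export
write_matrix <- function(mat, design, matrix_path, design_path) {
  df <- data.frame(
    feature_id = rownames(mat),
    apply(mat, 2, .fmt_num),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(df) <- c("feature_id", colnames(mat))
  utils::write.table(df, matrix_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = ""
  )
  write_results(design, design_path, format = "tsv")
  invisible(c(matrix_path, design_path))
}

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- NA_character_
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`, then
#' members. Duplicate members within a set are collapsed; a line with fewer
#' than 3 fields or a repeated set name is an error. An empty file yields an
#' empty collection.
#'
#' @param path path to the GMT file.
#' @return named list; each element has `description` and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(list(), names = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 fields")
  }
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop(
      "duplicate gene-set name(s): ",
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    )
  }
  sets <- lapply(parts, function(p) {
    list(description = p[2], members = unique(p[-(1:2)]))
  })
  names(sets) <- nm
  sets
}

#' Write a result table as TSV or JSON
#'
#' TSV output formats numeric columns at 17 significant digits (lossless for
#' doubles); JSON output keeps full precision via jsonlite. Column order is
#' preserved. [read_results()] restores the table with equal values.
#'
#' @param table a data frame.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(table, path,
      dataframe = "columns", digits = I(17),
      na = "null", auto_unbox = FALSE
    )
    return(invisible(path))
  }
  out <- table
  for (cn in names(out)) {
    if (is.double(out[[cn]])) out[[cn]] <- .fmt_num(out[[cn]])
  }
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA"
  )
  invisible(path)
}

#' Read a table written by [write_results()]
#'
#' @param path input path.
#' @param format `"tsv"` or `"json"`.
#' @return data frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    cols <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(as.data.frame(cols, stringsAsFactors = FALSE))
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}
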