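#' @title Feature matrices
#'
#' @description
#' Throughout this package a *feature matrix* is a plain numeric matrix with
#' samples in rows and features in columns, unique `rownames` (sample
#' identifiers), unique `colnames` (feature identifiers), and `NA` marking
#' missing entries. [read_matrix()] produces this representation from
#' delimited text and [write_matrix()] writes it back byte-stably.
#'
#' @name feature-matrix
#' @keywords internal
NULL

#' Validate a feature matrix
#'
#' Checks the invariants of the samples-by-features representation: at least
#' two samples, at least one feature, unique sample and feature identifiers,
#' and all non-missing values finite.
#'
#' @param x numeric matrix, samples in rows.
#' @param allow_missing logical; if `FALSE`, any `NA` entry is an error.
#' @return `x`, invisibly, after validation.
#' @export
validate_feature_matrix <- function(x, allow_missing = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("feature matrix must be a numeric matrix (samples x features)")
  }
  if (nrow(x) < 2L) stop("feature matrix needs at least 2 samples")
  if (ncol(x) < 1L) stop("feature matrix needs at least 1 feature")
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x))) {
    stop("duplicate sample identifiers")
  }
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) {
    stop("duplicate feature identifiers")
  }
  if (!allow_missing && anyNA(x)) {
    stop("feature matrix contains missing values; impute first")
  }
  if (any(is.infinite(x))) stop("feature matrix contains non-finite values")
  invisible(x)
}

# Attach default identifiers where the input had none.
.default_dimnames <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Read a delimited feature matrix
#'
#' Reads a delimited text file (CSV by default) into a samples-by-features
#' numeric matrix. The first row holds feature identifiers and the first
#' column sample identifiers. Cells must parse as numbers or match one of
#' the declared missing-value tokens, which become `NA`.
#'
#' @param path path to the file.
#' @param delimiter field separator, `","` by default.
#' @param orientation `"samples_in_rows"` (default) if rows are samples, or
#'   `"features_in_rows"` to transpose on read.
#' @param missing_tokens character vector of cell values treated as missing.
#' @return a numeric matrix, samples in rows, with `NA` for missing entries.
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("id,g1,g2", "s1,1,4", "s2,2,NA", "s3,3,6"), p)
#' read_matrix(p)
read_matrix <- function(path, delimiter = ",",
                        orientation = c("samples_in_rows", "features_in_rows"),
                        missing_tokens = c("NA", "NaN", "")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"",
                            comment.char = "")
  if (length(unique(nf)) != 1L) {
    stop("malformed matrix file: rows have unequal numbers of fields")
  }
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  ids <- raw[[1L]]
  header <- colnames(raw)[-1L]  # before subsetting, which repairs dupes
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  colnames(cells) <- header
  is_missing <- matrix(trimws(cells) %in% missing_tokens, nrow(cells))
  vals <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  bad <- is.na(vals) & !is_missing
  if (any(bad)) {
    stop("non-numeric cell(s) that are not declared missing tokens, e.g. ",
         dQuote(cells[which(bad)[1L]]))
  }
  vals[is_missing] <- NA_real_
  dimnames(vals) <- list(ids, colnames(cells))
  if (orientation == "features_in_rows") vals <- t(vals)
  if (anyDuplicated(rownames(vals))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(vals))) stop("duplicate feature identifiers")
  validate_feature_matrix(vals)
}

# %.6g formatting shared by all writers so repeated runs are byte-identical.
.fmt <- function(x) {
  out <- ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 6))
  dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Write a feature matrix as delimited text
#'
#' Inverse of [read_matrix()]: first row feature identifiers, first column
#' sample identifiers, values formatted with `%.6g` so that identical inputs
#' produce byte-identical files.
#'
#' @param x samples-by-features numeric matrix.
#' @param path output path.
#' @param delimiter field separator.
#' @param id_column name for the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delimiter = ",", id_column = "id") {
  x <- .default_dimnames(x)
  validate_feature_matrix(x)
  chr <- .fmt(x)
  header <- paste(c(id_column, colnames(chr)), collapse = delimiter)
  body <- vapply(seq_len(nrow(chr)), function(i) {
    paste(c(rownames(chr)[i], chr[i, ]), collapse = delimiter)
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a label file
#'
#' Two-column delimited file `(sample_id, label)` with a header row.
#'
#' @param path path to the file.
#' @param delimiter field separator.
#' @return a factor of class labels named by sample identifier.
#' @export
read_labels <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("label file must have columns (sample_id, label)")
  if (anyDuplicated(raw[[1L]])) stop("duplicate sample identifiers in labels")
  y <- factor(raw[[2L]])
  names(y) <- raw[[1L]]
  y
}

#' Write a label file
#'
#' @param y factor (or vector) of labels, optionally named by sample id.
#' @param path output path.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
write_labels <- function(y, path, delimiter = ",") {
  ids <- names(y)
  if (is.null(ids)) ids <- paste0("s", seq_along(y))
  writeLines(c(paste("sample_id", "label", sep = delimiter),
               paste(ids, as.character(y), sep = delimiter)), path)
  invisible(path)
}

# Align a label vector with a feature matrix, by name when both are named.
.match_labels <- function(x, y) {
  if (length(y) != nrow(x)) {
    stop("labels have length ", length(y), " but matrix has ", nrow(x),
         " samples")
  }
  if (!is.null(names(y)) && !is.null(rownames(x))) {
    if (!all(rownames(x) %in% names(y))) {
      stop("label names do not cover all sample identifiers")
    }
    y <- y[rownames(x)]
  }
  factor(y)
}
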