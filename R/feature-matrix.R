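#' Feature-group matrix
#'
#' An n x d block of named descriptors for one feature group. Thin S3
#' wrapper around a numeric matrix: row names are sample ids, column names
#' are descriptor names, and the group name ("DSSP", "AAsCPP", "PSSM",
#' "FunD", or any user-defined view) travels as an attribute.
#'
#' @param values numeric matrix (or a single feature vector) with column
#'   names; row names are taken as sample ids.
#' @param group_name character scalar naming the feature group.
#' @param sample_ids optional character vector overriding row names.
#' @return an object of class `feature_matrix`.
#' @examples
#' m <- feature_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("p1", "p2"), c("a", "b", "c"))), "demo")
#' dim(m)
#' @export
feature_matrix <- function(values, group_name, sample_ids = NULL) {
  if (is.null(dim(values))) {
    values <- matrix(values, nrow = 1, dimnames = list(NULL, names(values)))
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is_string(group_name)) stop_("'group_name' must be a single string")
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != nrow(values)) {
      stop_("length of 'sample_ids' (", length(sample_ids),
            ") does not match the number of rows (", nrow(values), ")")
    }
    rownames(values) <- sample_ids
  }
  if (is.null(rownames(values))) {
    rownames(values) <- if (nrow(values)) paste0("s", seq_len(nrow(values))) else character()
  }
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop_("feature matrix columns must be named")
  }
  if (anyDuplicated(rownames(values))) stop_("duplicated sample ids")
  structure(values, group_name = group_name, class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> group=%s  %d samples x %d descriptors\n",
              attr(x, "group_name"), nrow(x), ncol(x)))
  print(head(unclass(x), 4L))
  invisible(x)
}

#' @rdname feature_matrix
#' @param x object to query.
#' @export
group_name <- function(x) attr(x, "group_name")

# subsetting keeps the class and group attribute (drop is forced off)
#' @export
`[.feature_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, drop = FALSE]
  feature_matrix(out, group_name = attr(x, "group_name"))
}

#' Write / read a feature-group matrix as TSV
#'
#' The on-disk form is a tab-separated table whose header row holds the
#' descriptor names with a leading `sample_id` column. Values are written
#' with 17 significant digits so `read_feature_matrix(write_feature_matrix(m))`
#' is bit-exact.
#'
#' @param m a [feature_matrix()].
#' @param path file path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  header <- paste(c("sample_id", colnames(m)), collapse = "\t")
  body <- if (nrow(m)) {
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], sprintf("%.17g", unclass(m)[i, ])), collapse = "\t")
    }, character(1))
  } else {
    character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param group_name group name to attach on read; defaults to the file's
#'   base name without extension.
#' @export
read_feature_matrix <- function(path, group_name = NULL) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop_("empty feature matrix file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 1L || header[[1L]] != "sample_id") {
    stop_("feature matrix header must start with 'sample_id': ", path)
  }
  cols <- header[-1L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  ids <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(cols))
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header)) {
      stop_("row ", i, " of ", path, " has ", length(f),
            " fields; expected ", length(header))
    }
    ids[[i]] <- f[[1L]]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) stop_("non-numeric value in row ", i, " of ", path)
    vals[i, ] <- v
  }
  colnames(vals) <- cols
  rownames(vals) <- ids
  if (is.null(group_name)) {
    group_name <- tools::file_path_sans_ext(basename(path))
  }
  feature_matrix(vals, group_name = group_name)
}

#' Write / read a two-column label table
#'
#' Plain TSV with columns `sample_id` and `fold_label`.
#'
#' @param labels named character vector (names = sample ids).
#' @param path file path.
#' @export
write_labels <- function(labels, path) {
  if (is.null(names(labels))) stop_("'labels' must be named by sample id")
  writeLines(c("sample_id\tfold_label",
               paste(names(labels), as.character(labels), sep = "\t")), path)
  invisible(path)
}

#' @rdname write_labels
#' @return `read_labels` returns a named character vector.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (!all(c("sample_id", "fold_label") %in% names(tab))) {
    stop_("label file must have columns sample_id and fold_label: ", path)
  }
  setNames(tab$fold_label, tab$sample_id)
}
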