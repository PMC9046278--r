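#' Construct a feature matrix
#'
#' A `feature_matrix` is the unit the solvers consume: a samples x features
#' real matrix with feature labels, a set identifier and a flag recording
#' whether columns have been standardized (centered and scaled to unit
#' Euclidean norm).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param feature_labels Character vector of feature names; defaults to the
#'   matrix column names or `V1 ... Vp`.
#' @param set_id Identifier for the dataset (e.g. `"EEG"`, `"fNIRS"`).
#' @param standardized Logical; `TRUE` if columns are already centered with
#'   unit norm.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, feature_labels = NULL, set_id = "set",
                           standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("feature_matrix values must be finite", call. = FALSE)
  }
  if (is.null(feature_labels)) {
    feature_labels <- colnames(values)
    if (is.null(feature_labels)) {
      feature_labels <- paste0("V", seq_len(ncol(values)))
    }
  }
  if (length(feature_labels) != ncol(values)) {
    stop("feature_labels length must equal the number of columns",
         call. = FALSE)
  }
  colnames(values) <- feature_labels
  structure(
    list(values = values, feature_labels = as.character(feature_labels),
         set_id = set_id, standardized = isTRUE(standardized)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix '%s': %d samples x %d features%s>\n",
              x$set_id, nrow(x$values), ncol(x$values),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

as_feature_matrix <- function(x, set_id = "set") {
  if (inherits(x, "feature_matrix")) x else feature_matrix(x, set_id = set_id)
}

#' Standardize the columns of a feature matrix
#'
#' Columns are centered and scaled to unit Euclidean norm, the convention
#' under which cross-product terms such as \eqn{w_1^T X^T Y w_2} are bounded
#' and penalty scales are comparable across sets.  Constant columns cannot
#' be scaled; they are set to zero and a warning is raised.
#'
#' @param X A `feature_matrix` or plain matrix.
#' @return A standardized `feature_matrix`.
#' @export
standardize_columns <- function(X) {
  X <- as_feature_matrix(X)
  if (X$standardized) return(X)
  v <- X$values
  v <- sweep(v, 2, colMeans(v), "-")
  nrm <- sqrt(colSums(v^2))
  const <- nrm < .Machine$double.eps * nrow(v) * 10
  if (any(const)) {
    warning(sprintf("constant column(s) zeroed during standardization: %s",
                    paste(X$feature_labels[const], collapse = ", ")),
            call. = FALSE)
    nrm[const] <- 1
  }
  v <- sweep(v, 2, nrm, "/")
  v[, const] <- 0
  feature_matrix(v, X$feature_labels, X$set_id, standardized = TRUE)
}

#' Read a feature matrix from delimited text
#'
#' Expects a header row of feature labels; rows are samples.
#'
#' @param path File path.
#' @param set_id Set identifier to attach.
#' @param sep Field separator (default tab).
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, set_id = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (is.null(set_id)) {
    set_id <- sub("\\.[^.]*$", "", basename(path))
  }
  feature_matrix(as.matrix(df), colnames(df), set_id = set_id)
}

#' Write a feature matrix as delimited text
#'
#' @param X A `feature_matrix` or matrix.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @param digits Significant digits used for the decimal text (default 12;
#'   at this precision write/read/write round-trips are byte-identical).
#' @export
write_feature_matrix <- function(X, path, sep = "\t", digits = 12) {
  X <- as_feature_matrix(X)
  txt <- apply(X$values, c(1, 2), function(z) formatC(z, digits = digits,
                                                      format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(X$feature_labels, collapse = sep), con)
  utils::write.table(txt, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
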