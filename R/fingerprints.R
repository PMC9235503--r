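#' Construct a fingerprint matrix
#'
#' Binary label matrix over structures. Each label corresponds to one
#' substructure or molecular property; labels are never hashed, so a column
#' is interpretable on its own. Row names are structure keys, column names
#' are label identifiers.
#'
#' @param values numeric or integer matrix with entries in \{0, 1\};
#'   rownames = structure keys, colnames = label ids (generated when absent).
#' @param label_info optional data.frame of per-label metadata (one row per
#'   label, e.g. the source fingerprint family and SMARTS description).
#' @return object of class `fingerprint_matrix` with fields `values`,
#'   `structures`, `labels`, `positive_counts` and optional `label_info`.
#' @export
fingerprint_matrix <- function(values, label_info = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1))) stop("fingerprint values must be 0/1")
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%05d", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate structure_keys in fingerprint matrix")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("L%05d", seq_len(ncol(values)))
  structure(
    list(values = values,
         structures = rownames(values),
         labels = colnames(values),
         positive_counts = colSums(values),
         label_info = label_info),
    class = "fingerprint_matrix")
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d structures x %d labels, median positives/label %d\n",
              nrow(x$values), ncol(x$values),
              as.integer(stats::median(x$positive_counts))))
  invisible(x)
}

#' Restrict a fingerprint matrix to sufficiently frequent labels
#'
#' Labels that occur in very few training structures cannot be learned
#' reliably; only labels with at least `min_structures` positive training
#' structures are retained (the production pipeline uses 20). Counting must
#' be done on training structures only — pass the training-restricted
#' matrix, then apply the retained label set to evaluation data.
#'
#' @param fp a [fingerprint_matrix()].
#' @param min_structures minimum number of positive structures (default 20).
#' @return a `fingerprint_matrix` with the retained labels, order preserved.
#' @export
select_labels <- function(fp, min_structures = 20L) {
  stopifnot(inherits(fp, "fingerprint_matrix"), min_structures >= 1)
  keep <- fp$positive_counts >= min_structures
  if (!any(keep))
    stop("no labels have >= ", min_structures, " positive structures")
  fingerprint_matrix(fp$values[, keep, drop = FALSE],
                     label_info = if (!is.null(fp$label_info))
                       fp$label_info[keep, , drop = FALSE])
}

#' Read / write a fingerprint matrix as (optionally gzipped) TSV
#'
#' Format: header row of label ids; first column `structure_key`; cells 0/1.
#'
#' @param path file path (`.gz` handled transparently).
#' @return [fingerprint_matrix()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "structure_key")
    stop("first column must be 'structure_key', got '", names(df)[1], "'")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  fingerprint_matrix(m)
}

#' @rdname read_fingerprints
#' @param fp a [fingerprint_matrix()] to serialize.
#' @export
write_fingerprints <- function(fp, path) {
  stopifnot(inherits(fp, "fingerprint_matrix"))
  df <- data.frame(structure_key = fp$structures, check.names = FALSE)
  df <- cbind(df, as.data.frame(fp$values, check.names = FALSE))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
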