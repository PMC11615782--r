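#' Validate an OTU-by-sample abundance matrix
#'
#' Tables are OTU-rows x sample-columns everywhere in this package, matching
#' the `m x n` convention of amplicon workflows. This is the most common user
#' error, so validation is strict: nonnegative finite entries, unique labels,
#' and no all-zero sample.
#'
#' @param X numeric matrix, OTUs as rows, samples as columns, dimnames set.
#' @return `X`, invisibly, after validation.
#' @export
validate_abundance <- function(X) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("abundance table must be a numeric matrix (OTUs x samples)",
         call. = FALSE)
  }
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop("abundance table needs OTU rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(X))) {
    stop("duplicate OTU labels: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(X))) {
    stop("duplicate sample labels: ",
         paste(unique(colnames(X)[duplicated(colnames(X))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(X) | !is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite abundance at OTU '", rownames(X)[bad[1, 1]],
         "', sample '", colnames(X)[bad[1, 2]], "'", call. = FALSE)
  }
  neg <- which(X < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative abundance at OTU '", rownames(X)[neg[1, 1]],
         "', sample '", colnames(X)[neg[1, 2]], "'", call. = FALSE)
  }
  zero_samp <- colSums(X) == 0
  if (any(zero_samp)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(X)[zero_samp], collapse = ", "), call. = FALSE)
  }
  invisible(X)
}

#' Read / write an abundance table as TSV
#'
#' First column holds OTU identifiers, remaining columns one sample each.
#' Readers reject rather than coerce malformed input.
#'
#' @param path file path.
#' @return numeric matrix (OTUs x samples) with dimnames.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance TSV needs an id column plus >= 1 sample",
                          call. = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- as.character(df[[1]])
  validate_abundance(X)
  X
}

#' @rdname read_abundance_table
#' @param X abundance matrix to write.
#' @export
write_abundance_table <- function(X, path) {
  df <- data.frame(otu_id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize counts to relative abundances
#'
#' Each sample (column) is divided by its total so columns sum to one.
#'
#' @param X abundance matrix (OTUs x samples).
#' @return matrix of the same shape with unit column sums.
#' @export
relative_abundance <- function(X) {
  validate_abundance(X)
  sweep(X, 2, colSums(X), `/`)
}
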