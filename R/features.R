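#' Presence-based summation pooling of OTU embeddings per sample
#'
#' For each sample, the feature vector is the unweighted sum of the embedding
#' rows of the OTUs *present* (abundance > 0) in that sample. Pooling is over
#' presence, not weighted by abundance, so any positive rescaling of the
#' table leaves the features unchanged.
#'
#' @param X abundance matrix (OTUs x samples).
#' @param embedding a `pf_embedding` whose rownames cover the table's OTUs.
#' @return a `pf_features` with `F` (`n x d`), `kind = "phylogeny"`.
#' @export
sum_pool_phylo <- function(X, embedding) {
  validate_abundance(X)
  stopifnot(inherits(embedding, "pf_embedding"))
  E <- embedding$X
  missing <- setdiff(rownames(X), rownames(E))
  if (length(missing)) {
    stop("OTUs absent from embeddings: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  E <- E[rownames(X), , drop = FALSE]
  P <- (X > 0) * 1
  F_ <- t(P) %*% E    # n x d: each row sums embeddings of present OTUs
  rownames(F_) <- colnames(X)
  structure(list(F = F_, kind = "phylogeny"), class = "pf_features")
}

#' Concatenate abundance and phylogeny sample features
#'
#' Row-wise concatenation into fused per-sample features. By default each
#' block is z-scored per column first (`standardize = TRUE`): the RPCA scores
#' and pooled embeddings live on incommensurate scales, and balancing them
#' keeps one block from dominating Euclidean distances downstream.
#' Zero-variance columns are left unscaled.
#'
#' @param abundance `pf_features` of kind `"abundance"`.
#' @param phylogeny `pf_features` of kind `"phylogeny"`.
#' @param standardize z-score each block per column before concatenation.
#' @return a `pf_features` with `kind = "fused"`, `q = q_A + d` columns.
#' @export
fuse_features <- function(abundance, phylogeny, standardize = TRUE) {
  stopifnot(inherits(abundance, "pf_features"),
            inherits(phylogeny, "pf_features"))
  A <- abundance$F
  P <- phylogeny$F
  if (nrow(A) != nrow(P) || !identical(rownames(A), rownames(P))) {
    stop("sample mismatch between abundance and phylogeny features",
         call. = FALSE)
  }
  if (standardize) {
    A <- zscore_cols(A)
    P <- zscore_cols(P)
  }
  F_ <- cbind(A, P)
  colnames(F_) <- c(paste0("A", seq_len(ncol(A))), paste0("P", seq_len(ncol(P))))
  structure(list(F = F_, kind = "fused"), class = "pf_features")
}

zscore_cols <- function(M) {
  mu <- colMeans(M)
  sd_ <- apply(M, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  sweep(sweep(M, 2, mu, `-`), 2, sd_, `/`)
}

#' Write / read sample features as TSV
#'
#' @param features a `pf_features`.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "pf_features"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind\t", features$kind), con)
  df <- data.frame(sample_id = rownames(features$F), features$F,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  kind <- "fused"
  if (startsWith(lines[1], "#kind")) {
    kind <- strsplit(lines[1], "\t")[[1]][2]
    lines <- lines[-1]
  }
  df <- utils::read.delim(text = lines, check.names = FALSE,
                          stringsAsFactors = FALSE)
  F_ <- as.matrix(df[, -1, drop = FALSE])
  rownames(F_) <- df[[1]]
  structure(list(F = F_, kind = kind), class = "pf_features")
}
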