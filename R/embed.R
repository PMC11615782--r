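#' Phylogeny-aware OTU embeddings by PCA of the patristic distance matrix
#'
#' Each OTU's row of the patristic distance matrix (its vector of distances to
#' all OTUs) is one observation; features are mean-centered (no unit-variance
#' scaling) and the first `d` principal-component scores become the OTU's
#' embedding. Component signs are fixed by forcing the largest-magnitude
#' loading of each component positive, so output is reproducible across
#' linear-algebra backends.
#'
#' @param D symmetric patristic distance matrix with OTU dimnames, as from
#'   [patristic_distances()].
#' @param d embedding dimension, `1 <= d <= m`. Default 64, clipped to `m`.
#' @return a `pf_embedding`: list with `X` (`m x d` score matrix, rownames =
#'   OTU labels, colnames `PC1..PCd`) and `explained_variance` (nonincreasing,
#'   length `d`).
#' @export
pca_embed <- function(D, d = 64L) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("`D` must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(D))) stop("`D` contains non-finite entries", call. = FALSE)
  m <- nrow(D)
  d <- as.integer(d)
  if (is.na(d) || d < 1L) stop("`d` must be >= 1", call. = FALSE)
  if (d > m) stop("`d` (", d, ") exceeds the number of OTUs (", m, ")",
                  call. = FALSE)
  labels <- rownames(D) %||% paste0("otu", seq_len(m))
  Dc <- scale(D, center = TRUE, scale = FALSE)
  sv <- svd(Dc, nu = d, nv = d)
  scores <- sv$u %*% diag(sv$d[seq_len(d)], d, d)
  sf <- fix_signs(scores, sv$v)
  scores <- sf$scores
  ev <- sv$d[seq_len(d)]^2 / max(1L, m - 1L)
  dimnames(scores) <- list(labels, paste0("PC", seq_len(d)))
  structure(list(X = scores, explained_variance = ev), class = "pf_embedding")
}

#' @export
print.pf_embedding <- function(x, ...) {
  cat("pf_embedding:", nrow(x$X), "OTUs x", ncol(x$X), "components\n")
  cat("explained variance (first 5):",
      paste(signif(utils::head(x$explained_variance, 5), 4), collapse = " "),
      "\n")
  invisible(x)
}

#' Build embeddings directly from a tree
#'
#' Convenience wrapper: [patristic_distances()] then [pca_embed()].
#'
#' @inheritParams patristic_distances
#' @inheritParams pca_embed
#' @return a `pf_embedding`.
#' @export
phylo_embed <- function(tree, d = 64L) {
  D <- patristic_distances(tree)
  pca_embed(D, min(as.integer(d), nrow(D)))
}

#' Remove phylogenetic signal from a fraction of OTU embeddings
#'
#' Ablation: `round(fraction * m)` OTU rows, chosen uniformly at random under
#' `seed`, are replaced by i.i.d. standard-normal draws scaled to the
#' per-column standard deviation of the original embedding matrix. This
#' destroys phylogenetic structure while preserving scale, so the ablation
#' probes information content rather than magnitude.
#'
#' @param embedding a `pf_embedding`.
#' @param fraction fraction of rows to ablate, in `[0, 1]`.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return a `pf_embedding` with the ablated score matrix; the replaced row
#'   indices are attached as attribute `"ablated"`.
#' @export
remove_phylo_signal <- function(embedding, fraction, seed) {
  stopifnot(inherits(embedding, "pf_embedding"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    stop("`fraction` must be a single number in [0, 1]", call. = FALSE)
  }
  X <- embedding$X
  m <- nrow(X)
  n_rep <- round(fraction * m)
  out <- embedding
  if (n_rep == 0L) {
    attr(out, "ablated") <- integer(0)
    return(out)
  }
  col_sd <- apply(X, 2, stats::sd)
  col_sd[!is.finite(col_sd)] <- 0
  res <- with_seed(seed, {
    rows <- sort(sample.int(m, n_rep))
    noise <- matrix(stats::rnorm(n_rep * ncol(X)), n_rep, ncol(X))
    X[rows, ] <- sweep(noise, 2, col_sd, `*`)
    list(rows = rows, X = X)
  })
  out$X <- res$X
  attr(out, "ablated") <- res$rows
  out
}

#' Write / read an embedding matrix as TSV
#'
#' Header row of component names, leading `otu_id` column; explained variance
#' preserved in a `#explained_variance` comment line.
#'
#' @param embedding a `pf_embedding`.
#' @param path output path.
#' @return `path` invisibly (write); a `pf_embedding` (read).
#' @export
write_embeddings <- function(embedding, path) {
  stopifnot(inherits(embedding, "pf_embedding"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#explained_variance\t",
                    paste(format(embedding$explained_variance, digits = 17),
                          collapse = "\t")), con)
  df <- data.frame(otu_id = rownames(embedding$X), embedding$X,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  ev <- NULL
  if (startsWith(lines[1], "#explained_variance")) {
    ev <- as.numeric(strsplit(lines[1], "\t")[[1]][-1])
    lines <- lines[-1]
  }
  df <- utils::read.delim(text = lines, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df[[1]]
  if (is.null(ev)) ev <- rep(NA_real_, ncol(X))
  structure(list(X = X, explained_variance = ev), class = "pf_embedding")
}
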