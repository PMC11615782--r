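#' Robust centered log-ratio (rclr) transform
#'
#' Zeros are treated as missing rather than pseudocounted: each zero entry
#' becomes `NA`, and each nonzero entry is replaced by `log(value)` minus the
#' mean log over the *observed* entries of its sample (column). On a zero-free
#' table this reduces exactly to the classical clr transform.
#'
#' @param X abundance matrix (OTUs x samples), nonnegative.
#' @return an `m x n` matrix with `NA` at zero entries.
#' @export
rclr_transform <- function(X) {
  validate_abundance(X)
  L <- ifelse(X > 0, log(X), NA_real_)
  mu <- colMeans(L, na.rm = TRUE)
  sweep(L, 2, mu, `-`)
}

#' Robust Aitchison PCA sample features
#'
#' Low-rank factorization of the rclr-transformed table, fitted by iterative
#' imputation of the missing (zero) cells: missing entries start at 0, are
#' repeatedly replaced by the rank-`rank` truncated-SVD reconstruction, and
#' iteration stops when the relative change of the completed matrix drops
#' below `tol` or `max_iter` is reached. Per-sample scores (`n x rank`) are
#' returned as dense abundance features.
#'
#' @param X abundance matrix (OTUs x samples).
#' @param rank target rank, `<= min(m, n)`. Default 3, the usual RPCA
#'   ordination convention.
#' @param max_iter maximum completion iterations.
#' @param tol relative-change convergence tolerance.
#' @return a `pf_features` list: `F` (n x rank score matrix, rownames =
#'   sample labels), `kind = "abundance"`, `converged`, `n_iter`,
#'   `loadings` (m x rank), `eigenvalues`.
#' @export
rpca_features <- function(X, rank = 3L, max_iter = 500L, tol = 1e-6) {
  validate_abundance(X)
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(dim(X))) {
    stop("`rank` must be in [1, min(m, n)]", call. = FALSE)
  }
  M <- rclr_transform(X)
  miss <- is.na(M)
  Z <- M
  Z[miss] <- 0
  converged <- !any(miss)
  it <- 0L
  if (any(miss)) {
    prev <- Z
    for (it in seq_len(max_iter)) {
      sv <- svd(Z, nu = rank, nv = rank)
      recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
      Z[miss] <- recon[miss]
      delta <- sqrt(sum((Z - prev)^2)) / max(1e-12, sqrt(sum(prev^2)))
      prev <- Z
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("rpca_features: completion did not converge in ", max_iter,
            " iterations (tol = ", tol, ")", call. = FALSE)
  }
  sv <- svd(Z, nu = rank, nv = rank)
  d_r <- sv$d[seq_len(rank)]
  # samples are columns of X: sample scores come from right singular vectors
  scores <- sv$v %*% diag(d_r, rank, rank)
  sf <- fix_signs(scores, sv$u)
  scores <- sf$scores
  dimnames(scores) <- list(colnames(X), paste0("RPC", seq_len(rank)))
  loadings <- sf$loadings
  dimnames(loadings) <- list(rownames(X), paste0("RPC", seq_len(rank)))
  structure(list(F = scores, kind = "abundance", converged = converged,
                 n_iter = it, loadings = loadings, eigenvalues = d_r^2),
            class = "pf_features")
}

#' @export
print.pf_features <- function(x, ...) {
  cat("pf_features [", x$kind, "]: ", nrow(x$F), " samples x ", ncol(x$F),
      " features\n", sep = "")
  invisible(x)
}
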