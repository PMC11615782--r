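#' PERMANOVA pseudo-F on Euclidean feature distances
#'
#' Distance-based one-way PERMANOVA. With `N` samples in `a` groups and
#' pairwise Euclidean distances `d_ij` of the feature rows,
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` sums the same quantity
#' within each group (divided by the group size), `SS_between` is the
#' difference, and `F = (SS_between / (a - 1)) / (SS_within / (N - a))`.
#' Significance comes from permuting group labels.
#'
#' @param features `pf_features` or a plain numeric matrix (samples x q).
#' @param groups per-sample categorical labels (length n, >= 2 groups, each
#'   with >= 2 samples).
#' @param n_permutations permutations for the p-value (default 999).
#' @param seed integer RNG seed for the permutations.
#' @return list with `F`, `p`, `n_permutations`. `F` is `Inf` (with a
#'   warning) when `SS_within` is exactly zero.
#' @export
permanova_f <- function(features, groups, n_permutations = 999L, seed = 1L) {
  F_ <- feature_matrix(features)
  groups <- as.factor(groups)
  if (length(groups) != nrow(F_)) {
    stop("`groups` length must match the number of samples", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) < 2L) stop(">= 2 groups required", call. = FALSE)
  small <- table(groups) < 2L
  if (any(small)) {
    stop("group(s) with < 2 samples: ",
         paste(names(small)[small], collapse = ", "), call. = FALSE)
  }
  d2 <- as.matrix(stats::dist(F_))^2
  f_obs <- pseudo_f(d2, groups)
  if (!is.finite(f_obs)) {
    warning("SS_within is zero; F reported as Inf", call. = FALSE)
  }
  p <- NA_real_
  if (n_permutations > 0L) {
    n <- nrow(F_)
    f_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        pseudo_f(d2, groups[sample.int(n)])
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs)) / (n_permutations + 1)
  }
  list(F = f_obs, p = p, n_permutations = as.integer(n_permutations))
}

pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  a <- nlevels(droplevels(groups))
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(droplevels(groups))) {
    idx <- which(groups == g)
    dg <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(dg[upper.tri(dg)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  num <- ss_between / (a - 1)
  den <- ss_within / (n - a)
  if (den == 0) return(Inf)
  num / den
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two partitions; 1 for identical partitions,
#' ~0 for independent ones, can be negative.
#'
#' @param a,b label vectors of equal length.
#' @return numeric ARI in `[-1, 1]` (upper bound 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' K-means clustering agreement with known labels
#'
#' Runs seeded K-means (best of `n_init` restarts by within-cluster sum of
#' squares) on the feature rows and scores the assignment against the true
#' labels with the adjusted Rand index.
#'
#' @param features `pf_features` or matrix (samples x q).
#' @param true_labels per-sample reference labels.
#' @param k number of clusters (>= 2, <= n).
#' @param n_init random restarts.
#' @param seed integer RNG seed.
#' @return numeric ARI.
#' @export
kmeans_ari <- function(features, true_labels, k, n_init = 10L, seed = 1L) {
  F_ <- feature_matrix(features)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (k > nrow(F_)) stop("`k` exceeds the number of samples", call. = FALSE)
  if (length(true_labels) != nrow(F_)) {
    stop("`true_labels` length must match samples", call. = FALSE)
  }
  km <- with_seed(seed, stats::kmeans(F_, centers = k, nstart = as.integer(n_init),
                                      iter.max = 100L))
  adjusted_rand_index(km$cluster, true_labels)
}

#' Stratified cross-validated KNN evaluation
#'
#' Stratified `n_folds`-fold cross-validation of a K-nearest-neighbour
#' classifier on Euclidean distances. Out-of-fold class scores (fraction of
#' the `k_neighbors` nearest training points in the class, distance-weighted
#' tie-break) are pooled and summarized as AUPRC (trapezoidal PR integration)
#' and APS (step-wise average precision). Multiclass problems are handled
#' one-vs-rest and macro-averaged.
#'
#' @param features `pf_features` or matrix (samples x q).
#' @param labels per-sample class labels (>= 2 classes).
#' @param k_neighbors neighbours per vote (default 5).
#' @param n_folds folds (default 10); every class must have at least
#'   `n_folds` members.
#' @param seed integer RNG seed for fold assignment.
#' @return list with `auprc`, `aps`, and per-class `scores` matrix.
#' @export
knn_eval <- function(features, labels, k_neighbors = 5L, n_folds = 10L,
                     seed = 1L) {
  F_ <- feature_matrix(features)
  labels <- as.factor(labels)
  n <- nrow(F_)
  if (length(labels) != n) stop("`labels` length must match samples", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("need >= 2 classes for KNN evaluation", call. = FALSE)
  }
  if (n_folds < 2L) stop("`n_folds` must be >= 2", call. = FALSE)
  counts <- table(labels)
  if (any(counts < n_folds)) {
    stop("class(es) with fewer members than n_folds: ",
         paste(names(counts)[counts < n_folds], collapse = ", "),
         "; use fewer folds", call. = FALSE)
  }
  folds <- with_seed(seed, stratified_folds(labels, n_folds))
  classes <- levels(droplevels(labels))
  scores <- matrix(NA_real_, n, length(classes),
                   dimnames = list(rownames(F_), classes))
  d2 <- as.matrix(stats::dist(F_))
  for (f in seq_len(n_folds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    k_use <- min(k_neighbors, length(train))
    for (i in test) {
      dd <- d2[i, train]
      # deterministic neighbour selection: distance, then index order
      nb <- train[order(dd, train)[seq_len(k_use)]]
      scores[i, ] <- vapply(classes,
                            function(cl) mean(labels[nb] == cl), numeric(1))
    }
  }
  per_class <- vapply(classes, function(cl) {
    tc <- threshold_curves(scores[, cl], as.integer(labels == cl))
    c(tc$aupr, tc$aps)
  }, numeric(2))
  list(auprc = mean(per_class[1, ]), aps = mean(per_class[2, ]),
       scores = scores)
}

# Stratified fold ids: within each class, shuffled samples are dealt
# round-robin to folds, so fold class proportions match the data.
stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in levels(as.factor(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

feature_matrix <- function(features) {
  if (inherits(features, "pf_features")) return(features$F)
  if (is.matrix(features) && is.numeric(features)) return(features)
  stop("`features` must be a pf_features or a numeric matrix", call. = FALSE)
}
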