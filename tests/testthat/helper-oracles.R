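# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force patristic oracle: edge-weighted shortest paths on the tree
# graph, BFS/Dijkstra from each leaf. O(m * edges); fine for <= 30 leaves.
oracle_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (src in seq_len(n_tip)) {
    dist <- rep(NA_real_, n_node)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]; w <- adj[[v]][r, 2]
        if (is.na(dist[u])) {          # trees: first visit is the only path
          dist[u] <- dist[v] + w
          queue <- c(queue, u)
        }
      }
    }
    D[src, ] <- dist[seq_len(n_tip)]
  }
  D
}

# classical clr: log minus per-column mean log, defined only for zero-free
# columns
oracle_clr <- function(X) {
  L <- log(X)
  sweep(L, 2, colMeans(L), `-`)
}

# direct-formula confusion-matrix metrics (zero denominators -> 0)
oracle_binary_metrics <- function(TP, TN, FP, FN) {
  div <- function(a, b) if (b == 0) 0 else a / b
  sens <- div(TP, TP + FN)
  spec <- div(TN, TN + FP)
  acc <- (TP + TN) / (TP + TN + FP + FN)
  prec <- div(TP, TP + FP)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  den <- sqrt(TP + FN) * sqrt(TP + FP) * sqrt(TN + FN) * sqrt(TN + FP)
  mcc <- if (den == 0) 0 else (TP * TN - FP * FN) / den
  c(sensitivity = sens, specificity = spec, accuracy = acc,
    precision = prec, f1 = f1, mcc = mcc)
}

# pseudo-F from first principles on any tiny instance
oracle_pseudo_f <- function(F_, groups) {
  groups <- as.factor(groups)
  n <- nrow(F_)
  a <- nlevels(groups)
  d2 <- as.matrix(stats::dist(F_))^2
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in levels(groups)) {
    i <- which(groups == g)
    ss_w <- ss_w + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# small random tree with random topology and branch lengths
random_test_tree <- function(n_leaves) {
  tr <- ape::rtree(n_leaves)
  tr$tip.label <- paste0("L", seq_len(n_leaves))
  tr
}

# quick abundance fixture: m x n counts with guaranteed-valid columns
toy_table <- function(m = 8, n = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rpois(m * n, lambda = 5), m, n,
              dimnames = list(paste0("otu", 1:m), paste0("s", 1:n)))
  X[cbind(sample(m, n, replace = TRUE), 1:n)] <- 3  # no empty samples
  X
}
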