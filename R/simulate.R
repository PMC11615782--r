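#' Simulate a random birth-death tree
#'
#' Random birth-death phylogeny with `m` leaves (birth rate 1, death rate
#' 0.5), strictly positive branch lengths, leaves relabeled `otu1..otum`.
#' Deterministic under `seed`.
#'
#' @param m_otus number of leaves (>= 2).
#' @param seed integer RNG seed.
#' @param birth,death birth-death rates.
#' @return a `phylo` tree.
#' @export
simulate_tree <- function(m_otus, seed = 1L, birth = 1, death = 0.5) {
  m_otus <- as.integer(m_otus)
  if (m_otus < 2L) stop("`m_otus` must be >= 2", call. = FALSE)
  tr <- with_seed(seed, ape::rphylo(m_otus, birth = birth, death = death))
  tr$tip.label <- paste0("otu", seq_len(m_otus))
  # guard against zero-length edges from the sampler
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

#' Partition OTUs into phylogenetic clusters
#'
#' Average-linkage hierarchical clustering of the patristic distance matrix,
#' cut into exactly `K` groups. Emulates outcome-associated clusters at
#' varying phylogenetic depths: small `K` gives large, deep clades.
#'
#' @param tree a `phylo` tree.
#' @param K number of clusters, `1 <= K <= m`.
#' @return integer vector of cluster ids (1..K), named by OTU, in canonical
#'   leaf order.
#' @export
cluster_otus <- function(tree, K) {
  D <- patristic_distances(tree)
  K <- as.integer(K)
  if (K < 1L || K > nrow(D)) stop("`K` must be in [1, m]", call. = FALSE)
  if (K == nrow(D)) {
    cl <- seq_len(nrow(D))
    names(cl) <- rownames(D)
    return(cl)
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(hc, k = K)
  cl[rownames(D)]
}

#' Tree-decay correlation matrix for the copula
#'
#' `exp(-rho * D)` on the patristic distances, projected to the nearest
#' positive semi-definite correlation matrix (eigenvalue clipping followed by
#' rescaling to unit diagonal).
#'
#' @param D patristic distance matrix.
#' @param rho decay rate per unit branch length.
#' @return PSD correlation matrix in canonical leaf order.
#' @export
phylo_correlation <- function(D, rho = 1) {
  C <- exp(-rho * D)
  ei <- eigen(C, symmetric = TRUE)
  if (min(ei$values) < 1e-10) {
    vals <- pmax(ei$values, 1e-10)
    C <- ei$vectors %*% (vals * t(ei$vectors))
    C <- stats::cov2cor(C)
  }
  dimnames(C) <- dimnames(D)
  C
}

#' Default zero-inflated negative binomial marginals
#'
#' Per-OTU marginal count distributions: NB mean drawn log-normally
#' (heavy-tailed abundances, a few dominant taxa), common dispersion and
#' zero-inflation. Deterministic under `seed`.
#'
#' @param m number of OTUs.
#' @param seed integer RNG seed.
#' @param zero_inflation structural-zero probability per OTU.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param meanlog,sdlog log-normal parameters of the NB means.
#' @return data.frame with columns `pi0`, `size`, `mu` (one row per OTU).
#' @export
default_marginals <- function(m, seed = 1L, zero_inflation = 0.5,
                              dispersion = 0.5, meanlog = 1, sdlog = 1.5) {
  mu <- with_seed(seed, stats::rlnorm(m, meanlog = meanlog, sdlog = sdlog))
  data.frame(pi0 = rep(zero_inflation, m), size = rep(dispersion, m), mu = mu)
}

# inverse CDF of the zero-inflated negative binomial
qzinb <- function(u, pi0, size, mu) {
  q <- pmin(pmax((u - pi0) / (1 - pi0), 0), 1 - 1e-12)
  ifelse(u < pi0, 0L, stats::qnbinom(q, size = size, mu = mu))
}

#' Correlated OTU counts via the NorTA (Normal To Anything) construction
#'
#' Samples are drawn as multivariate normal with the target correlation,
#' mapped through the standard-normal CDF to uniforms and then through each
#' OTU's inverse marginal CDF (zero-inflated negative binomial), giving
#' correlated counts with realistic sparsity and overdispersion.
#'
#' @param n_samples number of samples.
#' @param correlation `m x m` correlation matrix (projected to PSD if
#'   needed); dimnames give the OTU labels.
#' @param marginals data.frame from [default_marginals()] (`pi0`, `size`,
#'   `mu` per OTU).
#' @param seed integer RNG seed.
#' @return count matrix (OTUs x samples) with dimnames; all-zero samples are
#'   re-seeded with a single pseudo-count at their most abundant OTU so the
#'   table validates.
#' @export
norta_counts <- function(n_samples, correlation, marginals, seed = 1L) {
  m <- nrow(correlation)
  stopifnot(nrow(marginals) == m)
  ei <- eigen(correlation, symmetric = TRUE)
  vals <- pmax(ei$values, 1e-10)      # clip to the nearest PSD matrix
  Lmat <- ei$vectors %*% diag(sqrt(vals), m, m)
  marg_sd <- sqrt(rowSums(Lmat^2))    # rescale rows to unit marginal variance
  Lmat <- Lmat / marg_sd
  Z <- with_seed(seed, matrix(stats::rnorm(m * n_samples), m, n_samples))
  U <- stats::pnorm(Lmat %*% Z)       # Gaussian copula uniforms
  counts <- matrix(0, m, n_samples)
  for (i in seq_len(m)) {
    counts[i, ] <- qzinb(U[i, ], marginals$pi0[i], marginals$size[i],
                         marginals$mu[i])
  }
  rownames(counts) <- rownames(correlation) %||% paste0("otu", seq_len(m))
  colnames(counts) <- paste0("s", seq_len(n_samples))
  empty <- which(colSums(counts) == 0)
  for (j in empty) counts[which.max(marginals$mu), j] <- 1
  counts
}

#' Simulate binary outcomes from cluster-level linear effects
#'
#' `round(signal_density * K)` clusters are drawn uniformly at random as
#' outcome-associated (aClusters); each gets an effect `beta_k ~ N(0,
#' sigma_beta_sq)`. The linear predictor is
#' `eta_i = sum_k sum_{j in C_k} beta_k * x_ij` on relative abundances; under
#' a non-informative tree the sign of `beta_k` is flipped for a uniformly
#' random half (`floor(|C_k| / 2)`) of each aCluster. Outcomes are
#' `y_i ~ Bernoulli(sigmoid(eta_i))`.
#'
#' @param rel_abund relative-abundance matrix (OTUs x samples, columns sum
#'   to 1), rows in the same order as `clusters`.
#' @param clusters integer cluster ids per OTU (named, from
#'   [cluster_otus()]).
#' @param signal_density fraction of clusters that are outcome-associated,
#'   in `(0, 1]`; an error if `round(signal_density * K)` is 0.
#' @param informative logical; `FALSE` flips effect signs within clusters.
#' @param sigma_beta_sq effect-size variance (default 4).
#' @param seed integer RNG seed.
#' @param beta_override optional numeric vector overriding the drawn
#'   `beta_k` (recycled to the number of aClusters); `0` gives the pure-noise
#'   null with `p_i = 0.5` everywhere.
#' @return list: `y` (0/1), `p`, `eta` (per sample), and `outcome_model`
#'   (`associated` cluster ids, `beta` per aCluster, `inverted` OTU index
#'   sets).
#' @export
simulate_outcomes <- function(rel_abund, clusters, signal_density,
                              informative = TRUE, sigma_beta_sq = 4,
                              seed = 1L, beta_override = NULL) {
  stopifnot(is.matrix(rel_abund), length(clusters) == nrow(rel_abund))
  if (max(abs(colSums(rel_abund) - 1)) > 1e-8) {
    stop("`rel_abund` columns must sum to 1", call. = FALSE)
  }
  if (signal_density <= 0 || signal_density > 1) {
    stop("`signal_density` must be in (0, 1]", call. = FALSE)
  }
  K <- length(unique(clusters))
  n_assoc <- round(signal_density * K)
  if (n_assoc == 0L) {
    stop("signal_density * K rounds to 0 associated clusters", call. = FALSE)
  }
  res <- with_seed(seed, {
    assoc <- sort(sample(sort(unique(clusters)), n_assoc))
    beta <- stats::rnorm(n_assoc, mean = 0, sd = sqrt(sigma_beta_sq))
    if (!is.null(beta_override)) beta <- rep_len(beta_override, n_assoc)
    names(beta) <- assoc
    inverted <- vector("list", n_assoc)
    names(inverted) <- assoc
    w <- numeric(nrow(rel_abund))       # per-OTU signed effect weight
    for (a in seq_len(n_assoc)) {
      members <- which(clusters == assoc[a])
      w[members] <- beta[a]
      if (!informative) {
        n_inv <- floor(length(members) / 2)
        inv <- if (n_inv > 0) sort(sample(members, n_inv)) else integer(0)
        w[inv] <- -beta[a]
        inverted[[a]] <- inv
      } else {
        inverted[[a]] <- integer(0)
      }
    }
    eta <- as.numeric(crossprod(rel_abund, w))
    p <- sigmoid(eta)
    y <- stats::rbinom(length(p), 1, p)
    list(y = y, p = p, eta = eta,
         outcome_model = list(associated = assoc, beta = beta,
                              inverted = inverted, weights = w))
  })
  res
}

#' Generate a full simulation benchmark
#'
#' One call reproduces a complete simulation condition: birth-death tree,
#' NorTA counts over the tree-decay correlation, relative abundances,
#' cluster-structured binary outcomes, and the canonical train/validation/
#' test split (200:100:100 proportions).
#'
#' @param n_samples samples (default 400).
#' @param m_otus OTUs (default 927).
#' @param K_clusters cluster count: 50/20/10 = small/medium/large clusters.
#' @param signal_density fraction of associated clusters (0.1/0.2/0.4).
#' @param informative phylogenetic informativeness flag.
#' @param sigma_beta_sq effect variance (default 4).
#' @param zero_inflation,dispersion,correlation_decay copula/marginal knobs;
#'   the defaults (0.2, 0.02, 0.04) together with `death = 0.9` give tables
#'   that are ~90% zeros with heavy-tailed, clade-coherent blooms, the regime
#'   in which clade aggregate abundances vary enough across samples for the
#'   cluster-level outcome model to carry signal.
#' @param birth,death birth-death rates of the simulated tree; the high
#'   relative extinction (0.9) yields tight recent clades separated by long
#'   internal branches, so the tree-decay correlation is near 1 within a
#'   clade and near 0 between clades.
#' @param marginal_meanlog,marginal_sdlog log-normal hyperparameters of the
#'   per-OTU negative-binomial means (heavy right tail: a few dominant taxa).
#' @param split_ratios three integers summing to 100 (default 50:25:25,
#'   i.e. 200:100:100 at n = 400).
#' @param seed integer global seed; all stages derive child streams from it.
#' @return a `pf_simulation` list: `tree`, `counts`, `rel_abund`, `y`, `p`,
#'   `eta`, `clusters`, `outcome_model`, `split`, `design`.
#' @export
make_benchmark <- function(n_samples = 400L, m_otus = 927L, K_clusters = 20L,
                           signal_density = 0.2, informative = TRUE,
                           sigma_beta_sq = 4, zero_inflation = 0.2,
                           dispersion = 0.02, correlation_decay = 0.04,
                           birth = 1, death = 0.9,
                           marginal_meanlog = 1, marginal_sdlog = 3.5,
                           split_ratios = c(50, 25, 25), seed = 1L) {
  if (K_clusters > m_otus) stop("K_clusters > m_otus", call. = FALSE)
  tree <- simulate_tree(m_otus, seed = child_seed(seed, 1L),
                        birth = birth, death = death)
  D <- patristic_distances(tree)
  C <- phylo_correlation(D, rho = correlation_decay)
  marg <- default_marginals(m_otus, seed = child_seed(seed, 2L),
                            zero_inflation = zero_inflation,
                            dispersion = dispersion,
                            meanlog = marginal_meanlog,
                            sdlog = marginal_sdlog)
  counts <- norta_counts(n_samples, C, marg, seed = child_seed(seed, 3L))
  rel <- relative_abundance(counts)
  clusters <- cluster_otus(tree, K_clusters)
  out <- simulate_outcomes(rel[names(clusters), , drop = FALSE], clusters,
                           signal_density, informative, sigma_beta_sq,
                           seed = child_seed(seed, 4L))
  split <- split_dataset(n_samples, split_ratios,
                         stratify_labels = out$y,
                         seed = child_seed(seed, 5L))
  design <- list(n_samples = n_samples, m_otus = m_otus,
                 K_clusters = K_clusters, signal_density = signal_density,
                 informative = informative, sigma_beta_sq = sigma_beta_sq,
                 zero_inflation = zero_inflation, dispersion = dispersion,
                 correlation_decay = correlation_decay,
                 birth = birth, death = death,
                 marginal_meanlog = marginal_meanlog,
                 marginal_sdlog = marginal_sdlog,
                 split_ratios = split_ratios, seed = seed)
  structure(list(tree = tree, counts = counts, rel_abund = rel, y = out$y,
                 p = out$p, eta = out$eta, clusters = clusters,
                 outcome_model = out$outcome_model, split = split,
                 design = design),
            class = "pf_simulation")
}

#' Simulate two sample groups enriched in different clades
#'
#' Synthetic unsupervised benchmark: the tree is split into two deep clades
#' (average-linkage, K = 2) and the groups differ in which clade is
#' *prevalent*: in group 1, clade-1 OTUs have low structural-zero probability
#' (`prevalence_hi`) and clade-2 OTUs high (`prevalence_lo`); group 2 is the
#' mirror image. Nonzero count magnitudes follow identical marginals in both
#' groups, so the group difference lives in which taxa occur (presence
#' pattern) rather than in the values of the observed counts — the common
#' situation where clade-level enrichment is a prevalence shift.
#'
#' @param n_per_group samples per group.
#' @param m_otus number of OTUs.
#' @param prevalence_hi presence probability of the enriched clade.
#' @param prevalence_lo presence probability of the depleted clade.
#' @param seed integer seed.
#' @param dispersion,correlation_decay copula knobs.
#' @return list: `tree`, `counts`, `groups` (factor of length 2n), `clade`.
#' @export
simulate_clade_groups <- function(n_per_group = 40L, m_otus = 100L,
                                  prevalence_hi = 0.8, prevalence_lo = 0.35,
                                  seed = 1L, dispersion = 1,
                                  correlation_decay = 1) {
  tree <- simulate_tree(m_otus, seed = child_seed(seed, 11L))
  D <- patristic_distances(tree)
  C <- phylo_correlation(D, rho = correlation_decay)
  clade <- cluster_otus(tree, 2L)
  marg <- default_marginals(m_otus, seed = child_seed(seed, 12L),
                            zero_inflation = 0, dispersion = dispersion,
                            sdlog = 1)
  m1 <- marg
  m1$pi0 <- ifelse(clade == 1, 1 - prevalence_hi, 1 - prevalence_lo)
  m2 <- marg
  m2$pi0 <- ifelse(clade == 2, 1 - prevalence_hi, 1 - prevalence_lo)
  c1 <- norta_counts(n_per_group, C, m1, seed = child_seed(seed, 13L))
  c2 <- norta_counts(n_per_group, C, m2, seed = child_seed(seed, 14L))
  colnames(c1) <- paste0("g1_", seq_len(n_per_group))
  colnames(c2) <- paste0("g2_", seq_len(n_per_group))
  counts <- cbind(c1, c2)
  groups <- factor(rep(c("g1", "g2"), each = n_per_group))
  list(tree = tree, counts = counts, groups = groups, clade = clade)
}
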