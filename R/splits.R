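#' Train/validation/test split by integer ratios
#'
#' Splits `n_samples` indices into disjoint, exhaustive train/validation/test
#' sets whose sizes follow `ratios` (integers summing to 100, largest-
#' remainder rounding). With `stratify_labels`, the split is stratified so
#' each set mirrors the class proportions. Deterministic under `seed`.
#'
#' @param n_samples total number of samples.
#' @param ratios length-3 integer vector, e.g. `c(68, 12, 20)` (the default)
#'   or `c(50, 25, 25)` for a 200:100:100 split of 400 samples.
#' @param stratify_labels optional per-sample labels for stratification.
#' @param seed integer RNG seed.
#' @return list with integer vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n_samples, ratios = c(68, 12, 20),
                          stratify_labels = NULL, seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) != 100) {
    stop("`ratios` must be three nonnegative numbers summing to 100",
         call. = FALSE)
  }
  sizes <- ratio_sizes(n_samples, ratios)
  if (any(sizes == 0L & ratios > 0)) {
    stop("split ratio yields an empty set at n = ", n_samples, call. = FALSE)
  }
  idx <- with_seed(seed, {
    if (is.null(stratify_labels)) {
      sample.int(n_samples)
    } else {
      stopifnot(length(stratify_labels) == n_samples)
      # shuffle within each class, then apportion classes across the blocks
      shuffled <- unlist(lapply(split(seq_len(n_samples), stratify_labels),
                                function(ix) ix[sample.int(length(ix))]),
                         use.names = FALSE)
      interleave_classes(shuffled, stratify_labels, sizes)
    }
  })
  list(train = sort(idx[seq_len(sizes[1])]),
       val = sort(idx[sizes[1] + seq_len(sizes[2])]),
       test = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

# largest-remainder apportionment of n into three parts proportional to ratios
ratio_sizes <- function(n, ratios) {
  raw <- n * ratios / 100
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

# Reorder a vector of per-class shuffled indices so that carving contiguous
# train/val/test blocks gives each block near-proportional class mix: within
# each class, members are assigned to blocks by largest-remainder counts.
interleave_classes <- function(idx, labels, sizes) {
  labs <- labels[idx]
  blocks <- list(integer(0), integer(0), integer(0))
  for (cl in unique(labs)) {
    members <- idx[labs == cl]
    csize <- ratio_sizes(length(members), sizes / sum(sizes) * 100)
    # fix rounding drift so totals still match
    take1 <- seq_len(csize[1])
    take2 <- csize[1] + seq_len(csize[2])
    take3 <- csize[1] + csize[2] + seq_len(csize[3])
    blocks[[1]] <- c(blocks[[1]], members[take1])
    blocks[[2]] <- c(blocks[[2]], members[take2])
    blocks[[3]] <- c(blocks[[3]], members[take3])
  }
  # per-class rounding can leave block sizes off by a few; rebalance greedily
  for (b in 1:3) {
    while (length(blocks[[b]]) > sizes[b]) {
      mv <- blocks[[b]][length(blocks[[b]])]
      blocks[[b]] <- blocks[[b]][-length(blocks[[b]])]
      short <- which(vapply(blocks, length, 1L) <
                       sizes)[1]
      blocks[[short]] <- c(blocks[[short]], mv)
    }
  }
  c(blocks[[1]], blocks[[2]], blocks[[3]])
}

#' Leave-one-dataset-out folds
#'
#' One fold per study: that study's samples form the test set, all other
#' samples the training set. Every sample is tested exactly once.
#'
#' @param study_ids per-sample study identifiers (>= 2 distinct studies).
#' @return named list of folds, each a list with `train` and `test` index
#'   vectors.
#' @export
lodo_folds <- function(study_ids) {
  study_ids <- as.character(study_ids)
  studies <- unique(study_ids)
  if (length(studies) < 2L) {
    stop("LODO requires >= 2 distinct studies", call. = FALSE)
  }
  out <- lapply(studies, function(s) {
    test <- which(study_ids == s)
    list(train = which(study_ids != s), test = test)
  })
  names(out) <- studies
  out
}
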