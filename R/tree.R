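#' Read a rooted phylogenetic tree from a Newick file or string
#'
#' Thin validating wrapper around [ape::read.tree()]. Quoted labels are
#' supported. A bare single-leaf tree (`"A;"`), which `ape` cannot represent,
#' is returned as a one-tip stub of class `"pf_singleton"`.
#'
#' @param path path to a Newick file, or a Newick string when `text = TRUE`.
#' @param text logical; treat `path` as the Newick string itself.
#' @return an object of class `phylo` (or `pf_singleton` for one leaf).
#' @export
read_newick <- function(path, text = FALSE) {
  nwk <- if (text) path else paste(readLines(path, warn = FALSE), collapse = "")
  nwk <- trimws(nwk)
  if (!nzchar(nwk)) stop("empty Newick input", call. = FALSE)
  if (!grepl(";\\s*$", nwk)) {
    stop("Newick parse error: missing terminal ';' at position ",
         nchar(nwk), call. = FALSE)
  }
  n_open <- lengths(regmatches(nwk, gregexpr("\\(", nwk)))
  n_close <- lengths(regmatches(nwk, gregexpr("\\)", nwk)))
  if (n_open != n_close) {
    stop("Newick parse error: unbalanced parentheses (", n_open, " '(' vs ",
         n_close, "')')", call. = FALSE)
  }
  # single leaf, no parentheses: "A;" or "'A b':1.0;"
  if (n_open == 0L) {
    lab <- sub(";\\s*$", "", nwk)
    lab <- sub(":[0-9eE.+-]+$", "", lab)
    lab <- gsub("^'|'$", "", lab)
    out <- structure(list(tip.label = lab), class = "pf_singleton")
    return(out)
  }
  tr <- ape::read.tree(text = nwk)
  if (is.null(tr)) stop("Newick parse error: could not parse input", call. = FALSE)
  tr$tip.label <- gsub("^'(.*)'$", "\\1", tr$tip.label)
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` (or `pf_singleton`) object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "pf_singleton")) {
    writeLines(paste0(tree$tip.label, ";"), path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

#' Canonical leaf order of a rooted tree
#'
#' Leaves in the order they are encountered by a depth-first (post-order)
#' traversal from the root, children visited in stored edge order. This single
#' order is used everywhere: distance-matrix rows, embedding rows, and the
#' convolution input axis of the supervised model.
#'
#' @param tree a `phylo` object.
#' @return character vector of tip labels.
#' @export
leaf_order <- function(tree) {
  if (inherits(tree, "pf_singleton")) return(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "cladewise")
  tips <- tr$edge[, 2][tr$edge[, 2] <= length(tr$tip.label)]
  tr$tip.label[tips]
}

#' Patristic distance matrix of a rooted tree
#'
#' The patristic distance between two leaves is the sum of branch lengths
#' along the unique path connecting them. Rows/columns follow the canonical
#' [leaf_order()].
#'
#' @param tree a `phylo` object with branch lengths (all finite, `>= 0`).
#' @return an `m x m` symmetric numeric matrix with zero diagonal and
#'   dimnames set to the OTU labels.
#' @export
patristic_distances <- function(tree) {
  if (inherits(tree, "pf_singleton")) {
    D <- matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label))
    return(D)
  }
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  bad <- which(is.na(tree$edge.length) | !is.finite(tree$edge.length))
  if (length(bad)) {
    stop("missing/non-finite branch length on edge ", bad[1], " (",
         tree$edge[bad[1], 1], " -> ", tree$edge[bad[1], 2], ")", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  ord <- leaf_order(tree)
  D <- ape::cophenetic.phylo(tree)[ord, ord]
  diag(D) <- 0
  D
}
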