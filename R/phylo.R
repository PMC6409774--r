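#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]. Negative branch lengths
#' (which NJ can produce on non-additive matrices) are clamped to zero and
#' the deficit is moved to the sibling branch, preserving path lengths
#' through the parent node.
#'
#' @param dm symmetric distance matrix with unique labels (>= 3 taxa).
#' @return an `phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("nj_tree: need at least 3 taxa")
  tree <- ape::nj(as.dist(dm))
  clamp_negative_branches(tree)
}

# Move negative branch lengths onto the sibling edge and clamp to zero.
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    siblings <- setdiff(which(tree$edge[, 1L] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(siblings) > 0L) {
      tree$edge.length[siblings[1L]] <-
        tree$edge.length[siblings[1L]] + deficit
      if (tree$edge.length[siblings[1L]] < 0) {
        # sibling went negative in turn: clamp without further transfer
        tree$edge.length[siblings[1L]] <- 0
      }
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree from Poisson-corrected distances, then
#' resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree per replicate, and annotates each internal edge of the
#' full-data tree with the percentage of replicates containing that
#' bipartition (via [ape::prop.clades()]).
#'
#' @param msa named character vector of equal-length aligned sequences
#'   (>= 4).
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param correction distance correction passed to [distance_matrix()].
#' @return an `phylo` tree whose `node.label` holds integer supports
#'   0-100 (root label empty).
#' @export
bootstrap_support <- function(msa, n_reps = 100L, seed = 1L,
                              correction = "poisson") {
  if (length(msa) < 4L) stop("bootstrap_support: need at least 4 sequences")
  widths <- unique(nchar(msa))
  if (length(widths) != 1L) stop("bootstrap_support: ragged alignment")
  main <- nj_tree(distance_matrix(msa, correction))
  mat <- do.call(rbind, lapply(msa, seq_chars))
  boots <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      rep_msa <- setNames(apply(mat[, cols, drop = FALSE], 1L, paste,
                                collapse = ""), names(msa))
      nj_tree(distance_matrix(rep_msa, correction))
    })
  })
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / n_reps)
  supports[1L] <- NA  # root of the unrooted representation
  main$node.label <- ifelse(is.na(supports), "", as.character(supports))
  main
}

#' Root a tree on an outgroup's pendant edge
#'
#' @param tree an `phylo` tree.
#' @param label outgroup leaf label (must be present).
#' @return rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, label) {
  if (!label %in% tree$tip.label) {
    stop("root_with_outgroup: label '", label, "' not in tree")
  }
  ape::root(tree, outgroup = label, resolve.root = TRUE)
}

#' Is a label set monophyletic?
#'
#' True when the label set equals exactly one clade's complete leaf set.
#'
#' @param tree an `phylo` tree.
#' @param labels leaf labels (all must be present).
#' @return logical.
#' @export
is_monophyletic <- function(tree, labels) {
  missing_labels <- setdiff(labels, tree$tip.label)
  if (length(missing_labels) > 0L) {
    stop("is_monophyletic: label(s) not in tree: ",
         paste(missing_labels, collapse = ", "))
  }
  ape::is.monophyletic(tree, labels)
}

#' Read / write trees in newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; branch
#' lengths and integer node supports survive a round-trip.
#'
#' @param tree an `phylo` tree.
#' @param path file path.
#' @return the tree (read) or `path` invisibly (write).
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
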