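#' Neighbour-joining tree from a distance matrix
#'
#' Classic neighbour joining, made fully deterministic: ties in the
#' Q-criterion are broken by the lexicographically smallest label pair.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the adjacent branch of the same join, preserving the joined path
#' length.
#'
#' @param dmat symmetric distance matrix with at least 3 labelled rows.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dmat) {
  stopifnot(is.matrix(dmat), nrow(dmat) == ncol(dmat))
  n <- nrow(dmat)
  if (n < 3) stop("neighbour joining needs at least 3 labels")
  labels <- rownames(dmat)
  if (is.null(labels) || anyNA(labels)) stop("distance matrix must be labelled")
  d <- dmat
  # each active node is represented by a Newick fragment (no trailing ;)
  frag <- setNames(as.list(labels), labels)
  rownames(d) <- colnames(d) <- labels

  fmt <- function(x) sprintf("%.10g", max(x, 0))

  while (nrow(d) > 3) {
    m <- nrow(d)
    rs <- rowSums(d)
    lab <- rownames(d)
    # Q matrix; choose min with lexicographic tie-break
    best <- NULL; best_q <- Inf
    ord <- order(lab)
    for (ii in seq_len(m - 1)) {
      for (jj in (ii + 1):m) {
        i <- ord[ii]; j <- ord[jj]
        q <- (m - 2) * d[i, j] - rs[i] - rs[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_lab <- paste0("(", lab[i], ")(", lab[j], ")")
    new_frag <- paste0("(", frag[[lab[i]]], ":", fmt(li), ",",
                       frag[[lab[j]]], ":", fmt(lj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    du <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du),
                c(du, 0))
    rownames(d2) <- colnames(d2) <- c(lab[keep], new_lab)
    d <- d2
    frag[[new_lab]] <- new_frag
  }
  lab <- rownames(d)
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- paste0("(", frag[[lab[1]]], ":", fmt(l1), ",",
                   frag[[lab[2]]], ":", fmt(l2), ",",
                   frag[[lab[3]]], ":", fmt(l3), ");")
  ape::read.tree(text = newick)
}

#' Bootstrap trees from an alignment
#'
#' Each replicate resamples alignment columns with replacement (keeping
#' the column count), recomputes pairwise identity distances and builds a
#' neighbour-joining tree. Reproducible given `seed`.
#'
#' @param aln alignment with at least 3 rows.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer RNG seed.
#' @return list of `phylo` trees.
#' @export
bootstrap_trees <- function(aln, n_reps, seed = 1) {
  m <- aln$matrix
  if (nrow(m) < 3) stop("bootstrap needs at least 3 sequences")
  if (n_reps < 1) stop("n_reps must be at least 1")
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- timp_alignment(m[, cols, drop = FALSE])
    nj_tree(pairwise_identity_matrix(rep_aln))
  })
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaves in two; the split is encoded as a
#' canonical key (the side containing the alphabetically first leaf,
#' sorted and concatenated) so rooted and unrooted trees compare
#' directly. Trivial splits (single leaf against the rest) are excluded.
#'
#' @param tree a `phylo`.
#' @return character vector of unique split keys.
#' @export
tree_splits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(p) {
    side <- tips[p]
    size <- length(side)
    if (size <= 1 || size >= n - 1) return(NA_character_)
    if (!(anchor %in% side)) side <- setdiff(tips, side)
    paste(sort(side), collapse = "\r")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Annotate bootstrap support on a best tree
#'
#' Support of an internal edge is the fraction of bootstrap trees whose
#' split set contains that edge's bipartition (0-1 scale). The summed
#' support over the best tree's unique non-trivial splits is attached as
#' attribute `support_sum`.
#'
#' @param best `phylo` tree to annotate.
#' @param boots list of bootstrap `phylo` trees over the same leaf set.
#' @return `best` with `node.label` holding per-clade support (root and
#'   trivial clades `NA`), attribute `support_sum`, and attribute
#'   `supports` (named by split key).
#' @export
edge_support <- function(best, boots) {
  for (b in boots) {
    if (!setequal(b$tip.label, best$tip.label))
      stop("bootstrap trees must share the best tree's leaf set")
  }
  boot_keys <- unlist(lapply(boots, tree_splits), use.names = FALSE)
  counts <- table(boot_keys)
  keys <- tree_splits(best)
  supports <- setNames(as.numeric(counts[keys]), keys)
  supports[is.na(supports)] <- 0
  supports <- supports / length(boots)

  # per-node annotation
  tips <- best$tip.label
  n <- length(tips)
  anchor <- sort(tips)[1]
  parts <- ape::prop.part(best)
  node_lab <- vapply(seq_along(parts), function(k) {
    side <- tips[parts[[k]]]
    size <- length(side)
    if (size <= 1 || size >= n - 1) return(NA_character_)
    if (!(anchor %in% side)) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "\r")
    format(supports[[key]], digits = 4)
  }, character(1))
  best$node.label <- node_lab
  attr(best, "supports") <- supports
  attr(best, "support_sum") <- sum(supports)
  best
}

#' Summed bootstrap support on a tree
#'
#' @inheritParams edge_support
#' @return numeric: the sum of bipartition supports over the best tree's
#'   unique non-trivial splits.
#' @export
support_sum <- function(best, boots) {
  attr(edge_support(best, boots), "support_sum")
}

#' Restrict a tree to a subset of leaves
#'
#' Degree-2 nodes created by the restriction are suppressed, summing
#' their branch lengths.
#'
#' @param tree `phylo`.
#' @param tips leaf labels to keep.
#' @return `phylo`.
#' @export
restrict_tree <- function(tree, tips) {
  missing_tips <- setdiff(tips, tree$tip.label)
  if (length(missing_tips))
    stop("tips not in tree: ", paste(missing_tips, collapse = ", "))
  ape::keep.tip(tree, tips)
}
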