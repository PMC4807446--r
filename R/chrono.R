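#' Make a rooted tree ultrametric by mean path lengths
#'
#' Each internal node is aged at the mean path length (sum of branch
#' lengths) to its descendant leaves; ages are then forced monotone by
#' lowering any child that would be older than its parent to the parent's
#' age, and finally rescaled so the root sits at `root_age` with all
#' leaves at age 0. The root age is an arbitrary unit choice: it cancels
#' from any statistic that is invariant under uniform time rescaling (the
#' gamma statistic is).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param root_age age assigned to the root; default 100.
#' @return an ultrametric rooted `phylo` with attribute `root_age`.
#' @export
ultrametricize_mpl <- function(tree, root_age = 100) {
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it (e.g. ape::root on an outgroup) first")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L

  # mean path length to descendant leaves, by postorder accumulation of
  # (leaf count, total path length) per node
  cnt <- c(rep(1, n_tip), rep(0, n_node))
  tot <- rep(0, n_tip + n_node)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]; child <- po$edge[k, 2]
    len <- po$edge.length[k]
    cnt[parent] <- cnt[parent] + cnt[child]
    tot[parent] <- tot[parent] + tot[child] + cnt[child] * len
  }
  age <- rep(0, n_tip + n_node)
  internal <- (n_tip + 1L):(n_tip + n_node)
  age[internal] <- tot[internal] / cnt[internal]

  # monotonicity: children may not be older than their parents (preorder)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[k, 1]; child <- pre$edge[k, 2]
    if (child > n_tip && age[child] > age[parent]) age[child] <- age[parent]
  }

  if (age[root] <= 0) stop("root age is zero; tree has no depth")
  age <- age * (root_age / age[root])

  out <- tree
  out$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  attr(out, "root_age") <- root_age
  out
}

#' Prune a tree to one specimen's gene copies plus outgroups
#'
#' @param tree `phylo` whose tips are record ids.
#' @param records record set mapping ids to specimens.
#' @param focal_specimen specimen label; must have at least 3 tips in the
#'   tree.
#' @param outgroup_ids record ids retained as outgroups.
#' @return `phylo` restricted to the focal copies plus outgroups.
#' @export
prune_to_specimen <- function(tree, records, focal_specimen,
                              outgroup_ids = character(0)) {
  validate_records(records)
  focal <- records$id[records$specimen %in% focal_specimen]
  focal <- intersect(tree$tip.label, focal)
  if (length(focal) < 3)
    stop("specimen '", focal_specimen, "' has fewer than 3 tips in the tree")
  keep <- union(focal, intersect(outgroup_ids, tree$tip.label))
  restrict_tree(tree, keep)
}

#' Lineages-through-time profile of an ultrametric tree
#'
#' Orders the internal-node ages to obtain the internode intervals
#' `g_k` (the time during which exactly k lineages exist, k = 2..n) and
#' the cumulative sums `T_i = sum_{k=2..i} k g_k` used by the gamma
#' statistic.
#'
#' @param tree rooted ultrametric `phylo` with at least 3 tips.
#' @param tol relative tolerance for the ultrametricity check.
#' @return list of class `ltt_profile`: `n`, `g` (named `g2..gn`),
#'   `T_i` (length n-1, `T_i[k-1]` = T_k), `total` (= T_n) and
#'   `root_age`.
#' @export
ltt_profile <- function(tree, tol = 1e-6) {
  n <- length(tree$tip.label)
  if (n < 3) stop("LTT profile needs at least 3 tips")
  if (!ape::is.ultrametric(tree, tol = tol))
    stop("tree is not ultrametric; see ultrametricize_mpl()")
  ages <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  # ages[1] = root (2 lineages onwards), ages[k] = birth of lineage k+1
  g <- c(ages, 0)
  g <- g[-length(g)] - g[-1]          # g_k = ages[k-1] - ages[k], k = 2..n
  names(g) <- paste0("g", 2:n)
  kg <- (2:n) * g
  T_i <- cumsum(kg)
  structure(list(n = n, g = g, T_i = unname(T_i), total = unname(T_i[n - 1]),
                 root_age = ages[1]),
            class = "ltt_profile")
}

#' Gamma statistic of constant-rate diversification
#'
#' The Pybus-Harvey gamma compares the mean of the cumulative internode
#' sums `T_2..T_{n-1}` against half the total `T`, standardized so that a
#' pure-birth (Yule) history gives a standard normal deviate. Negative
#' values indicate early accumulation of lineages, positive values recent
#' accumulation. The two-tailed p-value is `2 * (1 - pnorm(abs(gamma)))`.
#'
#' @param x an `ltt_profile` or an ultrametric `phylo`.
#' @return list with `gamma`, `p` and `n`.
#' @export
gamma_stat <- function(x) {
  profile <- if (inherits(x, "ltt_profile")) x else ltt_profile(x)
  n <- profile$n
  if (n < 3) stop("gamma needs at least 3 tips")
  total <- profile$total
  if (!(total > 0)) stop("profile has zero total length")
  inner <- mean(profile$T_i[seq_len(n - 2)])
  gamma <- unname((inner - total / 2) / (total * sqrt(1 / (12 * (n - 2)))))
  list(gamma = gamma, p = 2 * (1 - pnorm(abs(gamma))), n = n)
}

#' Per-specimen diversification summary
#'
#' For every specimen with at least `min_copies` tips in the tree, prunes
#' to that specimen's copies plus the outgroups, extracts the LTT profile
#' and computes the gamma statistic.
#'
#' @param tree rooted ultrametric `phylo` with record-id tips.
#' @param records record set mapping ids to specimens.
#' @param outgroup_ids tips kept as outgroups in every pruned tree.
#' @param min_copies minimum gene-copy count per specimen; default 10.
#' @param include_outgroups keep the outgroups in the profile (default),
#'   or drop them before computing gamma.
#' @return data.frame with `specimen`, `n_copies`, `n_tips`, `gamma`, `p`.
#' @export
diversification_by_specimen <- function(tree, records, outgroup_ids,
                                        min_copies = 10,
                                        include_outgroups = TRUE) {
  validate_records(records)
  in_tree <- records[records$id %in% tree$tip.label, , drop = FALSE]
  in_tree <- in_tree[!in_tree$id %in% outgroup_ids, , drop = FALSE]
  copies <- table(in_tree$specimen)
  focal <- names(copies)[copies >= min_copies]
  rows <- lapply(sort(focal), function(sp) {
    sub <- prune_to_specimen(tree, records, sp,
                             if (include_outgroups) outgroup_ids else character(0))
    g <- gamma_stat(sub)
    data.frame(specimen = sp, n_copies = as.integer(copies[[sp]]),
               n_tips = length(sub$tip.label),
               gamma = g$gamma, p = g$p, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(specimen = character(0), n_copies = integer(0),
               n_tips = integer(0), gamma = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  out
}
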