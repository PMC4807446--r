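#' Greedy rogue-terminal pruning by summed-support improvement
#'
#' A rogue (or "bouncing") terminal attaches inconsistently across
#' bootstrap replicates, depressing support on the best tree. This
#' implements the per-terminal rule: at each step, every remaining leaf is
#' tentatively dropped, the best tree and all bootstrap trees are
#' restricted to the remaining leaves, and the summed bipartition support
#' on the restricted best tree is recomputed. The leaf giving the largest
#' improvement is removed if the improvement is at least
#' `min_improvement`; ties are broken by leaf id. The loop stops when no
#' removal qualifies or only 4 leaves remain.
#'
#' Supports are on the 0-1 scale, so the default threshold 0.2 is a fifth
#' of one fully supported edge.
#'
#' @param best best `phylo` tree.
#' @param boots list of bootstrap trees over the same leaf set.
#' @param min_improvement minimum gain in summed support; default 0.2.
#' @return list of class `rogue_report`: `removals` (data.frame with `id`,
#'   `support_sum_before`, `support_sum_after`, `improvement`), `tree`
#'   (final restricted best tree), `removed_ids`, `min_improvement`.
#' @export
prune_rogues <- function(best, boots, min_improvement = 0.2) {
  for (b in boots) {
    if (!setequal(b$tip.label, best$tip.label))
      stop("bootstrap trees must share the best tree's leaf set")
  }
  if (length(best$tip.label) < 5)
    stop("rogue pruning needs at least 5 leaves")

  leaves <- sort(best$tip.label)
  removals <- list()

  current_sum <- function(keep) {
    b <- restrict_tree(best, keep)
    bs <- lapply(boots, restrict_tree, tips = keep)
    support_sum(b, bs)
  }

  base <- current_sum(leaves)
  repeat {
    if (length(leaves) <= 4) break
    gains <- vapply(leaves, function(cand) {
      current_sum(setdiff(leaves, cand)) - base
    }, numeric(1))
    best_gain <- max(gains)
    if (best_gain < min_improvement || !is.finite(best_gain)) break
    cand <- sort(names(gains)[gains >= best_gain - 1e-12])[1]
    removals[[length(removals) + 1L]] <- data.frame(
      id = cand,
      support_sum_before = base,
      support_sum_after = base + gains[[cand]],
      improvement = gains[[cand]],
      stringsAsFactors = FALSE
    )
    leaves <- setdiff(leaves, cand)
    base <- base + gains[[cand]]
  }

  removal_df <- if (length(removals)) do.call(rbind, removals) else
    data.frame(id = character(0), support_sum_before = numeric(0),
               support_sum_after = numeric(0), improvement = numeric(0))
  rownames(removal_df) <- NULL
  structure(list(
    removals = removal_df,
    tree = restrict_tree(best, leaves),
    removed_ids = removal_df$id,
    min_improvement = min_improvement
  ), class = "rogue_report")
}
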