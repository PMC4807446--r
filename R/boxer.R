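#' Select a culled alignment by taxon retention under a gap ceiling
#'
#' Implements the grid-selection rule: among the culled alignments whose
#' overall gap fraction is at most `max_gap_pct` percent (and which retain
#' at least one sequence of `anchor_taxon`, when given), prefer the one
#' keeping the most unique taxa (specimens, not sequences); ties go to the
#' smaller gap fraction, remaining ties to the larger `(R, S)` key. If the
#' gap ceiling excludes every candidate, the rule relaxes to the
#' anchor-satisfying candidate with the smallest gap fraction and the
#' choice is flagged `relaxed`.
#'
#' @param grid a [cull_grid()].
#' @param max_gap_pct gap ceiling, percent of the whole alignment;
#'   default 50.
#' @param anchor_taxon optional specimen label that must survive in the
#'   chosen alignment.
#' @return list of class `boxer_choice`: `key`, `residue_overlap`,
#'   `sequence_overlap`, `unique_taxa`, `gap_fraction`,
#'   `anchor_satisfied`, `relaxed`, and `ranked` (all candidates with
#'   statistics, chosen row first).
#' @export
boxer_select <- function(grid, max_gap_pct = 50, anchor_taxon = NULL) {
  stopifnot(inherits(grid, "cull_grid"))
  tab <- grid$table
  if (nrow(tab) == 0) stop("empty cull grid")
  keys <- paste0(tab$residue_overlap, "_", tab$sequence_overlap)

  anchor_ok <- rep(TRUE, nrow(tab))
  if (!is.null(anchor_taxon)) {
    anchor_ok <- vapply(keys, function(k) {
      res <- grid$results[[k]]
      if (is.null(res$alignment)) return(FALSE)
      meta <- res$alignment$meta
      !is.null(meta) && anchor_taxon %in% meta$specimen
    }, logical(1))
    if (!any(anchor_ok)) {
      # report the cells where the anchor survived the most iterations
      last_iter <- vapply(keys, function(k) {
        rem <- grid$results[[k]]$removed
        max(c(0L, rem$iteration))
      }, numeric(1))
      stop("anchor taxon '", anchor_taxon,
           "' survives in no candidate; it lasted longest in cell(s): ",
           paste(keys[last_iter == max(last_iter)], collapse = ", "))
    }
  }

  cand <- which(anchor_ok & !is.na(tab$gap_fraction) &
                  tab$gap_fraction <= max_gap_pct / 100)
  relaxed <- FALSE
  if (!length(cand)) {
    relaxed <- TRUE
    pool <- which(anchor_ok & !is.na(tab$gap_fraction))
    cand <- pool[which.min(tab$gap_fraction[pool])]
  }

  ord <- order(-tab$unique_taxa[cand], tab$gap_fraction[cand],
               -tab$residue_overlap[cand], -tab$sequence_overlap[cand])
  pick <- cand[ord[1]]

  rank_all <- order(!anchor_ok, is.na(tab$gap_fraction),
                    tab$gap_fraction > max_gap_pct / 100,
                    -tab$unique_taxa, tab$gap_fraction,
                    -tab$residue_overlap, -tab$sequence_overlap)
  ranked <- tab[rank_all, , drop = FALSE]
  ranked$key <- keys[rank_all]
  ranked$anchor_satisfied <- anchor_ok[rank_all]
  ranked$chosen <- ranked$key == keys[pick]
  rownames(ranked) <- NULL

  structure(list(
    key = keys[pick],
    residue_overlap = tab$residue_overlap[pick],
    sequence_overlap = tab$sequence_overlap[pick],
    unique_taxa = tab$unique_taxa[pick],
    gap_fraction = tab$gap_fraction[pick],
    anchor_satisfied = anchor_ok[pick],
    relaxed = relaxed,
    ranked = ranked
  ), class = "boxer_choice")
}

#' @export
print.boxer_choice <- function(x, ...) {
  cat(sprintf(
    "boxer_choice: cell (R=%s, S=%s), %d unique taxa, gap fraction %.3f%s\n",
    x$residue_overlap, x$sequence_overlap, x$unique_taxa, x$gap_fraction,
    if (x$relaxed) " (gap ceiling relaxed)" else ""))
  invisible(x)
}
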