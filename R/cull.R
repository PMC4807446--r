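#' Column occupancy (residue overlap per column)
#'
#' @param aln alignment.
#' @return numeric vector: per column, the proportion of rows carrying a
#'   residue (not a gap).
#' @export
column_occupancy <- function(aln) {
  m <- aln$matrix
  if (length(m) == 0) stop("empty alignment")
  colMeans(m != "-")
}

#' Per-sequence overlap scores
#'
#' Two statistics per aligned sequence: `seq_overlap` is the percentage of
#' its positions carrying residues; `res_score` is 100 times the mean
#' column occupancy over the columns where the sequence has residues (a
#' residue sitting in a full column scores 100, one alone in an otherwise
#' gapped column scores near 0). A row with no residues scores (0, 0).
#'
#' @param aln alignment.
#' @return data.frame with `id`, `res_score`, `seq_overlap` in row order.
#' @export
sequence_scores <- function(aln) {
  m <- aln$matrix
  if (length(m) == 0) stop("empty alignment")
  occ <- colMeans(m != "-")
  res <- m != "-"
  seq_overlap <- 100 * rowMeans(res)
  res_score <- vapply(seq_len(nrow(m)), function(i) {
    cols <- res[i, ]
    if (!any(cols)) return(0)
    100 * mean(occ[cols])
  }, numeric(1))
  data.frame(id = rownames(m), res_score = res_score,
             seq_overlap = seq_overlap, stringsAsFactors = FALSE)
}

#' Iterative overlap culling at one threshold pair
#'
#' Align, score, remove every sequence failing either threshold, realign
#' the survivors, and repeat until no sequence fails, at most 2 survivors
#' remain, or the iteration cap is reached. A score exactly at a threshold
#' passes. Removal order is recorded by iteration and then by ascending
#' residue score.
#'
#' @param records record set (>= 2 rows).
#' @param residue_overlap threshold R in (0, 100] on `res_score`.
#' @param sequence_overlap threshold S in (0, 100] on `seq_overlap`.
#' @param settings [aligner_settings()].
#' @param max_iter iteration cap; default `nrow(records) + 1`.
#' @param cache optional environment memoizing alignments by survivor set
#'   (shared across grid cells).
#' @return list of class `cull_result`: `settings` (R, S), `alignment`,
#'   `removed` (data.frame `id`, `iteration`, `res_score`, `seq_overlap`),
#'   `removed_ids`, `n_iterations`, `gap_fraction`, `unique_taxa`,
#'   `degenerate`.
#' @export
cull_iterate <- function(records, residue_overlap, sequence_overlap,
                         settings = NULL, max_iter = NULL, cache = NULL) {
  validate_records(records)
  if (nrow(records) < 2) stop("culling needs at least 2 records")
  stopifnot(residue_overlap > 0, residue_overlap <= 100,
            sequence_overlap > 0, sequence_overlap <= 100)
  if (is.null(max_iter)) max_iter <- nrow(records) + 1L
  if (is.null(settings))
    settings <- aligner_settings(
      alphabet = if (records$seq_type[1] == "aa") "aa" else "nuc")

  align_cached <- function(rec) {
    if (is.null(cache)) return(align_records(rec, settings))
    key <- paste(rec$id, collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- align_records(rec, settings)
    cache[[key]]
  }

  surv <- records
  removed <- list()
  iter <- 0L
  aln <- align_cached(surv)
  degenerate <- FALSE
  repeat {
    iter <- iter + 1L
    sc <- sequence_scores(aln)
    fail <- sc$res_score < residue_overlap | sc$seq_overlap < sequence_overlap
    if (!any(fail) || iter > max_iter) break
    dropped <- sc[fail, , drop = FALSE]
    dropped <- dropped[order(dropped$res_score, dropped$id), , drop = FALSE]
    dropped$iteration <- iter
    removed[[length(removed) + 1L]] <- dropped
    surv <- surv[!surv$id %in% dropped$id, , drop = FALSE]
    if (nrow(surv) < 2) { degenerate <- TRUE; break }
    aln <- align_cached(surv)
    if (nrow(surv) == 2) break
  }
  removed_df <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(0), res_score = numeric(0),
               seq_overlap = numeric(0), iteration = integer(0))
  rownames(removed_df) <- NULL
  if (nrow(surv) == 0) {
    aln <- NULL
  } else if (nrow(surv) == 1) {
    aln <- align_records(surv, settings)
  }
  taxa <- if (nrow(surv)) length(unique(surv$specimen[!is.na(surv$specimen)]))
          else 0L
  structure(list(
    settings = c(residue_overlap = residue_overlap,
                 sequence_overlap = sequence_overlap),
    alignment = aln,
    removed = removed_df,
    removed_ids = removed_df$id,
    n_iterations = iter,
    gap_fraction = if (is.null(aln)) NA_real_ else gap_fraction(aln),
    unique_taxa = taxa,
    degenerate = degenerate
  ), class = "cull_result")
}

#' Cull over the full threshold grid
#'
#' Runs [cull_iterate()] independently for every combination of the
#' residue- and sequence-overlap thresholds (default 50..100 by 10,
#' giving 36 culled alignments). Alignments are memoized across cells by
#' survivor set, so identical culling paths are aligned once.
#'
#' @param records record set.
#' @param settings [aligner_settings()].
#' @param thresholds threshold values used for both parameters.
#' @return list of class `cull_grid`: `results` (list keyed `"R_S"`),
#'   `thresholds`, and `table` (data.frame with one row per cell:
#'   `residue_overlap`, `sequence_overlap`, `n_kept`, `unique_taxa`,
#'   `gap_fraction`, `n_iterations`, `degenerate`).
#' @export
cull_grid <- function(records, settings = NULL,
                      thresholds = seq(50, 100, by = 10)) {
  validate_records(records)
  cache <- new.env(parent = emptyenv())
  results <- list()
  rows <- list()
  for (R in thresholds) {
    for (S in thresholds) {
      res <- cull_iterate(records, R, S, settings = settings, cache = cache)
      key <- paste0(R, "_", S)
      results[[key]] <- res
      rows[[key]] <- data.frame(
        residue_overlap = R, sequence_overlap = S,
        n_kept = nrow(records) - length(res$removed_ids),
        unique_taxa = res$unique_taxa,
        gap_fraction = res$gap_fraction,
        n_iterations = res$n_iterations,
        degenerate = res$degenerate
      )
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(results = results, thresholds = thresholds, table = tab),
            class = "cull_grid")
}
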