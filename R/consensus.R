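#' Threshold consensus of an alignment, counting gaps as sites
#'
#' For each column, the most frequent residue is emitted iff its count
#' over *all* selected rows -- gapped rows included in the denominator --
#' reaches `threshold_pct` percent. Gaps are never emitted as consensus;
#' columns failing the threshold, and columns where two residues tie at
#' the maximal count, print `-`.
#'
#' @param aln alignment.
#' @param threshold_pct threshold in (0, 100].
#' @param ids optional row ids selecting a group (default: all rows).
#' @param group label stored on the profile (e.g. a clade name).
#' @return list of class `consensus_profile`: `consensus` (string over
#'   alignment columns), `sites` (data.frame `position`, `residue` of
#'   conserved sites, 1-based alignment coordinates), `threshold_pct`,
#'   `group`, `n_rows`.
#' @export
threshold_consensus <- function(aln, threshold_pct, ids = NULL,
                                group = "all") {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  m <- aln$matrix
  if (!is.null(ids)) {
    keep <- rownames(m) %in% ids
    if (!any(keep)) stop("group selects no rows")
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m)
  need <- threshold_pct / 100
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    if (!length(col)) return("-")
    counts <- sort(table(col), decreasing = TRUE)
    top <- counts[1]
    if (top / n < need) return("-")
    if (sum(counts == top) > 1) return("-")   # tied winners are ambiguous
    names(top)
  }, character(1))
  sites <- data.frame(position = which(cons != "-"),
                      residue = cons[cons != "-"],
                      stringsAsFactors = FALSE)
  structure(list(consensus = paste(cons, collapse = ""), sites = sites,
                 threshold_pct = threshold_pct, group = group, n_rows = n),
            class = "consensus_profile")
}

#' Consensus profiles for several groups and thresholds
#'
#' @param aln alignment whose metadata carries a `clade` column.
#' @param thresholds percentage thresholds for the "all" group.
#' @param group_threshold threshold used for each per-clade consensus.
#' @return list of `consensus_profile`s named `"all<t>"` and
#'   `"<clade><group_threshold>"`.
#' @export
group_consensus <- function(aln, thresholds = c(90, 80, 70, 60, 50),
                            group_threshold = 70) {
  out <- list()
  for (t in thresholds)
    out[[paste0("all", t)]] <- threshold_consensus(aln, t, group = "all")
  meta <- aln$meta
  if (!is.null(meta)) {
    for (cl in sort(unique(meta$clade))) {
      ids <- meta$id[meta$clade == cl]
      out[[paste0(cl, group_threshold)]] <-
        threshold_consensus(aln, group_threshold, ids = ids, group = cl)
    }
  }
  out
}

#' Positions of a conserved residue in a consensus profile
#'
#' @param profile a `consensus_profile`.
#' @param residue single residue character, e.g. `"C"` for the cysteine
#'   inventory.
#' @return list with `positions` (1-based alignment coordinates) and
#'   `count`.
#' @export
conserved_inventory <- function(profile, residue) {
  stopifnot(inherits(profile, "consensus_profile"), nchar(residue) == 1)
  hit <- profile$sites[profile$sites$residue == toupper(residue), ,
                       drop = FALSE]
  list(positions = hit$position, count = nrow(hit))
}

#' Scan degapped sequences for an exact motif
#'
#' Sequences are degapped before scanning, so a motif interrupted by
#' alignment gaps (e.g. an H-P-Q split across columns) still counts --
#' the alignment-column view and the degapped view differ exactly when
#' gaps interrupt the motif.
#'
#' @param records record set (gap characters, if any, are removed).
#' @param motif motif string, length >= 2 (e.g. `"HPQ"`, `"VIRAK"`).
#' @return list of class `motif_hits`: `motif`, `hits` (data.frame `id`,
#'   `specimen`, `clade`, `position` in degapped coordinates),
#'   `by_group` (named counts of hit-carrying records per clade),
#'   `by_specimen` (same per specimen).
#' @export
motif_scan <- function(records, motif) {
  validate_records(records)
  motif <- toupper(motif)
  if (nchar(motif) < 2) stop("motif must have at least 2 residues")
  rows <- list()
  for (i in seq_len(nrow(records))) {
    seq <- gsub("-", "", records$sequence[i], fixed = TRUE)
    pos <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    pos <- pos[pos > 0]
    for (p in pos)
      rows[[length(rows) + 1L]] <- data.frame(
        id = records$id[i], specimen = records$specimen[i],
        clade = records$clade[i], position = p, stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), specimen = character(0),
               clade = character(0), position = integer(0))
  carriers <- unique(hits[, c("id", "specimen", "clade")])
  structure(list(
    motif = motif,
    hits = hits,
    by_group = if (nrow(carriers)) table(carriers$clade) else
      table(character(0)),
    by_specimen = if (nrow(carriers)) table(carriers$specimen) else
      table(character(0))
  ), class = "motif_hits")
}
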