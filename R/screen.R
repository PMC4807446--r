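#' Flag highly divergent records from a distance matrix
#'
#' Applies a robust outlier rule to the per-record mean distance to all
#' other records: a record is flagged when its mean distance exceeds
#' `median + z_cut * MAD` of the mean-distance distribution. When the MAD
#' is zero (all records equidistant) nothing is flagged. The result is
#' ordered by descending mean distance.
#'
#' @param dmat symmetric distance matrix with labelled rows (see
#'   [pairwise_identity_matrix()]).
#' @param z_cut positive multiplier on the MAD; default 3.
#' @return character vector of flagged ids (possibly empty).
#' @export
flag_divergent <- function(dmat, z_cut = 3) {
  stopifnot(is.matrix(dmat), nrow(dmat) == ncol(dmat), z_cut > 0)
  n <- nrow(dmat)
  if (n < 3) stop("divergence screening needs at least 3 records")
  mean_d <- rowSums(dmat) / (n - 1)
  med <- median(mean_d)
  scale <- mad(mean_d, center = med)
  if (scale == 0) return(character(0))
  hits <- mean_d > med + z_cut * scale
  names(sort(mean_d[hits], decreasing = TRUE))
}

#' Remove byte-identical duplicate sequences
#'
#' Within each group of identical (degapped) sequences one keeper is
#' retained: the record with the highest read depth, ties broken by the
#' lexicographically smallest id. Intended for nucleotide record sets; the
#' removed ids can be mirrored onto companion amino-acid / coding sets by
#' id.
#'
#' @param records record set.
#' @return list with `kept` (record set), `removed_ids` and
#'   `duplicate_groups` (list of data.frames with `id`, `read_depth`,
#'   `keeper`).
#' @export
dedup_identical <- function(records) {
  validate_records(records)
  grp <- split(seq_len(nrow(records)), records$sequence)
  grp <- grp[lengths(grp) > 1]
  removed <- character(0)
  groups <- list()
  for (idx in grp) {
    sub <- records[idx, , drop = FALSE]
    depth <- ifelse(is.na(sub$read_depth), -Inf, sub$read_depth)
    ord <- order(-depth, sub$id)
    keeper <- sub$id[ord[1]]
    removed <- c(removed, setdiff(sub$id, keeper))
    groups[[length(groups) + 1L]] <-
      data.frame(id = sub$id, read_depth = sub$read_depth,
                 keeper = sub$id == keeper, stringsAsFactors = FALSE)
  }
  list(
    kept = records[!records$id %in% removed, , drop = FALSE],
    removed_ids = removed,
    duplicate_groups = groups
  )
}

#' Flag putative cross-clade contaminants
#'
#' A record is flagged when it shares a long exact run of residues with a
#' reference from a distant clade (longest common substring at least
#' `min_run`) *and* its read depth is below `depth_cut`. Records from the
#' same clade as a reference are never compared against it, and records
#' with no read depth are never flagged (they are returned in the
#' `unevaluable` attribute instead).
#'
#' @param records record set to screen.
#' @param references record set of distant-clade references.
#' @param min_run minimum shared exact run, residues; default 50.
#' @param depth_cut read-depth ceiling for flagging; default 50.
#' @return character vector of flagged ids, with attribute `unevaluable`.
#' @export
flag_contaminant <- function(records, references, min_run = 50,
                             depth_cut = 50) {
  validate_records(records)
  validate_records(references)
  stopifnot(min_run >= 20)
  flagged <- character(0)
  uneval <- character(0)
  for (i in seq_len(nrow(records))) {
    refs <- references[references$clade != records$clade[i], , drop = FALSE]
    if (nrow(refs) == 0) next
    run <- max(vapply(refs$sequence, lcs_substring_cpp,
                      integer(1), a = records$sequence[i]))
    if (run < min_run) next
    if (is.na(records$read_depth[i])) {
      uneval <- c(uneval, records$id[i])
    } else if (records$read_depth[i] < depth_cut) {
      flagged <- c(flagged, records$id[i])
    }
  }
  structure(flagged, unevaluable = uneval)
}

#' Run the full pre-culling screen
#'
#' Convenience wrapper: aligns the records (or uses a supplied alignment),
#' flags divergent records, removes identical duplicates and flags
#' contaminants against the supplied references.
#'
#' @param records record set.
#' @param references optional distant-clade references for the contaminant
#'   screen.
#' @param alignment optional precomputed [timp_alignment()].
#' @param z_cut,min_run,depth_cut screen parameters.
#' @param settings aligner settings used if `alignment` is `NULL`.
#' @return list of class `screen_report`: `divergent_ids`,
#'   `duplicate_groups`, `removed_duplicate_ids`, `contaminant_ids`,
#'   `kept` (record set after removing all of the above), `parameters`.
#' @export
screen_records <- function(records, references = NULL, alignment = NULL,
                           z_cut = 3, min_run = 50, depth_cut = 50,
                           settings = NULL) {
  validate_records(records)
  if (is.null(alignment)) {
    if (is.null(settings)) settings <- aligner_settings(
      alphabet = if (records$seq_type[1] == "aa") "aa" else "nuc")
    alignment <- align_records(records, settings)
  }
  divergent <- if (nrow(records) >= 3)
    flag_divergent(pairwise_identity_matrix(alignment), z_cut)
  else character(0)
  dd <- dedup_identical(records)
  contaminants <- if (!is.null(references))
    flag_contaminant(records, references, min_run, depth_cut)
  else character(0)
  drop <- union(union(divergent, dd$removed_ids), contaminants)
  structure(list(
    divergent_ids = divergent,
    duplicate_groups = dd$duplicate_groups,
    removed_duplicate_ids = dd$removed_ids,
    contaminant_ids = as.character(contaminants),
    kept = records[!records$id %in% drop, , drop = FALSE],
    parameters = list(z_cut = z_cut, min_run = min_run,
                      depth_cut = depth_cut)
  ), class = "screen_report")
}

#' Write a screen report as TSV
#'
#' One row per action: `id`, `action` (divergent / duplicate /
#' contaminant), `reason`, `statistic`.
#'
#' @param report a `screen_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path) {
  rows <- list()
  for (id in report$divergent_ids)
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, action = "divergent", reason = "mean distance outlier",
      statistic = NA_real_)
  for (g in report$duplicate_groups)
    for (i in which(!g$keeper))
      rows[[length(rows) + 1L]] <- data.frame(
        id = g$id[i], action = "duplicate",
        reason = paste0("identical to ", g$id[g$keeper][1]),
        statistic = g$read_depth[i])
  for (id in report$contaminant_ids)
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, action = "contaminant", reason = "shared run with distant clade",
      statistic = NA_real_)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), action = character(0),
               reason = character(0), statistic = numeric(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
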