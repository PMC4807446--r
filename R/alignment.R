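#' Alignment container
#'
#' An alignment is a character matrix of single residues or `"-"`, with row
#' names equal to record ids, plus the metadata of the underlying records.
#' `"?"` and `"."` are normalized to `"-"` on construction; `X`/`N` are
#' residues, not gaps. Degapping a row must reproduce the source sequence.
#'
#' @param seqs named character vector of gapped sequences, all the same
#'   length, or a character matrix of single characters with row names.
#' @param meta optional record metadata (`data.frame` with at least `id`;
#'   matched by id).
#' @return An object of class `timp_alignment` with elements `matrix`
#'   (characters) and `meta`.
#' @export
timp_alignment <- function(seqs, meta = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by record id")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1)
      stop("gapped sequences differ in length")
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
  }
  m[m %in% c("?", ".")] <- "-"
  m <- toupper(m)
  if (is.null(rownames(m))) stop("alignment rows must be named")
  aln <- structure(list(matrix = m, meta = NULL), class = "timp_alignment")
  if (!is.null(meta)) {
    hit <- match(rownames(m), meta$id)
    if (anyNA(hit)) {
      aln$meta <- NULL
    } else {
      aln$meta <- meta[hit, , drop = FALSE]
      rownames(aln$meta) <- NULL
    }
  }
  aln
}

#' @export
print.timp_alignment <- function(x, ...) {
  cat(sprintf("timp_alignment: %d sequences x %d columns (gap fraction %.3f)\n",
              nrow(x$matrix), ncol(x$matrix), gap_fraction(x)))
  invisible(x)
}

#' @export
dim.timp_alignment <- function(x) dim(x$matrix)

#' Alignment ids
#' @param aln alignment.
#' @return character vector of row ids.
#' @export
alignment_ids <- function(aln) rownames(aln$matrix)

#' Number of alignment columns
#' @param aln alignment.
#' @return integer.
#' @export
n_columns <- function(aln) ncol(aln$matrix)

#' Degap an alignment back to records
#'
#' @param aln alignment.
#' @param seq_type sequence type for the resulting records.
#' @return record set in alignment row order.
#' @export
alignment_to_records <- function(aln, seq_type = "aa") {
  seqs <- apply(aln$matrix, 1L, function(r) paste(r[r != "-"], collapse = ""))
  if (!is.null(aln$meta)) {
    rec <- aln$meta
    rec$sequence <- unname(seqs)
    rec[, c("id", "sequence", "specimen", "clade", "read_depth", "seq_type")]
  } else {
    timp_records(rownames(aln$matrix), unname(seqs), seq_type = seq_type)
  }
}

#' Read a NEXUS alignment
#'
#' Accepts both sequential and interleaved DATA/CHARACTERS blocks; `"?"`
#' and `"."` are read as gaps.
#'
#' @param path NEXUS file.
#' @param meta optional record metadata matched by taxon label.
#' @return A [timp_alignment()].
#' @export
load_nexus_alignment <- function(path, meta = NULL) {
  dat <- tryCatch(ape::read.nexus.data(path),
                  error = function(e) stop("failed to parse NEXUS: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dat) == 0) stop("NEXUS file contains no taxa")
  lens <- lengths(dat)
  if (length(unique(lens)) != 1)
    stop("NEXUS taxa have unequal sequence lengths")
  m <- do.call(rbind, dat)
  timp_alignment(toupper(m), meta = meta)
}

#' Validate an externally produced alignment against a record set
#'
#' Lets a production aligner's output (aligned FASTA) be substituted for
#' the built-in engine: ids and degapped sequences must match the record
#' set exactly.
#'
#' @param path aligned FASTA.
#' @param records the record set the alignment claims to align.
#' @return A [timp_alignment()] carrying the records' metadata.
#' @export
external_alignment_adapter <- function(path, records) {
  validate_records(records)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  missing_ids <- setdiff(records$id, ids)
  extra_ids <- setdiff(ids, records$id)
  if (length(missing_ids) || length(extra_ids))
    stop("alignment/record id mismatch; missing: [",
         paste(missing_ids, collapse = ", "), "] extra: [",
         paste(extra_ids, collapse = ", "), "]")
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs <- seqs[records$id]
  aln <- timp_alignment(seqs, meta = records)
  degap <- apply(aln$matrix, 1L, function(r) paste(r[r != "-"], collapse = ""))
  bad <- records$id[degap != records$sequence]
  if (length(bad))
    stop("degapped sequence mismatch for id(s): ", paste(bad, collapse = ", "))
  aln
}

#' Pairwise identity distance matrix
#'
#' `d(i, j) = 1 - matches / shared`, where only columns in which both rows
#' carry residues are counted; rows with no shared residue columns are at
#' distance 1. This is the usual "pairwise gap deletion" identity distance.
#'
#' @param aln alignment with at least two rows.
#' @return symmetric numeric matrix with zero diagonal, labelled by id.
#' @export
pairwise_identity_matrix <- function(aln) {
  m <- aln$matrix
  if (nrow(m) < 2) stop("need at least two sequences for a distance matrix")
  codes <- matrix(match(m, c("-", LETTERS, "*")) - 1L, nrow = nrow(m))
  codes[is.na(codes)] <- 28L  # unexpected symbols pooled as one residue code
  d <- identity_dist_cpp(codes)
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Overall gap fraction of an alignment
#'
#' @param aln alignment.
#' @return gaps / (rows x columns), in `[0, 1]`.
#' @export
gap_fraction <- function(aln) {
  m <- aln$matrix
  if (length(m) == 0) stop("empty alignment")
  mean(m == "-")
}

#' Restrict an alignment to a subset of rows
#'
#' @param aln alignment.
#' @param ids row ids to keep (order preserved from the alignment).
#' @param drop_empty_columns drop columns that become all-gap.
#' @return alignment.
#' @export
subset_alignment <- function(aln, ids, drop_empty_columns = FALSE) {
  keep <- rownames(aln$matrix) %in% ids
  m <- aln$matrix[keep, , drop = FALSE]
  if (drop_empty_columns && nrow(m) > 0) {
    m <- m[, colSums(m != "-") > 0, drop = FALSE]
  }
  meta <- if (!is.null(aln$meta)) aln$meta[keep, , drop = FALSE] else NULL
  timp_alignment(m, meta = meta)
}
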