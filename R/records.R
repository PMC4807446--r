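#' Construct a set of transcript records
#'
#' A record set is the package's core sequence container: one row per
#' transcript, holding the ungapped sequence, the specimen it was assembled
#' from, a clade label (e.g. one of the five echinoderm classes, "chordate",
#' "protostome" or "outgroup"), and the per-contig read depth when known.
#'
#' @param id character vector of unique record ids.
#' @param sequence character vector of gap-free residue strings; stored
#'   upper-case.
#' @param specimen specimen labels (recycled).
#' @param clade clade labels (recycled); `"unknown"` when absent.
#' @param read_depth non-negative integer read depths, `NA` when absent.
#' @param seq_type one of `"aa"`, `"cds"`, `"nuc"`.
#' @return A `data.frame` with columns `id`, `sequence`, `specimen`,
#'   `clade`, `read_depth`, `seq_type`.
#' @export
timp_records <- function(id, sequence, specimen = NA_character_,
                         clade = "unknown", read_depth = NA_real_,
                         seq_type = c("aa", "cds", "nuc")) {
  seq_type <- match.arg(seq_type)
  rec <- data.frame(
    id = as.character(id),
    sequence = toupper(as.character(sequence)),
    specimen = as.character(specimen),
    clade = as.character(clade),
    read_depth = as.numeric(read_depth),
    seq_type = seq_type,
    stringsAsFactors = FALSE
  )
  validate_records(rec)
  rec
}

validate_records <- function(rec) {
  stopifnot(is.data.frame(rec))
  need <- c("id", "sequence", "specimen", "clade", "read_depth", "seq_type")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols))
    stop("record set lacks columns: ", paste(missing_cols, collapse = ", "))
  dup <- unique(rec$id[duplicated(rec$id)])
  if (length(dup))
    stop("duplicate record id(s): ", paste(dup, collapse = ", "))
  if (any(!nzchar(rec$sequence)))
    stop("empty sequence for record(s): ",
         paste(rec$id[!nzchar(rec$sequence)], collapse = ", "))
  if (any(rec$read_depth < 0, na.rm = TRUE))
    stop("negative read_depth")
  invisible(rec)
}

#' Read transcripts from FASTA with a metadata table
#'
#' Metadata is a tab-separated table with header
#' `id<TAB>specimen<TAB>clade<TAB>read_depth`. FASTA entries without a
#' metadata row get clade `"unknown"` and an absent read depth. Input order
#' is preserved and residues are upper-cased; gap characters are not
#' expected in input sequences (use [load_nexus_alignment()] for aligned
#' data).
#'
#' @param path FASTA file.
#' @param seq_type one of `"aa"`, `"cds"`, `"nuc"`.
#' @param metadata_path optional metadata TSV.
#' @return A record set (see [timp_records()]).
#' @export
load_fasta <- function(path, seq_type = c("aa", "cds", "nuc"),
                       metadata_path = NULL) {
  seq_type <- match.arg(seq_type)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  rec <- data.frame(
    id = ids, sequence = unname(seqs),
    specimen = NA_character_, clade = "unknown",
    read_depth = NA_real_, seq_type = seq_type,
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata_path)) {
    meta <- load_metadata(metadata_path)
    hit <- match(rec$id, meta$id)
    ok <- !is.na(hit)
    rec$specimen[ok] <- meta$specimen[hit[ok]]
    rec$clade[ok] <- meta$clade[hit[ok]]
    rec$read_depth[ok] <- meta$read_depth[hit[ok]]
  }
  validate_records(rec)
  rec
}

#' Read a record metadata table
#'
#' @param path TSV with header `id`, `specimen`, `clade`, `read_depth`.
#' @return data.frame.
#' @export
load_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "specimen", "clade", "read_depth")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  meta$read_depth <- as.numeric(meta$read_depth)
  meta
}

#' Write records or an alignment to FASTA
#'
#' Round trip: `load_fasta(write_fasta(x))` reproduces ids and sequences
#' exactly. Alignments keep their gap characters.
#'
#' @param x a record set or a [timp_alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "timp_alignment")) {
    ids <- rownames(x$matrix)
    seqs <- apply(x$matrix, 1L, paste, collapse = "")
  } else {
    validate_records(x)
    if (nrow(x) == 0) stop("refusing to write an empty record set")
    ids <- x$id
    seqs <- x$sequence
  }
  set <- Biostrings::BStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Write a record metadata table
#'
#' @param records record set.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  validate_records(records)
  write.table(records[, c("id", "specimen", "clade", "read_depth")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
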