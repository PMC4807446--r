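#' Aligner settings
#'
#' The built-in engine is a deterministic progressive aligner: a
#' neighbour-joining guide tree is built from k-mer distances and profiles
#' are merged by affine-gap dynamic programming. `global_pref` uses
#' Needleman-Wunsch-style end-to-end alignment; `local_pref` uses free end
#' gaps (Gotoh semi-global), which tolerates partial-length sequences the
#' way a local-pair strategy does. Amino acids are scored with BLOSUM62,
#' nucleotides with +1/-1.
#'
#' @param mode `"local_pref"` or `"global_pref"`.
#' @param alphabet `"aa"` or `"nuc"` (coding sequences align as `"nuc"`).
#' @param gap_open,gap_extend negative gap penalties; defaults -11/-1 for
#'   amino acids and -2/-1 for nucleotides. A length-L gap costs
#'   `gap_open + (L - 1) * gap_extend`.
#' @param kmer guide-tree k-mer size; default 3 for aa, 6 for nuc.
#' @param match,mismatch nucleotide scores.
#' @return list of class `aligner_settings`.
#' @export
aligner_settings <- function(mode = c("local_pref", "global_pref"),
                             alphabet = c("aa", "nuc"),
                             gap_open = NULL, gap_extend = -1,
                             kmer = NULL, match = 1, mismatch = -1) {
  mode <- match.arg(mode)
  alphabet <- match.arg(alphabet)
  if (is.null(gap_open)) gap_open <- if (alphabet == "aa") -11 else -2
  if (is.null(kmer)) kmer <- if (alphabet == "aa") 3L else 6L
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("need gap_open <= gap_extend <= 0")
  structure(list(mode = mode, alphabet = alphabet, gap_open = gap_open,
                 gap_extend = gap_extend, kmer = as.integer(kmer),
                 match = match, mismatch = mismatch),
            class = "aligner_settings")
}

aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
nuc_alphabet <- c("A", "C", "G", "T", "U", "N")

substitution_matrix <- function(settings) {
  if (settings$alphabet == "aa") {
    blosum <- get(utils::data("BLOSUM62", package = "Biostrings",
                              envir = environment()), envir = environment())
    S <- blosum[aa_alphabet, aa_alphabet]
  } else {
    a <- nuc_alphabet
    S <- matrix(settings$mismatch, length(a), length(a), dimnames = list(a, a))
    diag(S) <- settings$match
    S["U", "T"] <- S["T", "U"] <- settings$match
    S["N", ] <- S[, "N"] <- 0
  }
  unname(as.matrix(S))
}

alignment_alphabet <- function(settings) {
  if (settings$alphabet == "aa") aa_alphabet else nuc_alphabet
}

normalize_residues <- function(seq, alphabet, wildcard) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  chars[!chars %in% alphabet] <- wildcard
  chars
}

# profile: alphabet x columns relative-frequency matrix (gap mass omitted)
profile_from_rows <- function(rows, alphabet) {
  L <- ncol(rows)
  prof <- matrix(0, length(alphabet), L)
  for (a in seq_along(alphabet)) {
    prof[a, ] <- colSums(rows == alphabet[a])
  }
  prof / nrow(rows)
}

merge_by_path <- function(rows_a, rows_b, path) {
  na <- nrow(rows_a); nb <- nrow(rows_b)
  L <- length(path)
  out <- matrix("-", na + nb, L)
  ia <- 0L; ib <- 0L
  for (k in seq_len(L)) {
    mv <- path[k]
    if (mv == 1L || mv == 2L) {
      ia <- ia + 1L
      out[seq_len(na), k] <- rows_a[, ia]
    }
    if (mv == 1L || mv == 3L) {
      ib <- ib + 1L
      out[na + seq_len(nb), k] <- rows_b[, ib]
    }
  }
  rownames(out) <- c(rownames(rows_a), rownames(rows_b))
  out
}

kmer_distance_matrix <- function(seqs, k) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character(0)))
    table(substring(s, 1:(L - k + 1), k:L))
  })
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      common <- intersect(names(ci), names(cj))
      shared <- sum(pmin(ci[common], cj[common]))
      denom <- min(sum(ci), sum(cj))
      d[i, j] <- d[j, i] <- if (denom == 0) 1 else 1 - shared / denom
    }
  }
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Align records with the built-in progressive aligner
#'
#' Deterministic: the guide tree is neighbour joining on k-mer distances
#' (ties broken lexicographically), profile merges use affine-gap dynamic
#' programming with a fixed diagonal > up > left traceback preference, and
#' multifurcating guide nodes merge their children closest-first. Rows of
#' the result are in input order and every row degaps to its input
#' sequence.
#'
#' @param records record set (2 or more sequences; a single record is
#'   returned unchanged as a one-row alignment).
#' @param settings [aligner_settings()]; defaults chosen from the records'
#'   `seq_type`.
#' @return A [timp_alignment()].
#' @export
align_records <- function(records, settings = NULL) {
  validate_records(records)
  if (is.null(settings))
    settings <- aligner_settings(
      alphabet = if (records$seq_type[1] == "aa") "aa" else "nuc")
  alphabet <- alignment_alphabet(settings)
  wildcard <- if (settings$alphabet == "aa") "X" else "N"
  if (settings$alphabet == "nuc" &&
      any(grepl("[^ACGTUN]", toupper(records$sequence))))
    stop("mixed or non-nucleotide alphabet in nucleotide alignment")
  if (settings$alphabet == "aa" && records$seq_type[1] != "aa")
    stop("amino-acid settings given non-amino-acid records")

  n <- nrow(records)
  if (n == 1) {
    m <- matrix(normalize_residues(records$sequence, alphabet, wildcard),
                nrow = 1)
    rownames(m) <- records$id
    return(timp_alignment(m, meta = records))
  }

  S <- substitution_matrix(settings)
  free_ends <- settings$mode == "local_pref"
  rowsets <- lapply(seq_len(n), function(i) {
    m <- matrix(normalize_residues(records$sequence[i], alphabet, wildcard),
                nrow = 1)
    rownames(m) <- records$id[i]
    m
  })
  names(rowsets) <- records$id

  pair_merge <- function(ra, rb) {
    fa <- profile_from_rows(ra, alphabet)
    fb <- profile_from_rows(rb, alphabet)
    res <- profile_align_cpp(fa, fb, S, settings$gap_open,
                             settings$gap_extend, free_ends)
    merge_by_path(ra, rb, res$path)
  }

  merged <- if (n == 2) {
    pair_merge(rowsets[[1]], rowsets[[2]])
  } else {
    seqs <- setNames(records$sequence, records$id)
    d <- kmer_distance_matrix(seqs, settings$kmer)
    guide <- nj_tree(d)
    guide <- phangorn::midpoint(guide)
    merge_guide(guide, rowsets, pair_merge, d)
  }
  merged <- merged[records$id, , drop = FALSE]
  timp_alignment(merged, meta = records)
}

# Postorder merge over a rooted guide tree; multifurcations merge their
# child profiles closest-first by mean k-mer distance between tip sets.
merge_guide <- function(guide, rowsets, pair_merge, d) {
  n_tip <- length(guide$tip.label)
  children <- split(guide$edge[, 2], guide$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) return(rowsets[[guide$tip.label[node]]])
    kids <- children[[as.character(node)]]
    profs <- lapply(kids, rec)
    while (length(profs) > 1) {
      best <- c(1L, 2L); best_d <- Inf
      for (i in seq_len(length(profs) - 1)) {
        for (j in (i + 1):length(profs)) {
          dd <- mean(d[rownames(profs[[i]]), rownames(profs[[j]]),
                       drop = FALSE])
          if (dd < best_d - 1e-12) { best_d <- dd; best <- c(i, j) }
        }
      }
      m <- pair_merge(profs[[best[1]]], profs[[best[2]]])
      profs <- c(profs[-best], list(m))
    }
    profs[[1]]
  }
  rec(n_tip + 1L)
}
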