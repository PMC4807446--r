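# Shared fixtures and independent oracles used across the suite.

test_path_extdata <- function(f)
  system.file("extdata", f, package = "timpfam", mustWork = TRUE)

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# n similar full-length sequences derived from one template by light
# point mutation; deterministic given seed
similar_family <- function(n, len = 60, mut = 0.05, seed = 1,
                           seq_type = "aa", specimen = NULL) {
  set.seed(seed)
  template <- sample(aa20, len, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- template
    hit <- which(runif(len) < mut)
    s[hit] <- sample(aa20, length(hit), replace = TRUE)
    paste(s, collapse = "")
  }, character(1))
  timp_records(sprintf("seq%02d", seq_len(n)), seqs,
               specimen = if (is.null(specimen)) sprintf("sp%02d", seq_len(n))
                          else specimen,
               clade = "test", read_depth = 100, seq_type = seq_type)
}

# random gapped alignment (rows x cols) for property tests
random_alignment <- function(n_rows, n_cols, gap_p = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("-", aa20), n_rows * n_cols, replace = TRUE,
                     prob = c(gap_p, rep((1 - gap_p) / 20, 20))),
              n_rows, n_cols)
  # no all-gap rows
  for (i in seq_len(n_rows)) if (all(m[i, ] == "-")) m[i, 1] <- "A"
  rownames(m) <- sprintf("r%02d", seq_len(n_rows))
  timp_alignment(m)
}

# brute-force affine-gap global alignment score (3-state recursion with
# memoisation); independent of the package's DP
oracle_affine_score <- function(a, b, S, open, ext, lookup) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  memo <- new.env(parent = emptyenv())
  sc <- function(i, j) S[lookup[a[i]], lookup[b[j]]]
  best <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) {
      if (state == "M") 0 else -Inf
    } else if (state == "M") {
      if (i == 0 || j == 0) -Inf
      else sc(i, j) + max(best(i - 1, j - 1, "M"), best(i - 1, j - 1, "X"),
                          best(i - 1, j - 1, "Y"))
    } else if (state == "X") {
      if (i == 0) -Inf
      else max(best(i - 1, j, "M") + open, best(i - 1, j, "X") + ext,
               best(i - 1, j, "Y") + open)
    } else {
      if (j == 0) -Inf
      else max(best(i, j - 1, "M") + open, best(i, j - 1, "X") + open,
               best(i, j - 1, "Y") + ext)
    }
    memo[[key]] <- val
    val
  }
  max(best(n, m, "M"), best(n, m, "X"), best(n, m, "Y"))
}

# brute-force longest common substring
oracle_lcs <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      k <- 0
      while (i + k <= length(a) && j + k <= length(b) &&
             a[i + k] == b[j + k]) k <- k + 1
      best <- max(best, k)
    }
  }
  best
}

# small cull_grid stand-in for boxer tests: stats is a data.frame with
# residue_overlap, sequence_overlap, unique_taxa, gap_fraction and a list
# column `specimens` of surviving specimen vectors
fake_grid <- function(stats) {
  results <- list()
  for (i in seq_len(nrow(stats))) {
    key <- paste0(stats$residue_overlap[i], "_", stats$sequence_overlap[i])
    sp <- stats$specimens[[i]]
    m <- matrix("A", nrow = max(length(sp), 1), ncol = 4)
    rownames(m) <- sprintf("%s_rec%d", key, seq_len(nrow(m)))
    meta <- data.frame(id = rownames(m),
                       specimen = if (length(sp)) sp else "none",
                       clade = "x", read_depth = 1, seq_type = "aa",
                       stringsAsFactors = FALSE)
    aln <- timp_alignment(m, meta = meta)
    results[[key]] <- structure(list(
      settings = c(residue_overlap = stats$residue_overlap[i],
                   sequence_overlap = stats$sequence_overlap[i]),
      alignment = aln, removed = data.frame(
        id = character(0), res_score = numeric(0),
        seq_overlap = numeric(0), iteration = integer(0)),
      removed_ids = character(0), n_iterations = 1L,
      gap_fraction = stats$gap_fraction[i],
      unique_taxa = stats$unique_taxa[i], degenerate = FALSE),
      class = "cull_result")
  }
  tab <- stats[, c("residue_overlap", "sequence_overlap")]
  tab$n_kept <- vapply(stats$specimens, length, integer(1))
  tab$unique_taxa <- stats$unique_taxa
  tab$gap_fraction <- stats$gap_fraction
  tab$n_iterations <- 1L
  tab$degenerate <- FALSE
  structure(list(results = results,
                 thresholds = sort(unique(c(stats$residue_overlap,
                                            stats$sequence_overlap))),
                 table = tab),
            class = "cull_grid")
}

# independent re-statement of the grid-selection rule, by exhaustive
# enumeration (used as the boxer oracle)
oracle_boxer <- function(grid, max_gap_pct, anchor = NULL) {
  tab <- grid$table
  keys <- paste0(tab$residue_overlap, "_", tab$sequence_overlap)
  ok <- rep(TRUE, nrow(tab))
  if (!is.null(anchor)) {
    ok <- vapply(keys, function(k)
      anchor %in% grid$results[[k]]$alignment$meta$specimen, logical(1))
  }
  cand <- which(ok & tab$gap_fraction <= max_gap_pct / 100)
  if (!length(cand)) {
    pool <- which(ok)
    return(keys[pool[which.min(tab$gap_fraction[pool])]])
  }
  best <- cand[1]
  for (i in cand[-1]) {
    better <- FALSE
    if (tab$unique_taxa[i] > tab$unique_taxa[best]) better <- TRUE
    else if (tab$unique_taxa[i] == tab$unique_taxa[best]) {
      if (tab$gap_fraction[i] < tab$gap_fraction[best]) better <- TRUE
      else if (tab$gap_fraction[i] == tab$gap_fraction[best]) {
        if (tab$residue_overlap[i] > tab$residue_overlap[best] ||
            (tab$residue_overlap[i] == tab$residue_overlap[best] &&
             tab$sequence_overlap[i] > tab$sequence_overlap[best]))
          better <- TRUE
      }
    }
    if (better) best <- i
  }
  keys[best]
}
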