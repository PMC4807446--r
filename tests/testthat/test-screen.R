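# background distances jittered around `base` (as real identity matrices
# are), selected rows pushed out to `far`
make_dist <- function(n, base = 0.1, outliers = integer(0), far = 0.9,
                      seed = 42) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- base + runif(n * (n - 1) / 2, -0.03, 0.03)
  d <- d + t(d)
  for (o in outliers) { d[o, ] <- far; d[, o] <- far }
  diag(d) <- 0
  dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  d
}

test_that("divergence flagging applies the median + z * MAD rule", {
  d <- make_dist(11, base = 0.1, outliers = 11)
  flagged <- flag_divergent(d, z_cut = 3)
  expect_identical(flagged, "s11")
  # verified against direct recomputation of the rule
  mean_d <- rowSums(d) / (nrow(d) - 1)
  thr <- median(mean_d) + 3 * mad(mean_d)
  expect_identical(sort(names(mean_d)[mean_d > thr]), sort(flagged))
})

test_that("equidistant matrices flag nothing and tiny matrices error", {
  d <- matrix(0.3, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  diag(d) <- 0
  expect_length(flag_divergent(d, 3), 0)   # MAD is zero: no outliers
  d2 <- d[1:2, 1:2]
  expect_error(flag_divergent(d2, 3), "at least 3")
})

test_that("two outliers among 20 are both flagged, ordered by mean distance, invariant to relabeling", {
  d <- make_dist(20, base = 0.1, outliers = c(7, 13))
  d["s13", ] <- pmin(d["s13", ] + 0.05, 1); d[, "s13"] <- d["s13", ]
  diag(d) <- 0
  flagged <- flag_divergent(d, 3)
  expect_identical(flagged, c("s13", "s07"))  # descending mean distance
  set.seed(4)
  perm <- sample(20)
  flagged_perm <- flag_divergent(d[perm, perm], 3)
  expect_setequal(flagged_perm, flagged)
})

test_that("duplicate removal keeps the deepest record and is idempotent", {
  rec <- timp_records(c("a", "b", "c"), c("ACGT", "ACGT", "ACGA"),
                      read_depth = c(5, 100, 7), seq_type = "nuc")
  dd <- dedup_identical(rec)
  expect_equal(nrow(dd$kept), 2)
  expect_true("b" %in% dd$kept$id)       # highest depth kept
  expect_identical(dd$removed_ids, "a")
  expect_length(dd$duplicate_groups, 1)
  # idempotent
  dd2 <- dedup_identical(dd$kept)
  expect_identical(dd2$kept, dd$kept)
  expect_length(dd2$removed_ids, 0)
  # tie broken by smallest id
  tie <- timp_records(c("z", "y"), c("AAAA", "AAAA"),
                      read_depth = c(3, 3), seq_type = "nuc")
  expect_identical(dedup_identical(tie)$kept$id, "y")
  # all unique: identity
  uni <- timp_records(c("u1", "u2"), c("AC", "AG"), seq_type = "nuc")
  expect_identical(dedup_identical(uni)$kept, uni)
})

test_that("contaminant rule needs both a long shared run and low depth", {
  set.seed(11)
  ref_seq <- paste(sample(aa20, 120, replace = TRUE), collapse = "")
  refs <- timp_records("mouse_timp", ref_seq, specimen = "Mus musculus",
                       clade = "chordate")
  shared60 <- paste0(paste(sample(aa20, 30, replace = TRUE), collapse = ""),
                     substr(ref_seq, 20, 79))
  rec <- timp_records(c("low", "high", "short_run"),
                      c(shared60, shared60,
                        paste0(substr(ref_seq, 1, 10),
                               paste(rep("W", 70), collapse = ""))),
                      specimen = "ast1", clade = "Asteroidea",
                      read_depth = c(18, 5000, 18))
  flagged <- flag_contaminant(rec, refs, min_run = 50, depth_cut = 50)
  expect_identical(as.character(flagged), "low")
  # same clade as the reference: never compared
  same <- timp_records("self", shared60, specimen = "m", clade = "chordate",
                       read_depth = 18)
  expect_length(flag_contaminant(same, refs), 0)
  # absent depth: unevaluable, not flagged
  nodep <- timp_records("nd", shared60, specimen = "ast2",
                        clade = "Asteroidea", read_depth = NA)
  f <- flag_contaminant(nodep, refs)
  expect_length(as.character(f), 0)
  expect_identical(attr(f, "unevaluable"), "nd")
})

test_that("longest-common-substring matches a brute-force oracle", {
  set.seed(21)
  for (i in 1:25) {
    a <- paste(sample(c("A", "B", "C"), sample(5:60, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "B", "C"), sample(5:60, 1), replace = TRUE),
               collapse = "")
    expect_equal(timpfam:::lcs_substring_cpp(a, b), oracle_lcs(a, b))
  }
  expect_equal(timpfam:::lcs_substring_cpp("ABC", ""), 0)
})

test_that("screen_records combines the three screens into one report", {
  fam <- similar_family(8, len = 80, seed = 3)
  # append an identical duplicate and a divergent record
  set.seed(5)
  div <- paste(sample(aa20, 80, replace = TRUE), collapse = "")
  rec <- rbind(fam,
               timp_records("dup1", fam$sequence[1], specimen = "sp01",
                            clade = "test", read_depth = 1),
               timp_records("diverg", div, specimen = "sp09",
                            clade = "test", read_depth = 100))
  rep <- screen_records(rec, z_cut = 3)
  expect_true("diverg" %in% rep$divergent_ids)
  expect_true(any(vapply(rep$duplicate_groups,
                         function(g) "dup1" %in% g$id, logical(1))))
  expect_false(any(c("diverg") %in% rep$kept$id))
  p <- tempfile(fileext = ".tsv")
  write_screen_report(rep, p)
  tab <- read.delim(p)
  expect_true(all(c("id", "action", "reason") %in% names(tab)))
})
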