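test_that("column occupancy and sequence scores follow their definitions", {
  aln <- timp_alignment(c(a = "ACGT", b = "AC--", c = "A-GT", d = "ACGT"))
  occ <- column_occupancy(aln)
  expect_equal(unname(occ), c(1, 0.75, 0.75, 0.75))
  expect_equal(unname(column_occupancy(
    timp_alignment(c(a = "-A", b = "-C")))[1]), 0)

  two <- timp_alignment(c(a = "AC--", b = "ACGT"))
  sc <- sequence_scores(two)
  expect_equal(sc$seq_overlap[sc$id == "a"], 50)
  expect_equal(sc$res_score[sc$id == "a"], 100)  # both occupied columns full
  gapless <- random_alignment(4, 12, gap_p = 0)
  expect_true(all(sequence_scores(gapless)$res_score == 100))
  expect_true(all(sequence_scores(gapless)$seq_overlap == 100))
  allgap <- timp_alignment(rbind(x = rep("-", 4), y = c("A", "C", "G", "T")))
  expect_equal(unname(as.matrix(sequence_scores(allgap)[1, c("res_score", "seq_overlap")])),
               matrix(c(0, 0), 1))
})

test_that("well-behaved families survive culling in one iteration", {
  rec <- similar_family(5, len = 50, mut = 0.05, seed = 2)
  res <- cull_iterate(rec, 50, 50)
  expect_length(res$removed_ids, 0)
  expect_equal(res$n_iterations, 1L)
  expect_false(res$degenerate)
  expect_equal(res$unique_taxa, 5L)
})

test_that("a short fragment is culled at a sequence-overlap threshold it cannot meet", {
  rec <- similar_family(5, len = 60, mut = 0.05, seed = 3)
  frag <- timp_records("frag", substr(rec$sequence[1], 20, 37),
                       specimen = "spfrag", clade = "test", read_depth = 5)
  rec <- rbind(rec, frag)
  res <- cull_iterate(rec, 50, 60)
  expect_identical(res$removed_ids, "frag")
  expect_equal(res$removed$iteration, 1L)
  # survivors are a fixed point: re-culling removes nothing
  surv <- alignment_to_records(res$alignment)
  again <- cull_iterate(surv, 50, 60)
  expect_length(again$removed_ids, 0)
  # every survivor satisfies both thresholds in the final alignment
  sc <- sequence_scores(res$alignment)
  expect_true(all(sc$res_score >= 50 & sc$seq_overlap >= 60))
})

test_that("culling terminates within the iteration cap on hostile input", {
  # jagged staircase of partial sequences: every iteration exposes new
  # failures at a 100% residue-overlap demand
  set.seed(7)
  base <- paste(sample(aa20, 60, replace = TRUE), collapse = "")
  rec <- timp_records(
    sprintf("s%d", 1:6),
    c(base, substr(base, 1, 50), substr(base, 5, 60), substr(base, 1, 40),
      substr(base, 15, 60), substr(base, 25, 45)),
    specimen = sprintf("sp%d", 1:6), clade = "test", read_depth = 10)
  res <- cull_iterate(rec, 100, 50)
  expect_lte(res$n_iterations, nrow(rec) + 1)
  expect_true(is.null(res$alignment) || nrow(res$alignment$matrix) >= 1)
})

test_that("first-iteration failures grow monotonically with the sequence-overlap threshold", {
  rec <- similar_family(6, len = 60, mut = 0.1, seed = 5)
  rec$sequence[3] <- substr(rec$sequence[3], 1, 30)
  rec$sequence[6] <- substr(rec$sequence[6], 1, 45)
  aln <- align_records(rec)
  sc <- sequence_scores(aln)
  fail_at <- function(S) sort(sc$id[sc$seq_overlap < S])
  prev <- character(0)
  for (S in seq(50, 100, by = 10)) {
    cur <- fail_at(S)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("the cull grid covers every threshold pair and matches per-cell reruns", {
  rec <- similar_family(5, len = 50, mut = 0.05, seed = 11)
  rec$sequence[4] <- substr(rec$sequence[4], 1, 32)  # ~64% coverage fragment
  grid <- cull_grid(rec)
  expect_length(grid$results, 36)
  expect_setequal(names(grid$results),
                  as.vector(outer(seq(50, 100, 10), seq(50, 100, 10),
                                  function(r, s) paste0(r, "_", s))))
  # grid cells agree with independent single runs (no shared cache)
  for (key in c("50_50", "70_80", "100_100", "60_70")) {
    rs <- strsplit(key, "_")[[1]]
    solo <- cull_iterate(rec, as.numeric(rs[1]), as.numeric(rs[2]))
    expect_identical(grid$results[[key]]$removed_ids, solo$removed_ids)
    expect_equal(grid$results[[key]]$gap_fraction, solo$gap_fraction)
  }
  # a ~64%-coverage fragment is kept at S <= 60 and culled at S >= 70
  # (away from the degenerate R = 100 column, which cascades)
  for (R in seq(50, 90, 10)) {
    for (S in seq(50, 100, 10)) {
      removed <- "seq04" %in% grid$results[[paste0(R, "_", S)]]$removed_ids
      expect_identical(removed, S >= 70,
                       label = sprintf("fragment removal at R=%d S=%d", R, S))
    }
  }
  # homogeneous input: identical membership everywhere
  homog <- similar_family(4, len = 40, mut = 0.03, seed = 13)
  g2 <- cull_grid(homog)
  kept_ids <- lapply(g2$results, function(r) sort(alignment_ids(r$alignment)))
  expect_length(unique(kept_ids), 1)
})
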