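test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_timp_dataset(sim_config(seed = 5))
  s2 <- simulate_timp_dataset(sim_config(seed = 5))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$specimen_table, s2$specimen_table)
  expect_identical(lapply(s1$truth$gene_trees, ape::write.tree),
                   lapply(s2$truth$gene_trees, ape::write.tree))
})

test_that("the default configuration emulates the study design", {
  sim <- simulate_timp_dataset(sim_config(seed = 1))
  expect_equal(nrow(sim$specimen_table), 41)
  expect_equal(as.vector(table(sim$specimen_table$clade)[
    c("Asteroidea", "Crinoidea", "Echinoidea", "Holothuroidea",
      "Ophiuroidea")]), c(14, 9, 5, 9, 4))
  # specimen totals dominate the family counts
  expect_true(all(sim$specimen_table$contigs > sim$specimen_table$timp_contigs))
  expect_true(all(sim$specimen_table$reads > sim$specimen_table$timp_reads))
  # truth covers every emitted echinoderm record
  ech <- sim$records$id[sim$records$clade %in% names(sim$config$clades)]
  accounted <- c(
    unlist(lapply(names(sim$truth$copy_counts), function(sp)
      sprintf("%s_T%03d", sp, seq_len(sim$truth$copy_counts[[sp]])))),
    sim$truth$duplicate_ids, sim$truth$contaminant_ids)
  expect_setequal(ech, accounted)
  # one planted contaminant at the published low depth
  expect_length(sim$truth$contaminant_ids, 1)
  con <- sim$records[sim$records$id == sim$truth$contaminant_ids, ]
  expect_equal(con$read_depth, 18)
  expect_true(con$clade %in% names(sim$config$clades))
})

test_that("record totals fluctuate around the 405-transcript scale", {
  totals <- vapply(1:30, function(s) {
    sim <- simulate_timp_dataset(sim_config(seed = s))
    sum(sim$records$clade %in% names(sim$config$clades)) -
      length(sim$truth$duplicate_ids) - length(sim$truth$contaminant_ids)
  }, numeric(1))
  expect_gt(mean(totals), 405 * 0.7)
  expect_lt(mean(totals), 405 * 1.3)
})

test_that("disabling artifact rates yields a clean dataset", {
  cfg <- sim_config(seed = 3, truncation_rate = 0, duplicate_rate = 0,
                    n_contaminants = 0L, divergent_rate = 0)
  sim <- simulate_timp_dataset(cfg)
  expect_length(sim$truth$truncated_ids, 0)
  expect_length(sim$truth$duplicate_ids, 0)
  expect_length(sim$truth$contaminant_ids, 0)
  expect_length(sim$truth$divergent_ids, 0)
})

test_that("scaffold sites stay conserved while free sites diverge", {
  sim <- simulate_timp_dataset(sim_config(seed = 7, truncation_rate = 0,
                                          divergent_rate = 0))
  ech <- sim$records[sim$records$clade %in% names(sim$config$clades), ]
  ech <- ech[!ech$id %in% sim$truth$contaminant_ids, ]
  chars <- do.call(rbind, strsplit(ech$sequence, ""))
  cys <- sim$truth$scaffold$cys_pos
  frac_c <- mean(chars[, cys] == "C")
  expect_gt(frac_c, 0.9)
  free <- setdiff(seq_len(ncol(chars)),
                  c(cys, sim$truth$scaffold$hpq_pos,
                    sim$truth$scaffold$virak_pos))
  # free sites are far from monomorphic
  mono <- mean(apply(chars[, free[1:50]], 2,
                     function(col) max(table(col)) / length(col)))
  expect_lt(mono, 0.9)
  # HPQ is recoverable by motif scan in most copies
  hits <- motif_scan(ech, "HPQ")
  expect_gt(nrow(unique(hits$hits["id"])) / nrow(ech), 0.7)
})

test_that("burst gene trees carry recent-diversification signal (positive gamma)", {
  gaps <- vapply(1:25, function(s) {
    sim <- simulate_timp_dataset(sim_config(seed = s))
    trees <- sim$truth$gene_trees
    burst <- sim$truth$burst_specimens
    big <- names(trees)[vapply(trees, function(t) length(t$tip.label) >= 10,
                               logical(1))]
    b <- intersect(big, burst)
    s2 <- setdiff(big, burst)
    if (!length(b) || !length(s2)) return(NA_real_)
    mean(vapply(trees[b], function(t) gamma_stat(t)$gamma, numeric(1))) -
      mean(vapply(trees[s2], function(t) gamma_stat(t)$gamma, numeric(1)))
  }, numeric(1))
  # burst specimens have systematically larger gamma than steady ones
  expect_gt(mean(gaps > 0, na.rm = TRUE), 0.9)
})

test_that("simulations round-trip through the on-disk format", {
  dir <- tempfile("simout")
  sim <- simulate_timp_dataset(sim_config(seed = 11))
  write_simulation(sim, dir)
  back <- load_fasta(file.path(dir, "records.fasta"), "aa",
                     metadata_path = file.path(dir, "metadata.tsv"))
  expect_identical(back$id, sim$records$id)
  expect_identical(back$sequence, sim$records$sequence)
  expect_identical(back$clade, sim$records$clade)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(unlist(truth$contaminant_ids),
                   sim$truth$contaminant_ids)
})
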