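#' Configuration for the synthetic TIMP gene-family generator
#'
#' Defaults mirror the study conditions the analysis is designed for:
#' 41 specimens in five echinoderm classes (14/9/5/9/4 for Asteroidea /
#' Crinoidea / Echinoidea / Holothuroidea / Ophiuroidea), negative-
#' binomial TIMP copy numbers around the published per-class means
#' (7.6/7.2/4.0/22.4/3.0), log-normal read depths and assembly totals with
#' per-class scales taken from the same table, a conserved
#' cysteine/HPQ scaffold with the chordate-associated VIRAK motif planted
#' in 1 asteroid, 10 crinoid (two specimens, 4 + 6) and 2 holothuroid
#' copies, occasional large-indel divergent holothuroid copies with high
#' read depths, and injected artifacts: truncated partial records,
#' byte-identical duplicates, and one low-depth record copied from a
#' distant-clade reference.
#'
#' @param seed integer seed; every draw in [simulate_timp_dataset()] is
#'   reproducible from it.
#' @param clades named integer vector of specimens per clade.
#' @param copy_mean,copy_dispersion negative-binomial mean (per clade) and
#'   size for TIMP copy counts per specimen. A specimen's expected count
#'   scales with its own contig total (`copy_mean * contigs /
#'   contig_mean`), mirroring the observed coupling between family counts
#'   and assembly size; the clade-level expectation stays `copy_mean`.
#' @param depth_mean per-clade mean read depth per TIMP contig.
#' @param depth_sdlog log-sd of the read-depth log-normal.
#' @param contig_mean,reads_mean per-clade mean totals of assembled
#'   contigs and reads per specimen.
#' @param contig_sdlog,reads_sdlog log-sds of the totals.
#' @param seq_length amino-acid scaffold length.
#' @param subst_rate substitutions per free site per unit branch length.
#' @param scaffold_mult rate multiplier at scaffold (cysteine/motif)
#'   sites; near zero keeps them conserved.
#' @param clade_divergence,specimen_divergence,gene_tree_depth branch
#'   lengths (time units) from family root to clade ancestor, clade
#'   ancestor to specimen ancestor, and the within-specimen gene-tree
#'   depth.
#' @param burst named integer vector: number of specimens per clade whose
#'   gene trees are transformed into a recent duplication burst (ages
#'   compressed toward the present); applied to the highest-copy
#'   specimens of the clade.
#' @param burst_power exponent of the age compression (> 1 is a burst).
#' @param divergent_rate probability that a holothuroid copy carries a
#'   large indel (divergent copy).
#' @param divergent_depth_mult read-depth multiplier of divergent copies.
#' @param indel_length inserted-junk length for divergent copies.
#' @param virak_counts named integer vector of VIRAK-carrying records per
#'   echinoderm clade.
#' @param truncation_rate,duplicate_rate per-record artifact
#'   probabilities.
#' @param n_contaminants low-depth cross-clade contaminant records
#'   injected (default 1).
#' @param contaminant_depth read depth of the contaminant.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1,
    clades = c(Asteroidea = 14L, Crinoidea = 9L, Echinoidea = 5L,
               Holothuroidea = 9L, Ophiuroidea = 4L),
    copy_mean = c(Asteroidea = 7.6, Crinoidea = 7.2, Echinoidea = 4.0,
                  Holothuroidea = 22.4, Ophiuroidea = 3.0),
    copy_dispersion = 6,
    depth_mean = c(Asteroidea = 1521.9, Crinoidea = 2614.9,
                   Echinoidea = 174.1, Holothuroidea = 6782.6,
                   Ophiuroidea = 608.5),
    depth_sdlog = 1.2,
    contig_mean = c(Asteroidea = 42955, Crinoidea = 26221,
                    Echinoidea = 18454, Holothuroidea = 20571,
                    Ophiuroidea = 20985),
    contig_sdlog = 0.6,
    reads_mean = c(Asteroidea = 50925012, Crinoidea = 36121323,
                   Echinoidea = 16934202, Holothuroidea = 28322507,
                   Ophiuroidea = 15315718),
    reads_sdlog = 0.8,
    seq_length = 200L,
    subst_rate = 0.4,
    scaffold_mult = 0.02,
    clade_divergence = 0.5,
    specimen_divergence = 0.2,
    gene_tree_depth = 0.3,
    burst = c(Holothuroidea = 4L, Crinoidea = 1L),
    burst_power = 3,
    divergent_rate = 0.12,
    divergent_depth_mult = 10,
    indel_length = 60L,
    virak_counts = c(Asteroidea = 1L, Crinoidea = 10L, Holothuroidea = 2L),
    truncation_rate = 0.02,
    duplicate_rate = 0.01,
    n_contaminants = 1L,
    contaminant_depth = 18) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$clades > 0), all(cfg$copy_mean > 0),
            cfg$seq_length >= 60,
            cfg$truncation_rate >= 0, cfg$duplicate_rate >= 0,
            cfg$divergent_rate >= 0, cfg$subst_rate >= 0)
  if (!identical(sort(names(cfg$clades)), sort(names(cfg$copy_mean))))
    stop("clades and copy_mean must name the same clades")
  structure(cfg, class = "sim_config")
}

aa_residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# per-site substitution along a branch; rate_mult is a per-site vector
mutate_chars <- function(chars, t, rate, rate_mult) {
  p <- 1 - exp(-rate * rate_mult * t)
  hit <- which(runif(length(chars)) < p)
  if (length(hit)) {
    repl <- sample(aa_residues, length(hit), replace = TRUE)
    same <- repl == chars[hit]
    while (any(same)) {
      repl[same] <- sample(aa_residues, sum(same), replace = TRUE)
      same <- repl == chars[hit]
    }
    chars[hit] <- repl
  }
  chars
}

#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Internode intervals are exponential with rate `k * birth` while k
#' lineages exist (including a final interval with all n lineages), and
#' the topology follows the Yule-Harding distribution (uniform random
#' joins). The tree is ultrametric by construction and is the null model
#' under which the gamma statistic is calibrated.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param birth birth rate.
#' @return ultrametric `phylo` with tips `t1..tn`.
#' @export
yule_tree <- function(n_tips, seed = NULL, birth = 1) {
  if (n_tips < 2) stop("a Yule tree needs at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  g <- rexp(n_tips - 1, rate = (2:n_tips) * birth)   # g_2 .. g_n
  # node age of the merge from k+1 to k lineages, looking backward
  frag <- paste0("t", seq_len(n_tips))
  age <- rep(0, n_tips)
  merge_age <- rev(cumsum(rev(g)))   # merge_age[k-1] = age of split k-1 -> k
  for (k in n_tips:2) {
    a <- merge_age[k - 1]
    pick <- sort(sample.int(k, 2))
    newf <- paste0("(", frag[pick[1]], ":", sprintf("%.10g", a - age[pick[1]]),
                   ",", frag[pick[2]], ":", sprintf("%.10g", a - age[pick[2]]),
                   ")")
    frag <- c(frag[-pick], newf)
    age <- c(age[-pick], a)
  }
  ape::read.tree(text = paste0(frag, ";"))
}

# compress node ages toward the present (power > 1 = recent burst)
compress_node_ages <- function(tree, power) {
  ages <- ape::branching.times(tree)
  root_age <- max(ages)
  new_age <- root_age * (ages / root_age)^power
  n_tip <- length(tree$tip.label)
  age_of <- c(rep(0, n_tip), new_age[as.character((n_tip + 1):(n_tip + tree$Nnode))])
  tree$edge.length <- age_of[tree$edge[, 1]] - age_of[tree$edge[, 2]]
  tree
}

#' Simulate a multi-class TIMP gene-family dataset
#'
#' Generates specimens for each clade, draws per-specimen TIMP copy
#' numbers, evolves amino-acid sequences along per-specimen gene trees
#' hanging off clade ancestors, assigns log-normal read depths, and
#' injects the configured artifacts. Outgroup references (two
#' cephalochordate copies carrying VIRAK, two bivalve outgroup copies and
#' one mammalian TIMP-like reference) are appended with clade labels
#' `"chordate"` / `"outgroup"`; the contaminant is a low-depth copy of the
#' mammalian reference attributed to an echinoderm specimen.
#'
#' @param config a [sim_config()].
#' @return list of class `timp_simulation`: `records` (record set),
#'   `specimen_table` (per-specimen totals for [abundance_table()]),
#'   `truth` (copy counts, gene trees, artifact and motif-carrier ids,
#'   burst specimens, reference ids), `config`.
#' @export
simulate_timp_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$seq_length
  clade_names <- names(config$clades)
  abbrev <- toupper(substr(clade_names, 1, 3))

  # scaffold: 12 cysteines plus HPQ, near-invariant; VIRAK slot is free in
  # non-carriers
  root_seq <- sample(aa_residues, L, replace = TRUE)
  cys_pos <- unique(round(seq(0.10, 0.95, length.out = 12) * L))
  hpq_pos <- round(0.30 * L) + 0:2
  virak_pos <- round(0.45 * L) + 0:4
  taken <- c(hpq_pos, virak_pos)
  cys_pos <- setdiff(cys_pos, taken)
  root_seq[cys_pos] <- "C"
  root_seq[hpq_pos] <- c("H", "P", "Q")
  rate_mult <- rep(1, L)
  rate_mult[c(cys_pos, hpq_pos)] <- config$scaffold_mult

  mut <- function(chars, t) mutate_chars(chars, t, config$subst_rate, rate_mult)

  clade_anc <- lapply(clade_names, function(cl) mut(root_seq, config$clade_divergence))
  names(clade_anc) <- clade_names

  records <- list()
  truth_trees <- list()
  copy_counts <- integer(0)
  spec_rows <- list()
  divergent_ids <- character(0)

  # assembly totals, copy counts and burst flags, per clade; the expected
  # copy count scales with the specimen's contig total so that family
  # abundance tracks assembly size as in real transcriptomes
  specimen_names <- character(0)
  spec_clade <- character(0)
  burst_specimens <- character(0)
  counts_by_spec <- list()
  totals_by_spec <- list()
  for (ci in seq_along(clade_names)) {
    cl <- clade_names[ci]
    n_sp <- config$clades[[cl]]
    sp <- sprintf("%s%02d", abbrev[ci], seq_len(n_sp))
    contigs <- round(rlnorm(n_sp, log(config$contig_mean[[cl]]) -
                              config$contig_sdlog^2 / 2, config$contig_sdlog))
    reads <- round(rlnorm(n_sp, log(config$reads_mean[[cl]]) -
                            config$reads_sdlog^2 / 2, config$reads_sdlog))
    mu <- config$copy_mean[[cl]] * contigs / config$contig_mean[[cl]]
    k <- rnbinom(n_sp, size = config$copy_dispersion, mu = mu)
    specimen_names <- c(specimen_names, sp)
    spec_clade <- c(spec_clade, rep(cl, n_sp))
    counts_by_spec[sp] <- as.list(k)
    totals_by_spec[sp] <- lapply(seq_len(n_sp), function(i)
      c(contigs = contigs[i], reads = reads[i]))
    n_burst <- if (cl %in% names(config$burst)) config$burst[[cl]] else 0L
    if (n_burst > 0) {
      ord <- order(-k, sp)
      burst_specimens <- c(burst_specimens, sp[head(ord, n_burst)])
    }
  }

  for (si in seq_along(specimen_names)) {
    sp <- specimen_names[si]
    cl <- spec_clade[si]
    k <- counts_by_spec[[sp]]
    copy_counts[sp] <- k
    if (k == 0) next
    anc <- mut(clade_anc[[cl]], config$specimen_divergence)
    ids <- sprintf("%s_T%03d", sp, seq_len(k))
    seqs <- vector("list", k)
    if (k == 1) {
      seqs[[1]] <- mut(anc, config$gene_tree_depth)
    } else {
      gt <- yule_tree(k)
      # rescale to the configured depth
      root_age <- max(ape::branching.times(gt))
      gt$edge.length <- gt$edge.length * (config$gene_tree_depth / root_age)
      if (sp %in% burst_specimens) gt <- compress_node_ages(gt, config$burst_power)
      gt$tip.label <- ids[as.integer(sub("^t", "", gt$tip.label))]
      truth_trees[[sp]] <- gt
      # evolve along the tree, preorder
      n_tip <- length(gt$tip.label)
      node_seq <- vector("list", n_tip + gt$Nnode)
      node_seq[[n_tip + 1L]] <- anc
      pre <- ape::reorder.phylo(gt, "cladewise")
      for (e in seq_len(nrow(pre$edge))) {
        par <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
        node_seq[[ch]] <- mut(node_seq[[par]], pre$edge.length[e])
      }
      for (ti in seq_len(n_tip))
        seqs[[match(gt$tip.label[ti], ids)]] <- node_seq[[ti]]
    }
    depth_meanlog <- log(config$depth_mean[[cl]]) - config$depth_sdlog^2 / 2
    depth <- round(rlnorm(k, depth_meanlog, config$depth_sdlog)) + 1
    # divergent large-indel copies (holothuroid specialization)
    if (cl == "Holothuroidea" && config$divergent_rate > 0) {
      div <- which(runif(k) < config$divergent_rate)
      for (di in div) {
        ins_at <- sample.int(length(seqs[[di]]) - 1, 1)
        junk <- sample(aa_residues, config$indel_length, replace = TRUE)
        seqs[[di]] <- append(seqs[[di]], junk, after = ins_at)
        depth[di] <- depth[di] * config$divergent_depth_mult
        divergent_ids <- c(divergent_ids, ids[di])
      }
    }
    for (i in seq_len(k)) {
      records[[ids[i]]] <- list(id = ids[i], sequence = seqs[[i]],
                                specimen = sp, clade = cl,
                                read_depth = depth[i])
    }
  }

  # VIRAK carriers among echinoderm records
  all_ids <- names(records)
  rec_clade <- vapply(records, `[[`, character(1), "clade")
  rec_spec <- vapply(records, `[[`, character(1), "specimen")
  virak_ids <- character(0)
  for (cl in names(config$virak_counts)) {
    want <- config$virak_counts[[cl]]
    pool_ids <- all_ids[rec_clade == cl]
    if (!length(pool_ids) || want == 0) next
    if (cl == "Crinoidea" && want >= 2) {
      # split carriers over two specimens when possible (4 + 6 pattern)
      by_spec <- split(pool_ids, rec_spec[pool_ids])
      by_spec <- by_spec[order(-lengths(by_spec))]
      first <- min(ceiling(want * 0.4), length(by_spec[[1]]))
      chosen <- head(by_spec[[1]], first)
      rest <- setdiff(pool_ids, chosen)
      if (length(by_spec) > 1)
        rest <- c(by_spec[[2]], setdiff(rest, by_spec[[2]]))
      chosen <- c(chosen, head(rest, want - length(chosen)))
    } else if (cl == "Holothuroidea" && want >= 2) {
      by_spec <- split(pool_ids, rec_spec[pool_ids])
      by_spec <- by_spec[order(-lengths(by_spec))]
      chosen <- head(by_spec[[1]], want)
      if (length(chosen) < want)
        chosen <- c(chosen, head(setdiff(pool_ids, chosen), want - length(chosen)))
    } else {
      chosen <- head(sample(pool_ids), want)
    }
    for (id in chosen) {
      s <- records[[id]]$sequence
      if (length(s) >= max(virak_pos)) {
        s[virak_pos] <- c("V", "I", "R", "A", "K")
        records[[id]]$sequence <- s
        virak_ids <- c(virak_ids, id)
      }
    }
  }

  # outgroups and references
  chord_anc <- mut(root_seq, config$clade_divergence * 1.4)
  make_ref <- function(id, specimen, clade, base, t, virak = FALSE) {
    s <- mut(base, t)
    if (virak) s[virak_pos] <- c("V", "I", "R", "A", "K")
    list(id = id, sequence = s, specimen = specimen, clade = clade,
         read_depth = NA_real_)
  }
  refs <- list(
    make_ref("BFL_1", "Branchiostoma floridae", "chordate", chord_anc, 0.15,
             virak = TRUE),
    make_ref("BFL_2", "Branchiostoma floridae", "chordate", chord_anc, 0.15,
             virak = TRUE),
    make_ref("MMU_TIMP2", "Mus musculus", "chordate", chord_anc, 0.25,
             virak = TRUE),
    make_ref("CGI_1", "Crassostrea gigas", "outgroup",
             mut(root_seq, config$clade_divergence * 1.8), 0.1),
    make_ref("CGI_2", "Crassostrea gigas", "outgroup",
             mut(root_seq, config$clade_divergence * 1.8), 0.1)
  )
  for (r in refs) records[[r$id]] <- r
  reference_ids <- vapply(refs, `[[`, character(1), "id")

  # artifacts: truncation, byte-identical duplicates, contaminant
  truncated_ids <- character(0)
  echino_ids <- names(records)[vapply(records, `[[`, character(1), "clade")
                               %in% clade_names]
  if (config$truncation_rate > 0) {
    # planted motif carriers are left intact so the planted truth stays exact
    trunc_pool <- setdiff(echino_ids, virak_ids)
    for (id in trunc_pool[runif(length(trunc_pool)) < config$truncation_rate]) {
      s <- records[[id]]$sequence
      w <- max(20L, round(length(s) * runif(1, 0.3, 0.6)))
      start <- sample.int(length(s) - w + 1L, 1)
      records[[id]]$sequence <- s[start:(start + w - 1L)]
      truncated_ids <- c(truncated_ids, id)
    }
  }
  duplicate_ids <- character(0)
  if (config$duplicate_rate > 0) {
    for (id in echino_ids[runif(length(echino_ids)) < config$duplicate_rate]) {
      dup_id <- paste0(id, "_dup")
      dup <- records[[id]]
      dup$id <- dup_id
      dup$read_depth <- max(1, round(dup$read_depth * runif(1, 0.05, 0.5)))
      records[[dup_id]] <- dup
      duplicate_ids <- c(duplicate_ids, dup_id)
    }
  }
  contaminant_ids <- character(0)
  if (config$n_contaminants > 0) {
    hosts <- specimen_names[spec_clade == "Asteroidea"]
    hosts <- hosts[vapply(hosts, function(s) copy_counts[[s]] > 0, logical(1))]
    for (i in seq_len(config$n_contaminants)) {
      host <- sample(hosts, 1)
      con_id <- sprintf("%s_CON%02d", host, i)
      s <- records[["MMU_TIMP2"]]$sequence
      # light mutation outside a protected exact window
      win <- 40:(40 + 79)
      keep <- s[win]
      s <- mutate_chars(s, 0.05, config$subst_rate, rep(1, length(s)))
      s[win] <- keep
      records[[con_id]] <- list(id = con_id, sequence = s, specimen = host,
                                clade = spec_clade[specimen_names == host],
                                read_depth = config$contaminant_depth)
      contaminant_ids <- c(contaminant_ids, con_id)
    }
  }

  rec_df <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    sequence = vapply(records, function(r) paste(r$sequence, collapse = ""),
                      character(1)),
    specimen = vapply(records, `[[`, character(1), "specimen"),
    clade = vapply(records, `[[`, character(1), "clade"),
    read_depth = vapply(records, `[[`, numeric(1), "read_depth"),
    seq_type = "aa",
    stringsAsFactors = FALSE
  )
  rownames(rec_df) <- NULL
  validate_records(rec_df)

  # per-specimen assembly totals (drawn up front, before the gene family)
  for (si in seq_along(specimen_names)) {
    sp <- specimen_names[si]; cl <- spec_clade[si]
    n_timp <- sum(rec_df$specimen == sp)
    timp_reads <- sum(rec_df$read_depth[rec_df$specimen == sp], na.rm = TRUE)
    tot <- totals_by_spec[[sp]]
    spec_rows[[sp]] <- data.frame(
      specimen = sp, clade = cl,
      contigs = max(tot[["contigs"]], n_timp + 1),
      reads = max(tot[["reads"]], timp_reads + 1),
      timp_contigs = n_timp, timp_reads = timp_reads,
      stringsAsFactors = FALSE)
  }
  specimen_table <- do.call(rbind, spec_rows)
  rownames(specimen_table) <- NULL

  structure(list(
    records = rec_df,
    specimen_table = specimen_table,
    truth = list(
      copy_counts = copy_counts,
      gene_trees = truth_trees,
      burst_specimens = sort(burst_specimens),
      divergent_ids = divergent_ids,
      truncated_ids = truncated_ids,
      duplicate_ids = duplicate_ids,
      contaminant_ids = contaminant_ids,
      virak_ids = virak_ids,
      reference_ids = reference_ids,
      scaffold = list(cys_pos = cys_pos, hpq_pos = hpq_pos,
                      virak_pos = virak_pos)
    ),
    config = config
  ), class = "timp_simulation")
}

#' Write a simulated dataset to disk
#'
#' Emits `records.fasta`, `metadata.tsv`, `specimens.tsv` and
#' `truth.json` under `dir`.
#'
#' @param sim a `timp_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "timp_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$records, file.path(dir, "records.fasta"))
  write_metadata(sim$records, file.path(dir, "metadata.tsv"))
  write.table(sim$specimen_table, file.path(dir, "specimens.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$gene_trees <- lapply(truth$gene_trees, ape::write.tree)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
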