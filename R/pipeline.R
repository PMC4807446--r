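#' Pipeline configuration
#'
#' Parameters for [run_pipeline()], covering every stage from screening to
#' diversification. Curator-style decisions are explicit lists rather
#' than heuristics: `force_include` ids are never removed by any culling
#' stage, `force_exclude` ids are dropped up front.
#'
#' @param seed integer seed propagated to every stochastic stage.
#' @param stages character vector of stages to run, in fixed order;
#'   subset of `c("screen", "cull", "boxer", "tree", "rogue", "realign",
#'   "diversify", "consensus", "abundance")`.
#' @param z_cut,min_run,depth_cut screening parameters (see
#'   [screen_records()]).
#' @param thresholds culling grid thresholds.
#' @param max_gap_pct,anchor_taxon grid selection parameters (see
#'   [boxer_select()]).
#' @param n_boot bootstrap replicates.
#' @param min_improvement rogue-pruning threshold.
#' @param outgroup_ids record ids used to root trees and kept as
#'   outgroups in per-specimen pruning.
#' @param root_age ultrametric root age.
#' @param min_copies minimum copies per specimen for the diversification
#'   summary.
#' @param consensus_thresholds thresholds for the "all" consensus.
#' @param force_include,force_exclude record id lists.
#' @param out_dir optional directory for per-stage artifacts.
#' @param aligner optional [aligner_settings()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(
    seed = 1,
    stages = c("screen", "cull", "boxer", "tree", "rogue", "realign",
               "diversify", "consensus", "abundance"),
    z_cut = 3, min_run = 50, depth_cut = 50,
    thresholds = seq(50, 100, by = 10),
    max_gap_pct = 50, anchor_taxon = NULL,
    n_boot = 100, min_improvement = 0.2,
    outgroup_ids = character(0), root_age = 100, min_copies = 10,
    consensus_thresholds = c(90, 80, 70, 60, 50),
    force_include = character(0), force_exclude = character(0),
    out_dir = NULL, aligner = NULL) {
  cfg <- as.list(environment())
  known <- c("screen", "cull", "boxer", "tree", "rogue", "realign",
             "diversify", "consensus", "abundance")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg$stages <- known[known %in% cfg$stages]
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates screen -> cull grid -> grid selection -> distance tree
#' with bootstrap -> rogue pruning -> realignment and final tree ->
#' diversification, consensus and abundance summaries, recording a
#' manifest row per stage (inputs, outputs, parameters, record counts) so
#' every removal is traceable. Stages can be toggled off; a disabled
#' stage passes its input through.
#'
#' @param records record set to analyse.
#' @param config a [pipeline_config()].
#' @param references optional distant-clade references for the
#'   contaminant screen.
#' @param specimen_table optional per-specimen count table for the
#'   abundance stage.
#' @return list of class `pipeline_run`: `manifest` (data.frame),
#'   `records` (surviving records), `alignment` (final alignment),
#'   `tree` (final supported tree, when built), plus per-stage artifacts
#'   (`screen`, `grid`, `boxer`, `rogue`, `diversification`, `consensus`,
#'   `abundance`).
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         references = NULL, specimen_table = NULL) {
  validate_records(records)
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list()
  out <- list(manifest = NULL)
  note_stage <- function(name, n_in, n_out, params = list(),
                         outputs = character(0)) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = name, n_in = n_in, n_out = n_out,
      parameters = paste(names(params), unlist(lapply(params, paste,
        collapse = ",")), sep = "=", collapse = "; "),
      outputs = paste(outputs, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  save_fasta <- function(x, name) {
    if (is.null(config$out_dir)) return(character(0))
    p <- file.path(config$out_dir, name)
    write_fasta(x, p)
    p
  }
  on_stage <- function(s) s %in% config$stages
  protect <- function(drop_ids) setdiff(drop_ids, config$force_include)

  current <- records[!records$id %in% config$force_exclude, , drop = FALSE]
  if (nrow(current) < nrow(records))
    note_stage("force_exclude", nrow(records), nrow(current),
               list(ids = config$force_exclude))
  settings <- config$aligner
  if (is.null(settings))
    settings <- aligner_settings(
      alphabet = if (current$seq_type[1] == "aa") "aa" else "nuc")

  if (on_stage("screen")) {
    n_in <- nrow(current)
    scr <- screen_records(current, references = references,
                          z_cut = config$z_cut, min_run = config$min_run,
                          depth_cut = config$depth_cut, settings = settings)
    drop <- protect(setdiff(current$id, scr$kept$id))
    current <- current[!current$id %in% drop, , drop = FALSE]
    out$screen <- scr
    outp <- character(0)
    if (!is.null(config$out_dir)) {
      p <- file.path(config$out_dir, "screen_report.tsv")
      write_screen_report(scr, p)
      outp <- p
    }
    note_stage("screen", n_in, nrow(current),
               list(z_cut = config$z_cut, min_run = config$min_run,
                    depth_cut = config$depth_cut), outp)
  }

  aln <- NULL
  if (on_stage("cull")) {
    n_in <- nrow(current)
    grid <- cull_grid(current, settings = settings,
                      thresholds = config$thresholds)
    out$grid <- grid
    note_stage("cull", n_in, n_in,
               list(thresholds = config$thresholds))
    if (on_stage("boxer")) {
      choice <- boxer_select(grid, max_gap_pct = config$max_gap_pct,
                             anchor_taxon = config$anchor_taxon)
      out$boxer <- choice
      chosen <- grid$results[[choice$key]]
      keep <- union(alignment_ids(chosen$alignment), config$force_include)
      current <- current[current$id %in% keep, , drop = FALSE]
      aln <- if (setequal(current$id, alignment_ids(chosen$alignment)))
        chosen$alignment else align_records(current, settings)
      note_stage("boxer", n_in, nrow(current),
                 list(cell = choice$key, max_gap_pct = config$max_gap_pct,
                      relaxed = choice$relaxed),
                 save_fasta(aln, "boxer_alignment.fasta"))
    }
  }
  if (is.null(aln)) aln <- align_records(current, settings)

  tree <- NULL; boots <- NULL
  if (on_stage("tree") && nrow(current) >= 3) {
    d <- pairwise_identity_matrix(aln)
    tree <- nj_tree(d)
    boots <- bootstrap_trees(aln, config$n_boot, seed = config$seed)
    note_stage("tree", nrow(current), nrow(current),
               list(n_boot = config$n_boot, engine = "nj"))
  }

  if (on_stage("rogue") && !is.null(tree) && length(tree$tip.label) >= 5) {
    n_in <- nrow(current)
    rp <- prune_rogues(tree, boots, min_improvement = config$min_improvement)
    out$rogue <- rp
    drop <- protect(rp$removed_ids)
    current <- current[!current$id %in% drop, , drop = FALSE]
    note_stage("rogue", n_in, nrow(current),
               list(min_improvement = config$min_improvement))
  }

  if (on_stage("realign") && nrow(current) >= 2) {
    aln <- align_records(current, settings)
    if (nrow(current) >= 3) {
      tree <- nj_tree(pairwise_identity_matrix(aln))
      boots <- bootstrap_trees(aln, config$n_boot,
                               seed = config$seed + 1L)
      tree <- edge_support(tree, boots)
    }
    note_stage("realign", nrow(current), nrow(current), list(),
               save_fasta(aln, "final_alignment.fasta"))
  }

  # root by outgroup when available
  rooted <- NULL
  og <- intersect(config$outgroup_ids, if (is.null(tree)) character(0)
                  else tree$tip.label)
  if (!is.null(tree) && length(og)) {
    rooted <- tryCatch(
      ape::root(tree, outgroup = og, resolve.root = TRUE),
      error = function(e)
        # outgroup not monophyletic in the distance tree: root on its
        # first member instead
        ape::root(tree, outgroup = og[1], resolve.root = TRUE))
  }

  if (on_stage("diversify") && !is.null(rooted)) {
    chrono <- ultrametricize_mpl(rooted, root_age = config$root_age)
    out$chronogram <- chrono
    out$diversification <- diversification_by_specimen(
      chrono, current, outgroup_ids = og, min_copies = config$min_copies)
    note_stage("diversify", nrow(current), nrow(current),
               list(root_age = config$root_age,
                    min_copies = config$min_copies))
  }

  if (on_stage("consensus")) {
    out$consensus <- group_consensus(aln,
                                     thresholds = config$consensus_thresholds)
    note_stage("consensus", nrow(current), nrow(current),
               list(thresholds = config$consensus_thresholds))
  }

  if (on_stage("abundance") && !is.null(specimen_table)) {
    tab <- abundance_table(specimen_table)
    out$abundance <- list(
      table = tab,
      class_means = class_means(tab),
      kruskal_pct_timps = kruskal_wallis(tab$pct_timps, tab$clade),
      kruskal_pct_timp_reads = kruskal_wallis(tab$pct_timp_reads, tab$clade))
    note_stage("abundance", nrow(tab), nrow(tab))
  }

  out$records <- current
  out$alignment <- aln
  out$tree <- if (!is.null(rooted)) rooted else tree
  out$manifest <- do.call(rbind, manifest)
  class(out) <- "pipeline_run"
  out
}
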