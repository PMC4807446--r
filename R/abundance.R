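#' Read a per-specimen count table
#'
#' Expected columns: `specimen`, `clade`, `contigs`, `reads`,
#' `timp_contigs`, `timp_reads`.
#'
#' @param path TSV file.
#' @return data.frame of raw counts.
#' @export
load_specimen_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("specimen", "clade", "contigs", "reads", "timp_contigs",
            "timp_reads")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("specimen table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' The bundled echinoderm TIMP specimen counts
#'
#' Raw per-specimen totals (contigs and reads assembled, TIMP contigs and
#' TIMP-mapped reads) for the 41 echinoderm transcriptomes spanning the
#' five extant classes, as published with the TIMP gene-family survey the
#' package's methods follow. All derived statistics in the package are
#' recomputed from these integers.
#'
#' @return data.frame of raw counts (41 rows).
#' @export
echinoderm_timp_counts <- function() {
  load_specimen_table(system.file("extdata", "table1_counts.tsv",
                                  package = "timpfam", mustWork = TRUE))
}

#' Per-specimen abundance table
#'
#' Derives, per specimen: reads per TIMP contig (`avg_reads_per_timp`,
#' undefined for specimens with no TIMP contigs), TIMP contigs and reads
#' as percentages of all contigs / reads, and the rank of each percentage
#' across specimens (descending: the largest proportion ranks 1; ties get
#' the mean of their rank span).
#'
#' @param counts raw count table (see [load_specimen_table()]).
#' @return data.frame with the raw and derived columns.
#' @export
abundance_table <- function(counts) {
  need <- c("specimen", "clade", "contigs", "reads", "timp_contigs",
            "timp_reads")
  stopifnot(all(need %in% names(counts)))
  bad <- counts$specimen[counts$contigs <= 0 | counts$reads <= 0]
  if (length(bad))
    stop("zero contig or read totals for specimen(s): ",
         paste(bad, collapse = ", "))
  tab <- counts[, need]
  tab$avg_reads_per_timp <-
    ifelse(tab$timp_contigs > 0, tab$timp_reads / tab$timp_contigs, NA_real_)
  tab$pct_timps <- 100 * tab$timp_contigs / tab$contigs
  tab$pct_timp_reads <- 100 * tab$timp_reads / tab$reads
  tab$rank_pct_timps <- rank(-tab$pct_timps, ties.method = "average")
  tab$rank_pct_timp_reads <- rank(-tab$pct_timp_reads, ties.method = "average")
  tab
}

#' Per-class summary means
#'
#' Arithmetic means of every numeric abundance column per clade;
#' `avg_reads_per_timp` is averaged only over specimens with at least one
#' TIMP contig.
#'
#' @param tab output of [abundance_table()].
#' @return data.frame with one row per clade plus an `n` column.
#' @export
class_means <- function(tab) {
  stopifnot(nrow(tab) > 0)
  num_cols <- c("contigs", "reads", "timp_contigs", "timp_reads",
                "avg_reads_per_timp", "pct_timps", "rank_pct_timps",
                "pct_timp_reads", "rank_pct_timp_reads")
  clades <- sort(unique(tab$clade))
  rows <- lapply(clades, function(cl) {
    sub <- tab[tab$clade == cl, , drop = FALSE]
    means <- vapply(num_cols, function(col) {
      if (col == "avg_reads_per_timp")
        mean(sub[[col]], na.rm = TRUE)
      else mean(sub[[col]])
    }, numeric(1))
    cbind(data.frame(clade = cl, n = nrow(sub)), as.data.frame(t(means)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `groups - 1` degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param values numeric vector.
#' @param groups grouping factor or vector, at least 2 non-empty groups.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  fit <- kruskal.test(values, groups)
  list(H = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Welch two-sample t-test with per-mean confidence half-widths
#'
#' Two-tailed t-test with unequal variances (Welch-Satterthwaite degrees
#' of freedom), plus the normal-approximation 95% confidence half-width
#' of each sample mean (`qnorm(0.975) * s / sqrt(n)`), the form used to
#' report mean +/- CI.
#'
#' @param sample_a,sample_b numeric vectors with at least 2 values each.
#' @return list with `t`, `df`, `p`, `means` and `ci95_half_widths`
#'   (each length 2).
#' @export
welch_t <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  means <- c(mean(sample_a), mean(sample_b))
  vars <- c(var(sample_a), var(sample_b))
  if (all(vars == 0)) {
    if (means[1] == means[2])
      return(list(t = 0, df = NA_real_, p = 1, means = means,
                  ci95_half_widths = c(0, 0)))
    stop("zero variance in both samples with unequal means")
  }
  fit <- t.test(sample_a, sample_b, var.equal = FALSE)
  half <- qnorm(0.975) * sqrt(vars / c(length(sample_a), length(sample_b)))
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, means = means, ci95_half_widths = unname(half))
}

#' Ratio range of a focal clade's mean against the others
#'
#' @param summaries output of [class_means()].
#' @param focal_clade clade whose mean goes in the numerator.
#' @param column summary column to compare, e.g. `"pct_timps"`.
#' @return list with `min_ratio`, `max_ratio`, `ratios` (named by clade)
#'   and `excluded` (clades with zero mean, left out).
#' @export
ratio_range <- function(summaries, focal_clade, column) {
  stopifnot(column %in% names(summaries))
  if (!focal_clade %in% summaries$clade)
    stop("focal clade '", focal_clade, "' absent from summaries")
  focal <- summaries[[column]][summaries$clade == focal_clade]
  others <- summaries[summaries$clade != focal_clade, , drop = FALSE]
  zero <- others$clade[others[[column]] == 0]
  others <- others[others[[column]] != 0, , drop = FALSE]
  ratios <- setNames(focal / others[[column]], others$clade)
  if (!length(ratios)) stop("no non-focal clade with nonzero mean")
  list(min_ratio = min(ratios), max_ratio = max(ratios),
       ratios = ratios, excluded = zero)
}

#' @importFrom stats var
NULL
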