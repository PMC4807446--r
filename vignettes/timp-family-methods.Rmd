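---
title: "Methods: gene-family screening, culling, and diversification in timpfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family screening, culling, and diversification in timpfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timpfam)
```

`timpfam` analyses a multi-copy gene family — tissue inhibitors of
metalloproteinases (TIMPs) as the reference case — recovered from
transcriptomes of many specimens. This vignette documents the models and
procedures, the parameters that matter, the numerical conventions, and the
choices we made where the design was genuinely open.

## The analysis chain

The pipeline assumes annotation is finished: each record is one transcript
with a specimen label, a clade label, and (for transcriptome contigs) a
read depth. The stages are:

1. **Divergence screen.** From a pairwise identity distance matrix, a
   record is an outlier when its mean distance to all others exceeds
   `median + z_cut * MAD` (normal-consistent MAD, `z_cut = 3`). A manual
   by-eye screen of a distance matrix is common practice; we substitute
   this explicit robust rule because reproducibility requires a stated
   criterion, and we do not claim it reproduces any particular manual
   cull. When all records are equidistant the MAD is zero and nothing is
   flagged.
2. **Duplicate removal.** Byte-identical sequences (typical of redundant
   database downloads) collapse to one keeper: highest read depth, ties
   to the lexicographically smallest id. The keeper rule is our
   convention; only the removal itself is principled.
3. **Contaminant screen.** A record is a suspected cross-clade contaminant
   when it shares an exact residue run of at least `min_run = 50` with a
   reference from a distant clade *and* its read depth is below
   `depth_cut = 50`. Both conditions matter: deep homology produces long
   similar-but-not-identical stretches, whereas an index-hopping or
   carryover contaminant is near-identical yet poorly supported by reads
   (the motivating case had depth 18). Records without depths are
   reported as unevaluable rather than flagged.
4. **Overlap culling.** Two statistics drive sequence removal from an
   alignment: *residue overlap* (the occupancy of a column: residues /
   rows) and *sequence overlap* (the percentage of an aligned sequence's
   positions that are residues). The published definitions are one per
   column and one per sequence; combining them into a per-sequence test
   is left open, so we score each sequence by the mean occupancy of the
   columns where it has residues and threshold that at R, alongside its
   own coverage thresholded at S. Scores exactly at a threshold pass.
   All failing sequences in an iteration are removed together, the
   survivors realigned, and the loop repeats until a fixed point, at
   most 2 survivors (fewer than 2 flags the cell degenerate), or
   `n + 1` iterations. The full 6 x 6 grid over thresholds
   {50, 60, 70, 80, 90, 100} yields 36 culled alignments. The first
   iteration is provably monotone in S; the full loop is not, because
   realignment changes the column space — we assert the former and only
   the former.
5. **Grid selection ("Boxer").** Among the 36 candidates with overall gap
   fraction at or below `max_gap_pct` (default 50%; the original ceiling
   is not published, so the full ranked table is always emitted for
   manual judgment), prefer the most unique *specimens* retained; break
   ties by smaller gap fraction, then by the larger `(R, S)` pair. An
   anchor taxon (e.g. a key outgroup lineage) can be required to
   survive; if the ceiling empties the candidate set the rule relaxes to
   the least-gapped anchor-satisfying cell and says so.
6. **Trees, support, and rogues.** The built-in tree engine is neighbour
   joining on identity distances with column-resampling bootstraps.
   Maximum-likelihood search is deliberately out of scope: it is an
   external tool in the workflow this package reimplements, not part of
   the contribution, and externally computed best/bootstrap trees can be
   supplied as Newick so the downstream logic runs unchanged on them.
   Support of an internal edge is the fraction of bootstrap trees
   containing its bipartition, on the 0-1 scale. Rogue pruning is the
   printed per-terminal rule: greedily remove the leaf whose exclusion
   raises the summed support on the (restricted) best tree the most,
   while the gain is at least `min_improvement = 0.2`; ties break by
   leaf id; stop at 4 leaves. Because removing a leaf also removes an
   internal edge, the sum can drop by up to 1 for a blameless leaf — a
   removal must overcome that, which is what makes the 0.2 rule
   conservative. Whether the published 0.2 was on the 0-1 or percent
   scale is not stated; we default to 0.2 summed proportion
   (configurable), its natural reading.
7. **Diversification.** Trees are made ultrametric by mean path lengths:
   each internal node's raw age is the mean branch-length distance to its
   descendant leaves, child ages are capped at their parent's age, and
   ages rescale so the root sits at `root_age = 100`. The root age is an
   arbitrary unit: the gamma statistic is invariant under uniform time
   rescaling (a property test asserts this), so the choice of 100 cannot
   leak into results. Per focal specimen (those with `min_copies >= 10`
   gene copies), the tree is pruned to that specimen's copies plus the
   outgroups, the lineages-through-time profile is read off the node
   ages (simultaneous nodes give zero-length internode intervals, which
   are legal), and the Pybus-Harvey gamma with
   `p = 2 * (1 - pnorm(abs(gamma)))` tests constant-rate accumulation.
   Outgroups stay in the pruned trees by default, matching the workflow
   this follows; a flag drops them for sensitivity analysis.
8. **Conservation.** A threshold consensus emits a column's most frequent
   residue iff its count over *all* rows of the group — gapped rows
   included in the denominator ("counting gaps as sites") — reaches the
   threshold; gaps are never emitted; two residues tied at the maximal
   count are ambiguous and print `-`. The threshold is "at least", so a
   count exactly at threshold qualifies. Motif scans (HPQ, VIRAK) run on
   degapped sequences: an alignment can interleave gap columns inside a
   motif, and the degapped scan is exactly what recovers those split
   occurrences.
9. **Abundance statistics.** Per specimen: family contigs and reads as
   percentages of assembly totals, reads per family contig (undefined at
   zero contigs), and descending tie-averaged ranks. Class means average
   reads-per-contig only over specimens with at least one family contig
   — the published crinoid mean only reproduces under that exclusion,
   which pins the convention. Group contrasts use the tie-corrected
   Kruskal-Wallis H against chi-square (via `stats::kruskal.test`), and
   culled-versus-kept depth contrasts use Welch's t-test with
   normal-approximation 95% CI half-widths per mean.

## The built-in aligner

The aligner exists so the pipeline runs deterministically with no external
binary; it is a stand-in for a production aligner, not a reimplementation
of one, and `external_alignment_adapter()` validates and injects real
aligner output (ids and degapped sequences must match exactly).

It is progressive: a neighbour-joining guide tree on k-mer distances
(k = 3 for amino acids, 6 for nucleotides; distance = 1 − shared k-mers /
smaller k-mer count), midpoint-rooted, then postorder profile merges by
affine-gap dynamic programming. Profiles are alphabet-frequency columns
with gap mass simply absent, so column-column scores scale with occupancy
while gap penalties stay constant. Scoring: BLOSUM62 for amino acids,
+1/−1 for nucleotides (N and X score 0); gap open −11 (aa) / −2 (nuc),
extend −1, a length-L gap costing `open + (L−1) * ext`. `local_pref` mode
uses free end gaps (appropriate for partial-length transcripts),
`global_pref` end-to-end alignment. Every tie in the DP breaks
diagonal > up > left, and multifurcating guide nodes merge children
closest-first, so identical inputs give byte-identical alignments. The
pairwise kernel is verified against a brute-force three-state recursion on
short sequences.

One behaviour worth knowing: a sequence carrying a private large insertion
receives private columns, so a handful of such sequences can dominate the
column space of a *small* alignment and push every normal sequence's
coverage below the overlap thresholds. At realistic family sizes insertion
regions are shared among related copies and the effect fades; the overlap
cull is itself the intended remedy, since it removes the indel-bearing
divergent copies at stricter settings.

## The synthetic generator

`simulate_timp_dataset()` generates datasets with the statistical
structure the analysis assumes, plus ground truth for every planted
feature. Defaults are fixed to the reference study design and are not
tuning knobs:

* 41 specimens in five classes (14 Asteroidea / 9 Crinoidea / 5
  Echinoidea / 9 Holothuroidea / 4 Ophiuroidea).
* Per-specimen assembly totals are log-normal with per-class means taken
  from the published table (e.g. holothuroid mean 20,571 contigs);
  `sdlog` 0.6/0.8 approximates the observed within-class spread.
* TIMP copy counts are negative binomial with per-class means
  7.6/7.2/4.0/22.4/3.0 and size 6, with a specimen's expectation scaled
  by its own contig total. Both choices are fit to the table's moments:
  the marginal count variance among holothuroids implies size ≈ 6 once
  the count-vs-assembly-size coupling is modelled, and without the
  coupling the within-class spread of copy *proportions* is far wider
  than observed.
* Read depths per copy are log-normal with per-class means equal to the
  published reads-per-contig means and `sdlog = 1.2` (heavy-tailed, as
  observed depths are).
* Sequences (length 200 aa) evolve along per-specimen Yule gene trees
  hanging off clade ancestors, at 0.4 substitutions per free site per
  unit time; twelve cysteine positions and an HPQ tripeptide form a
  near-invariant scaffold (rate multiplier 0.02). The VIRAK pentapeptide
  is planted in 1 asteroid, 10 crinoid (split 4 + 6 over two specimens)
  and 2 holothuroid copies — the published carrier pattern — and in the
  chordate references, where it is a real vertebrate-associated motif.
* Burst specimens (default: the four highest-copy holothuroids and one
  crinoid, mirroring the taxa that showed recent radiations) have their
  gene-tree node ages compressed toward the present (`age^3` scaling), a
  positive-gamma signature; all other gene trees are plain Yule.
* Artifacts: 12% of holothuroid copies carry a 60-residue insertion and a
  10x read-depth multiplier (the "highly divergent, heavily used" copy
  class; the fraction is sized so the culled-vs-kept depth contrast has
  the published order of magnitude at a realistic culled-set size); 2% of
  records are truncated to a 30–60% window; 1% get byte-identical
  duplicates; and exactly one low-depth (18 reads) copy of the mammalian
  reference is attributed to an asteroid specimen, reproducing the single
  observed contamination case. Planted motif carriers are exempt from
  truncation so the planted truth stays exact.

What the generator does *not* emulate: codon structure and selection
(sequences are i.i.d.-site amino acids with rate multipliers), read-level
noise and assembly chimeras, orthology/paralogy conflation across
specimens (each specimen's family is simulated independently of the
others'), and alignment ambiguity of the real data. Passing recovery
tests therefore demonstrate that the *statistical machinery* detects the
planted structure at study-like sizes — not that any particular biological
conclusion is certified.

## Numerical conventions and degenerate inputs

* Identity distance ignores columns where either row is gapped; disjoint
  coverage gives distance 1. Whether the original distance screen
  counted pairwise-gapped columns is unpublished; this is the common
  convention and is documented, not asserted as anyone else's.
* Alignments are upper-case; `?` and `.` normalize to `-`; `X`/`N` are
  residues, not gaps.
* Neighbour joining breaks Q-criterion ties by the lexicographically
  smallest label pair; negative branch lengths clamp to zero with the
  deficit moved to the sibling branch, preserving the joined path
  length. NJ on additive matrices is exact to 1e-9.
* Ultrametricity checks use a relative tolerance of 1e-6; dating a tree
  with zero root depth is an error.
* `kruskal_wallis` with identical values in all groups returns H = 0,
  p = 1 (inherited from `stats::kruskal.test`); `welch_t` with two
  zero-variance equal-mean samples returns p = 1 rather than NaN.
* The pipeline roots on the configured outgroup; when the outgroup set is
  not monophyletic in the distance tree it falls back to rooting on its
  first member.
* Curator decisions (re-added or force-removed records, representative
  selection) are explicit `force_include` / `force_exclude` id lists in
  the pipeline configuration, not heuristics, because they were judgment
  calls in the original workflow.
* The command-line surface is the R API plus `scripts/acceptance.R`; the
  stages are library functions (`run_pipeline()` orchestrates them), the
  natural interface for an R analysis package.

## Test problem sizes

The suite verifies oracle examples at hand-checkable sizes (alignments of
2–12 sequences, trees of 3–10 leaves), property tests at moderate sizes
(random grids of 36 cells, 100-replicate bootstraps on 10 sequences), and
the stochastic calibrations at 500–1000 Yule trees of 40 tips and 100–200
simulated datasets at the full 41-specimen design — sizes at which the
binomial error of a rate estimate is a percent or two, which is what the
acceptance bands require. The end-to-end pipeline test runs a reduced
two-class design (6 specimens, 3-threshold grid, 25 bootstraps) because
the full 36-cell grid on hundreds of sequences is a production run, not a
unit test.

## Known limitations

* The distance-tree engine is a stand-in; published terminal counts that
  depend on maximum-likelihood searches and their bootstrap samples
  (selected-alignment sizes, exact rogue-removal counts) are not
  reproduced by it and are not claimed.
* The per-sequence residue-overlap score is an interpretation (mean
  occupancy over the sequence's residue-bearing columns); the trimming
  tool that inspired the statistic defines column-level quantities only.
* Greedy single-leaf rogue pruning can miss multi-leaf dropsets that are
  only jointly beneficial; the exhaustive comparison in the tests bounds
  this on small trees.
* The consensus tie rule (`-` on tied winners) and the duplicate keeper
  rule are conventions chosen here and documented as such.
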