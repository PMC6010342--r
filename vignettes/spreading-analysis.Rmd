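---
title: "Detecting histone-mark spreading with summit-centered metaprofiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting histone-mark spreading with summit-centered metaprofiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromspread)
```

## The analysis problem

Some chromatin factors do not deposit a histone mark but *confine* it:
when the factor is lost, the mark's domains broaden ("spread") into the
flanks of the factor's binding sites, sometimes with consequences for the
expression of nearby genes. chromspread implements the quantitative chain
needed to detect and characterize such spreading from binned ChIP-seq
coverage of two genotypes (a wild type and a factor-null mutant):

1. **Signal normalization** — per-bin ChIP z-scores, i.e. genome-wide
   standardized log2 ratios of ChIP over a control track.
2. **Peak statistics** — overlap fractions between peak sets, Fisher tests
   of list overlap over a stated universe, a permutation null for interval
   overlap, and strand-aware closest-gene assignment.
3. **Metaprofiles** — summit-centered matrices of signal, oriented 5'→3'
   along each summit's assigned gene, with subsample-bootstrap confidence
   bands; spreading is called where the mutant band separates from the
   wild-type band over a sustained run of bins.
4. **Integration** — a simplified sliding-window differential-signal
   caller, the fraction of elevated regions, gene-list overlap with
   direction, and correlation of per-gene mark change with expression
   change.
5. **Synthetic forward model** — a generator that plants known effects so
   that every stage can be validated against ground truth.

## The normalization model

Raw coverage is binned (mean per fixed-width bin; a final partial bin is
averaged over its actual width). `log2_ratio()` computes
`log2((chip + pc) / (control + pc))` after rescaling the control to the
ChIP track's genome-wide mean, which removes sequencing-depth differences
while keeping the pseudocount `pc` (default 1.0, count scale) meaningful.
Which control to use — input DNA, or an H3 ChIP when the mark of interest
sits on H3 — is always an explicit argument, never inferred. `zscore()`
standardizes with a *single* genome-wide mean and SD (population SD,
denominator *n*, so `[0, 0, 2, 2]` maps to `[-1, -1, 1, 1]`); per-chromosome
scaling would break cross-chromosome comparability of one "z-score track".

## Coordinates and peak statistics

All coordinates are 0-based half-open (the BED/bedGraph convention).
Two peaks overlap when they share at least `min_overlap_bp` bases
(default 1 bp) under half-open arithmetic, so `[0,100)` and `[99,150)`
overlap while `[0,100)` and `[100,150)` do not. Overlap percentages are
asymmetric by definition: `overlap_fraction(a, b)` is the percentage of
*A* peaks with at least one partner in *B*.

`fisher_overlap_test()` runs the standard two-sided Fisher exact test on
the 2×2 table of two id lists over a stated universe and additionally
reports whether the observed overlap is above or below the
hypergeometric expectation `|A||B|/N`. The universe is the caller's
choice (all genes, or only detectably expressed genes when an expression
table is available); the package supports both and asserts neither as
canonical. For interval-level questions where no natural universe
exists, `shuffle_overlap_null()` instead re-places the A peaks uniformly
at random (length-preserving, within chromosome) and reports the empirical
p-value `(1 + #{perm ≥ obs})/(1 + n_perm)`; note its floor is
`1/(1 + n_perm)` and saturated configurations correctly give p = 1.

`assign_closest_gene()` measures from the peak *summit* to the gene
interval on the coordinate number line (0 inside the gene,
`start − summit` to the left, `summit − end` to the right); a TSS mode is
available by flag. Ties are broken by lexicographically smaller gene id
and counted, so assignments are deterministic and auditable.

## Oriented metaprofiles and the subsample bootstrap

`extract_oriented_matrix()` builds a summits × offsets matrix: 3000 bp on
each side of the summit in 50 bp windows at the defaults (120 columns,
offset 0 at the boundary between columns 59 and 60, columns labeled by
window start). Each row is flipped when its summit's assigned gene is on
the minus strand, so offsets always run 5'→3' of the gene: for a
minus-strand gene with summit X the window runs X+3000 down to X−3000.
Windows are snapped to the underlying track grid (summit rounded to the
nearest track-bin boundary, at most half a track bin of shift), and
window bins beyond a chromosome end are masked as `NA` and excluded from
all means and bootstrap denominators — zero-filling would bias flank
means downward.

The confidence procedure is a *subsample* bootstrap: each of 1000
replicates draws 10% of the rows and records the per-bin mean; the band
is the full-sample mean ± `z₀.₉₇₅ · SD(replicate means)`, treating the
replicate means as normal. Three deliberate choices, each exposed as an
argument:

* **Without replacement** by default (`replace = TRUE` gives the
  classical flavor). The replicate-mean SD then follows the
  finite-population law `sqrt(S²/m · (n−m)/n)`, which the test suite
  verifies directly.
* **One row-subset shared across all bins** of a replicate, preserving
  the cross-bin correlation of profiles.
* **Centered on the full-sample mean**, with normal quantiles rather than
  bootstrap percentiles.

Because the spread of 10%-subsample means is roughly `sqrt(10)` times the
standard error of the full-sample mean, the band is *conservative*: its
empirical coverage of the true mean is essentially 100%, and any
separation between two genotypes' bands is correspondingly demanding.

`detect_spreading()` marks a bin significant when the mutant's lower
bound exceeds the wild type's upper bound, and calls the onset on each
side of the summit as the summit-proximal edge of the nearest run of at
least `min_run_bins` (default 3 bins = 150 bp) consecutive significant
bins; single-bin excursions therefore never produce a call. Onsets are
reported in oriented bp and are multiples of the bin width.

## Differential regions and expression coupling

`call_differential_regions()` is an effect-size caller, documented as
*not* a reimplementation of count-based differential-binding statistics:
it thresholds the sliding mean (default 20 bins = 1000 bp) of the per-bin
z-score difference at `min_abs_delta` (default 1.2 z units) and merges
same-direction windows within `merge_gap_bins`. Because each genotype's
track is standardized on its own genome-wide moments, a genotype with
substantial extra signal mass has a slightly shifted, compressed
background; the caller therefore centers the difference on its
genome-wide median before thresholding (the analogue of the background
normalization dedicated tools perform). The defaults were chosen so that,
on the generator's default conditions, background noise contributes a
negligible number of windows: the per-bin difference of two z-tracks has
SD ≈ √2, so a 20-bin window mean has SD ≈ 0.32 and the 1.2 threshold sits
at ≈ 3.8 background SDs.

`integrate_mark_expression()` chains normalization, region calling,
closest-gene assignment, the directional Fisher comparison of
differential-mark genes against up-regulated DE genes, and the per-gene
correlation of mark change with expression change (Spearman by default —
the scale linking the two is unknown; Pearson by flag). When the binding
factor's peak set is supplied as `target_peaks`, the correlation is
computed over the factor's target genes, each paired with the mean
(centered) delta in a fixed ±2 kb window around its target summit. The
fixed window matters: a called region's own mean is censored at the
calling threshold, which compresses between-gene variance and can hide a
real coupling.

## What the synthetic generator emulates

The forward model is the package's ground-truth test surface:

* **Genes** — non-overlapping stranded intervals, uniform strands,
  lengths uniform on 800–2500 bp, placed by distributing free space
  uniformly; infeasible packings are an error, never silent truncation.
* **Coverage** — per-bin counts `Poisson(background · 2^(e + ε))` with
  `background = 50` per 50 bp bin, `ε ~ N(0, 0.5²)` on the log2 scale,
  and `e` the injected log2 enrichment: a triangular kernel of height 2
  and width 500 bp at each mark summit. These values put the genome-wide
  log2-ratio SD near 0.6, so an injected log2 elevation of 1 lands near
  1.7 z-score units — a clearly detectable but not caricatural effect for
  a deeply sequenced ChIP experiment.
* **Spreading** — in the mutant only, flanks of affected summits are
  elevated by `spread_amplitude` (default 1.0) from `spread_onset_bp`
  (default 500 bp, matching the flank-elevation picture the method is
  meant to resolve) decaying linearly over `spread_extent_bp` (default
  2000 bp). Each site draws a strength factor uniform on 0.5–1.5, shared
  between genotypes and recorded in the truth table — real sites do not
  spread identically, and the factor is what expression coupling tracks.
* **Binder** — a second ChIP/control pair whose summits sit
  `binder_summit_offset_bp` (default −150 bp, i.e. 100–200 bp upstream)
  from the mark summits in gene orientation, with 50 bp placement jitter.
* **Expression** — affected genes gain `de_effect_log2 × strength factor`
  log2 units with probability `de_coupling_prob` (defaults 1.0 and 1.0);
  logFC noise is N(0, 0.3²), a typical replicate-level dispersion for
  detectably expressed genes, and the DE flag is Benjamini–Hochberg at 5%
  on a normal null — an explicit stand-in for a count-based test,
  sufficient to exercise the list logic.
* **Paired genotypes** — peak placement is biology and is shared between
  the genotypes of a pair (`placement_seed` / `generate_genotype_pair()`),
  while coverage noise is experiment-specific and independent. With
  `spread_amplitude = 0` and equal seeds the genotypes are bit-identical,
  giving an exact null.

What the generator does *not* emulate: read-level artifacts (fragment
lengths, duplicates, mappability), GC or copy-number structure,
autocorrelated background, replicate structure, germline/soma cell
mixtures (germline specificity is a plain gene flag), and asymmetric
spreading. Passing tests therefore demonstrate correctness of the
*computational chain* under a clean count model, not robustness to every
artifact of real libraries.

## Numerical and design notes

* Determinism: every stochastic operation takes an explicit seed and
  restores the caller's RNG state; equal seeds give bit-identical output.
* Validation scales used by the test suite: oracle equivalence on 200
  random instances per operation; exhaustive Fisher enumeration for all
  2×2 tables to N = 22 plus a random sweep to N = 60; spreading-onset
  recovery on 50 simulations of 1000 summits (and 200 null simulations of
  300 summits); the joint integration property on 50 simulations of 150
  peaks over a 3 Mb genome.
* Degenerate inputs error loudly: constant tracks (zero variance),
  empty chromosomes, peaks without genes on their chromosome, summits
  outside their peak, overlapping bedGraph records, start ≥ end with the
  offending line number.
* The CLI (`inst/scripts/chromspread-cli.R`) is a thin wrapper: seven
  subcommands mapping one-to-one onto exported functions, `#` headers
  recording version and seed in every output, atomic writes, exit code 2
  for usage errors and 1 for runtime failures.

## Worked example

```{r example, eval = FALSE}
gs <- genome_spec(c("chrI", "chrII", "chrIII"), rep(2e6, 3))
genes <- generate_genome(gs, 1200, seed = 1)
pair <- generate_genotype_pair(genes, gs, n_peaks = 800,
                               truth = synthetic_truth(), seed = 1)

z_wt <- normalize_tracks(pair$wt$chip, pair$wt$control)
z_mut <- normalize_tracks(pair$mut$chip, pair$mut$control)
asg <- assign_closest_gene(pair$wt$mark_peaks, genes)

ci_wt <- bootstrap_ci(extract_oriented_matrix(z_wt, pair$wt$mark_peaks, asg),
                      seed = 1001)
ci_mut <- bootstrap_ci(extract_oriented_matrix(z_mut, pair$mut$mark_peaks, asg),
                       seed = 2001)
detect_spreading(ci_wt, ci_mut)
#> spreading_call: upstream onset -500 bp, downstream onset +500 bp (...)
plot_profile_ci(WT = ci_wt, MUT = ci_mut)
```
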