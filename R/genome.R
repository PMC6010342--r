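#' Genome specification
#'
#' A minimal description of a genome as a set of named chromosomes with
#' lengths, used to validate coordinates and to size binned tracks.
#'
#' @param chrom_names Character vector of unique chromosome names.
#' @param chrom_lengths Integer vector of chromosome lengths in base pairs
#'   (all positive), one per name.
#'
#' @return An object of class `genome_spec`: a list with elements
#'   `chrom_names` and `chrom_lengths` (named by chromosome).
#' @examples
#' gs <- genome_spec(c("chrI", "chrII"), c(1e6, 5e5))
#' @export
genome_spec <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0) ||
      any(chrom_lengths != floor(chrom_lengths)))
    stop("chromosome lengths must be positive integers")
  names(chrom_lengths) <- chrom_names
  structure(list(chrom_names = chrom_names, chrom_lengths = chrom_lengths),
            class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  invisible(x)
}

stopifnot_genome <- function(genome) {
  if (!inherits(genome, "genome_spec")) stop("expected a genome_spec object")
  genome
}

# check a chrom vector against a genome; used by track/peak validators
check_chroms <- function(chrom, genome, what = "intervals") {
  bad <- setdiff(unique(chrom), genome$chrom_names)
  if (length(bad))
    stop(sprintf("%s reference chromosome(s) absent from genome: %s",
                 what, paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Ground-truth parameters for the synthetic forward model
#'
#' Collects the injected effects that the synthetic generator plants and the
#' downstream analysis is expected to recover: the signed offset between
#' binder and mark summits, the genotype-dependent flank elevation
#' ("spreading") of the mark, and the coupling between spreading and
#' expression change.
#'
#' @param binder_summit_offset_bp Signed offset in bp of the binder summit
#'   relative to the mark summit, in the 5'->3' orientation of the assigned
#'   gene (negative = upstream of the oriented mark). Default -150, i.e. the
#'   binder sits 100-200 bp upstream of the mark summit.
#' @param spread_amplitude Elevation (in log2-ratio units, approximately
#'   z-score units after genome-wide standardization) added to mutant flank
#'   signal. 0 disables spreading entirely (null model).
#' @param spread_onset_bp Distance from the summit (bp, >= 0) at which the
#'   flank elevation begins.
#' @param spread_extent_bp Distance (bp, > 0) over which the elevation
#'   decays linearly from `spread_amplitude` back to zero.
#' @param de_coupling_prob Probability that a spread-affected gene receives
#'   a positive expression shift of `de_effect_log2` in the mutant.
#' @param de_effect_log2 Mean log2 fold-change given coupling.
#'
#' @return An object of class `synthetic_truth`; after
#'   [generate_peaks_and_tracks()] its `peaks` element holds the per-peak
#'   record of injected effects (peak id, gene id, summits, affected flag).
#' @seealso [generate_peaks_and_tracks()], [generate_expression()]
#' @export
synthetic_truth <- function(binder_summit_offset_bp = -150,
                            spread_amplitude = 1.0,
                            spread_onset_bp = 500,
                            spread_extent_bp = 2000,
                            de_coupling_prob = 1.0,
                            de_effect_log2 = 1.0) {
  if (spread_onset_bp < 0) stop("spread_onset_bp must be >= 0")
  if (spread_extent_bp <= 0) stop("spread_extent_bp must be > 0")
  if (de_coupling_prob < 0 || de_coupling_prob > 1)
    stop("de_coupling_prob must be in [0, 1]")
  if (spread_amplitude < 0) stop("spread_amplitude must be >= 0")
  structure(list(binder_summit_offset_bp = binder_summit_offset_bp,
                 spread_amplitude = spread_amplitude,
                 spread_onset_bp = spread_onset_bp,
                 spread_extent_bp = spread_extent_bp,
                 de_coupling_prob = de_coupling_prob,
                 de_effect_log2 = de_effect_log2,
                 peaks = NULL),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth: binder offset", x$binder_summit_offset_bp,
      "bp; spreading amp", x$spread_amplitude,
      "onset", x$spread_onset_bp, "bp extent", x$spread_extent_bp,
      "bp; DE coupling", x$de_coupling_prob, "\n")
  if (!is.null(x$peaks))
    cat("  per-peak records:", nrow(x$peaks), "peaks,",
        sum(x$peaks$spread_affected), "spread-affected\n")
  invisible(x)
}
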