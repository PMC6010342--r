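#' Binned genome signal track
#'
#' A fixed-bin numeric signal over a genome: one vector per chromosome with
#' `ceiling(chrom_length / bin_bp)` bins. The `kind` field records where the
#' track sits in the normalization chain `raw -> log2ratio -> zscore`.
#'
#' @param values Named list of numeric vectors, one per chromosome of
#'   `genome`, each of length `ceiling(chrom_length / bin_bp)`.
#' @param bin_bp Bin width in bp (positive integer).
#' @param genome A [genome_spec()].
#' @param kind One of `"raw"`, `"log2ratio"`, `"zscore"`.
#'
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_bp, genome, kind = c("raw", "log2ratio", "zscore")) {
  kind <- match.arg(kind)
  stopifnot_genome(genome)
  if (bin_bp < 1 || bin_bp != floor(bin_bp)) stop("bin_bp must be a positive integer")
  if (!is.list(values) || is.null(names(values)))
    stop("values must be a named list of numeric vectors")
  check_chroms(names(values), genome, "track")
  missing <- setdiff(genome$chrom_names, names(values))
  if (length(missing))
    stop("track missing chromosome(s): ", paste(missing, collapse = ", "))
  for (chrom in genome$chrom_names) {
    expected <- n_bins(genome$chrom_lengths[[chrom]], bin_bp)
    if (length(values[[chrom]]) != expected)
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   chrom, expected, length(values[[chrom]])))
  }
  structure(list(values = values[genome$chrom_names], bin_bp = as.integer(bin_bp),
                 genome = genome, kind = kind),
            class = "binned_track")
}

n_bins <- function(chrom_length, bin_bp) as.integer(ceiling(chrom_length / bin_bp))

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track [", x$kind, "]: bin ", x$bin_bp, " bp, ",
      length(x$values), " chromosome(s), ",
      format(sum(lengths(x$values)), big.mark = ","), " bins\n", sep = "")
  invisible(x)
}

# pooled genome-wide vector (all chromosomes concatenated in genome order)
track_pool <- function(track) unlist(track$values, use.names = FALSE)

check_same_geometry <- function(a, b) {
  if (!inherits(a, "binned_track") || !inherits(b, "binned_track"))
    stop("expected binned_track objects")
  if (a$bin_bp != b$bin_bp) stop("tracks have different bin sizes")
  if (!identical(a$genome$chrom_names, b$genome$chrom_names) ||
      !identical(unname(a$genome$chrom_lengths), unname(b$genome$chrom_lengths)))
    stop("tracks are on different genomes")
  invisible(TRUE)
}

#' Bin per-base coverage into a fixed-bin track
#'
#' Each bin takes the mean of the per-base values it covers; a final partial
#' bin is averaged over its actual width, not the nominal bin width.
#'
#' @param per_base_values Named list of per-base numeric vectors, one per
#'   chromosome; vector length defines the chromosome length.
#' @param bin_bp Bin width in bp.
#' @return A `raw`-kind [binned_track()].
#' @examples
#' bt <- bin_coverage(list(chr = rep(4, 200)), bin_bp = 50)
#' bt$values$chr  # 4 4 4 4
#' @export
bin_coverage <- function(per_base_values, bin_bp) {
  if (bin_bp < 1) stop("bin_bp must be >= 1")
  if (!is.list(per_base_values) || is.null(names(per_base_values)))
    stop("per_base_values must be a named list")
  if (any(lengths(per_base_values) == 0)) stop("empty chromosome in per-base input")
  genome <- genome_spec(names(per_base_values), lengths(per_base_values))
  values <- lapply(per_base_values, function(x) {
    n <- length(x)
    nb <- n_bins(n, bin_bp)
    starts <- (seq_len(nb) - 1L) * bin_bp
    ends <- pmin(starts + bin_bp, n)
    cs <- c(0, cumsum(as.numeric(x)))
    (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts)
  })
  binned_track(values, bin_bp, genome, kind = "raw")
}

#' Log2 ratio of ChIP over control
#'
#' Computes the per-bin log2 ratio of ChIP to control signal with a
#' pseudocount: `log2((chip + pc) / (control + pc))`. By default the control
#' track is first rescaled to the ChIP track's genome-wide mean, making the
#' ratio insensitive to sequencing-depth differences (the role bamCoverage
#' scaling plays upstream in a real pipeline); the pseudocount therefore
#' stays on the ChIP count scale.
#'
#' @param chip,control `raw`-kind [binned_track()]s with identical geometry.
#' @param pseudocount Positive value added to both tracks before the ratio.
#' @param scale_libsize If `TRUE` (default), multiply the control by
#'   `mean(chip) / mean(control)` (genome-wide means) before the ratio.
#' @return A `log2ratio`-kind track.
#' @export
log2_ratio <- function(chip, control, pseudocount = 1, scale_libsize = TRUE) {
  check_same_geometry(chip, control)
  if (chip$kind != "raw" || control$kind != "raw")
    stop("log2_ratio expects raw coverage tracks")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  scale <- 1
  if (scale_libsize) {
    mc <- mean(track_pool(control))
    if (mc <= 0) stop("control track has non-positive genome-wide mean")
    scale <- mean(track_pool(chip)) / mc
  }
  values <- mapply(function(a, b) log2((a + pseudocount) / (b * scale + pseudocount)),
                   chip$values, control$values, SIMPLIFY = FALSE)
  binned_track(values, chip$bin_bp, chip$genome, kind = "log2ratio")
}

#' Genome-wide z-score standardization
#'
#' Standardizes a log2-ratio track to mean 0 and SD 1 using a single
#' genome-wide mean and SD pooled over all chromosomes (one "z-score track",
#' not per-chromosome scaling). The population SD (denominator `n`) is
#' used, so e.g. bins `[0, 0, 2, 2]` standardize to `[-1, -1, 1, 1]`.
#'
#' @param track A `log2ratio`-kind (or already standardized `zscore`-kind)
#'   [binned_track()] with at least two non-identical bins.
#' @return A `zscore`-kind track with pooled mean 0 and SD 1.
#' @export
zscore <- function(track) {
  if (!inherits(track, "binned_track")) stop("expected a binned_track")
  if (track$kind == "raw")
    stop("zscore expects a log2ratio track; call log2_ratio() first")
  pooled <- track_pool(track)
  if (length(pooled) < 2) stop("need at least 2 bins to standardize")
  mu <- mean(pooled)
  sigma <- sqrt(mean((pooled - mu)^2))
  if (!is.finite(sigma) || sigma == 0)
    stop("track has zero variance; cannot compute z-scores")
  values <- lapply(track$values, function(v) (v - mu) / sigma)
  binned_track(values, track$bin_bp, track$genome, kind = "zscore")
}

#' One-call ChIP z-score normalization
#'
#' Convenience chain `zscore(log2_ratio(chip, control, ...))`, producing the
#' standardized log2 ratio ("ChIP z-score") track used by the metaprofile
#' and differential-region stages.
#'
#' @inheritParams log2_ratio
#' @return A `zscore`-kind track.
#' @export
normalize_tracks <- function(chip, control, pseudocount = 1, scale_libsize = TRUE) {
  zscore(log2_ratio(chip, control, pseudocount = pseudocount,
                    scale_libsize = scale_libsize))
}
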