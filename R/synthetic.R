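#' Generate a random non-overlapping gene annotation
#'
#' Places `n_genes` non-overlapping stranded genes on the chromosomes of
#' `genome`. Genes are allocated to chromosomes with probability
#' proportional to chromosome length, gene lengths are uniform on
#' `[min_gene_len, max_gene_len]`, strands are uniform on `{+, -}`, and
#' placement fills each chromosome by distributing the free (non-genic)
#' space uniformly between genes.
#'
#' @param genome A [genome_spec()].
#' @param n_genes Number of genes (>= 1).
#' @param min_gene_len,max_gene_len Gene length bounds in bp.
#' @param seed Integer seed; the call is deterministic given the seed.
#'
#' @return A BED6-style data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `id`, `score`, `strand`, sorted by chromosome
#'   then start.
#' @export
generate_genome <- function(genome, n_genes, min_gene_len = 800,
                            max_gene_len = 2500, seed = 1) {
  stopifnot_genome(genome)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (min_gene_len < 1 || max_gene_len < min_gene_len)
    stop("invalid gene length bounds")
  if (max_gene_len > min(genome$chrom_lengths))
    stop("max_gene_len exceeds the shortest chromosome")
  withr::with_seed(seed, {
    chrom_idx <- sample.int(length(genome$chrom_names), n_genes, replace = TRUE,
                            prob = genome$chrom_lengths)
    lens <- sample(seq.int(min_gene_len, max_gene_len), n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    out <- vector("list", length(genome$chrom_names))
    for (ci in seq_along(genome$chrom_names)) {
      sel <- which(chrom_idx == ci)
      if (!length(sel)) next
      L <- genome$chrom_lengths[[ci]]
      glens <- lens[sel]
      free <- L - sum(glens)
      if (free < 0)
        stop(sprintf(
          "cannot fit %d genes (%d bp) on chromosome %s (%d bp)",
          length(sel), sum(glens), genome$chrom_names[ci], L))
      offsets <- floor(sort(stats::runif(length(sel), 0, free + 1)))
      offsets <- pmin(offsets, free)
      starts <- offsets + cumsum(c(0, glens[-length(glens)]))
      out[[ci]] <- data.frame(chrom = genome$chrom_names[ci],
                              start = starts, end = starts + glens,
                              strand = strand[sel],
                              stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    genes <- genes[order(match(genes$chrom, genome$chrom_names), genes$start), ]
    rownames(genes) <- NULL
    data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
               id = sprintf("g%05d", seq_len(nrow(genes))),
               score = 0L, strand = genes$strand, stringsAsFactors = FALSE)
  })
}

# log2-enrichment profile contributed by one peak, evaluated at bin centers.
# Triangular kernel of height `height` and half-width `half` at the summit;
# plus, when `spread`, a flank elevation of `amp` beginning `onset` bp from
# the summit and decaying linearly to zero over `extent` bp.
peak_log2_profile <- function(centers, summit, height, half,
                              spread = FALSE, amp = 0, onset = 0, extent = 1) {
  d <- abs(centers - summit)
  e <- height * pmax(0, 1 - d / half)
  if (spread && amp > 0) {
    w <- 1 - (d - onset) / extent
    e <- e + amp * ifelse(d >= onset, pmax(0, pmin(1, w)), 0)
  }
  e
}

#' Simulate mark/binder peak sets and ChIP coverage tracks
#'
#' Forward model for a histone mark whose domains are restricted by a
#' chromatin-binding factor ("binder"). Mark peaks are anchored near gene 5'
#' ends (strand-aware); per-bin coverage is count-like,
#' `Poisson(background * 2^(enrichment + noise))` with a triangular
#' log2-enrichment kernel around each summit. For `genotype = "MUT"` the
#' flanks of spread-affected summits are additionally elevated by
#' `truth$spread_amplitude` starting `truth$spread_onset_bp` from the summit
#' and decaying linearly over `truth$spread_extent_bp`. Binder summits are
#' offset from mark summits by `truth$binder_summit_offset_bp` in the
#' orientation of the anchor gene (plus per-peak Gaussian jitter), and a
#' second ChIP/control track pair carries the binder signal.
#'
#' The random number stream does not depend on `genotype`, so with
#' `spread_amplitude = 0` the WT and MUT outputs are identical for equal
#' seeds (a by-construction null).
#'
#' When simulating a genotype pair, peak placement is biology shared by
#' both genotypes while coverage noise is experiment-specific: pass the
#' same `placement_seed` with different `seed`s (or use
#' [generate_genotype_pair()]) so both genotypes carry identical peaks and
#' summits but independent track noise.
#'
#' @param genes Gene annotation from [generate_genome()].
#' @param genome The [genome_spec()] the genes live on.
#' @param n_peaks Number of mark peaks (<= number of genes).
#' @param bin_bp Track bin size in bp.
#' @param enrich_height Peak log2-enrichment at the summit.
#' @param peak_width_bp Total width of the triangular enrichment (and of the
#'   emitted peak intervals); must be >= `bin_bp`.
#' @param truth A [synthetic_truth()] holding the injected effects.
#' @param genotype `"WT"` or `"MUT"`; only MUT receives spreading.
#' @param noise_sd SD of per-bin Gaussian noise added on the log2 scale.
#' @param background_rate Poisson background rate per bin.
#' @param anchor_jitter_bp Mark summits are placed uniformly within this
#'   distance of the gene 5' end.
#' @param binder_jitter_sd SD (bp) of per-peak jitter around the binder
#'   summit offset.
#' @param seed Integer seed for the coverage noise (and, when
#'   `placement_seed` is `NULL`, for placement too).
#' @param placement_seed Optional separate seed for peak placement (gene
#'   choice, summit jitter, binder jitter).
#'
#' @return A list with elements `mark_peaks` and `binder_peaks` (data.frames
#'   with `chrom`, `start`, `end`, `id`, `summit`), `chip` / `control`
#'   (mark ChIP and its control, `raw` [binned_track()]s), `chip_binder` /
#'   `control_binder` (binder ChIP pair), and `truth` (input truth with the
#'   per-peak effect record filled in).
#' @export
generate_peaks_and_tracks <- function(genes, genome, n_peaks, bin_bp = 50,
                                      enrich_height = 2.0, peak_width_bp = 500,
                                      truth = synthetic_truth(),
                                      genotype = c("WT", "MUT"),
                                      noise_sd = 0.5, background_rate = 50,
                                      anchor_jitter_bp = 500,
                                      binder_jitter_sd = 50, seed = 1,
                                      placement_seed = NULL) {
  genotype <- match.arg(genotype)
  stopifnot_genome(genome)
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  if (n_peaks < 1) stop("n_peaks must be >= 1")
  if (n_peaks > nrow(genes))
    stop(sprintf("n_peaks (%d) exceeds available gene anchors (%d)",
                 n_peaks, nrow(genes)))
  if (peak_width_bp < bin_bp) stop("peak_width_bp must be >= bin_bp")
  check_chroms(genes$chrom, genome, "genes")

  half <- floor(peak_width_bp / 2)
  place <- function() {
    gi <- sort(sample.int(nrow(genes), n_peaks))
    anchor <- genes[gi, ]
    tss <- ifelse(anchor$strand == "+", anchor$start, anchor$end - 1L)
    L <- genome$chrom_lengths[anchor$chrom]
    summit <- tss + sample(seq.int(-anchor_jitter_bp, anchor_jitter_bp),
                           n_peaks, replace = TRUE)
    summit <- pmin(pmax(summit, half), L - half - 1)
    # binder offset applied in the gene's 5'->3' orientation
    orient <- ifelse(anchor$strand == "+", 1, -1)
    bjit <- round(stats::rnorm(n_peaks, 0, binder_jitter_sd))
    bsummit <- summit + orient * truth$binder_summit_offset_bp + bjit
    bsummit <- pmin(pmax(bsummit, half), L - half - 1)
    # per-site spreading strength; expression coupling follows it
    amp_factor <- stats::runif(n_peaks, 0.5, 1.5)
    list(anchor = anchor, summit = summit, bsummit = bsummit,
         amp_factor = amp_factor)
  }
  pl <- if (is.null(placement_seed)) NULL else withr::with_seed(placement_seed, place())

  withr::with_seed(seed, {
    if (is.null(pl)) pl <- place()
    anchor <- pl$anchor
    summit <- pl$summit
    bsummit <- pl$bsummit

    mark_peaks <- data.frame(chrom = anchor$chrom, start = summit - half,
                             end = summit + half,
                             id = sprintf("mk%05d", seq_len(n_peaks)),
                             summit = summit, stringsAsFactors = FALSE)
    binder_peaks <- data.frame(chrom = anchor$chrom, start = bsummit - half,
                               end = bsummit + half,
                               id = sprintf("bd%05d", seq_len(n_peaks)),
                               summit = bsummit, stringsAsFactors = FALSE)

    affected <- rep(truth$spread_amplitude > 0, n_peaks)
    spread <- genotype == "MUT"
    reach <- max(half, truth$spread_onset_bp + truth$spread_extent_bp)

    mk_e <- enrichment_by_chrom(genome, bin_bp, mark_peaks$chrom,
                                mark_peaks$summit, enrich_height, half,
                                spread = spread & affected,
                                amp = truth$spread_amplitude * pl$amp_factor,
                                onset = truth$spread_onset_bp,
                                extent = truth$spread_extent_bp, reach = reach)
    bd_e <- enrichment_by_chrom(genome, bin_bp, binder_peaks$chrom,
                                binder_peaks$summit, enrich_height, half,
                                spread = rep(FALSE, n_peaks),
                                amp = numeric(n_peaks), onset = 0, extent = 1,
                                reach = half)

    draw_pair <- function(e) {
      chip <- lapply(genome$chrom_names, function(ch) {
        n <- length(e[[ch]])
        lam <- background_rate * 2^(e[[ch]] + stats::rnorm(n, 0, noise_sd))
        as.numeric(stats::rpois(n, lam))
      })
      names(chip) <- genome$chrom_names
      ctrl <- lapply(genome$chrom_names, function(ch) {
        as.numeric(stats::rpois(length(e[[ch]]), background_rate))
      })
      names(ctrl) <- genome$chrom_names
      list(chip = binned_track(chip, bin_bp, genome, "raw"),
           control = binned_track(ctrl, bin_bp, genome, "raw"))
    }
    mk <- draw_pair(mk_e)
    bd <- draw_pair(bd_e)

    truth$peaks <- data.frame(peak_id = mark_peaks$id,
                              binder_id = binder_peaks$id,
                              gene_id = anchor$id, chrom = anchor$chrom,
                              strand = anchor$strand,
                              mark_summit = summit, binder_summit = bsummit,
                              spread_affected = affected,
                              spread_amp_factor = pl$amp_factor,
                              stringsAsFactors = FALSE)
    list(mark_peaks = mark_peaks, binder_peaks = binder_peaks,
         chip = mk$chip, control = mk$control,
         chip_binder = bd$chip, control_binder = bd$control,
         truth = truth)
  })
}

# accumulate per-peak log2 enrichment into per-chromosome bin vectors;
# amp is a per-peak vector of spreading amplitudes
enrichment_by_chrom <- function(genome, bin_bp, chrom, summit, height, half,
                                spread, amp, onset, extent, reach) {
  e <- lapply(genome$chrom_names, function(ch)
    numeric(n_bins(genome$chrom_lengths[[ch]], bin_bp)))
  names(e) <- genome$chrom_names
  for (i in seq_along(summit)) {
    ch <- chrom[i]
    nb <- length(e[[ch]])
    r <- if (spread[i]) reach else half
    i0 <- max(0L, floor((summit[i] - r) / bin_bp))
    i1 <- min(nb - 1L, ceiling((summit[i] + r) / bin_bp))
    idx <- seq.int(i0, i1)
    centers <- idx * bin_bp + bin_bp / 2
    e[[ch]][idx + 1L] <- e[[ch]][idx + 1L] +
      peak_log2_profile(centers, summit[i], height, half,
                        spread = spread[i], amp = amp[i],
                        onset = onset, extent = extent)
  }
  e
}

#' Simulate a matched WT/MUT genotype pair
#'
#' Runs [generate_peaks_and_tracks()] twice with shared peak placement
#' (same genes, summits and binder summits) but independent coverage noise,
#' the design of a two-genotype ChIP comparison. Noise seeds are derived
#' from `seed` as `2 * seed` (WT) and `2 * seed + 1` (MUT) with the
#' placement seeded by `seed` itself.
#'
#' @inheritParams generate_peaks_and_tracks
#' @param ... Further arguments passed to [generate_peaks_and_tracks()].
#' @return List with elements `wt` and `mut`, each as returned by
#'   [generate_peaks_and_tracks()] (their `truth$peaks` records are
#'   identical).
#' @export
generate_genotype_pair <- function(genes, genome, n_peaks,
                                   truth = synthetic_truth(), seed = 1, ...) {
  list(wt = generate_peaks_and_tracks(genes, genome, n_peaks, truth = truth,
                                      genotype = "WT", seed = 2L * seed,
                                      placement_seed = seed, ...),
       mut = generate_peaks_and_tracks(genes, genome, n_peaks, truth = truth,
                                       genotype = "MUT", seed = 2L * seed + 1L,
                                       placement_seed = seed, ...))
}

#' Simulate a differential-expression table coupled to spreading
#'
#' Genes whose mark peak was spread-affected (per the per-peak record in
#' `truth$peaks`) receive, with probability `truth$de_coupling_prob`, a
#' positive mean log2 fold-change of `truth$de_effect_log2` scaled by the
#' peak's spreading-strength factor (`spread_amp_factor`), so that stronger
#' spreading drives larger expression gain; all other genes are centered at
#' zero. A differential-expression flag is
#' derived from a normal null model on the observed logFC with
#' Benjamini-Hochberg control at `fdr_alpha` (a stand-in for a full
#' count-based test, sufficient to exercise list-comparison logic).
#'
#' @param genes Gene annotation from [generate_genome()].
#' @param truth A [synthetic_truth()] whose `peaks` record was filled by
#'   [generate_peaks_and_tracks()] on the same gene set (or `NULL` peaks for
#'   a pure-noise table).
#' @param base_logfc_sd SD of the per-gene logFC noise (log2 units).
#' @param fdr_alpha FDR level for the DE flag.
#' @param seed Integer seed.
#'
#' @return data.frame with columns `gene_id`, `logfc` (log2 MUT/WT), `de`
#'   (logical), `germline` (logical; TRUE for spread-affected target genes).
#' @export
generate_expression <- function(genes, truth, base_logfc_sd = 0.3,
                                fdr_alpha = 0.05, seed = 1) {
  if (!inherits(truth, "synthetic_truth")) stop("truth must be a synthetic_truth")
  affected_genes <- character(0)
  amp_factor <- numeric(0)
  if (!is.null(truth$peaks)) {
    bad <- setdiff(truth$peaks$gene_id, genes$id)
    if (length(bad))
      stop("truth refers to gene ids absent from `genes`: ",
           paste(utils::head(bad, 5), collapse = ", "))
    aff <- truth$peaks[truth$peaks$spread_affected, ]
    affected_genes <- aff$gene_id
    amp_factor <- aff$spread_amp_factor
  }
  withr::with_seed(seed, {
    n <- nrow(genes)
    is_aff <- genes$id %in% affected_genes
    coupled <- is_aff & (stats::runif(n) < truth$de_coupling_prob)
    factor_of <- rep(1, n)
    m <- match(genes$id, affected_genes)
    factor_of[!is.na(m)] <- amp_factor[m[!is.na(m)]]
    mu <- ifelse(coupled, truth$de_effect_log2 * factor_of, 0)
    logfc <- stats::rnorm(n, mu, base_logfc_sd)
    p <- 2 * stats::pnorm(-abs(logfc) / base_logfc_sd)
    de <- stats::p.adjust(p, method = "BH") < fdr_alpha
    data.frame(gene_id = genes$id, logfc = logfc, de = de,
               germline = is_aff, stringsAsFactors = FALSE)
  })
}
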