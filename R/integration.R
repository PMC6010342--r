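#' Simplified sliding-window differential-signal caller
#'
#' Scans the per-bin difference `alt - ref` with a sliding mean of
#' `window_bins` bins, keeps windows whose absolute mean reaches
#' `min_abs_delta`, and merges same-direction windows separated by at most
#' `merge_gap_bins` bins into regions. This is a deliberately simple
#' effect-size caller for exercising the downstream gene-joining logic; it
#' is not a reimplementation of count-based differential-binding statistics
#' (csaw/edgeR) and performs no FDR control across windows.
#'
#' Because each genotype's track is standardized on its own genome-wide
#' mean and SD, a genotype with substantial extra signal mass has its
#' background compressed and shifted; by default the scan therefore centers
#' the per-bin difference on its genome-wide median (the background mode)
#' before thresholding, the analogue of the background normalization
#' dedicated differential-binding tools apply.
#'
#' @param ref,alt `zscore`-kind [binned_track()]s with identical geometry
#'   (reference and alternative condition).
#' @param window_bins Sliding window width in bins (>= 1).
#' @param min_abs_delta Minimum absolute window mean difference (z units).
#' @param merge_gap_bins Maximum gap (bins) bridged when merging
#'   same-direction windows.
#' @param center Subtract the genome-wide median difference before
#'   thresholding (default `TRUE`).
#' @param genes Optional gene data.frame; when given each region is
#'   assigned its closest gene via [assign_closest_gene()], anchored at the
#'   region's maximal-|delta| bin.
#' @return data.frame of regions: `chrom`, `start`, `end` (bp, bin-aligned),
#'   `summit` (center of the peak-|delta| bin), `mean_delta`, `direction`
#'   (`up`/`down`), `id`, and `gene_id`/`gene_distance` when `genes` given.
#'   Zero rows when nothing passes the threshold.
#' @export
call_differential_regions <- function(ref, alt, window_bins = 20,
                                      min_abs_delta = 1.2, merge_gap_bins = 5,
                                      genes = NULL, center = TRUE) {
  check_same_geometry(ref, alt)
  if (window_bins < 1) stop("window_bins must be >= 1")
  bs <- ref$bin_bp
  shift <- 0
  if (center)
    shift <- stats::median(track_pool(alt) - track_pool(ref))
  regions <- list()
  for (ch in names(ref$values)) {
    d <- alt$values[[ch]] - ref$values[[ch]] - shift
    nb <- length(d)
    if (nb < window_bins) next
    cs <- c(0, cumsum(d))
    nw <- nb - window_bins + 1L
    sm <- (cs[(window_bins + 1L):(nb + 1L)] - cs[1:nw]) / window_bins
    for (dir in c("up", "down")) {
      keep <- if (dir == "up") sm >= min_abs_delta else sm <= -min_abs_delta
      w <- which(keep)
      if (!length(w)) next
      # window w covers bins [w-1, w-1+window_bins) in 0-based bin space
      iv <- merge_bin_intervals(w - 1L, w - 1L + window_bins, merge_gap_bins)
      for (r in seq_len(nrow(iv))) {
        bins <- seq.int(iv$start[r] + 1L, iv$end[r])
        peak_bin <- bins[which.max(abs(d[bins]))]
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = ch, start = iv$start[r] * bs,
          end = min(iv$end[r] * bs, ref$genome$chrom_lengths[[ch]]),
          summit = as.integer((peak_bin - 1L) * bs + bs / 2),
          mean_delta = mean(d[bins]), direction = dir,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(regions)) {
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      summit = integer(0), mean_delta = numeric(0),
                      direction = character(0), id = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, regions)
  out <- out[order(match(out$chrom, names(ref$values)), out$start), ]
  rownames(out) <- NULL
  out$id <- sprintf("dr%05d", seq_len(nrow(out)))
  if (!is.null(genes)) {
    asg <- assign_closest_gene(
      data.frame(chrom = out$chrom, summit = out$summit, id = out$id,
                 stringsAsFactors = FALSE), genes)
    out$gene_id <- asg$gene_id[match(out$id, asg$peak_id)]
    out$gene_distance <- asg$distance[match(out$id, asg$peak_id)]
  }
  out
}

# merge 0-based half-open bin intervals whose gap is <= gap bins
merge_bin_intervals <- function(starts, ends, gap) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me <= gap) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Percentage of differential regions with elevated signal
#'
#' @param regions Region table from [call_differential_regions()] (nonempty).
#' @return Percentage (0-100) of regions with `direction == "up"`.
#' @export
fraction_elevated <- function(regions) {
  if (nrow(regions) == 0) stop("no differential regions")
  100 * mean(regions$direction == "up")
}

#' Directional overlap of a differential-mark gene list with a DE gene list
#'
#' Thin wrapper over [fisher_overlap_test()] making the reporting direction
#' (more/less overlap than the hypergeometric expectation) explicit for
#' gene-list comparisons.
#'
#' @param diff_genes Genes assigned to differential mark regions.
#' @param de_genes Differentially expressed genes.
#' @param universe Gene universe (all genes, or all expressed genes).
#' @param alpha Significance level.
#' @return An `enrichment_result` (see [fisher_overlap_test()]).
#' @export
gene_change_overlap <- function(diff_genes, de_genes, universe, alpha = 0.05) {
  fisher_overlap_test(diff_genes, de_genes, universe, alpha = alpha)
}

#' Correlate per-gene mark change with expression change
#'
#' @param mark_delta Numeric vector of per-gene mark changes (e.g. mean
#'   z-score difference of the gene's differential region).
#' @param logfc Matched per-gene expression log2 fold-changes.
#' @param method `"spearman"` (default; rank-based, robust to the unknown
#'   scale linking mark change to expression) or `"pearson"`.
#' @return An object of class `change_coupling`: list with `r`, `p_value`,
#'   `n`, `method`, and the paired `data`.
#' @export
correlate_changes <- function(mark_delta, logfc,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(mark_delta) != length(logfc)) stop("inputs must be paired")
  if (length(mark_delta) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(mark_delta)) || any(!is.finite(logfc)))
    stop("non-finite values in input")
  if (stats::sd(mark_delta) == 0 || stats::sd(logfc) == 0)
    stop("zero variance in one of the margins")
  ct <- stats::cor.test(mark_delta, logfc, method = method, exact = FALSE)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(mark_delta), method = method,
                 data = data.frame(mark_delta = mark_delta, logfc = logfc)),
            class = "change_coupling")
}

#' @export
print.change_coupling <- function(x, ...) {
  cat(sprintf("change_coupling: %s r = %.3f, p = %.3g (n = %d)\n",
              x$method, x$r, x$p_value, x$n))
  invisible(x)
}

#' End-to-end mark-change vs expression-change integration
#'
#' Runs the full downstream chain on two simulated (or real) genotypes:
#' z-score normalization of both ChIP/control pairs, sliding-window
#' differential-region calling, closest-gene assignment, the directional
#' Fisher comparison of differential-mark genes against up-regulated DE
#' genes, and the per-gene mark-vs-expression correlation.
#'
#' When `target_peaks` is supplied (the binding-factor peak set), the
#' correlation is computed over the factor's target genes: each target
#' peak's closest gene is paired with the mean mark delta in a fixed
#' window around the target summit, the analysis style used when asking
#' whether mark elevation at bound genes tracks their expression change.
#' Without `target_peaks` the pairs fall back to the genes of the called
#' differential regions (anchored at each gene's strongest region).
#'
#' @param wt,mut Simulation outputs of [generate_peaks_and_tracks()] (or
#'   any lists with `chip`/`control` tracks) for the two genotypes.
#' @param expression Expression table (`gene_id`, `logfc`, `de`).
#' @param genes Gene annotation shared by both genotypes.
#' @param window_bins,min_abs_delta,merge_gap_bins,center Passed to
#'   [call_differential_regions()].
#' @param alpha Significance level for the Fisher direction.
#' @param coupling_flank_bp Half-width of the fixed window around each
#'   anchor summit over which the per-gene mark delta is averaged for the
#'   correlation. A fixed window avoids the threshold censoring a region's
#'   own mean suffers (regions exist only where the sliding mean exceeded
#'   the calling threshold, which compresses between-gene variance).
#' @param target_peaks Optional peak data.frame of binding-factor target
#'   sites used to define the correlation gene set (see Details).
#' @return List with `regions`, `pct_elevated`, `enrichment`
#'   (`enrichment_result` of differential-mark genes vs up-regulated DE
#'   genes over all genes), and `coupling` (`change_coupling`), the latter
#'   two `NULL` when no regions/too few pairs exist.
#' @export
integrate_mark_expression <- function(wt, mut, expression, genes,
                                      window_bins = 20, min_abs_delta = 1.2,
                                      merge_gap_bins = 5, alpha = 0.05,
                                      center = TRUE, coupling_flank_bp = 2000,
                                      target_peaks = NULL) {
  z_wt <- normalize_tracks(wt$chip, wt$control)
  z_mut <- normalize_tracks(mut$chip, mut$control)
  regions <- call_differential_regions(z_wt, z_mut, window_bins = window_bins,
                                       min_abs_delta = min_abs_delta,
                                       merge_gap_bins = merge_gap_bins,
                                       genes = genes, center = center)
  if (nrow(regions) == 0)
    return(list(regions = regions, pct_elevated = NA_real_,
                enrichment = NULL, coupling = NULL))
  pct <- fraction_elevated(regions)
  up_de <- expression$gene_id[expression$de & expression$logfc > 0]
  enr <- gene_change_overlap(unique(regions$gene_id), up_de, genes$id,
                             alpha = alpha)
  # per-gene anchors for the correlation: target-peak summits when a
  # target set is given, else each gene's strongest differential region;
  # mark delta measured over a fixed +/- coupling_flank_bp window (not the
  # censored region mean)
  shift <- if (center) stats::median(track_pool(z_mut) - track_pool(z_wt)) else 0
  bs <- z_wt$bin_bp
  fb <- as.integer(coupling_flank_bp / bs)
  window_delta <- function(chrom, summit) {
    vapply(seq_along(summit), function(i) {
      d <- z_mut$values[[chrom[i]]] - z_wt$values[[chrom[i]]] - shift
      b <- as.integer(summit[i] / bs)
      idx <- max(1L, b + 1L - fb):min(length(d), b + 1L + fb)
      mean(d[idx])
    }, numeric(1))
  }
  if (!is.null(target_peaks)) {
    asg <- assign_closest_gene(target_peaks, genes)
    anchor <- data.frame(chrom = target_peaks$chrom,
                         summit = target_peaks$summit,
                         gene_id = asg$gene_id[match(target_peaks$id,
                                                     asg$peak_id)],
                         stringsAsFactors = FALSE)
    anchor <- anchor[!duplicated(anchor$gene_id), ]
  } else {
    o <- order(-abs(regions$mean_delta))
    anchor <- regions[o, ][!duplicated(regions$gene_id[o]),
                           c("chrom", "summit", "gene_id")]
  }
  mark_delta <- window_delta(anchor$chrom, anchor$summit)
  m <- match(anchor$gene_id, expression$gene_id)
  ok <- !is.na(m)
  coupling <- NULL
  if (sum(ok) >= 3 && stats::sd(mark_delta[ok]) > 0 &&
      stats::sd(expression$logfc[m[ok]]) > 0)
    coupling <- correlate_changes(mark_delta[ok], expression$logfc[m[ok]])
  list(regions = regions, pct_elevated = pct, enrichment = enr,
       coupling = coupling)
}
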