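#' @importFrom S4Vectors queryHits subjectHits
NULL

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges0 <- function(df) {
  if (any(df$start >= df$end)) stop("invalid interval: start >= end")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Peak-overlap summary between two peak sets
#'
#' Determines which peaks of `a` overlap at least one peak of `b` by at
#' least `min_overlap_bp` base pairs under 0-based half-open arithmetic (the
#' bedtools convention; 1 bp is the default threshold). Each A peak is
#' counted once however many partners it has.
#'
#' @param a,b Peak data.frames with `chrom`, `start`, `end` (0-based
#'   half-open) and `id` columns.
#' @param min_overlap_bp Minimum overlap length in bp (>= 1).
#' @param genome Optional [genome_spec()]; when supplied, both sets'
#'   chromosomes are validated against it and a mismatch is an error.
#' @return An object of class `overlap_summary`: list with `n_a`, `n_b`,
#'   `n_a_overlapping`, `fraction` (`n_a_overlapping / n_a`), and `pairs`
#'   (data.frame of overlapping `a_id`/`b_id`).
#' @export
find_overlaps <- function(a, b, min_overlap_bp = 1, genome = NULL) {
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  if (!is.null(genome)) {
    check_chroms(a$chrom, genome, "peak set A")
    check_chroms(b$chrom, genome, "peak set B")
  }
  ga <- as_granges0(a)
  gb <- as_granges0(b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap_bp)
  pairs <- data.frame(a_id = a$id[queryHits(hits)],
                      b_id = b$id[subjectHits(hits)],
                      stringsAsFactors = FALSE)
  n_over <- length(unique(queryHits(hits)))
  structure(list(n_a = nrow(a), n_b = nrow(b), n_a_overlapping = n_over,
                 fraction = if (nrow(a) > 0) n_over / nrow(a) else NA_real_,
                 pairs = pairs),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap_summary: %d / %d A peaks (%.1f%%) overlap >=1 of %d B peaks\n",
              x$n_a_overlapping, x$n_a, 100 * x$fraction, x$n_b))
  invisible(x)
}

#' Percentage of A peaks overlapping B
#'
#' The asymmetric overlap percentage `100 * n_a_overlapping / n_a` (the
#' "X% of A peaks overlapped with B peaks" reporting style).
#'
#' @inheritParams find_overlaps
#' @return A percentage in `[0, 100]`.
#' @export
overlap_fraction <- function(a, b, min_overlap_bp = 1) {
  if (nrow(a) == 0) stop("peak set A is empty")
  100 * find_overlaps(a, b, min_overlap_bp)$fraction
}

#' Fisher's exact test for two item lists over a universe
#'
#' Builds the 2x2 contingency table (overlap, A-only, B-only, neither) of
#' two id sets over a stated universe and runs a two-sided Fisher's exact
#' test, reporting the direction of departure from the hypergeometric
#' expectation `|A||B|/N`.
#'
#' @param set_a,set_b Character vectors of item ids (subsets of `universe`).
#' @param universe Character vector of all items under consideration.
#' @param alpha Significance level for calling a direction.
#' @return An object of class `enrichment_result`: list with `table` (2x2
#'   matrix), `n_overlap`, `expected`, `odds_ratio`, `p_value`, `direction`
#'   (`more_than_expected`, `less_than_expected`, or `ns`), and `alpha`.
#' @export
fisher_overlap_test <- function(set_a, set_b, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(universe) < 2) stop("universe must contain at least 2 items")
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop("set_a and set_b must be subsets of the universe")
  n <- length(universe)
  k <- length(intersect(set_a, set_b))
  a_only <- length(set_a) - k
  b_only <- length(set_b) - k
  neither <- n - k - a_only - b_only
  tab <- matrix(c(k, a_only, b_only, neither), nrow = 2,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  ft <- stats::fisher.test(tab)
  expected <- length(set_a) * length(set_b) / n
  direction <- "ns"
  if (ft$p.value <= alpha && k != expected)
    direction <- if (k > expected) "more_than_expected" else "less_than_expected"
  structure(list(table = tab, n_overlap = k, expected = expected,
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                 direction = direction, alpha = alpha),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: overlap %d (expected %.2f), OR %.3g, p = %.3g [%s]\n",
              x$n_overlap, x$expected, x$odds_ratio, x$p_value, x$direction))
  print(x$table)
  invisible(x)
}

# does each [s, e) interval overlap any of the merged sorted intervals?
overlaps_merged <- function(s, e, mstart, mend) {
  if (!length(mstart)) return(rep(FALSE, length(s)))
  j <- findInterval(s, mstart)                    # last mstart <= s (0 if none)
  hit_left <- j >= 1 & ifelse(j >= 1, mend[pmax(j, 1)] > s, FALSE)
  jn <- j + 1L
  hit_right <- jn <= length(mstart) & mstart[pmin(jn, length(mstart))] < e
  hit_left | hit_right
}

#' Permutation null for peak-set overlap
#'
#' Places the A peaks uniformly at random (length-preserving, each on its
#' own chromosome) `n_perm` times and compares the observed number of A
#' peaks overlapping B (1 bp rule) against the permutation distribution.
#' The empirical enrichment p-value is
#' `(1 + #\{perm >= observed\}) / (1 + n_perm)`; a depletion p-value is
#' reported symmetrically.
#'
#' @inheritParams find_overlaps
#' @param genome A [genome_spec()] giving chromosome lengths.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; deterministic given the seed.
#' @return List with `observed`, `expected` (mean permuted overlap count),
#'   `p_enrich`, `p_deplete`, `n_perm`, and the permuted counts `perm`.
#' @export
shuffle_overlap_null <- function(a, b, genome, n_perm = 1000, seed = 1) {
  stopifnot_genome(genome)
  if (n_perm < 100) stop("n_perm must be >= 100")
  check_chroms(a$chrom, genome, "peak set A")
  check_chroms(b$chrom, genome, "peak set B")
  lens <- a$end - a$start
  Lc <- genome$chrom_lengths[a$chrom]
  if (any(lens > Lc)) stop("peak longer than its chromosome")
  # merged B intervals per chromosome for fast any-overlap queries
  gb <- GenomicRanges::reduce(as_granges0(b))
  merged <- split(data.frame(start = GenomicRanges::start(gb) - 1L,
                             end = GenomicRanges::end(gb)),
                  as.character(GenomicRanges::seqnames(gb)))
  count_overlapping <- function(starts) {
    tot <- 0L
    for (ch in names(merged)) {
      sel <- a$chrom == ch
      if (!any(sel)) next
      tot <- tot + sum(overlaps_merged(starts[sel], starts[sel] + lens[sel],
                                       merged[[ch]]$start, merged[[ch]]$end))
    }
    tot
  }
  observed <- find_overlaps(a, b)$n_a_overlapping
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      starts <- floor(stats::runif(nrow(a), 0, Lc - lens + 1))
      count_overlapping(starts)
    }, numeric(1))
  })
  list(observed = observed, expected = mean(perm),
       p_enrich = (1 + sum(perm >= observed)) / (1 + n_perm),
       p_deplete = (1 + sum(perm <= observed)) / (1 + n_perm),
       n_perm = n_perm, perm = perm)
}

#' Assign each peak to its closest gene
#'
#' Distance is measured from the peak summit to the gene interval on the
#' coordinate number line: 0 when the summit lies inside the gene,
#' `start - summit` left of the gene and `summit - end` right of it (the
#' half-open `end` being one past the last base). With `mode = "tss"` the
#' distance is to the gene's strand-aware 5' end instead. Equidistant ties are broken by
#' the lexicographically smaller gene id and counted in the `n_ties`
#' attribute.
#'
#' @param peaks Peak data.frame with `chrom`, `summit`, `id`.
#' @param genes Gene data.frame with `chrom`, `start`, `end`, `id`, `strand`.
#' @param mode `"interval"` (default) or `"tss"`.
#' @return data.frame with `peak_id`, `gene_id`, `distance` (signed bp;
#'   negative when the summit lies left of the gene in genomic coordinates,
#'   0 inside), and `strand` of the assigned gene. Attribute `n_ties` counts
#'   tie-broken assignments.
#' @export
assign_closest_gene <- function(peaks, genes, mode = c("interval", "tss")) {
  mode <- match.arg(mode)
  orphan <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(orphan)) {
    off <- peaks$id[peaks$chrom %in% orphan]
    stop("peak(s) on chromosome(s) with no genes: ",
         paste(utils::head(off, 10), collapse = ", "))
  }
  n_ties <- 0L
  res <- vector("list", nrow(peaks))
  gsplit <- split(genes, genes$chrom)
  for (i in seq_len(nrow(peaks))) {
    g <- gsplit[[peaks$chrom[i]]]
    s <- peaks$summit[i]
    if (mode == "interval") {
      mag <- pmax(0, g$start - s, s - g$end)
      signed <- ifelse(s < g$start, s - g$start,
                       ifelse(s >= g$end, s - g$end, 0))
    } else {
      tss <- ifelse(g$strand == "+", g$start, g$end - 1)
      signed <- s - tss
      mag <- abs(signed)
    }
    best <- which(mag == min(mag))
    if (length(best) > 1) {
      n_ties <- n_ties + 1L
      best <- best[order(g$id[best])]
    }
    j <- best[1]
    res[[i]] <- data.frame(peak_id = peaks$id[i], gene_id = g$id[j],
                           distance = signed[j], strand = g$strand[j],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (n_ties > 0)
    message(n_ties, " closest-gene tie(s) broken by lexicographic gene id")
  attr(out, "n_ties") <- n_ties
  out
}
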