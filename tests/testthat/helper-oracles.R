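# Independent brute-force oracles and small fixture generators.
# Each oracle implements the documented contract by the most direct route
# (nested loops, full enumeration), never by calling the code under test.

# O(n*m) overlap pair enumeration under half-open arithmetic
brute_overlap_pairs <- function(a, b, min_overlap_bp = 1) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap_bp)
        pairs[[length(pairs) + 1L]] <- c(a$id[i], b$id[j])
    }
  }
  if (!length(pairs)) return(data.frame(a_id = character(0), b_id = character(0)))
  m <- do.call(rbind, pairs)
  data.frame(a_id = m[, 1], b_id = m[, 2], stringsAsFactors = FALSE)
}

# exhaustive nearest-gene search; number-line distance, lexicographic ties
brute_closest_gene <- function(peaks, genes) {
  out <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$summit[i]
    best_d <- Inf
    best_id <- NA_character_
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != peaks$chrom[i]) next
      d <- if (s < genes$start[j]) genes$start[j] - s
           else if (s >= genes$end[j]) s - genes$end[j] else 0
      if (d < best_d || (d == best_d && genes$id[j] < best_id)) {
        best_d <- d
        best_id <- genes$id[j]
      }
    }
    out[i] <- best_id
  }
  out
}

# per-bin mean of a per-base vector, partial last bin over actual width
brute_bin_means <- function(x, bin_bp) {
  nb <- ceiling(length(x) / bin_bp)
  vapply(seq_len(nb), function(b) {
    mean(x[((b - 1) * bin_bp + 1):min(b * bin_bp, length(x))])
  }, numeric(1))
}

# per-row oriented window extraction: snap summit to the track grid,
# gather 2*flank of track bins (NA outside), average groups, reverse '-'
brute_extract_row <- function(v, summit, strand, flank_bp, bin_bp, tb) {
  k <- bin_bp / tb
  sbin <- round(summit / tb)
  idx <- (sbin - flank_bp / tb) + seq_len(2 * flank_bp / tb) - 1
  raw <- ifelse(idx >= 0 & idx < length(v), v[pmax(idx, 0) + 1], NA)
  nc <- 2 * flank_bp / bin_bp
  prof <- vapply(seq_len(nc), function(j) {
    chunk <- raw[((j - 1) * k + 1):(j * k)]
    if (all(is.na(chunk))) NA_real_ else mean(chunk, na.rm = TRUE)
  }, numeric(1))
  if (strand == "-") rev(prof) else prof
}

# sliding-window differential scan by direct loops
brute_differential <- function(d, window, thresh, gap, bin_bp) {
  nb <- length(d)
  keep_dir <- list(up = integer(0), down = integer(0))
  for (i in seq_len(nb - window + 1)) {
    m <- mean(d[i:(i + window - 1)])
    if (m >= thresh) keep_dir$up <- c(keep_dir$up, i)
    if (m <= -thresh) keep_dir$down <- c(keep_dir$down, i)
  }
  out <- list()
  for (dir in c("up", "down")) {
    w <- keep_dir[[dir]]
    if (!length(w)) next
    s <- w - 1
    e <- w - 1 + window
    cur_s <- s[1]; cur_e <- e[1]
    for (i in seq_along(s)[-1]) {
      if (s[i] - cur_e <= gap) cur_e <- max(cur_e, e[i])
      else {
        out[[length(out) + 1]] <- data.frame(start = cur_s * bin_bp,
                                             end = cur_e * bin_bp, direction = dir)
        cur_s <- s[i]; cur_e <- e[i]
      }
    }
    out[[length(out) + 1]] <- data.frame(start = cur_s * bin_bp,
                                         end = cur_e * bin_bp, direction = dir)
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0),
                                      direction = character(0)))
  out <- do.call(rbind, out)
  out[order(out$start, out$direction), , drop = FALSE]
}

# two-sided Fisher p by full enumeration with choose(); ties handled with
# the same relative tolerance stats::fisher.test documents (1 + 1e-7)
enum_fisher_p <- function(N, nA, nB, k) {
  kk <- max(0, nA + nB - N):min(nA, nB)
  logp <- lchoose(nB, kk) + lchoose(N - nB, nA - kk) - lchoose(N, nA)
  p <- exp(logp)
  sum(p[p <= p[kk == k] * (1 + 1e-7)])
}

# random peak set on a genome, uniform placement, widths in [wmin, wmax]
random_peaks <- function(n, genome, wmin = 20, wmax = 200, prefix = "p") {
  ci <- sample.int(length(genome$chrom_names), n, replace = TRUE,
                   prob = genome$chrom_lengths)
  w <- sample(wmin:wmax, n, replace = TRUE)
  L <- genome$chrom_lengths[ci]
  start <- floor(runif(n, 0, L - w))
  smt <- start + sample.int(min(w), n, replace = TRUE) - 1
  data.frame(chrom = genome$chrom_names[ci], start = start, end = start + w,
             id = sprintf("%s%04d", prefix, seq_len(n)),
             summit = smt, stringsAsFactors = FALSE)
}

# tiny binned track from a named list of values
make_track <- function(values, bin_bp, kind = "zscore") {
  genome <- genome_spec(names(values), lengths(values) * bin_bp)
  binned_track(values, bin_bp, genome, kind = kind)
}

# one-peak world with a single off-summit spike; exercises orientation
spike_world <- function(strand, spike_offset = 100, spike_value = 5) {
  L <- 20000
  v <- numeric(L / 50)
  summit <- 10000
  bin0 <- (summit + spike_offset) / 50
  v[bin0 + 1] <- spike_value
  track <- make_track(list(c = v), 50)
  peaks <- data.frame(chrom = "c", start = summit - 100, end = summit + 100,
                      id = "p1", summit = summit, stringsAsFactors = FALSE)
  asg <- data.frame(peak_id = "p1", gene_id = "g1", distance = 0,
                    strand = strand, stringsAsFactors = FALSE)
  extract_oriented_matrix(track, peaks, asg, flank_bp = 3000, bin_bp = 50)
}

# small shared simulation for end-to-end tests
sim_world <- function(seed, n_genes = 1000, n_peaks = 150,
                      chrom_lengths = c(1.5e6, 1.5e6), truth = synthetic_truth()) {
  gs <- genome_spec(paste0("chr", seq_along(chrom_lengths)), chrom_lengths)
  genes <- generate_genome(gs, n_genes, seed = seed)
  pair <- generate_genotype_pair(genes, gs, n_peaks, truth = truth, seed = seed)
  list(genome = gs, genes = genes, wt = pair$wt, mut = pair$mut,
       truth = pair$mut$truth)
}
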