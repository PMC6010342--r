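test_that("oriented extraction puts a +100 bp spike in the documented columns", {
  pm_plus <- spike_world("+")
  expect_equal(ncol(pm_plus), 120)
  offsets <- attr(pm_plus, "offsets")
  expect_equal(offsets[63], 100)           # 0-based column 62 covers [100, 150)
  expect_equal(unname(pm_plus[1, 63]), 5)
  expect_equal(sum(pm_plus != 0), 1)
  # minus-strand gene: reversed, 0-based column 57 covers oriented [-150, -100)
  pm_minus <- spike_world("-")
  expect_equal(offsets[58], -150)
  expect_equal(unname(pm_minus[1, 58]), 5)
  expect_equal(sum(pm_minus != 0), 1)
})

test_that("extraction validates geometry and assignments", {
  v <- make_track(list(c = numeric(100)), 50)
  peaks <- data.frame(chrom = "c", start = 0, end = 100, id = "p1",
                      summit = 50, stringsAsFactors = FALSE)
  asg <- data.frame(peak_id = "other", gene_id = "g", distance = 0,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_oriented_matrix(v, peaks, asg), "unassigned")
  asg$peak_id <- "p1"
  expect_error(extract_oriented_matrix(v, peaks, asg, flank_bp = 3010,
                                       bin_bp = 50), "multiple")
  expect_error(extract_oriented_matrix(v, peaks, asg, flank_bp = 3000,
                                       bin_bp = 30), "divide")
})

test_that("extraction matches the per-row brute-force oracle, with edge masking", {
  gs <- genome_spec(c("c1", "c2"), c(20000, 15000))
  withr::with_seed(30, {
    tb <- 25
    vals <- list(c1 = rnorm(20000 / tb), c2 = rnorm(15000 / tb))
    track <- binned_track(vals, tb, gs, "zscore")
    peaks <- random_peaks(40, gs)
    asg <- data.frame(peak_id = peaks$id, gene_id = peaks$id, distance = 0,
                      strand = sample(c("+", "-"), 40, TRUE),
                      stringsAsFactors = FALSE)
    pm <- extract_oriented_matrix(track, peaks, asg, flank_bp = 2000,
                                  bin_bp = 100)
    for (i in seq_len(nrow(peaks))) {
      want <- brute_extract_row(vals[[peaks$chrom[i]]], peaks$summit[i],
                                asg$strand[i], 2000, 100, tb)
      expect_equal(unname(pm[i, ]), want, tolerance = 1e-12)
    }
    # summits near chromosome start must carry masked (NA) leading bins
    edge <- peaks[peaks$summit < 2000, ]
    if (nrow(edge)) expect_true(anyNA(pm[peaks$summit < 2000, ]))
  })
})

test_that("mean_profile averages columns excluding masked bins", {
  m <- structure(rbind(c(1, 2, NA), c(3, 4, 5)),
                 class = c("profile_matrix", "matrix"),
                 offsets = c(-75, -25, 25), flank_bp = 75, bin_bp = 50)
  expect_equal(unname(mean_profile(m)), c(2, 3, 5))
  r <- c(1, -2, 3)
  m2 <- structure(rbind(r, -r), class = c("profile_matrix", "matrix"),
                  offsets = c(-75, -25, 25), flank_bp = 75, bin_bp = 50)
  expect_equal(unname(mean_profile(m2)), c(0, 0, 0))
  expect_error(mean_profile(m[0, , drop = FALSE]), "no rows")
})

test_that("mirror symmetry: reflecting the genome reverses the profile matrix", {
  withr::with_seed(31, {
    L <- 20000; tb <- 50
    v <- rnorm(L / tb)
    track <- make_track(list(c = v), tb)
    track_rev <- make_track(list(c = rev(v)), tb)
    cand <- seq(2000, 18000, by = 10)
    cand <- cand[cand %% 50 != 25]   # avoid round-half ambiguity at reflection
    summits <- sort(sample(cand, 15))
    peaks <- data.frame(chrom = "c", start = summits - 50, end = summits + 50,
                        id = sprintf("p%02d", 1:15), summit = summits,
                        stringsAsFactors = FALSE)
    refl <- peaks; refl$summit <- L - summits
    refl$start <- L - peaks$end; refl$end <- L - peaks$start
    asg <- function(p, s) data.frame(peak_id = p$id, gene_id = p$id,
                                     distance = 0, strand = s,
                                     stringsAsFactors = FALSE)
    pm <- extract_oriented_matrix(track, peaks, asg(peaks, "+"),
                                  flank_bp = 1000, bin_bp = 50)
    pm_refl <- extract_oriented_matrix(track_rev, refl, asg(refl, "+"),
                                       flank_bp = 1000, bin_bp = 50)
    expect_equal(unname(pm_refl), unname(pm[, rev(seq_len(ncol(pm)))]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    # flipping strand on the reflected genome restores the original profile
    pm_back <- extract_oriented_matrix(track_rev, refl, asg(refl, "-"),
                                       flank_bp = 1000, bin_bp = 50)
    expect_equal(unname(mean_profile(pm_back)), unname(mean_profile(pm)),
                 tolerance = 1e-12)
  })
})

fake_matrix <- function(n, bins, gen) {
  m <- matrix(gen(n * bins), n, bins)
  structure(m, class = c("profile_matrix", "matrix"),
            offsets = seq(-bins / 2, bins / 2 - 1) * 50,
            flank_bp = bins / 2 * 50, bin_bp = 50)
}

test_that("bootstrap_ci is deterministic, ordered, and degenerate on identical rows", {
  m <- fake_matrix(50, 8, function(k) rep(seq_len(8), each = 50)[
    order(rep(seq_len(50), 8))])
  m[] <- rep(1:8, each = 50)    # all rows identical per bin
  ci <- bootstrap_ci(m, fraction = 0.2, n_reps = 100, seed = 1)
  expect_equal(ci$upper - ci$lower, rep(0, 8))
  expect_equal(unname(ci$mean), 1:8)
  withr::with_seed(32, m2 <- fake_matrix(200, 6, rnorm))
  ci_a <- bootstrap_ci(m2, seed = 42)
  ci_b <- bootstrap_ci(m2, seed = 42)
  expect_identical(ci_a, ci_b)
  expect_true(all(ci_a$lower <= ci_a$mean & ci_a$mean <= ci_a$upper))
  expect_error(bootstrap_ci(m2, fraction = 0.001), ">= 2")
})

test_that("bootstrap band tightens as the subsample fraction grows", {
  withr::with_seed(33, m <- fake_matrix(400, 5, rnorm))
  widths <- vapply(c(0.1, 0.5, 0.9), function(f) {
    ci <- bootstrap_ci(m, fraction = f, n_reps = 400, seed = 7)
    mean(ci$upper - ci$lower)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("replicate-mean spread matches the without-replacement sampling law", {
  withr::with_seed(34, m <- fake_matrix(800, 5, rnorm))
  ci <- bootstrap_ci(m, fraction = 0.1, n_reps = 1500, seed = 8)
  x <- unclass(m)
  n <- nrow(x); k <- floor(0.1 * n)
  # finite-population SD of a without-replacement subsample mean
  want <- sqrt(apply(x, 2, var) / k * (n - k) / n)
  expect_lt(max(abs(ci$sd_rep / want - 1)), 0.10)
})

test_that("spreading calls come from sustained CI separation", {
  offs <- seq(-3000, 2950, by = 50)
  mk_ci <- function(lo, hi) {
    structure(list(offsets = offs, mean = (lo + hi) / 2, lower = lo,
                   upper = hi, sd_rep = rep(0.1, 120), n_summits = 100,
                   subsample_fraction = 0.1, n_replicates = 1000,
                   alpha = 0.05, bin_bp = 50, flank_bp = 3000),
              class = "profile_ci")
  }
  ref <- mk_ci(rep(0.9, 120), rep(1.1, 120))
  lo <- rep(0.9, 120); hi <- rep(1.1, 120)
  elev <- offs >= 500 | offs + 50 <= -500      # bins fully beyond +/-500
  lo[elev] <- 1.5; hi[elev] <- 1.7
  call <- detect_spreading(ref, mk_ci(lo, hi))
  expect_equal(call$downstream_onset_bp, 500)
  expect_equal(call$upstream_onset_bp, -500)
  # identical bands -> no call
  none <- detect_spreading(ref, ref)
  expect_true(is.na(none$upstream_onset_bp) && is.na(none$downstream_onset_bp))
  # short runs below min_run_bins are ignored
  lo2 <- rep(0.9, 120); hi2 <- rep(1.1, 120)
  lo2[61:62] <- 1.5; hi2[61:62] <- 1.7
  short <- detect_spreading(ref, mk_ci(lo2, hi2), min_run_bins = 3)
  expect_true(is.na(short$downstream_onset_bp))
  # geometry mismatch
  bad <- mk_ci(rep(0.9, 120), rep(1.1, 120)); bad$bin_bp <- 25
  expect_error(detect_spreading(ref, bad), "geometry")
})

test_that("center exclusion masks bins near the summit", {
  offs <- seq(-3000, 2950, by = 50)
  base <- structure(list(offsets = offs, mean = rep(1, 120),
                         lower = rep(0.9, 120), upper = rep(1.1, 120),
                         sd_rep = rep(0.05, 120), n_summits = 10,
                         subsample_fraction = 0.1, n_replicates = 100,
                         alpha = 0.05, bin_bp = 50, flank_bp = 3000),
                    class = "profile_ci")
  alt <- base
  alt$lower <- rep(1.5, 120); alt$upper <- rep(1.7, 120); alt$mean <- rep(1.6, 120)
  with_excl <- detect_spreading(base, alt, exclude_center_bp = 400)
  expect_equal(with_excl$downstream_onset_bp, 400)
  expect_equal(with_excl$upstream_onset_bp, -400)
})
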