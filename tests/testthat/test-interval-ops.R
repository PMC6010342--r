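peakdf <- function(chrom, start, end, id = NULL, summit = NULL) {
  id <- if (is.null(id)) sprintf("p%d", seq_along(start)) else id
  summit <- if (is.null(summit)) floor((start + end) / 2) else summit
  data.frame(chrom = chrom, start = start, end = end, id = id,
             summit = summit, stringsAsFactors = FALSE)
}

test_that("overlap detection honours the 1 bp half-open rule", {
  a <- peakdf("c", 0, 100)
  expect_equal(find_overlaps(a, peakdf("c", 99, 150))$n_a_overlapping, 1)
  expect_equal(find_overlaps(a, peakdf("c", 100, 150))$n_a_overlapping, 0)
  expect_equal(find_overlaps(a, peakdf("c", 90, 150),
                             min_overlap_bp = 11)$n_a_overlapping, 0)
  expect_equal(find_overlaps(a, peakdf("c", 90, 150),
                             min_overlap_bp = 10)$n_a_overlapping, 1)
  gs <- genome_spec("c", 1000)
  expect_error(find_overlaps(peakdf("other", 0, 10), a, genome = gs), "absent")
})

test_that("overlap pairs match brute force and are symmetric as a relation", {
  gs <- genome_spec(c("c1", "c2"), c(10000, 8000))
  withr::with_seed(10, {
    for (i in 1:10) {
      a <- random_peaks(60, gs, prefix = "a")
      b <- random_peaks(60, gs, prefix = "b")
      got <- find_overlaps(a, b)$pairs
      want <- brute_overlap_pairs(a, b)
      key <- function(d) sort(paste(d[[1]], d[[2]]))
      expect_identical(key(got), key(want))
      # symmetry: pair set of (B, A) is the transpose
      rev_pairs <- find_overlaps(b, a)$pairs
      expect_identical(sort(paste(rev_pairs$b_id, rev_pairs$a_id)),
                       key(got))
    }
  })
})

test_that("overlap_fraction is an asymmetric percentage", {
  a <- peakdf("c", c(0, 200, 400, 600), c(100, 300, 500, 700))
  b <- peakdf("c", c(50, 250, 450), c(60, 260, 460), id = c("x", "y", "z"))
  expect_equal(overlap_fraction(a, b), 75.0)
  expect_equal(overlap_fraction(b, a), 100.0)
  far <- peakdf("c", 5000, 5100)
  expect_equal(overlap_fraction(a, far), 0.0)
  expect_error(overlap_fraction(a[0, ], b), "empty")
})

test_that("fisher_overlap_test matches hypergeometric enumeration and reports direction", {
  u <- sprintf("g%03d", 1:10)
  r <- fisher_overlap_test(u[1:5], u[1:5], u)
  # all-overlap table: one-sided enrichment mass is 1/choose(10,5)
  expect_equal(enum_fisher_p(10, 5, 5, 5), r$p_value, tolerance = 1e-12)
  expect_equal(1 / choose(10, 5), 1 / 252)
  expect_equal(r$direction, "more_than_expected")
  # observed == expected -> ns, odds ratio 1
  u4 <- c("a", "b", "c", "d")
  r2 <- fisher_overlap_test(c("a", "b"), c("a", "c"), u4)
  expect_equal(r2$direction, "ns")
  expect_equal(r2$p_value, 1)
  # strong depletion
  u1k <- sprintf("g%04d", 1:1000)
  r3 <- fisher_overlap_test(u1k[1:100], u1k[101:200], u1k)
  expect_equal(r3$direction, "less_than_expected")
  expect_lt(r3$p_value, 0.01)
  expect_equal(r3$p_value, enum_fisher_p(1000, 100, 100, 0), tolerance = 1e-12)
  expect_error(fisher_overlap_test(c("zz"), u[1:2], u), "subsets")
  expect_true(all(r$table >= 0) && sum(r$table) == 10)
})

test_that("shuffle null saturates on a tiling and flags depletion", {
  gs <- genome_spec("c", 10000)
  a <- peakdf("c", seq(0, 900, 100), seq(10, 910, 100))
  tiling <- peakdf("c", 0, 10000)
  r <- shuffle_overlap_null(a, tiling, gs, n_perm = 100, seed = 1)
  expect_equal(r$observed, nrow(a))
  expect_equal(r$expected, nrow(a))
  # every permutation ties the saturated observation; 1/(1+n_perm) is the
  # smallest p the procedure can ever report
  expect_equal(r$p_enrich, 1)
  expect_true(all(r$perm == nrow(a)))
  # depleted arrangement: A kept outside B's half of the chromosome
  b_half <- peakdf("c", 0, 5000)
  a_out <- peakdf("c", seq(5000, 9500, 500), seq(5010, 9510, 500))
  r2 <- shuffle_overlap_null(a_out, b_half, gs, n_perm = 200, seed = 2)
  expect_equal(r2$observed, 0)
  expect_gt(r2$expected, 3)
  expect_lt(r2$p_deplete, 0.05)
  expect_gt(r2$p_enrich, 0.95)
  # determinism
  r3 <- shuffle_overlap_null(a_out, b_half, gs, n_perm = 200, seed = 2)
  expect_identical(r2$perm, r3$perm)
  long <- peakdf("c", 0, 10001)
  expect_error(shuffle_overlap_null(long, b_half, gs, seed = 1), "longer")
  expect_error(shuffle_overlap_null(a, b_half, gs, n_perm = 10), "n_perm")
})

test_that("shuffle null p-values are calibrated under independence", {
  # p_enrich lives on a discrete lattice (overlap counts are integers), so
  # uniformity is checked as tail calibration rather than by a KS test
  gs <- genome_spec("c", 50000)
  withr::with_seed(77, {
    b <- random_peaks(40, gs, wmin = 100, wmax = 400, prefix = "b")
    ps <- vapply(1:200, function(i) {
      a <- random_peaks(40, gs, wmin = 100, wmax = 400, prefix = "a")
      shuffle_overlap_null(a, b, gs, n_perm = 199, seed = 1000 + i)$p_enrich
    }, numeric(1))
  })
  # valid (never anti-conservative beyond Monte-Carlo noise) and not
  # grossly conservative at the tails used in practice
  expect_lte(mean(ps <= 0.05), 0.10)
  expect_gte(mean(ps <= 0.25), 0.10)
  expect_gte(mean(ps <= 0.60), 0.40)
})

test_that("closest-gene assignment uses number-line distance with lexicographic ties", {
  genes <- data.frame(chrom = "c", start = c(1000, 0), end = c(2000, 100),
                      id = c("X", "Y"), score = 0, strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  asg <- assign_closest_gene(peakdf("c", 400, 600, id = "p1", summit = 500), genes)
  expect_equal(asg$gene_id, "Y")        # 400 to Y vs 500 to X
  expect_equal(asg$distance, 400)
  expect_equal(asg$strand, "-")
  # summit inside a gene -> distance 0
  asg0 <- assign_closest_gene(peakdf("c", 1400, 1600, id = "p2", summit = 1500),
                              genes)
  expect_equal(asg0$gene_id, "X")
  expect_equal(asg0$distance, 0)
  # equidistant tie broken by smaller gene id, and counted
  tie_genes <- data.frame(chrom = "c", start = c(0, 200), end = c(100, 300),
                          id = c("B", "A"), score = 0, strand = c("+", "+"),
                          stringsAsFactors = FALSE)
  expect_message(
    tie <- assign_closest_gene(peakdf("c", 140, 160, id = "p", summit = 150),
                               tie_genes),
    "tie")
  expect_equal(tie$gene_id, "A")
  expect_equal(attr(tie, "n_ties"), 1L)
  expect_error(assign_closest_gene(peakdf("chrZ", 0, 10), genes), "no genes")
})

test_that("closest-gene assignment matches exhaustive search and is translation-invariant", {
  gs <- genome_spec(c("c1", "c2"), c(50000, 30000))
  withr::with_seed(20, {
    genes <- generate_genome(gs, 200, min_gene_len = 50, max_gene_len = 300,
                             seed = 21)
    peaks <- random_peaks(500, gs)
    got <- assign_closest_gene(peaks, genes)
    expect_identical(got$gene_id, brute_closest_gene(peaks, genes))
    shift <- function(d, c) { d$start <- d$start + c; d$end <- d$end + c; d }
    peaks2 <- peaks; peaks2$summit <- peaks2$summit + 1000
    got2 <- assign_closest_gene(shift(peaks2, 1000), shift(genes, 1000))
    expect_identical(got2$gene_id, got$gene_id)
    expect_identical(got2$distance, got$distance)
  })
})

test_that("tss mode measures to the strand-aware 5' end", {
  genes <- data.frame(chrom = "c", start = 1000, end = 2000, id = "X",
                      score = 0, strand = "-", stringsAsFactors = FALSE)
  asg <- assign_closest_gene(peakdf("c", 1400, 1600, id = "p", summit = 1500),
                             genes, mode = "tss")
  expect_equal(asg$distance, 1500 - 1999)
})
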