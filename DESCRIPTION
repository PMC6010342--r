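Package: chromspread
Title: Summit-Centered ChIP-Seq Metaprofiles and Histone-Mark Spreading
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genotype-dependent broadening
    ("spreading") of histone-mark domains around chromatin-factor binding
    sites. Provides z-score normalization of binned ChIP-seq coverage
    (standardized log2 ratios of ChIP over input or H3 control), peak
    overlap statistics with Fisher and permutation tests, strand-aware
    closest-gene assignment, summit-centered gene-oriented metagene
    profiles with subsample-bootstrap confidence intervals, detection of
    mark spreading as sustained non-overlap of genotype confidence
    envelopes, a simplified sliding-window differential-signal caller,
    and mark-change versus expression-change integration. A synthetic
    data generator with known injected effects (summit offsets, flank
    spreading, expression coupling) provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
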