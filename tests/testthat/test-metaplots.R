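loci2 <- tibble::tibble(chrom = "chr1", start = c(1000L, 5000L),
                        end = c(1200L, 5200L))

test_that("methylation profiles average tiles and honour the missing-tile rule", {
  tiles <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 5000L), end = c(1100L, 5100L),
    context = "CHH", n_sites = 5L, count_meth = 1L, count_total = 2L,
    percent = c(80, 20))
  pr <- methylation_profile(loci2, tiles, flank = 200L, context = "CHH")
  expect_s3_class(pr, "meta_profile")
  expect_equal(pr$value[pr$offset == 0], 50)
  expect_equal(pr$n_contrib[pr$offset == 0], 2L)
  # a locus whose tile is missing at an offset drops out of the mean there
  pr_miss <- methylation_profile(loci2, tiles[1, ], flank = 200L, context = "CHH")
  expect_equal(pr_miss$value[pr_miss$offset == 0], 80)
  expect_equal(pr_miss$n_contrib[pr_miss$offset == 0], 1L)
  # offsets with no tile anywhere are NA with zero contributors
  expect_true(all(is.na(pr$value[pr$offset != 0])))
  expect_true(all(pr$n_contrib[pr$offset != 0] == 0L))
})

test_that("a constant tile track yields a flat profile at that constant", {
  grid <- expand.grid(chrom = "chr1", start = seq(0L, 9900L, by = 100L))
  tiles <- tibble::tibble(chrom = grid$chrom, start = grid$start,
                          end = grid$start + 100L, context = "CG",
                          n_sites = 1L, count_meth = 1L, count_total = 4L,
                          percent = 25)
  pr <- methylation_profile(loci2, tiles, flank = 500L, context = "CG")
  expect_true(all(pr$value == 25))
  expect_true(all(pr$n_contrib == 2L))
})

test_that("the coverage-plot worked example holds: 80 of 100 loci give 80%", {
  set.seed(41)
  starts <- sort(sample.int(1e6, 100)) + 2000L
  loci <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 200L)
  genes <- make_features(loci$start[1:80] - 50L, loci$start[1:80] + 120L,
                         feature_kind = "gene")
  pr <- presence_profile(loci, genes, flank = 100L, kind = "gene")
  expect_equal(pr$value[pr$offset == 0], 80)
  expect_equal(pr$n_contrib[pr$offset == 0], 100L)
})

test_that("presence profiles hit the trivial extremes", {
  none <- presence_profile(loci2, make_features(integer(0), integer(0)),
                           flank = 100L, kind = "gene")
  expect_true(all(none$value == 0))
  blanket <- make_features(0L, 10000L, feature_kind = "TE", subtype = "Gypsy")
  all_cov <- presence_profile(loci2, blanket, flank = 100L, kind = "TE")
  expect_true(all(all_cov$value == 100))
})

test_that("presence profiles equal the per-locus per-nucleotide scan", {
  set.seed(42)
  starts <- sample(500:20000, 30)
  loci <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 150L)
  feats <- make_features(sample(0:20000, 40), feature_kind = "gene",
                         start = sort(sample(0:20000, 40)))
  feats$end <- feats$start + sample(100:2000, 40, replace = TRUE)
  pr <- presence_profile(loci, feats, flank = 300L, kind = "gene")
  want <- brute_force_presence(loci, feats, flank = 300L)
  expect_equal(pr$value, want$value)
})

test_that("profiles are equivariant under a genome-wide shift", {
  set.seed(43)
  starts <- sample(2000:20000, 20)
  loci <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 200L)
  fs <- sort(sample(0:20000, 25))
  feats <- make_features(fs, fs + 500L, feature_kind = "gene")
  shift <- 777L
  pr0 <- presence_profile(loci, feats, flank = 200L, kind = "gene")
  pr1 <- presence_profile(
    dplyr::mutate(loci, start = start + shift, end = end + shift),
    dplyr::mutate(feats, start = start + shift, end = end + shift),
    flank = 200L, kind = "gene")
  expect_equal(pr0$value, pr1$value)
})

test_that("GC profiles read composition directly off the sequence", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("A", 1000), strrep("G", 500), strrep("T", 1000))))
  loci <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L)
  pr <- gc_profile(loci, genome, flank = 500L, window = 100L)
  expect_equal(pr$value[pr$offset == 0], 100)        # all-GC window
  expect_equal(pr$value[pr$offset == -500], 0)       # all-AT window
  expect_equal(pr$value[pr$offset == 400], 100)      # last all-G window
  expect_equal(pr$value[pr$offset == 500], 0)        # back into the T run
  # windows beyond the chromosome are skipped with n_contrib decremented
  edge <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L)
  pr_edge <- gc_profile(edge, genome, flank = 500L, window = 100L)
  expect_equal(pr_edge$n_contrib[pr_edge$offset == -500], 0L)
  expect_true(is.na(pr_edge$value[pr_edge$offset == -500]))
})

test_that("N bases are excluded from the GC denominator", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("N", 50), strrep("G", 50), strrep("A", 200))))
  loci <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  pr <- gc_profile(loci, genome, flank = 100L, window = 100L)
  expect_equal(pr$value[pr$offset == 0], 100)  # 50 G over 50 non-N bases
})
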