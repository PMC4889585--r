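test_that("low-RPM stacks are removed per (position, strand, length) stack", {
  one <- make_reads(100)
  expect_equal(nrow(filter_low_rpm(one, total_aligned = 1e6)), 0L)  # 1 RPM < 2
  three <- make_reads(rep(100, 3))
  expect_equal(nrow(filter_low_rpm(three, total_aligned = 1e6)), 3L)  # 3 RPM
  mixed <- dplyr::bind_rows(make_reads(rep(100, 3)), make_reads(500))
  kept <- filter_low_rpm(mixed, total_aligned = 1e6)
  expect_equal(sort(unique(kept$start)), 100L)
  expect_equal(nrow(filter_low_rpm(mixed, total_aligned = 1e6, min_rpm = 0)),
               nrow(mixed))  # threshold 0 is the identity
  # stacks are distinguished by length and strand, not only position
  stacked <- dplyr::bind_rows(make_reads(rep(100, 2), length = 21L),
                              make_reads(100, length = 24L))
  expect_equal(filter_low_rpm(stacked, total_aligned = 1e6)$length, c(21L, 21L))
})

test_that("gap-based merging produces maximal clusters with the stated boundary", {
  reads <- make_reads(c(100, 121, 142, 400, 421))
  cl <- call_clusters(reads)
  expect_equal(cl$start, c(100L, 400L))
  expect_equal(cl$end, c(163L, 442L))  # gap 237 > 100 splits
  single <- call_clusters(make_reads(999))
  expect_equal(c(single$start, single$end), c(999L, 1020L))
  # gap of exactly max_gap merges
  boundary <- call_clusters(make_reads(c(0, 121)))  # gap = 121 - 21 = 100
  expect_equal(nrow(boundary), 1L)
  beyond <- call_clusters(make_reads(c(0, 122)))
  expect_equal(nrow(beyond), 2L)
  # strand is ignored for merging
  two_str <- call_clusters(make_reads(c(0, 50), strand = c("+", "-")))
  expect_equal(nrow(two_str), 1L)
})

test_that("cluster calling matches a brute-force pairwise-merge oracle", {
  set.seed(31)
  for (rep in 1:40) {
    n <- sample(2:120, 1)
    reads <- make_reads(sample.int(3000, n, replace = TRUE),
                        length = sample(c(21L, 24L), n, replace = TRUE),
                        chrom = sample(c("chr1", "chr2"), n, replace = TRUE))
    max_gap <- sample(c(0L, 10L, 100L), 1)
    got <- call_clusters(reads, max_gap = max_gap)
    want <- brute_force_clusters(reads, max_gap = max_gap)
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # idempotence: clusters re-clustered (as pseudo-reads) are unchanged
    pseudo <- tibble::tibble(chrom = got$chrom, start = got$start, end = got$end,
                             strand = "+", length = 21L)
    again <- call_clusters(pseudo, max_gap = max_gap)
    expect_equal(again$start, got$start)
    expect_equal(again$end, got$end)
  }
})

test_that("size classes follow plurality with ties toward the smaller length", {
  expect_equal(assign_size_class(rep(c(21L, 22L, 24L), c(10, 2, 3))), "21")
  expect_equal(assign_size_class(rep(c(21L, 24L), c(5, 5))), "21")
  expect_equal(assign_size_class(rep(c(19L, 21L), c(7, 3))), "other")
  expect_error(assign_size_class(integer(0)), "empty")
})

test_that("effective phase positions implement the 2-nt overhang duplex geometry", {
  p <- 1000L
  plus <- make_reads(p, length = 21L, strand = "+")
  expect_equal(effective_phase_position(plus), p)
  # the duplex partner of [p, p+21) occupies [p-2, p+19): same residue mod 21
  partner <- make_reads(p - 2L, length = 21L, strand = "-")
  expect_equal(effective_phase_position(partner), p + 21L)
  expect_equal(effective_phase_position(partner) %% 21L, p %% 21L)
  minus0 <- make_reads(0L, length = 21L, strand = "-")
  expect_equal(effective_phase_position(minus0), 23L)
  un <- make_reads(10L, strand = "*")
  expect_error(effective_phase_position(un), "strand")
})

test_that("the phase score equals exhaustive hypergeometric tail summation", {
  # perfect register: 10 occupied positions, all one residue class, W = 210
  res <- phase_pvalue(1000L + 21L * (0:9), 1000L, 210L, 21L)
  expect_equal(res$k, 10L)
  expect_equal(res$n, 10L)
  expect_equal(res$p_value, 21 * enum_hyper_tail(10, 210, 10, 10), tolerance = 1e-12)
  expect_lt(res$p_value, 1e-9)
  # mixed case cross-checked against the enumeration oracle
  occ <- c(1000L + 21L * (0:6), 1003L, 1010L, 1017L)
  res2 <- phase_pvalue(occ, 1000L, 210L, 21L)
  expect_equal(res2$k, 7L)
  expect_equal(res2$n, 10L)
  expect_equal(res2$p_value, min(1, 21 * enum_hyper_tail(7, 210, 10, 10)),
               tolerance = 1e-12)
  # a single occupied position carries no phasing evidence
  res3 <- phase_pvalue(1000L, 1000L, 210L, 21L)
  expect_equal(res3$p_value, 1)
})

test_that("the phase score decreases as in-register occupancy grows", {
  p_at <- function(k) {
    occ <- c(1000L + 21L * seq_len(k) - 21L,          # k in-register
             1001L + seq_len(10 - k))                 # rest off-register
    phase_pvalue(occ, 1000L, 210L, 21L)$p_value
  }
  ps <- vapply(3:10, p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("null occupied positions are essentially never called phased", {
  set.seed(99)
  ps <- replicate(1000, {
    occ <- sample.int(210L, 10L) - 1L
    phase_pvalue(occ, 0L, 210L, 21L)$p_value
  })
  expect_equal(sum(ps <= 1e-9), 0L)
  # tail no heavier than uniform at moderate alpha (Bonferroni is conservative)
  expect_lte(mean(ps <= 0.05), 0.06)
})

test_that("cluster phasing classifies phased stacks and skips sparse registers", {
  # a clean phased locus: 12 duplex positions at 21-nt spacing, both strands
  eff <- 5000L + 21L * (0:11)
  reads <- dplyr::bind_rows(
    make_reads(eff[1:6], length = 21L, strand = "+"),
    make_reads(eff[7:12] - 23L, length = 21L, strand = "-"))
  cl <- cluster_phasing(call_clusters(reads), reads)
  expect_equal(cl$register, 21L)
  expect_equal(cl$phase_k, 12L)
  expect_true(cl$is_phasi)
  # fewer than min_reads reads of the register length: no test at all
  sparse <- make_reads(c(0, 21, 42, 63), length = 21L)
  cl2 <- cluster_phasing(call_clusters(sparse), sparse)
  expect_true(is.na(cl2$p_value))
  expect_false(cl2$is_phasi)
})

test_that("known-miRNA flagging requires a true 1-nt overlap", {
  cl <- call_clusters(make_reads(seq(100, 179, by = 20), length = 21L))
  expect_equal(c(cl$start, cl$end), c(100L, 181L))
  mir_in <- make_features(150L, 170L, feature_kind = "miRNA")
  expect_true(flag_known_mirna(cl, mir_in)$known_mirna)
  mir_adj <- make_features(181L, 220L, feature_kind = "miRNA")  # adjacent, half-open
  expect_false(flag_known_mirna(cl, mir_adj)$known_mirna)
  none <- make_features(integer(0), integer(0), feature_kind = "miRNA")
  expect_false(flag_known_mirna(cl, none)$known_mirna)
})

test_that("locus-set comparison counts private loci, pairs and base-pair Jaccard", {
  a <- tibble::tibble(chrom = "chr1", start = c(0L, 500L), end = c(100L, 600L))
  ident <- compare_locus_sets(a, a)
  expect_equal(unlist(ident), c(a_only = 0, b_only = 0, n_both = 2, jaccard_bp = 1))
  b_disj <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L)
  disj <- compare_locus_sets(a, b_disj)
  expect_equal(unlist(disj), c(a_only = 2, b_only = 1, n_both = 0, jaccard_bp = 0))
  part <- compare_locus_sets(
    tibble::tibble(chrom = "chr1", start = 0L, end = 100L),
    tibble::tibble(chrom = "chr1", start = 50L, end = 150L))
  expect_equal(part$n_both, 1L)
  expect_equal(part$jaccard_bp, 1 / 3)
  bad <- tibble::tibble(chrom = "chr1", start = c(0L, 50L), end = c(100L, 150L))
  expect_error(compare_locus_sets(bad, a), "overlapping")
})

test_that("tidy and glance summarise a cluster set", {
  reads <- dplyr::bind_rows(make_reads(c(100, 121, 142), length = 21L),
                            make_reads(c(5000, 5020), length = 24L))
  cl <- cluster_phasing(call_clusters(reads), reads)
  g <- glance(cl)
  expect_equal(g$n_clusters, 2L)
  expect_equal(g$n_class_21, 1L)
  expect_equal(g$n_class_24, 1L)
  td <- tidy(cl)
  expect_false(inherits(td, "srna_clusters"))
  expect_equal(nrow(td), 2L)
})
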