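# A small configuration keeps generator tests fast; the full-size default
# fixture is exercised by the acceptance suite.
small_cfg <- function(...) {
  args <- list(seed = 13, n_chrom = 1L, chrom_length = 2e5L,
               n_phasi_loci = c("21" = 6L, "24" = 6L),
               background_te_reads = 5e3, degradation_reads = 1e3,
               n_te = 20L, n_genes = 15L, n_mirna = 5L, coverage_mean = 5)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("configurations validate fractions and locus capacity", {
  expect_error(sim_config(base_gc = 1.2), "fractions")
  expect_error(sim_config(phase_fidelity = -0.1), "fractions")
  expect_error(sim_config(meth_base = c(CG = 0.8, CHG = 0.6, CHH = 0.95),
                          chh_delta = 0.10), "exceed")
  over <- sim_config(chrom_length = 5e4L, n_chrom = 1L)
  expect_error(simulate_genome(over), "capacity")
})

test_that("identical config and seed give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(small_cfg(), d1)
  s2 <- simulate_dataset(small_cfg(), d2)
  for (f in c("genome.fa", "annotations.gff3", "cytosines_meiocytes.cx.tsv",
              "truth.tsv", "reads_meiocytes.bed", "reads_anthers.bed",
              "reads_seedlings.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("ground-truth loci never overlap and annotations mirror the truth", {
  gt <- simulate_genome(small_cfg())
  expect_silent(phasir:::check_nonoverlapping(gt$truth))
  feats <- phasir:::truth_features(gt$truth)
  expect_setequal(unique(feats$feature_kind), c("TE", "gene", "miRNA"))
  expect_true(all(nzchar(feats$subtype[feats$feature_kind == "TE"])))
  expect_true(all(is.na(feats$has_introns[feats$feature_kind != "gene"])))
})

test_that("a flat GC design realises the base composition", {
  cfg <- small_cfg(gc_valley = c(halfwidth = 1000, depth = 0),
                   gc_peak = c(halfwidth = 150, height = 0))
  gt <- simulate_genome(cfg)
  win <- Biostrings::subseq(gt$genome[["chr1"]], 1, 1e4)
  gc <- sum(Biostrings::letterFrequency(win, c("G", "C"))) / 1e4
  se <- sqrt(cfg$base_gc * (1 - cfg$base_gc) / 1e4)
  expect_lt(abs(gc - cfg$base_gc), 3 * se)
})

test_that("an all-GC genome contains only G and C", {
  gt <- simulate_genome(small_cfg(base_gc = 1,
                                  gc_valley = c(halfwidth = 1000, depth = 0),
                                  gc_peak = c(halfwidth = 150, height = 0)))
  freq <- Biostrings::letterFrequency(gt$genome[["chr1"]], c("A", "T"))
  expect_equal(sum(freq), 0)
})

test_that("the GC peak-in-valley signature is injected at phased loci", {
  cfg <- small_cfg(n_phasi_loci = c("21" = 30L, "24" = 30L),
                   chrom_length = 1e6L)
  gt <- simulate_genome(cfg)
  loci <- gt$truth[gt$truth$kind == "phasi", ]
  mids <- (loci$start + loci$end) %/% 2L
  peak_bases <- unlist(lapply(mids, function(m) (m - 75):(m + 74))) + 1L
  valley_bases <- unlist(lapply(mids, function(m) c((m - 700):(m - 400),
                                                    (m + 400):(m + 700)))) + 1L
  s <- gt$genome[["chr1"]]
  gc_at <- function(idx) {
    b <- strsplit(as.character(s), "")[[1]][idx]
    mean(b %in% c("G", "C"))
  }
  contrast <- gc_at(peak_bases) - gc_at(valley_bases)
  se <- sqrt(0.25 / length(peak_bases) + 0.25 / length(valley_bases))
  expect_lt(abs(contrast - cfg$gc_peak[["height"]]), 3 * se)
})

test_that("read phasing fidelity is realised as the in-register fraction", {
  cfg <- small_cfg(phase_fidelity = 0.5, reads_per_locus = 100,
                   background_te_reads = 0, degradation_reads = 0,
                   reads_per_mirna = 0)
  gt <- simulate_genome(cfg)
  reads <- simulate_reads(cfg, gt$truth)
  loci <- gt$truth[gt$truth$kind == "phasi", ]
  eff <- effective_phase_position(reads)
  in_reg <- vapply(seq_len(nrow(reads)), function(i) {
    hit <- which(loci$start - 30L <= reads$start[i] & reads$end[i] <= loci$end + 30L)
    if (length(hit) == 0) return(NA)
    L <- loci$register[hit[1]]
    reads$length[i] == L && (eff[i] - loci$start[hit[1]]) %% L == 0
  }, logical(1))
  frac <- mean(in_reg, na.rm = TRUE)
  # off-register draws can land in register by chance (~1/L)
  expected <- 0.5 + 0.5 / 21
  se <- sqrt(expected * (1 - expected) / sum(!is.na(in_reg)))
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("perfect-fidelity plus-strand reads all start in register", {
  cfg <- small_cfg(phase_fidelity = 1, reads_per_locus = 40,
                   background_te_reads = 0, degradation_reads = 0,
                   reads_per_mirna = 0)
  gt <- simulate_genome(cfg)
  reads <- simulate_reads(cfg, gt$truth)
  plus <- reads[reads$strand == "+", ]
  loci <- gt$truth[gt$truth$kind == "phasi", ]
  ok <- vapply(seq_len(nrow(plus)), function(i) {
    hit <- which(loci$chrom == plus$chrom[i] &
                   loci$start <= plus$start[i] & plus$end[i] <= loci$end)
    length(hit) == 1 &&
      (plus$start[i] - loci$start[hit]) %% loci$register[hit] == 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("zero locus reads leave only background populations", {
  cfg <- small_cfg(reads_per_locus = 0, reads_per_mirna = 0)
  gt <- simulate_genome(cfg)
  reads <- simulate_reads(cfg, gt$truth)
  expect_equal(nrow(reads), as.integer(cfg$background_te_reads + cfg$degradation_reads))
  loci <- gt$truth[gt$truth$kind == "phasi", ]
  cnt <- locus_counts(reads, loci)
  # phased loci sit in wide exclusion margins: only stray degradation lands there
  expect_lt(sum(cnt$meiocytes), 20)
})

test_that("methylome depth and null CHH design behave as configured", {
  cfg0 <- small_cfg(coverage_mean = 0)
  gt <- simulate_genome(cfg0)
  meth0 <- simulate_methylome(cfg0, gt$truth, gt$genome)
  expect_true(all(meth0$count_total == 0L))
  cfg_null <- small_cfg(chh_delta = 0)
  gt <- simulate_genome(cfg_null)  # truth carries the per-locus null delta
  meth <- simulate_methylome(cfg_null, gt$truth, gt$genome)
  chh <- meth[meth$context == "CHH" & meth$count_total > 0, ]
  inside <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(chh$chrom, IRanges::IRanges(chh$pos + 1L, chh$pos + 1L)),
    phasir:::as_gr0(gt$truth[gt$truth$kind == "phasi", ])) > 0
  lev_in <- sum(chh$count_meth[inside]) / sum(chh$count_total[inside])
  lev_out <- sum(chh$count_meth[!inside]) / sum(chh$count_total[!inside])
  se <- sqrt(lev_out * (1 - lev_out) * (1 / sum(chh$count_total[inside]) +
                                          1 / sum(chh$count_total[!inside])))
  expect_lt(abs(lev_in - lev_out), 3 * se)
})

test_that("simulated methylome contexts match the genome sequence", {
  cfg <- small_cfg()
  gt <- simulate_genome(cfg)
  meth <- simulate_methylome(cfg, gt$truth, gt$genome)
  idx <- sample(nrow(meth), 200)
  expect_equal(meth$context[idx],
               assign_context(gt$genome, meth$chrom[idx], meth$pos[idx],
                              meth$strand[idx]))
})
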