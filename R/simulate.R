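#' Configuration for the synthetic small-RNA / methylome fixture
#'
#' Bundles every tunable of the generator with validated defaults. The
#' defaults describe a miniature two-chromosome genome carrying phased
#' 21- and 24-nt siRNA loci in intergenic space, a 24-nt read background on
#' transposable elements, degradation noise across the full 15-36 nt size
#' range, a bisulfite methylome with CHH hypermethylation confined to the
#' phased loci, and a GC "peak-in-valley" sequence signature centred on
#' them.
#'
#' @param seed Integer seed; every generator stage derives its stream from
#'   it, so identical configs give byte-identical outputs.
#' @param n_chrom,chrom_length Genome shape (default 2 x 2 Mb).
#' @param base_gc Genome-wide GC probability per base.
#' @param n_phasi_loci Named counts of phased loci per register
#'   (`c("21" = 60, "24" = 60)`).
#' @param locus_length_range Phased-locus lengths are drawn uniformly from
#'   this range (default 150-236 nt, the length scale of reported clusters).
#' @param phase_fidelity Fraction of locus reads whose effective position is
#'   in-register; the rest land uniformly in the locus.
#' @param reads_per_locus Mean reads per phased locus (Poisson).
#' @param background_te_reads Total 24-nt reads scattered over TEs.
#' @param degradation_reads Total random-length reads scattered genome-wide.
#' @param reads_per_mirna Reads stacked at each miRNA locus (single
#'   position, as a mature miRNA presents).
#' @param meth_base Baseline methylation fraction per context
#'   (named: CG, CHG, CHH).
#' @param chh_delta Additive CHH methylation inside phased loci.
#' @param coverage_mean Mean bisulfite depth per cytosine (Poisson).
#' @param gc_valley,gc_peak Named `c(halfwidth, depth)` / `c(halfwidth,
#'   height)`: around each phased-locus midpoint the per-base GC probability
#'   drops by `depth` within the valley half-width, then rises by `height`
#'   within the peak half-width.
#' @param n_te,te_length_range,te_superfamilies TE annotation shape.
#' @param n_genes,gene_length_range,intron_fraction Gene annotation shape.
#' @param n_mirna,mirna_length_range miRNA annotation shape.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 2L, chrom_length = 2e6L, base_gc = 0.45,
                       n_phasi_loci = c("21" = 60L, "24" = 60L),
                       locus_length_range = c(150L, 236L),
                       phase_fidelity = 0.9,
                       reads_per_locus = 50,
                       background_te_reads = 4e5,
                       degradation_reads = 2e4,
                       reads_per_mirna = 30,
                       meth_base = c(CG = 0.80, CHG = 0.60, CHH = 0.05),
                       chh_delta = 0.10,
                       coverage_mean = 10,
                       gc_valley = c(halfwidth = 1000, depth = 0.05),
                       gc_peak = c(halfwidth = 150, height = 0.08),
                       n_te = 300L, te_length_range = c(1000L, 4000L),
                       te_superfamilies = c("Gypsy", "Copia", "hAT", "CACTA", "Mutator"),
                       n_genes = 200L, gene_length_range = c(1500L, 3000L),
                       intron_fraction = 0.5,
                       n_mirna = 30L, mirna_length_range = c(120L, 200L)) {
  cfg <- as.list(environment())
  fracs <- c(base_gc = base_gc, phase_fidelity = phase_fidelity,
             intron_fraction = intron_fraction, meth_base,
             valley_depth = unname(gc_valley["depth"]),
             peak_height = unname(gc_peak["height"]))
  if (any(fracs < 0 | fracs > 1)) {
    rlang::abort("all fractions in the configuration must lie in [0, 1]")
  }
  if (meth_base[["CHH"]] + chh_delta > 1) {
    rlang::abort("meth_base['CHH'] + chh_delta must not exceed 1")
  }
  if (is.null(names(n_phasi_loci)) || !all(names(n_phasi_loci) %in% c("21", "24"))) {
    rlang::abort("`n_phasi_loci` must be named by register ('21', '24')")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Uniform non-overlapping placement: k intervals of given (margin-inflated)
# lengths dropped into [0, chrom_length). Stick-breaking construction gives
# exact uniformity conditional on non-overlap.
place_nonoverlapping <- function(lengths, chrom_length) {
  k <- length(lengths)
  if (k == 0) return(integer(0))
  total <- sum(lengths)
  if (total > chrom_length) {
    rlang::abort(sprintf(
      "requested loci (%d bp with margins) exceed chromosome capacity (%d bp) without overlap",
      total, chrom_length))
  }
  slack <- chrom_length - total
  u <- sort(floor(stats::runif(k, 0, slack + 1)))
  as.integer(u + cumsum(c(0, lengths[-k])))
}

# Lay out all ground-truth loci and annotation features, mutually
# non-overlapping. Phased loci get a wide exclusion margin so their 2-kb
# flanks and GC valleys stay clear of other injected signals.
simulate_layout <- function(config) {
  set.seed(config$seed)
  phasi_margin <- 2500L
  feat_margin <- 300L
  regs <- rep(as.integer(names(config$n_phasi_loci)), config$n_phasi_loci)
  spec <- dplyr::bind_rows(
    tibble::tibble(kind = "phasi", register = sample(regs),
                   len = sample(config$locus_length_range[1]:config$locus_length_range[2],
                                length(regs), replace = TRUE),
                   margin = phasi_margin),
    tibble::tibble(kind = "te", register = NA_integer_,
                   len = sample(config$te_length_range[1]:config$te_length_range[2],
                                config$n_te, replace = TRUE),
                   margin = feat_margin),
    tibble::tibble(kind = "gene", register = NA_integer_,
                   len = sample(config$gene_length_range[1]:config$gene_length_range[2],
                                config$n_genes, replace = TRUE),
                   margin = feat_margin),
    tibble::tibble(kind = "mirna", register = NA_integer_,
                   len = sample(config$mirna_length_range[1]:config$mirna_length_range[2],
                                config$n_mirna, replace = TRUE),
                   margin = feat_margin)
  )
  spec$chrom_i <- sample(config$n_chrom, nrow(spec), replace = TRUE)
  out <- vector("list", config$n_chrom)
  for (ci in seq_len(config$n_chrom)) {
    sub <- spec[spec$chrom_i == ci, , drop = FALSE]
    sub <- sub[sample(nrow(sub)), , drop = FALSE]  # random order along chromosome
    starts <- place_nonoverlapping(sub$len + 2L * sub$margin, config$chrom_length)
    sub$start <- starts + sub$margin
    sub$end <- sub$start + sub$len
    sub$chrom <- paste0("chr", ci)
    out[[ci]] <- sub
  }
  truth <- dplyr::bind_rows(out)
  truth$superfamily <- ifelse(
    truth$kind == "te",
    sample(config$te_superfamilies, nrow(truth), replace = TRUE), "")
  truth$has_introns <- ifelse(
    truth$kind == "gene", stats::runif(nrow(truth)) < config$intron_fraction, NA)
  truth$strand <- sample(c("+", "-"), nrow(truth), replace = TRUE)
  truth$chh_delta <- ifelse(truth$kind == "phasi", config$chh_delta, 0)
  truth <- dplyr::arrange(truth, .data$chrom, .data$start)
  truth$id <- paste0(truth$kind, sprintf("%04d", seq_len(nrow(truth))))
  dplyr::select(truth, "chrom", "start", "end", "strand", "kind", "register",
                "superfamily", "has_introns", "chh_delta", "id")
}

#' Simulate the synthetic genome and its ground truth
#'
#' Lays out phased-siRNA loci, TEs, genes and miRNA loci mutually
#' non-overlapping, then draws the genome sequence with a per-base GC
#' probability of `base_gc` everywhere except around phased-locus midpoints,
#' where the probability first drops by the valley depth within the valley
#' half-width and then additionally rises by the peak height within the peak
#' half-width — the "peak in an otherwise dip" GC signature.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named `DNAStringSet`) and `truth` (tibble of
#'   all injected loci with kind, register, superfamily, intron flag and
#'   per-locus CHH increment).
#' @export
simulate_genome <- function(config) {
  truth <- simulate_layout(config)
  set.seed(config$seed + 1L)
  seqs <- character(config$n_chrom)
  for (ci in seq_len(config$n_chrom)) {
    ch <- paste0("chr", ci)
    p <- rep(config$base_gc, config$chrom_length)
    phasi <- truth[truth$chrom == ch & truth$kind == "phasi", , drop = FALSE]
    if (nrow(phasi) > 0) {
      mids <- (phasi$start + phasi$end) %/% 2L
      vh <- as.integer(config$gc_valley[["halfwidth"]])
      ph <- as.integer(config$gc_peak[["halfwidth"]])
      for (m in mids) {
        vi <- max(1L, m - vh + 1L):min(config$chrom_length, m + vh)
        p[vi] <- p[vi] - config$gc_valley[["depth"]]
        pi <- max(1L, m - ph + 1L):min(config$chrom_length, m + ph)
        p[pi] <- p[pi] + config$gc_peak[["height"]]
      }
      p <- pmin(pmax(p, 0), 1)
    }
    is_gc <- stats::runif(config$chrom_length) < p
    strong <- stats::runif(config$chrom_length) < 0.5
    base <- ifelse(is_gc, ifelse(strong, "G", "C"), ifelse(strong, "A", "T"))
    seqs[ci] <- paste(base, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(config$n_chrom))
  list(genome = genome, truth = truth)
}

#' Simulate aligned small-RNA reads for one library
#'
#' Three read populations: (i) phased-locus reads — for each phased locus
#' with register L, effective 5' positions are drawn from the in-register
#' positions with probability `phase_fidelity`, else uniformly in the locus;
#' strands are balanced, and minus-strand reads are placed with the 2-nt
#' 3'-overhang duplex geometry so their effective position
#' ([effective_phase_position()]) shares the register's residue class;
#' (ii) 24-nt background reads on TE intervals (multi-mapping, as TE reads
#' are); (iii) degradation reads of uniform 15-36 nt length at uniform
#' genomic positions. miRNA loci additionally receive a single-position
#' read stack. Per-register scaling emulates tissue contrasts.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth tibble from [simulate_genome()].
#' @param sample_id Library label.
#' @param register_scale Named multipliers of `reads_per_locus` per register
#'   (e.g. `c("21" = 1.5, "24" = 0.7)`).
#' @param mirna_scale Multiplier for the miRNA read stacks.
#' @param seed_offset Stream offset so different libraries from one config
#'   are independent but reproducible.
#' @return A read tibble sorted by coordinate.
#' @export
simulate_reads <- function(config, truth, sample_id = "meiocytes",
                           register_scale = c("21" = 1, "24" = 1),
                           mirna_scale = 1, seed_offset = 2L) {
  set.seed(config$seed + seed_offset)
  parts <- list()
  phasi <- truth[truth$kind == "phasi", , drop = FALSE]
  for (i in seq_len(nrow(phasi))) {
    L <- phasi$register[i]
    s <- phasi$start[i]; len <- phasi$end[i] - phasi$start[i]
    n <- stats::rpois(1, config$reads_per_locus * register_scale[[as.character(L)]])
    if (n == 0) next
    J <- (len - L) %/% L
    in_reg <- stats::runif(n) < config$phase_fidelity
    eff <- integer(n)
    eff[in_reg] <- s + L * sample(0:J, sum(in_reg), replace = TRUE)
    eff[!in_reg] <- s + floor(stats::runif(sum(!in_reg), 0, len - L + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    start <- ifelse(strand == "+", eff, eff - L - 2L)
    start <- pmax(start, 0L)
    parts[[length(parts) + 1L]] <- tibble::tibble(
      chrom = phasi$chrom[i], start = as.integer(start),
      end = as.integer(start + L),
      strand = strand, length = L, n_hits = 1L)
  }
  te <- truth[truth$kind == "te", , drop = FALSE]
  if (nrow(te) > 0 && config$background_te_reads > 0) {
    n <- as.integer(config$background_te_reads)
    idx <- sample(nrow(te), n, replace = TRUE, prob = te$end - te$start)
    start <- te$start[idx] +
      floor(stats::runif(n, 0, te$end[idx] - te$start[idx] - 24 + 1))
    parts[[length(parts) + 1L]] <- tibble::tibble(
      chrom = te$chrom[idx], start = as.integer(start),
      end = as.integer(start + 24L),
      strand = sample(c("+", "-"), n, replace = TRUE),
      length = 24L,
      n_hits = sample(1:5, n, replace = TRUE,
                      prob = c(0.25, 0.25, 0.2, 0.15, 0.15)))
  }
  if (config$degradation_reads > 0) {
    n <- as.integer(config$degradation_reads)
    len <- sample(15:36, n, replace = TRUE)
    ci <- sample(config$n_chrom, n, replace = TRUE)
    start <- floor(stats::runif(n, 0, config$chrom_length - len + 1))
    parts[[length(parts) + 1L]] <- tibble::tibble(
      chrom = paste0("chr", ci), start = as.integer(start),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), n, replace = TRUE),
      length = as.integer(len), n_hits = 1L)
  }
  mir <- truth[truth$kind == "mirna", , drop = FALSE]
  if (nrow(mir) > 0 && config$reads_per_mirna * mirna_scale > 0) {
    for (i in seq_len(nrow(mir))) {
      n <- stats::rpois(1, config$reads_per_mirna * mirna_scale)
      if (n == 0) next
      s <- mir$start[i] + 10L
      parts[[length(parts) + 1L]] <- tibble::tibble(
        chrom = mir$chrom[i], start = s, end = s + 21L,
        strand = "+", length = 21L, n_hits = 1L)[rep(1, n), ]
    }
  }
  reads <- dplyr::bind_rows(parts)
  reads$sample_id <- sample_id
  dplyr::arrange(reads, .data$chrom, .data$start, .data$end, .data$strand)
}

#' Simulate a bisulfite methylome over the synthetic genome
#'
#' Every genomic cytosine (both strands) receives its sequence context from
#' [cytosine_contexts()], a Poisson read depth, and a binomial methylated
#' count at the context's baseline rate — plus the per-locus CHH increment
#' inside phased loci.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth tibble.
#' @param genome The simulated genome.
#' @param seed_offset Stream offset (default keeps the methylome independent
#'   of the read streams).
#' @return A cytosine-call tibble (see [read_cx_report()]).
#' @export
simulate_methylome <- function(config, truth, genome, seed_offset = 10L) {
  set.seed(config$seed + seed_offset)
  ctx <- cytosine_contexts(genome)
  n <- nrow(ctx)
  depth <- stats::rpois(n, config$coverage_mean)
  p <- unname(config$meth_base[ctx$context])
  phasi <- truth[truth$kind == "phasi", , drop = FALSE]
  if (nrow(phasi) > 0 && any(phasi$chh_delta > 0)) {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(ctx$chrom, IRanges::IRanges(ctx$pos + 1L, ctx$pos + 1L)),
      as_gr0(phasi))
    qh <- S4Vectors::queryHits(hits)
    inside_chh <- qh[ctx$context[qh] == "CHH"]
    p[inside_chh] <- p[inside_chh] +
      phasi$chh_delta[S4Vectors::subjectHits(hits)[ctx$context[qh] == "CHH"]]
  }
  tibble::tibble(
    chrom = ctx$chrom, pos = ctx$pos, strand = ctx$strand,
    context = ctx$context,
    count_meth = stats::rbinom(n, depth, pmin(p, 1)),
    count_total = depth)
}

# Ground truth as a feature tibble for the annotation-facing functions.
truth_features <- function(truth) {
  kinds <- c(te = "TE", gene = "gene", mirna = "miRNA")
  feat <- truth[truth$kind %in% names(kinds), , drop = FALSE]
  tibble::tibble(
    chrom = feat$chrom, start = feat$start, end = feat$end,
    strand = feat$strand, feature_kind = unname(kinds[feat$kind]),
    subtype = feat$superfamily, has_introns = feat$has_introns, id = feat$id)
}

#' Generate and write the complete synthetic dataset
#'
#' One call produces a self-contained analysis fixture in `dir`: genome
#' FASTA, GFF3 annotation, one read BED per library (meiocytes, anthers and
#' seedlings, with register scalings echoing the tissue contrast: 21-nt
#' loci up in meiocytes, 24-nt loci up in anthers, both near-silent in
#' seedlings), a CX-style methylome for the meiocyte sample, and the
#' ground-truth locus table. All outputs are byte-deterministic under the
#' config seed.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `genome`, `truth`, `features`, `reads`
#'   (all samples bound), `methylome`, and the file paths.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("phasir_sim_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- simulate_genome(config)
  features <- truth_features(gt$truth)
  scales <- list(
    meiocytes = list(reg = c("21" = 1.5, "24" = 0.7), mir = 1, off = 2L),
    anthers   = list(reg = c("21" = 0.7, "24" = 1.5), mir = 1, off = 3L),
    seedlings = list(reg = c("21" = 0.05, "24" = 0.1), mir = 1, off = 4L))
  reads <- lapply(names(scales), function(s) {
    simulate_reads(config, gt$truth, sample_id = s,
                   register_scale = scales[[s]]$reg,
                   mirna_scale = scales[[s]]$mir,
                   seed_offset = scales[[s]]$off)
  })
  names(reads) <- names(scales)
  methylome <- simulate_methylome(config, gt$truth, gt$genome)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotations = file.path(dir, "annotations.gff3"),
    methylome = file.path(dir, "cytosines_meiocytes.cx.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_genome(gt$genome, paths$genome)
  write_features_gff3(features, paths$annotations)
  write_cx_report(methylome, paths$methylome)
  readr::write_tsv(gt$truth, paths$truth, progress = FALSE)
  for (s in names(reads)) {
    p <- file.path(dir, paste0("reads_", s, ".bed"))
    r <- reads[[s]]
    write_bed(tibble::tibble(chrom = r$chrom, start = r$start, end = r$end,
                             name = sprintf("r%07d", seq_len(nrow(r))),
                             score = r$n_hits, strand = r$strand), p)
    paths[[paste0("reads_", s)]] <- p
  }
  invisible(list(genome = gt$genome, truth = gt$truth, features = features,
                 reads = dplyr::bind_rows(reads), methylome = methylome,
                 dir = dir, paths = paths))
}

#' Score called phasiRNA loci against the ground truth
#'
#' Matches predicted phased loci to injected ones by >= 1 nt overlap.
#' Recall is the fraction of truth loci hit by a predicted phased locus;
#' precision the fraction of predicted phased loci that hit a truth locus.
#'
#' @param predicted Interval tibble of predicted phasiRNA loci (e.g.
#'   `dplyr::filter(clusters, is_phasi)`).
#' @param truth Ground-truth tibble (rows with `kind == "phasi"` are used;
#'   a plain interval tibble also works).
#' @return Tibble with `n_truth`, `n_predicted`, `recall`, `precision`.
#' @export
score_locus_recovery <- function(predicted, truth) {
  if ("kind" %in% names(truth)) truth <- truth[truth$kind == "phasi", , drop = FALSE]
  if (nrow(truth) == 0) rlang::abort("no truth loci to score against")
  if (nrow(predicted) == 0) {
    return(tibble::tibble(n_truth = nrow(truth), n_predicted = 0L,
                          recall = 0, precision = NA_real_))
  }
  hits <- GenomicRanges::findOverlaps(as_gr0(predicted), as_gr0(truth))
  tibble::tibble(
    n_truth = nrow(truth),
    n_predicted = nrow(predicted),
    recall = length(unique(S4Vectors::subjectHits(hits))) / nrow(truth),
    precision = length(unique(S4Vectors::queryHits(hits))) / nrow(predicted))
}
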