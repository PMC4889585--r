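#' Remove read stacks below an RPM threshold
#'
#' Background suppression ahead of cluster calling: reads are grouped into
#' stacks by (chromosome, 5' position, strand, length) and every stack whose
#' summed count falls below `min_rpm` reads-per-million is dropped. This is
#' the strictest (per-position) reading of removing loci under the
#' threshold, and what makes downstream clusters stand out from degradation
#' noise at real library depths.
#'
#' @param reads Read tibble.
#' @param total_aligned Library size used for RPM; defaults to `nrow(reads)`.
#' @param min_rpm Threshold in RPM; stacks with RPM < `min_rpm` are removed.
#' @return The retained reads, unchanged, in the input order.
#' @export
filter_low_rpm <- function(reads, total_aligned = nrow(reads), min_rpm = 2) {
  if (total_aligned <= 0) rlang::abort("`total_aligned` must be positive")
  if (min_rpm <= 0 || nrow(reads) == 0) return(reads)
  pos5 <- read_pos5(reads)
  key <- paste(reads$chrom, pos5, reads$strand, reads$length, sep = "\r")
  stack_n <- table(key)
  keep_keys <- names(stack_n)[rpm(as.vector(stack_n), total_aligned) >= min_rpm]
  reads[key %in% keep_keys, , drop = FALSE]
}

#' Dominant size class of a set of read lengths
#'
#' The plurality read length, reported as one of "21", "22", "24" or
#' "other". Ties are broken toward the smaller length; if the plurality
#' length is not 21, 22 or 24 the class is "other".
#'
#' @param lengths Integer vector of member read lengths (nonempty).
#' @return A single string.
#' @export
assign_size_class <- function(lengths) {
  if (length(lengths) == 0) rlang::abort("cannot assign a size class to an empty cluster")
  tab <- table(lengths)
  winners <- as.integer(names(tab)[tab == max(tab)])
  winner <- min(winners)
  if (winner %in% c(21L, 22L, 24L)) as.character(winner) else "other"
}

#' Call small-RNA clusters by gap-based merging
#'
#' Single linear sweep per chromosome over reads sorted by start: a read
#' joins the open cluster iff the gap between the cluster's current right
#' edge and the read start is at most `max_gap` nt (a gap of exactly
#' `max_gap` merges). Strand is ignored for merging — phasiRNA loci produce
#' reads from both strands. Clusters are maximal, non-overlapping and
#' sorted. Run [filter_low_rpm()] first to reproduce the
#' background-suppressed locus definition.
#'
#' @param reads Read tibble (typically after [filter_low_rpm()]).
#' @param max_gap Maximum merge gap in nt.
#' @param total_aligned Library size for the per-cluster `rpm_sum` column;
#'   defaults to `nrow(reads)`.
#' @return An `srna_clusters` tibble: `cluster_id`, `chrom`, `start`, `end`,
#'   `width`, `n_reads`, `rpm_sum`, per-length counts `n21`, `n22`, `n24`,
#'   and `size_class`.
#' @export
call_clusters <- function(reads, max_gap = 100L, total_aligned = nrow(reads)) {
  if (nrow(reads) == 0) {
    out <- tibble::tibble(cluster_id = integer(), chrom = character(),
                          start = integer(), end = integer(), width = integer(),
                          n_reads = integer(), rpm_sum = double(),
                          n21 = integer(), n22 = integer(), n24 = integer(),
                          size_class = character())
    return(new_srna_clusters(out, max_gap, total_aligned))
  }
  check_interval_cols(reads, "reads")
  rs <- dplyr::arrange(reads, .data$chrom, .data$start, .data$end)
  new_chrom <- rs$chrom != dplyr::lag(rs$chrom, default = "\r")
  # running right edge within each chromosome
  edge <- rs$end
  run_max <- edge
  for (ch in unique(rs$chrom)) {
    sel <- rs$chrom == ch
    run_max[sel] <- cummax(edge[sel])
  }
  prev_edge <- dplyr::lag(run_max, default = 0L)
  breaks <- new_chrom | (rs$start - prev_edge > max_gap)
  rs$cluster_id <- cumsum(breaks)
  out <- rs |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_reads = dplyr::n(),
      n21 = sum(.data$length == 21L),
      n22 = sum(.data$length == 22L),
      n24 = sum(.data$length == 24L),
      size_class = assign_size_class(.data$length),
      .groups = "drop") |>
    dplyr::mutate(width = .data$end - .data$start,
                  rpm_sum = rpm(.data$n_reads, total_aligned)) |>
    dplyr::select("cluster_id", "chrom", "start", "end", "width", "n_reads",
                  "rpm_sum", "n21", "n22", "n24", "size_class") |>
    dplyr::arrange(.data$chrom, .data$start)
  out$cluster_id <- seq_len(nrow(out))
  new_srna_clusters(out, max_gap, total_aligned)
}

new_srna_clusters <- function(df, max_gap, total_aligned) {
  attr(df, "max_gap") <- max_gap
  attr(df, "total_aligned") <- total_aligned
  class(df) <- unique(c("srna_clusters", class(df)))
  df
}

#' Effective phase position of aligned reads
#'
#' The coordinate used for phase-register arithmetic. Dicer processes a
#' double-stranded precursor into duplexes with 2-nt 3' overhangs, so the
#' 5' end of a minus-strand read sits 2 nt 3' of its plus-strand partner's
#' 3' end. Mapping a plus read to its start and a minus read to its
#' (half-open) end + 2 places perfect duplex partners in the same residue
#' class modulo the register.
#'
#' @param reads Read tibble; every read must be stranded.
#' @return Integer vector of effective genomic positions.
#' @export
effective_phase_position <- function(reads) {
  if (any(!reads$strand %in% c("+", "-"))) {
    rlang::abort("phase positions require stranded reads ('+' or '-')")
  }
  as.integer(ifelse(reads$strand == "-", reads$end + 2L, reads$start))
}

#' Hypergeometric phase score for a set of occupied positions
#'
#' The phasing statistic: within a window of width `width` starting at
#' `window_start`, the distinct effective read positions are reduced modulo
#' the register `L` (relative to the window start). For the best-populated
#' residue class, the probability of seeing at least that many of the `n`
#' occupied positions fall into the class if positions were drawn uniformly
#' without replacement is the hypergeometric tail
#' \eqn{P[X \ge k]} with \eqn{X \sim \mathrm{Hyper}(N = width, m, n)},
#' where `m` is the number of window positions in the class. The reported
#' p-value is Bonferroni-corrected for the `L` candidate registers
#' (`p = L * tail`, capped at 1).
#'
#' @param positions Integer vector of effective positions (duplicates are
#'   collapsed: evidence is occupied positions, not read depth).
#' @param window_start,width Window origin and width in nt.
#' @param L Phase register (e.g. 21 or 24).
#' @return A list: `k` (occupied positions in the best register), `n`
#'   (occupied positions), `register_offset` (residue of the best class),
#'   `p_value`.
#' @export
phase_pvalue <- function(positions, window_start, width, L) {
  L <- as.integer(L)
  width <- as.integer(width)
  occ <- unique(as.integer(positions))
  n <- length(occ)
  if (n == 0) return(list(k = 0L, n = 0L, register_offset = NA_integer_, p_value = 1))
  r <- (occ - as.integer(window_start)) %% L
  k_r <- tabulate(r + 1L, nbins = L)
  # positions 0..width-1 in each residue class
  m_r <- vapply(0:(L - 1L), function(res) {
    if (res >= width) 0L else (width - res - 1L) %/% L + 1L
  }, integer(1))
  best <- which.max(k_r)  # ties -> smallest residue
  k <- k_r[best]
  m <- m_r[best]
  if (n >= width || m == 0L) return(list(k = k, n = n,
                                         register_offset = best - 1L, p_value = 1))
  k_eff <- min(k, m, n)
  tail <- stats::phyper(k_eff - 1L, m, width - m, min(n, width),
                        lower.tail = FALSE)
  list(k = k, n = n, register_offset = best - 1L,
       p_value = min(1, L * tail))
}

#' Score clusters for phasing and classify phasiRNA loci
#'
#' For each cluster and each candidate register (21 and 24 nt by default),
#' reads of that exact length belonging to the cluster are reduced to their
#' distinct effective phase positions ([effective_phase_position()]) and
#' scored with [phase_pvalue()]. A register is only tested when the cluster
#' holds at least `min_reads` reads of that length (hypergeometric tails
#' are meaningless for tiny n). The register with the smallest p-value is
#' reported, and `is_phasi` is `TRUE` when that p-value is at most `alpha`.
#'
#' @param clusters An `srna_clusters` tibble from [call_clusters()].
#' @param reads The (filtered) reads the clusters were called from.
#' @param registers Candidate phase registers.
#' @param alpha Classification threshold on the corrected p-value.
#' @param min_reads Minimum reads of the register length for a test.
#' @return `clusters` with columns `register`, `phase_k`, `phase_n`,
#'   `p_value`, `is_phasi` added. Untested clusters have `NA` register and
#'   p-value and `is_phasi = FALSE`.
#' @export
cluster_phasing <- function(clusters, reads, registers = c(21L, 24L),
                            alpha = 1e-9, min_reads = 5L) {
  n_cl <- nrow(clusters)
  register <- rep(NA_integer_, n_cl)
  phase_k <- rep(NA_integer_, n_cl)
  phase_n <- rep(NA_integer_, n_cl)
  p_value <- rep(NA_real_, n_cl)
  if (n_cl > 0 && nrow(reads) > 0) {
    stranded <- reads[reads$strand %in% c("+", "-"), , drop = FALSE]
    pos5 <- read_pos5(stranded)
    eff <- effective_phase_position(stranded)
    hit_gr <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(stranded$chrom, IRanges::IRanges(pos5 + 1L, pos5 + 1L)),
      as_gr0(clusters))
    cl_of_read <- rep(NA_integer_, nrow(stranded))
    cl_of_read[S4Vectors::queryHits(hit_gr)] <- S4Vectors::subjectHits(hit_gr)
    for (i in seq_len(n_cl)) {
      members <- which(cl_of_read == i)
      if (length(members) == 0) next
      best <- NULL
      for (L in registers) {
        sel <- members[stranded$length[members] == L]
        if (length(sel) < min_reads) next
        res <- phase_pvalue(eff[sel], clusters$start[i], clusters$width[i], L)
        if (is.null(best) || res$p_value < best$p_value) {
          best <- res; best$L <- L
        }
      }
      if (!is.null(best)) {
        register[i] <- best$L
        phase_k[i] <- best$k
        phase_n[i] <- best$n
        p_value[i] <- best$p_value
      }
    }
  }
  clusters$register <- register
  clusters$phase_k <- phase_k
  clusters$phase_n <- phase_n
  clusters$p_value <- p_value
  clusters$is_phasi <- !is.na(p_value) & p_value <= alpha
  clusters
}

#' Flag clusters overlapping known miRNA loci
#'
#' The annotation-driven route to miRNA identification: a cluster is flagged
#' iff it overlaps a known miRNA feature by at least 1 nt (intervals are
#' half-open, so mere adjacency does not flag).
#'
#' @param clusters An `srna_clusters` tibble.
#' @param features Feature tibble; only `feature_kind == "miRNA"` rows are
#'   used.
#' @return `clusters` with a logical `known_mirna` column.
#' @export
flag_known_mirna <- function(clusters, features) {
  mir <- dplyr::filter(features, .data$feature_kind == "miRNA")
  flag <- rep(FALSE, nrow(clusters))
  if (nrow(mir) > 0 && nrow(clusters) > 0) {
    hits <- GenomicRanges::findOverlaps(as_gr0(clusters), as_gr0(mir))
    flag[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  clusters$known_mirna <- flag
  clusters
}

#' Compare two locus sets by interval overlap
#'
#' Counts loci private to each set and overlapping pairs, plus a base-pair
#' Jaccard index (intersection bases over union bases). Each set must be
#' internally non-overlapping — sets of called clusters are by construction.
#'
#' @param set_a,set_b Interval tibbles (`chrom`, `start`, `end`).
#' @param min_overlap Minimum overlap in nt for two loci to match.
#' @return Tibble with one row: `a_only`, `b_only`, `n_both` (matching
#'   pairs), `jaccard_bp`.
#' @export
compare_locus_sets <- function(set_a, set_b, min_overlap = 1L) {
  check_nonoverlapping(set_a, "set_a")
  check_nonoverlapping(set_b, "set_b")
  gra <- as_gr0(set_a); grb <- as_gr0(set_b)
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap)
  inter_bp <- sum(GenomicRanges::width(GenomicRanges::intersect(gra, grb)))
  union_bp <- sum(GenomicRanges::width(GenomicRanges::union(gra, grb)))
  tibble::tibble(
    a_only = nrow(set_a) - length(unique(S4Vectors::queryHits(hits))),
    b_only = nrow(set_b) - length(unique(S4Vectors::subjectHits(hits))),
    n_both = length(hits),
    jaccard_bp = if (union_bp == 0) 0 else inter_bp / union_bp
  )
}

#' @method tidy srna_clusters
#' @export
tidy.srna_clusters <- function(x, ...) {
  out <- x
  attr(out, "max_gap") <- NULL
  attr(out, "total_aligned") <- NULL
  class(out) <- setdiff(class(out), "srna_clusters")
  tibble::as_tibble(out)
}

#' @method glance srna_clusters
#' @export
glance.srna_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x),
    n_phasi = if ("is_phasi" %in% names(x)) sum(x$is_phasi) else NA_integer_,
    n_class_21 = sum(x$size_class == "21"),
    n_class_22 = sum(x$size_class == "22"),
    n_class_24 = sum(x$size_class == "24"),
    n_class_other = sum(x$size_class == "other"),
    median_width = stats::median(x$width),
    total_reads = sum(x$n_reads),
    max_gap = attr(x, "max_gap") %||% NA_integer_
  )
}
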