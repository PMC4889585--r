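#' Classify clusters against genomic annotations
#'
#' Assigns each cluster exactly one feature class by overlap (at least 1 nt)
#' with precedence miRNA > TE > gene > unannotated when several feature
#' kinds overlap. The TE class carries the superfamily of the TE with the
#' largest base-pair overlap (ties broken alphabetically, then by annotation
#' order). `report_all = TRUE` instead returns the full multi-label overlap
#' table for audit.
#'
#' @param clusters An `srna_clusters` tibble (any interval tibble works).
#' @param features Feature tibble (see [read_features_gff3()]).
#' @param report_all Return one row per (cluster, overlapping feature)
#'   instead of the single-class assignment.
#' @return `clusters` with `feature_class` ("gene", "TE", "miRNA",
#'   "unannotated") and `te_superfamily` columns added; or, with
#'   `report_all`, a long tibble `cluster_id`, `feature_kind`, `subtype`,
#'   `feature_id`, `overlap_bp`.
#' @export
classify_clusters <- function(clusters, features, report_all = FALSE) {
  if (nrow(clusters) == 0) {
    clusters$feature_class <- character(0)
    clusters$te_superfamily <- character(0)
    return(clusters)
  }
  gr_c <- as_gr0(clusters)
  gr_f <- as_gr0(features)
  hits <- GenomicRanges::findOverlaps(gr_c, gr_f)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov_bp <- GenomicRanges::width(IRanges::pintersect(gr_c[qh], gr_f[sh]))
  long <- tibble::tibble(
    cluster_row = qh,
    feature_kind = features$feature_kind[sh],
    subtype = features$subtype[sh],
    feature_id = features$id[sh],
    overlap_bp = ov_bp)
  if (report_all) {
    long$cluster_id <- clusters$cluster_id[long$cluster_row] %||% long$cluster_row
    return(dplyr::select(long, "cluster_id", "feature_kind", "subtype",
                         "feature_id", "overlap_bp"))
  }
  feature_class <- rep("unannotated", nrow(clusters))
  te_superfamily <- rep(NA_character_, nrow(clusters))
  for (kind in c("gene", "TE", "miRNA")) {  # ascending precedence: last write wins
    rows <- unique(long$cluster_row[long$feature_kind == kind])
    feature_class[rows] <- kind
  }
  te_rows <- which(feature_class == "TE")
  if (length(te_rows) > 0) {
    best <- long |>
      dplyr::filter(.data$feature_kind == "TE", .data$cluster_row %in% te_rows) |>
      dplyr::arrange(.data$cluster_row, dplyr::desc(.data$overlap_bp), .data$subtype) |>
      dplyr::distinct(.data$cluster_row, .keep_all = TRUE)
    te_superfamily[best$cluster_row] <- best$subtype
  }
  clusters$feature_class <- feature_class
  clusters$te_superfamily <- te_superfamily
  clusters
}

#' Summarise cluster classes and TE superfamilies
#'
#' Locus counts, proportions and base-pair totals per feature class, with a
#' per-superfamily breakdown of the TE class. Because classification is by
#' precedence, class locus counts partition the cluster set and proportions
#' sum to 1.
#'
#' @param classified Output of [classify_clusters()].
#' @return Tibble `feature_class`, `te_superfamily` (NA except for TE rows),
#'   `n_loci`, `prop_loci`, `bp`.
#' @export
overlap_summary <- function(classified) {
  total <- nrow(classified)
  by_class <- classified |>
    dplyr::group_by(.data$feature_class) |>
    dplyr::summarise(n_loci = dplyr::n(), bp = sum(.data$end - .data$start),
                     .groups = "drop") |>
    dplyr::mutate(te_superfamily = NA_character_)
  by_sf <- classified |>
    dplyr::filter(.data$feature_class == "TE") |>
    dplyr::group_by(.data$te_superfamily) |>
    dplyr::summarise(n_loci = dplyr::n(), bp = sum(.data$end - .data$start),
                     .groups = "drop") |>
    dplyr::mutate(feature_class = "TE")
  dplyr::bind_rows(by_class, by_sf) |>
    dplyr::mutate(prop_loci = .data$n_loci / total) |>
    dplyr::select("feature_class", "te_superfamily", "n_loci", "prop_loci", "bp") |>
    dplyr::arrange(is.na(.data$te_superfamily) == FALSE, dplyr::desc(.data$n_loci))
}

#' Genes overlapped by small-RNA clusters
#'
#' Extracts the unique genes hit by any cluster (at least 1 nt overlap),
#' with the read-length histogram of the member reads of their overlapping
#' clusters — the downstream question being what size class of small RNA a
#' gene attracts (22-nt enrichment at histone genes being the canonical
#' example). Intronless genes are flagged so they can be reported
#' separately.
#'
#' @param clusters An `srna_clusters` tibble.
#' @param reads The reads the clusters were called from.
#' @param genes Feature tibble rows with `feature_kind == "gene"`.
#' @return Tibble `gene_id`, `has_introns`, `n_clusters`, `n_reads`,
#'   `length_mode` (smallest modal read length), plus one `len_<L>` count
#'   column per observed read length.
#' @export
overlapped_genes <- function(clusters, reads, genes) {
  genes <- dplyr::filter(genes, .data$feature_kind == "gene")
  empty <- tibble::tibble(gene_id = character(), has_introns = logical(),
                          n_clusters = integer(), n_reads = integer(),
                          length_mode = integer())
  if (nrow(genes) == 0 || nrow(clusters) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(as_gr0(clusters), as_gr0(genes))
  if (length(hits) == 0) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  # member reads per cluster via 5' position containment
  pos5 <- read_pos5(reads)
  rhits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(pos5 + 1L, pos5 + 1L)),
    as_gr0(clusters))
  read_cluster <- tibble::tibble(
    read = S4Vectors::queryHits(rhits), cluster_row = S4Vectors::subjectHits(rhits))
  gene_cluster <- tibble::tibble(gene_row = sh, cluster_row = qh)
  gene_reads <- dplyr::inner_join(gene_cluster, read_cluster, by = "cluster_row",
                                  relationship = "many-to-many")
  gene_reads$length <- reads$length[gene_reads$read]
  hist_wide <- gene_reads |>
    dplyr::count(.data$gene_row, .data$length) |>
    tidyr::pivot_wider(names_from = "length", values_from = "n",
                       names_prefix = "len_", values_fill = 0L,
                       names_sort = TRUE)
  summary <- gene_reads |>
    dplyr::group_by(.data$gene_row) |>
    dplyr::summarise(
      n_clusters = dplyr::n_distinct(.data$cluster_row),
      n_reads = dplyr::n(),
      length_mode = {
        tab <- table(.data$length)
        min(as.integer(names(tab)[tab == max(tab)]))
      },
      .groups = "drop")
  out <- dplyr::left_join(summary, hist_wide, by = "gene_row")
  out$gene_id <- genes$id[out$gene_row]
  out$has_introns <- genes$has_introns[out$gene_row]
  dplyr::select(out, "gene_id", "has_introns", "n_clusters", "n_reads",
                "length_mode", dplyr::starts_with("len_"))
}
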