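#' Read gene, TE and miRNA annotations from GFF3
#'
#' Parses GFF3 via \pkg{rtracklayer} and flattens the feature hierarchy into
#' the package's feature tibble. Coordinates are converted from GFF3's
#' 1-based inclusive convention to 0-based half-open. A gene is flagged
#' `has_introns = TRUE` iff at least one of its mRNA children carries two or
#' more exons. TE records (type `transposable_element`) must carry a
#' `superfamily` attribute; miRNA records have type `miRNA`.
#'
#' @param path Path to a GFF3 file.
#' @return A feature tibble: `chrom`, `start`, `end`, `strand`,
#'   `feature_kind` (gene/TE/miRNA), `subtype` (TE superfamily or ""),
#'   `has_introns` (genes only, else `NA`), `id`.
#' @export
read_features_gff3 <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID %||% rep(NA_character_, length(gr)))
  parents <- meta$Parent
  parent1 <- if (is.null(parents)) rep(NA_character_, length(gr)) else
    vapply(as.list(parents), function(p) if (length(p)) p[[1]] else NA_character_, "")

  # exon children per mRNA, then mRNA -> parent gene
  is_mrna <- type == "mRNA"
  is_exon <- type == "exon"
  exon_per_mrna <- table(parent1[is_exon])
  gene_of_mrna <- setNames(parent1[is_mrna], ids[is_mrna])
  multi_exon_genes <- unique(stats::na.omit(
    gene_of_mrna[names(exon_per_mrna)[exon_per_mrna >= 2]]))

  to_tbl <- function(sel, kind) {
    if (!any(sel)) return(NULL)
    sub <- gr[sel]
    m <- S4Vectors::mcols(sub)
    tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(sub)),
      start = GenomicRanges::start(sub) - 1L,
      end = GenomicRanges::end(sub),
      strand = ifelse(as.character(GenomicRanges::strand(sub)) %in% c("+", "-"),
                      as.character(GenomicRanges::strand(sub)), "*"),
      feature_kind = kind,
      subtype = if (kind == "TE") {
        sf <- as.character(m$superfamily %||% rep("", length(sub)))
        if (any(!nzchar(sf) | is.na(sf))) {
          rlang::abort(sprintf("%s: transposable_element record without a superfamily attribute", path))
        }
        sf
      } else "",
      has_introns = if (kind == "gene") {
        as.character(m$ID) %in% multi_exon_genes
      } else NA,
      id = as.character(m$ID %||% paste0(kind, "_", seq_along(sub)))
    )
  }

  out <- dplyr::bind_rows(
    to_tbl(type == "gene", "gene"),
    to_tbl(type == "transposable_element", "TE"),
    to_tbl(type == "miRNA", "miRNA")
  )
  if (nrow(out) == 0) {
    rlang::abort(sprintf("%s: no gene, transposable_element or miRNA records found", path))
  }
  check_interval_cols(out, "GFF3 features")
  out
}

# Deterministic GFF3 writer for the synthetic annotation (hand-formatted so
# that identical inputs give byte-identical files). Genes are written with an
# mRNA child and 1 or 3 exons according to has_introns.
write_features_gff3 <- function(features, path) {
  hdr <- "##gff-version 3"
  fmt <- function(chrom, start0, end0, type, strand, attrs) {
    paste(chrom, "phasir", type, start0 + 1L, end0, ".",
          ifelse(strand %in% c("+", "-"), strand, "."), ".", attrs, sep = "\t")
  }
  lines <- character(0)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (f$feature_kind == "gene") {
      gid <- f$id
      mid <- paste0(gid, ".m1")
      lines <- c(lines,
        fmt(f$chrom, f$start, f$end, "gene", f$strand, paste0("ID=", gid)),
        fmt(f$chrom, f$start, f$end, "mRNA", f$strand,
            paste0("ID=", mid, ";Parent=", gid)))
      if (isTRUE(f$has_introns)) {
        w <- f$end - f$start
        b1 <- f$start + max(1L, w %/% 4L); b2 <- f$start + max(2L, w %/% 2L)
        b3 <- f$start + max(3L, (3L * w) %/% 4L)
        exons <- list(c(f$start, b1), c(b2, b3), c(b3 + min(10L, f$end - b3 - 1L), f$end))
        for (k in seq_along(exons)) {
          lines <- c(lines, fmt(f$chrom, exons[[k]][1], exons[[k]][2], "exon",
                                f$strand, paste0("ID=", mid, ".e", k, ";Parent=", mid)))
        }
      } else {
        lines <- c(lines, fmt(f$chrom, f$start, f$end, "exon", f$strand,
                              paste0("ID=", mid, ".e1;Parent=", mid)))
      }
    } else if (f$feature_kind == "TE") {
      lines <- c(lines, fmt(f$chrom, f$start, f$end, "transposable_element", f$strand,
                            paste0("ID=", f$id, ";superfamily=", f$subtype)))
    } else if (f$feature_kind == "miRNA") {
      lines <- c(lines, fmt(f$chrom, f$start, f$end, "miRNA", f$strand,
                            paste0("ID=", f$id)))
    }
  }
  readr::write_lines(c(hdr, lines), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that keeps only the
#' first whitespace-delimited token of each header as the chromosome name.
#'
#' @param path FASTA path.
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# Deterministic FASTA writer (60-column wrapping).
write_genome <- function(genome, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- as.character(genome[[nm]])
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}
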