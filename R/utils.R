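# Internal helpers shared across modules.
#
# Coordinate convention: every interval inside the package is 0-based,
# half-open [start, end). Conversion to/from 1-based conventions (GFF3,
# CX reports, GRanges) happens only at the I/O or GRanges boundary.

# Convert a 0-based half-open interval tibble to a GRanges (1-based closed).
as_gr0 <- function(df, use_strand = FALSE) {
  strand <- if (use_strand && "strand" %in% names(df)) {
    ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  } else {
    "*"
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand   = strand
  )
}

# Round half away from zero (report-time rounding for percentages/ratios;
# base round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_bad_line <- function(path, line_no, msg) {
  rlang::abort(sprintf("%s: line %d: %s", path, line_no, msg))
}

check_interval_cols <- function(df, what = "interval table") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    rlang::abort(sprintf("%s must have columns %s (missing: %s)",
                         what, paste(need, collapse = ", "),
                         paste(miss, collapse = ", ")))
  }
  bad <- which(!(df$start < df$end) | df$start < 0 | is.na(df$chrom) | df$chrom == "")
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "%s: invalid interval(s) at row(s) %s (need chrom nonempty, 0 <= start < end)",
      what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(df)
}

# Assert that loci within one set are pairwise non-overlapping.
check_nonoverlapping <- function(df, what = "locus set") {
  if (nrow(df) < 2) return(invisible(df))
  gr <- as_gr0(df)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(hits) > 0) {
    rlang::abort(sprintf("%s contains overlapping intervals (e.g. rows %d and %d)",
                         what, S4Vectors::queryHits(hits)[1], S4Vectors::subjectHits(hits)[1]))
  }
  invisible(df)
}

# 5' genomic position of a read on its own strand; unstranded reads are
# treated as plus-strand for binning but rejected where phasing needs strand.
read_pos5 <- function(reads) {
  ifelse(reads$strand == "-", reads$end - 1L, reads$start)
}
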