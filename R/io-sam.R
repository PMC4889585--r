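#' Read aligned small-RNA reads from a minimal SAM subset
#'
#' A deliberately narrow, read-only SAM consumer: header lines are skipped,
#' the strand comes from FLAG bit 0x10, unmapped records (FLAG bit 0x4) are
#' dropped, only fully-matching alignments (CIGAR of the form `<n>M`) are
#' accepted, and an `NH:i:` tag, when present, supplies `n_hits`. Anything
#' else (indels, clipping, spliced CIGARs) is rejected with a message naming
#' the offending line: this package consumes alignments, it does not
#' interpret them.
#'
#' @inheritParams read_srna_bed
#' @param path Path to a SAM file.
#' @return A read tibble as from [read_srna_bed()].
#' @export
read_srna_sam <- function(path, sample_id = "sample", min_length = 15L, max_length = 36L) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  idx <- which(!startsWith(lines, "@") & nzchar(lines))
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop_bad_line(path, i, "fewer than 11 SAM fields")
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop_bad_line(path, i, "non-integer FLAG")
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    cigar <- f[6]
    if (!grepl("^\\d+M$", cigar)) {
      stop_bad_line(path, i, sprintf(
        "unsupported CIGAR '%s' (only fully-matching '<n>M' alignments are accepted)",
        cigar))
    }
    len <- as.integer(sub("M$", "", cigar))
    pos1 <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos1) || pos1 < 1) stop_bad_line(path, i, "invalid POS")
    nh <- 1L
    nh_tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(nh_tag) > 0) nh <- as.integer(sub("^NH:i:", "", nh_tag[1]))
    out[[j]] <- list(chrom = f[3], start = pos1 - 1L, end = pos1 - 1L + len,
                     strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
                     length = len, n_hits = nh)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          strand = character(), length = integer(),
                          n_hits = integer(), sample_id = character()))
  }
  reads <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  reads$sample_id <- sample_id
  bad <- which(reads$length < min_length | reads$length > max_length)
  if (length(bad) > 0) {
    rlang::abort(sprintf("%s: read length %d outside the %d-%d nt range",
                         path, reads$length[bad[1]], min_length, max_length))
  }
  reads
}
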