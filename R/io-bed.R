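#' Read a BED file into an interval tibble
#'
#' Parses BED3/BED6 into a tibble of 0-based half-open intervals. BED is
#' already 0-based half-open, so coordinates pass through unchanged. A strand
#' column ("+"/"-") is honoured when present; records without one (or with
#' ".") are unstranded ("*").
#'
#' @param path Path to a tab-separated BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`. `name` is `NA` and `score` 0 when the file has only 3 columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          name = character(), score = double(), strand = character()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop_bad_line(path, idx[which(nf < 3)[1]], "fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    stop_bad_line(path, idx[which(is.na(start) | is.na(end))[1]],
                  "non-integer start or end")
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    stop_bad_line(path, idx[bad[1]],
                  sprintf("empty or inverted interval (start %d, end %d)",
                          start[bad[1]], end[bad[1]]))
  }
  getcol <- function(i) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else NA_character_, "")
  }
  name <- getcol(4)
  score <- suppressWarnings(as.numeric(getcol(5)))
  score[is.na(score)] <- 0
  strand <- getcol(6)
  strand[!strand %in% c("+", "-")] <- "*"
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = name, score = score, strand = strand)
}

#' Read aligned small-RNA reads from BED6
#'
#' Each BED record is one aligned read; `length` is `end - start`. The score
#' column, when a positive integer, is interpreted as the aligner's reported
#' number of genomic placements (`n_hits`); otherwise `n_hits` is 1.
#'
#' @param path Path to a BED file of aligned reads.
#' @param sample_id Library label attached to every read.
#' @param min_length,max_length Permitted read-length range; records outside
#'   it are an error (small-RNA libraries are size-selected to 15-36 nt).
#' @return A read tibble: `chrom`, `start`, `end`, `strand`, `length`,
#'   `n_hits`, `sample_id`.
#' @export
read_srna_bed <- function(path, sample_id = "sample", min_length = 15L, max_length = 36L) {
  bed <- read_bed(path)
  reads <- tibble::tibble(
    chrom = bed$chrom, start = bed$start, end = bed$end, strand = bed$strand,
    length = bed$end - bed$start,
    n_hits = ifelse(bed$score >= 1 & bed$score == floor(bed$score),
                    as.integer(bed$score), 1L),
    sample_id = sample_id
  )
  bad <- which(reads$length < min_length | reads$length > max_length)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "%s: %d read(s) outside the %d-%d nt length range (first at record %d, length %d)",
      path, length(bad), min_length, max_length, bad[1], reads$length[bad[1]]))
  }
  reads
}

#' Read genomic features from BED
#'
#' @param path BED file path.
#' @param feature_kind One of "gene", "TE", "miRNA", applied to all records.
#' @param subtype TE superfamily label (TE features only).
#' @return A feature tibble: `chrom`, `start`, `end`, `strand`,
#'   `feature_kind`, `subtype`, `has_introns`, `id`.
#' @export
read_feature_bed <- function(path, feature_kind = c("gene", "TE", "miRNA"),
                             subtype = "") {
  feature_kind <- match.arg(feature_kind)
  if (feature_kind == "TE" && !nzchar(subtype)) {
    rlang::abort("TE features require a nonempty superfamily `subtype`")
  }
  if (feature_kind != "TE") subtype <- ""
  bed <- read_bed(path)
  tibble::tibble(
    chrom = bed$chrom, start = bed$start, end = bed$end, strand = bed$strand,
    feature_kind = feature_kind, subtype = subtype,
    has_introns = NA,
    id = ifelse(is.na(bed$name), paste0(feature_kind, "_", seq_len(nrow(bed))), bed$name)
  )
}

#' Write an interval tibble as BED6
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end` plus `name`
#' (default "."), `score` (default 0) and `strand` ("*" written as ".").
#'
#' @param df Interval tibble (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  check_interval_cols(df, "BED output")
  name <- if ("name" %in% names(df)) ifelse(is.na(df$name), ".", df$name) else
    if ("id" %in% names(df)) df$id else rep(".", nrow(df))
  score <- if ("score" %in% names(df)) df$score else
    if ("n_hits" %in% names(df)) df$n_hits else rep(0, nrow(df))
  strand <- if ("strand" %in% names(df)) ifelse(df$strand %in% c("+", "-"), df$strand, ".")
    else rep(".", nrow(df))
  lines <- paste(df$chrom, df$start, df$end, name, score, strand, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
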