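#' Count reads per locus across samples
#'
#' A read counts toward the locus containing its 5' end (on the read's own
#' strand); reads outside every locus are uncounted. Loci must be
#' non-overlapping so each read has at most one home.
#'
#' @param reads Read tibble (multiple samples distinguished by `sample_id`).
#' @param loci Non-overlapping interval tibble; a `locus_id` column is used
#'   if present, else ids are generated from coordinates.
#' @return Wide tibble: `locus_id`, `chrom`, `start`, `end`, one count
#'   column per sample (zero-filled).
#' @export
locus_counts <- function(reads, loci) {
  check_nonoverlapping(loci, "loci")
  ids <- if ("locus_id" %in% names(loci)) loci$locus_id else
    sprintf("%s:%d-%d", loci$chrom, loci$start, loci$end)
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"
  samples <- unique(reads$sample_id)
  base <- tibble::tibble(locus_id = ids, chrom = loci$chrom,
                         start = loci$start, end = loci$end)
  if (nrow(reads) == 0 || nrow(loci) == 0) {
    for (s in samples) base[[s]] <- 0L
    return(base)
  }
  pos5 <- read_pos5(reads)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(pos5 + 1L, pos5 + 1L)),
    as_gr0(loci))
  counted <- tibble::tibble(
    locus_id = ids[S4Vectors::subjectHits(hits)],
    sample_id = reads$sample_id[S4Vectors::queryHits(hits)]) |>
    dplyr::count(.data$locus_id, .data$sample_id)
  wide <- tidyr::pivot_wider(counted, names_from = "sample_id",
                             values_from = "n", values_fill = 0L)
  out <- dplyr::left_join(base, wide, by = "locus_id")
  for (s in setdiff(samples, names(out))) out[[s]] <- 0L
  for (s in samples) out[[s]] <- dplyr::coalesce(out[[s]], 0L)
  out
}

#' Expression ratio between two samples
#'
#' The plain RPM quotient as printed in expression tables, rounded
#' half-away-from-zero to 3 decimals. A zero numerator gives 0 (printed
#' "0.000" in such tables); a zero denominator with positive numerator is
#' flagged infinite (`Inf`); 0/0 is undefined (`NA`).
#'
#' @param rpm_a,rpm_b Non-negative RPM values (vectorised).
#' @return Numeric vector of ratios.
#' @export
expression_ratio <- function(rpm_a, rpm_b) {
  if (any(rpm_a < 0 | rpm_b < 0)) rlang::abort("RPM values must be non-negative")
  out <- dplyr::case_when(
    rpm_a == 0 & rpm_b == 0 ~ NA_real_,
    rpm_a == 0 ~ 0,
    rpm_b == 0 ~ Inf,
    TRUE ~ rpm_a / rpm_b
  )
  ifelse(is.finite(out), round_half_up(out, 3), out)
}

#' Flag a fold-change of at least a threshold in either direction
#'
#' `TRUE` iff `max(a/b, b/a) >= threshold`. Zero against a positive value
#' counts as exceeding any threshold; zero against zero is `FALSE`.
#'
#' @param rpm_a,rpm_b Non-negative RPM values (vectorised).
#' @param threshold Fold-change threshold (default 10).
#' @return Logical vector.
#' @export
fold_flag <- function(rpm_a, rpm_b, threshold = 10) {
  if (any(rpm_a < 0 | rpm_b < 0)) rlang::abort("RPM values must be non-negative")
  dplyr::case_when(
    rpm_a == 0 & rpm_b == 0 ~ FALSE,
    rpm_a == 0 | rpm_b == 0 ~ TRUE,
    TRUE ~ pmax(rpm_a / rpm_b, rpm_b / rpm_a) >= threshold
  )
}

#' Pairwise sample correlation of a locus expression table
#'
#' Rank correlation by default: per-locus RPM distributions are heavy-tailed
#' (a few phasiRNA loci dominate), where Spearman is the robust choice;
#' Pearson is available. Constant columns have undefined correlation and
#' get `NA` against every other sample; the diagonal is always 1.
#'
#' @param x Wide locus table (numeric sample columns; non-numeric columns
#'   ignored) or a numeric matrix with >= 3 rows.
#' @param method "spearman" (default) or "pearson".
#' @return Symmetric correlation matrix with sample names.
#' @export
sample_correlation <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (is.data.frame(x)) {
    num <- x[, vapply(x, is.numeric, TRUE) &
               !names(x) %in% c("start", "end"), drop = FALSE]
    x <- as.matrix(num)
  }
  if (ncol(x) < 2) rlang::abort("need at least 2 samples")
  if (nrow(x) < 3) rlang::abort("need at least 3 loci")
  constant <- apply(x, 2, function(v) length(unique(v)) == 1)
  r <- suppressWarnings(stats::cor(x, method = method))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  r
}

#' M and A values for a two-sample comparison
#'
#' MA-plot coordinates with a pseudocount: `M = log2((a+pc)/(b+pc))` and
#' `A = 0.5 * log2((a+pc) * (b+pc))`.
#'
#' @param rpm_a,rpm_b Non-negative RPM values (vectorised).
#' @param pseudocount Added to both values before logging (default 1 RPM).
#' @return Tibble with columns `M` and `A`.
#' @export
ma_values <- function(rpm_a, rpm_b, pseudocount = 1) {
  if (any(rpm_a < 0 | rpm_b < 0)) rlang::abort("RPM values must be non-negative")
  a <- rpm_a + pseudocount
  b <- rpm_b + pseudocount
  tibble::tibble(M = log2(a / b), A = 0.5 * log2(a * b))
}
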