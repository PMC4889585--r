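#' Reads-per-million normalisation
#'
#' @param count Read count (vectorised).
#' @param total_aligned Total aligned reads in the library; must be positive.
#' @return `count * 1e6 / total_aligned`.
#' @export
rpm <- function(count, total_aligned) {
  if (length(total_aligned) != 1 || is.na(total_aligned) || total_aligned <= 0) {
    rlang::abort("`total_aligned` must be a single positive count")
  }
  if (any(count < 0)) rlang::abort("`count` must be non-negative")
  count * 1e6 / total_aligned
}

#' Alignment rate of a library, in percent
#'
#' @param aligned_reads,total_reads Read counts (vectorised).
#' @return `100 * aligned / total`, rounded half-away-from-zero to 2
#'   decimals (report precision; keep raw counts for further arithmetic).
#' @export
alignment_rate <- function(aligned_reads, total_reads) {
  if (any(total_reads <= 0)) rlang::abort("`total_reads` must be positive")
  if (any(aligned_reads > total_reads)) {
    rlang::abort("`aligned_reads` cannot exceed `total_reads`")
  }
  round_half_up(100 * aligned_reads / total_reads, 2)
}

#' Change between two rates, as percentage points and percent increase
#'
#' Distinguishes the two ways a rate change is commonly reported: the
#' absolute difference in percentage points and the relative increase in
#' percent of the starting rate.
#'
#' @param rate_a Starting rate (percent, > 0).
#' @param rate_b New rate (percent).
#' @return Tibble with columns `pp` (percentage points, `rate_b - rate_a`)
#'   and `pct_increase` (`100 * (rate_b - rate_a) / rate_a`), both rounded
#'   half-away-from-zero to 2 decimals.
#' @export
rate_change <- function(rate_a, rate_b) {
  if (any(rate_a <= 0)) rlang::abort("`rate_a` must be positive")
  tibble::tibble(
    pp = round_half_up(rate_b - rate_a, 2),
    pct_increase = round_half_up(100 * (rate_b - rate_a) / rate_a, 2)
  )
}

#' Read-length distribution of a library
#'
#' Counts reads per length and renormalises proportions within a reporting
#' window (default 20-25 nt, the size range where miRNAs and phasiRNAs
#' live). Lengths outside the window keep their counts but get `NA`
#' proportions.
#'
#' @param reads Read tibble (one row per aligned read, `length` column).
#' @param window Length-2 integer vector, inclusive reporting window.
#' @return A `size_distribution` tibble: `sample_id`, `length`, `count`,
#'   `proportion`.
#' @export
size_distribution <- function(reads, window = c(20L, 25L)) {
  if (nrow(reads) == 0) rlang::abort("`reads` is empty")
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"
  out <- reads |>
    dplyr::count(.data$sample_id, .data$length, name = "count") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      in_window = .data$length >= window[1] & .data$length <= window[2],
      proportion = dplyr::if_else(
        .data$in_window,
        .data$count / sum(.data$count[.data$in_window]),
        NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "length", "count", "proportion") |>
    dplyr::arrange(.data$sample_id, .data$length)
  class(out) <- c("size_distribution", class(out))
  out
}

#' Fraction of uniquely-mapping reads per library
#'
#' @param reads Read tibble with an `n_hits` column.
#' @return Tibble `sample_id`, `n_reads`, `n_unique`, `frac_unique`.
#' @export
uniqueness_summary <- function(reads) {
  if (nrow(reads) == 0) rlang::abort("`reads` is empty")
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"
  reads |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      n_unique = sum(.data$n_hits == 1L),
      frac_unique = .data$n_unique / .data$n_reads,
      .groups = "drop")
}

#' Binned genome-wide read-count track
#'
#' Assigns each read to the bin containing its 5' end (on the read's own
#' strand) and counts reads per fixed-width bin, optionally restricted to
#' given read lengths. With `seqlengths` supplied, all bins of each
#' chromosome are emitted (zeros included); otherwise bins run to the last
#' read.
#'
#' @param reads Read tibble.
#' @param bin_size Bin width in nt (>= 1).
#' @param lengths Optional integer vector of read lengths to keep.
#' @param seqlengths Optional named chromosome lengths.
#' @return Tibble `chrom`, `start`, `end`, `count`.
#' @export
binned_track <- function(reads, bin_size, lengths = NULL, seqlengths = NULL) {
  if (bin_size < 1) rlang::abort("`bin_size` must be >= 1")
  if (!is.null(lengths)) reads <- dplyr::filter(reads, .data$length %in% !!lengths)
  pos5 <- read_pos5(reads)
  counted <- tibble::tibble(chrom = reads$chrom,
                            start = (pos5 %/% bin_size) * bin_size) |>
    dplyr::count(.data$chrom, .data$start, name = "count")
  if (is.null(seqlengths)) {
    chroms <- unique(reads$chrom)
    seqlengths <- vapply(chroms, function(ch) {
      mx <- suppressWarnings(max(counted$start[counted$chrom == ch]))
      if (!is.finite(mx)) 0 else mx + bin_size
    }, numeric(1))
  }
  grid <- dplyr::bind_rows(lapply(names(seqlengths), function(ch) {
    starts <- seq(0L, max(0L, seqlengths[[ch]] - 1L), by = bin_size)
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + bin_size, seqlengths[[ch]]))
  }))
  grid |>
    dplyr::left_join(counted, by = c("chrom", "start")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(.data$chrom, .data$start)
}
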