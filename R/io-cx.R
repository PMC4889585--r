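#' Read a per-cytosine bisulfite report
#'
#' Consumes the Bismark-style CX report dialect: one tab-separated row per
#' cytosine with columns chrom, 1-based position, strand, methylated count,
#' unmethylated count, context (CG/CHG/CHH), trinucleotide. Positions are
#' shifted to the package-internal 0-based convention and
#' `count_total = count_meth + count_unmeth` is precomputed. Rows with
#' `count_total` 0 are retained: they carry no information and downstream
#' tiling ignores them, but they round-trip.
#'
#' @param path Path to a CX-style TSV.
#' @return A cytosine-call tibble: `chrom`, `pos` (0-based), `strand`,
#'   `context`, `count_meth`, `count_total`.
#' @export
read_cx_report <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "pos1", "strand", "count_meth", "count_unmeth",
                  "context", "tri"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos1 = readr::col_integer(),
      strand = readr::col_character(), count_meth = readr::col_integer(),
      count_unmeth = readr::col_integer(), context = readr::col_character(),
      tri = readr::col_character()),
    progress = FALSE
  )
  bad_ctx <- which(!df$context %in% c("CG", "CHG", "CHH"))
  if (length(bad_ctx) > 0) {
    stop_bad_line(path, bad_ctx[1],
                  sprintf("unknown cytosine context '%s'", df$context[bad_ctx[1]]))
  }
  bad_n <- which(df$count_meth < 0 | df$count_unmeth < 0 |
                   is.na(df$count_meth) | is.na(df$count_unmeth))
  if (length(bad_n) > 0) stop_bad_line(path, bad_n[1], "negative or missing count")
  tibble::tibble(
    chrom = df$chrom, pos = df$pos1 - 1L, strand = df$strand,
    context = df$context, count_meth = df$count_meth,
    count_total = df$count_meth + df$count_unmeth
  )
}

#' Write cytosine calls as a CX-style report
#'
#' Inverse of [read_cx_report()] (the trinucleotide column is written as the
#' context token; it is informational only and ignored on read).
#'
#' @param calls Cytosine-call tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(calls, path) {
  lines <- paste(calls$chrom, calls$pos + 1L, calls$strand, calls$count_meth,
                 calls$count_total - calls$count_meth, calls$context,
                 calls$context, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}
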