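#' Assign a methylation sequence context to cytosines
#'
#' Classifies each (position, strand) as CG, CHG or CHH by reading the two
#' bases 3' of the cytosine on its own strand (H = A, C or T): next base G
#' gives CG, otherwise next-next base G gives CHG, otherwise CHH. On the
#' minus strand the rule is evaluated on the reverse complement. Cytosines
#' within 2 nt of a chromosome end that lack the full lookahead default to
#' CHH (an undetermined H): any non-G (including N or "past the end")
#' continues the H branch.
#'
#' @param genome A named `DNAStringSet` (see [read_genome()]).
#' @param chrom,pos,strand Parallel vectors: chromosome, 0-based position of
#'   the cytosine, strand ("+" or "-").
#' @return Character vector of contexts ("CG", "CHG", "CHH").
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  out <- character(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (!ch %in% names(genome)) rlang::abort(sprintf("chromosome '%s' not in genome", ch))
    s <- genome[[ch]]
    L <- length(s)
    p <- pos[sel]; st <- strand[sel]
    if (any(p < 0 | p >= L)) rlang::abort("position outside chromosome")
    base <- as.character(Biostrings::extractAt(s, IRanges::IRanges(p + 1L, p + 1L)))
    sense_c <- ifelse(st == "-", base == "G", base == "C")
    if (!all(sense_c)) {
      i <- which(!sense_c)[1]
      rlang::abort(sprintf(
        "base at %s:%d (%s) is not a cytosine on that strand (plus-strand base '%s')",
        ch, p[i], st[i], base[i]))
    }
    get_base <- function(at) {
      ok <- at >= 0L & at < L
      b <- rep("N", length(at))
      if (any(ok)) {
        b[ok] <- as.character(Biostrings::extractAt(
          s, IRanges::IRanges(at[ok] + 1L, at[ok] + 1L)))
      }
      b
    }
    plus <- st != "-"
    b1 <- character(sum(sel)); b2 <- character(sum(sel))
    b1[plus] <- get_base(p[plus] + 1L)
    b2[plus] <- get_base(p[plus] + 2L)
    # minus strand: next base 3' is plus-position pos-1, complemented
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    b1[!plus] <- comp[get_base(p[!plus] - 1L)]
    b2[!plus] <- comp[get_base(p[!plus] - 2L)]
    out[sel] <- ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH"))
  }
  out
}

#' Enumerate every cytosine in a genome with its context
#'
#' Finds all cytosines on both strands (C on plus, G on plus = C on minus)
#' and assigns contexts in bulk. This is the engine behind methylome
#' simulation and context bookkeeping.
#'
#' @param genome A named `DNAStringSet`.
#' @return Tibble `chrom`, `pos` (0-based), `strand`, `context`, sorted by
#'   chromosome and position.
#' @export
cytosine_contexts <- function(genome) {
  res <- vector("list", 2L * length(genome))
  k <- 0L
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- length(s)
    padded <- Biostrings::xscat(Biostrings::DNAString("NN"), s,
                                Biostrings::DNAString("NN"))
    # plus strand Cs: trinucleotide at pos..pos+2 (padded offset +2)
    cpos <- Biostrings::start(Biostrings::matchPattern("C", s))  # 1-based
    if (length(cpos) > 0) {
      tri <- as.character(Biostrings::extractAt(
        padded, IRanges::IRanges(cpos + 2L, cpos + 4L)))
      b1 <- substr(tri, 2L, 2L); b2 <- substr(tri, 3L, 3L)
      k <- k + 1L
      res[[k]] <- tibble::tibble(
        chrom = ch, pos = cpos - 1L, strand = "+",
        context = ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH")))
    }
    # minus strand Cs sit at plus-strand Gs; read pos, pos-1, pos-2 complemented
    gpos <- Biostrings::start(Biostrings::matchPattern("G", s))
    if (length(gpos) > 0) {
      tri_fwd <- Biostrings::extractAt(padded, IRanges::IRanges(gpos, gpos + 2L))
      tri <- as.character(Biostrings::reverseComplement(
        methods::as(tri_fwd, "DNAStringSet")))
      b1 <- substr(tri, 2L, 2L); b2 <- substr(tri, 3L, 3L)
      k <- k + 1L
      res[[k]] <- tibble::tibble(
        chrom = ch, pos = gpos - 1L, strand = "-",
        context = ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH")))
    }
  }
  dplyr::arrange(dplyr::bind_rows(res[seq_len(k)]), .data$chrom, .data$pos)
}

#' Aggregate cytosine calls into fixed-width methylation tiles
#'
#' Tiles are anchored at position 0 of each chromosome (0, 100, 200, ... for
#' the default width) and strands are merged within a context. The tile value
#' is the coverage-weighted percentage 100 * sum(meth) / sum(total) over
#' covered cytosines (`count_total > 0`); `site_mean = TRUE` instead averages
#' per-site percentages. Tiles containing no covered cytosine of a context do
#' not appear in the output: absence of information is absence of a row,
#' never 0%.
#'
#' @param calls Cytosine-call tibble (see [read_cx_report()]).
#' @param tile Tile width in nt.
#' @param site_mean Use the unweighted mean of per-site percentages.
#' @return Tibble `chrom`, `start`, `end`, `context`, `n_sites`,
#'   `count_meth`, `count_total`, `percent`.
#' @export
tile_methylation <- function(calls, tile = 100L, site_mean = FALSE) {
  stopifnot(tile >= 1)
  covered <- dplyr::filter(calls, .data$count_total > 0)
  out <- covered |>
    dplyr::mutate(start = (.data$pos %/% tile) * tile) |>
    dplyr::group_by(.data$chrom, .data$start, .data$context) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      percent_site = mean(100 * .data$count_meth / .data$count_total),
      count_meth = sum(.data$count_meth),
      count_total = sum(.data$count_total),
      .groups = "drop") |>
    dplyr::mutate(
      end = .data$start + tile,
      percent = if (site_mean) .data$percent_site
                else 100 * .data$count_meth / .data$count_total) |>
    dplyr::select("chrom", "start", "end", "context", "n_sites",
                  "count_meth", "count_total", "percent") |>
    dplyr::arrange(.data$chrom, .data$start, .data$context)
  out
}

#' Write one context's methylation tiles as BED4
#'
#' When `seqlengths` is supplied, every tile of each chromosome is written
#' and uncovered tiles get "." in the value column; on read those rows are
#' skipped, so missing stays missing rather than becoming 0%.
#'
#' @param tiles Output of [tile_methylation()].
#' @param path Output path.
#' @param context Context to write (one of CG, CHG, CHH).
#' @param seqlengths Named vector of chromosome lengths, or NULL to write
#'   only covered tiles.
#' @param tile Tile width (must match the tiling).
#' @return `path`, invisibly.
#' @export
write_tile_bed <- function(tiles, path, context, seqlengths = NULL, tile = 100L) {
  sub <- dplyr::filter(tiles, .data$context == !!context)
  if (is.null(seqlengths)) {
    lines <- paste(sub$chrom, sub$start, sub$end,
                   formatC(sub$percent, format = "f", digits = 6), sep = "\t")
  } else {
    full <- dplyr::bind_rows(lapply(names(seqlengths), function(ch) {
      starts <- seq(0L, seqlengths[[ch]] - 1L, by = tile)
      tibble::tibble(chrom = ch, start = starts,
                     end = pmin(starts + tile, seqlengths[[ch]]))
    }))
    full <- dplyr::left_join(full, sub[, c("chrom", "start", "percent")],
                             by = c("chrom", "start"))
    lines <- paste(full$chrom, full$start, full$end,
                   ifelse(is.na(full$percent), ".",
                          formatC(full$percent, format = "f", digits = 6)),
                   sep = "\t")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a methylation tile BED4, skipping missing tiles
#'
#' @param path BED4 path as written by [write_tile_bed()].
#' @param context Context label to attach.
#' @return Tibble `chrom`, `start`, `end`, `context`, `percent` with "."
#'   rows removed.
#' @export
read_tile_bed <- function(path, context) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciic", progress = FALSE)
  df <- df[df$value != ".", ]
  tibble::tibble(chrom = df$chrom, start = df$start, end = df$end,
                 context = context, percent = as.numeric(df$value))
}
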