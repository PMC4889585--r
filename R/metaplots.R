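#' Anchored methylation metaprofile over a locus set
#'
#' Aligns all loci at a common anchor (the locus start by default; "0" on
#' the offset axis) and averages the 100-bp methylation tile values of one
#' context at each offset bin from `-flank` to `+flank`. A locus contributes
#' to a bin only if the tile under that genomic position exists, i.e. holds
#' at least one covered cytosine of the context: tiles without information
#' are ignored, never treated as 0%. Loci are treated as unstranded —
#' phasiRNA loci are double-stranded products.
#'
#' @param loci Interval tibble of loci (nonempty).
#' @param tiles Tile tibble from [tile_methylation()].
#' @param flank Flank width in nt on each side (a multiple of `tile_width`).
#' @param context Methylation context to profile (CG, CHG or CHH).
#' @param tile_width Width of the tiles in `tiles`.
#' @param anchor "start" (default) or "mid" of each locus.
#' @return A `meta_profile` tibble: `offset`, `value` (mean percent,
#'   0-100), `n_contrib`, `kind` = "methylation", `label` = context.
#' @export
methylation_profile <- function(loci, tiles, flank = 2000L, context = "CHH",
                                tile_width = 100L, anchor = c("start", "mid")) {
  anchor <- match.arg(anchor)
  if (nrow(loci) == 0) rlang::abort("`loci` is empty")
  if (flank %% tile_width != 0) rlang::abort("`flank` must be a multiple of `tile_width`")
  anchors <- locus_anchor(loci, anchor)
  offsets <- seq(-flank, flank, by = tile_width)
  sub <- dplyr::filter(tiles, .data$context == !!context)
  grid <- tidyr::expand_grid(locus = seq_len(nrow(loci)), offset = offsets)
  grid$chrom <- loci$chrom[grid$locus]
  pos <- anchors[grid$locus] + grid$offset
  grid$tile_start <- (pos %/% tile_width) * tile_width
  grid <- dplyr::left_join(
    grid, sub[, c("chrom", "start", "percent")],
    by = c("chrom", "tile_start" = "start"))
  out <- grid |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(value = mean(.data$percent, na.rm = TRUE),
                     n_contrib = sum(!is.na(.data$percent)),
                     .groups = "drop") |>
    dplyr::mutate(value = ifelse(.data$n_contrib == 0, NA_real_, .data$value),
                  kind = "methylation", label = context)
  new_meta_profile(out)
}

#' Anchored feature-presence metaprofile (coverage plot)
#'
#' At nucleotide resolution: for each offset from `-flank` to `+flank`
#' relative to the locus anchor, the value is the percentage of loci whose
#' genome position at that offset lies inside at least one feature of the
#' queried kind. If 100 loci are profiled and 80 overlap a gene at their
#' anchor, the value at offset 0 is 80; it decays with distance as feature
#' and locus lengths vary.
#'
#' @param loci Interval tibble of loci.
#' @param features Feature tibble.
#' @param flank Flank width in nt on each side.
#' @param kind Restrict to one `feature_kind` (gene/TE/miRNA); NULL = all.
#' @param subtype Restrict TEs to one superfamily.
#' @param has_introns Restrict genes to intron-containing (TRUE) or
#'   intronless (FALSE) genes.
#' @param seqlengths Optional named chromosome lengths; positions outside a
#'   chromosome are dropped from the denominator (`n_contrib` decremented).
#' @param anchor "start" or "mid".
#' @return A `meta_profile` tibble (`kind` = "presence", values 0-100).
#' @export
presence_profile <- function(loci, features, flank = 2000L, kind = NULL,
                             subtype = NULL, has_introns = NULL,
                             seqlengths = NULL, anchor = c("start", "mid")) {
  anchor <- match.arg(anchor)
  if (nrow(loci) == 0) rlang::abort("`loci` is empty")
  feats <- features
  if (!is.null(kind)) feats <- dplyr::filter(feats, .data$feature_kind == !!kind)
  if (!is.null(subtype)) feats <- dplyr::filter(feats, .data$subtype == !!subtype)
  if (!is.null(has_introns)) feats <- dplyr::filter(feats, .data$has_introns == !!has_introns)
  anchors <- locus_anchor(loci, anchor)
  offsets <- seq(-flank, flank)
  n_off <- length(offsets)
  presence_sum <- numeric(n_off)
  contrib <- integer(n_off)
  # per-chromosome 0/1 coverage vectors, long enough for every query
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    f <- feats[feats$chrom == ch, , drop = FALSE]
    max_need <- max(anchors[li]) + flank + 1L
    covlen <- if (!is.null(seqlengths) && ch %in% names(seqlengths))
      seqlengths[[ch]] else max(max_need, if (nrow(f)) max(f$end) else 0L)
    covvec <- integer(max(covlen, 1L))
    if (nrow(f) > 0) {
      red <- IRanges::reduce(IRanges::IRanges(f$start + 1L, pmin(f$end, covlen)))
      for (j in seq_along(red)) {
        covvec[IRanges::start(red)[j]:IRanges::end(red)[j]] <- 1L
      }
    }
    for (i in li) {
      pos <- anchors[i] + offsets  # 0-based
      ok <- pos >= 0L & pos < covlen
      if (!is.null(seqlengths) && ch %in% names(seqlengths)) {
        # out-of-chromosome offsets drop out of the denominator
        contrib[ok] <- contrib[ok] + 1L
        presence_sum[ok] <- presence_sum[ok] + covvec[pos[ok] + 1L]
      } else {
        contrib <- contrib + 1L
        presence_sum[ok] <- presence_sum[ok] + covvec[pos[ok] + 1L]
      }
    }
  }
  out <- tibble::tibble(
    offset = offsets,
    value = ifelse(contrib == 0, NA_real_, 100 * presence_sum / contrib),
    n_contrib = contrib,
    kind = "presence",
    label = kind %||% "any")
  new_meta_profile(out)
}

#' Anchored GC-content metaprofile
#'
#' Mean GC fraction (in percent) over loci, in fixed-width windows at each
#' offset bin around the anchor. N bases are excluded from the denominator;
#' windows extending beyond a chromosome are skipped for that locus with
#' `n_contrib` decremented.
#'
#' @param loci Interval tibble of loci.
#' @param genome Named `DNAStringSet`.
#' @param flank Flank width in nt (a multiple of `window`).
#' @param window Window width per offset bin.
#' @param anchor "start" or "mid".
#' @return A `meta_profile` tibble (`kind` = "gc", values 0-100).
#' @export
gc_profile <- function(loci, genome, flank = 2000L, window = 100L,
                       anchor = c("start", "mid")) {
  anchor <- match.arg(anchor)
  if (nrow(loci) == 0) rlang::abort("`loci` is empty")
  if (flank %% window != 0) rlang::abort("`flank` must be a multiple of `window`")
  anchors <- locus_anchor(loci, anchor)
  offsets <- seq(-flank, flank, by = window)
  n_off <- length(offsets)
  gc_sum <- numeric(n_off); contrib <- integer(n_off)
  for (ch in unique(loci$chrom)) {
    if (!ch %in% names(genome)) rlang::abort(sprintf("chromosome '%s' not in genome", ch))
    s <- genome[[ch]]
    L <- length(s)
    for (i in which(loci$chrom == ch)) {
      starts <- anchors[i] + offsets           # 0-based window starts
      ok <- starts >= 0L & (starts + window) <= L
      if (!any(ok)) next
      v <- Biostrings::Views(s, start = starts[ok] + 1L, width = window)
      freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "N"))
      denom <- window - freq[, "N"]
      gcv <- ifelse(denom > 0, (freq[, "G"] + freq[, "C"]) / denom, NA_real_)
      has <- !is.na(gcv)
      idx <- which(ok)[has]
      gc_sum[idx] <- gc_sum[idx] + gcv[has]
      contrib[idx] <- contrib[idx] + 1L
    }
  }
  out <- tibble::tibble(
    offset = offsets,
    value = ifelse(contrib == 0, NA_real_, 100 * gc_sum / pmax(contrib, 1L)),
    n_contrib = contrib,
    kind = "gc", label = "GC")
  new_meta_profile(out)
}

locus_anchor <- function(loci, anchor) {
  if (anchor == "mid") (loci$start + loci$end) %/% 2L else loci$start
}

new_meta_profile <- function(df) {
  class(df) <- unique(c("meta_profile", class(df)))
  df
}

#' @method autoplot meta_profile
#' @export
autoplot.meta_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "offset from locus anchor (nt)",
      y = switch(object$kind[1],
                 methylation = paste0(object$label[1], " methylation (%)"),
                 presence = paste0(object$label[1], " presence (%)"),
                 gc = "GC content (%)",
                 "value")) +
    ggplot2::theme_minimal()
}
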