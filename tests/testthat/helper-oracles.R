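# Fixture builders and independent brute-force oracles used across tests.

make_reads <- function(start, length = 21L, chrom = "chr1", strand = "+",
                       n_hits = 1L, sample_id = "s1") {
  tibble::tibble(
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + length),
    strand = strand, length = as.integer(length),
    n_hits = as.integer(n_hits), sample_id = sample_id)
}

make_features <- function(start, end, feature_kind = "gene", chrom = "chr1",
                          strand = "+", subtype = "", has_introns = NA,
                          id = NULL) {
  n <- length(start)
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = strand, feature_kind = feature_kind, subtype = subtype,
    has_introns = has_introns,
    id = id %||% paste0(feature_kind, seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) pairwise-merge cluster oracle. Repeated pairwise merging at
# gap <= max_gap is the transitive closure of the pairwise within-gap
# relation (the gap from a read to a merged cluster is the minimum gap to
# any member), so connected components of the all-pairs gap matrix give the
# fixpoint directly.
brute_force_clusters <- function(reads, max_gap = 100L) {
  res <- list()
  for (ch in sort(unique(reads$chrom))) {
    iv <- reads[reads$chrom == ch, c("start", "end")]
    n <- nrow(iv)
    d <- outer(iv$start, iv$end, "-")
    adj <- pmax(d, t(d)) <= max_gap   # interval gap (negative = overlap)
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (!is.na(comp[i])) next
      cid <- cid + 1L
      frontier <- i
      comp[i] <- cid
      while (length(frontier) > 0) {
        nb <- which(is.na(comp) &
                      colSums(adj[frontier, , drop = FALSE]) > 0)
        comp[nb] <- cid
        frontier <- nb
      }
    }
    res[[ch]] <- tibble::tibble(
      chrom = ch,
      start = as.integer(tapply(iv$start, comp, min)),
      end = as.integer(tapply(iv$end, comp, max)))
  }
  out <- dplyr::bind_rows(res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Character-level two-strand context scan on a plain string (0-based pos).
brute_force_context <- function(seq_string, pos, strand) {
  n <- nchar(seq_string)
  at <- function(p) ifelse(p >= 0 & p < n, substring(seq_string, p + 1, p + 1), "N")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b1 <- ifelse(strand == "+", at(pos + 1), comp[at(pos - 1)])
  b2 <- ifelse(strand == "+", at(pos + 2), comp[at(pos - 2)])
  unname(ifelse(b1 == "G", "CG", ifelse(b2 == "G", "CHG", "CHH")))
}

# All cytosines of a plain string on both strands, brute force.
brute_force_all_contexts <- function(seq_string) {
  chars <- strsplit(seq_string, "")[[1]]
  cpos <- which(chars == "C") - 1L
  gpos <- which(chars == "G") - 1L
  tibble::tibble(
    pos = c(cpos, gpos),
    strand = rep(c("+", "-"), c(length(cpos), length(gpos))),
    context = c(brute_force_context(seq_string, cpos, rep("+", length(cpos))),
                brute_force_context(seq_string, gpos, rep("-", length(gpos)))))
}

# Exhaustive hypergeometric tail by direct combinatorial summation,
# independent of stats::phyper.
enum_hyper_tail <- function(k, N, m, n) {
  js <- seq(k, min(m, n))
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# Per-locus, per-nucleotide membership scan: the presence-profile oracle.
brute_force_presence <- function(loci, features, flank) {
  offsets <- seq(-flank, flank)
  vals <- sapply(offsets, function(o) {
    hit <- vapply(seq_len(nrow(loci)), function(i) {
      p <- loci$start[i] + o
      any(features$chrom == loci$chrom[i] & features$start <= p & p < features$end)
    }, logical(1))
    100 * mean(hit)
  })
  tibble::tibble(offset = offsets, value = vals)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}
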