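# Assembly summary statistics: N50, GC content, length distribution.

#' N50 of a set of contig lengths
#'
#' Sorts descending and returns the first length at which the cumulative
#' sum reaches at least half the total.
#'
#' @param lengths Non-empty vector of positive integer lengths.
#' @return N50 in bp (always one of `lengths`).
#' @export
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("n50: empty length vector")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' GC fraction of nucleotide sequences
#'
#' `(#G + #C) / (#A + #C + #G + #T)`, pooled over all sequences; `N`
#' bases are excluded from the denominator.
#'
#' @param sequences Character vector of nucleotide sequences.
#' @return GC fraction in `[0, 1]`.
#' @export
#' @examples
#' gc_content("ANGC")  # 2/3
gc_content <- function(sequences) {
  if (length(sequences) == 0L) stop("gc_content: no sequences")
  bases <- unlist(strsplit(sequences, "", fixed = TRUE))
  counted <- bases[bases %in% c("A", "C", "G", "T")]
  if (length(counted) == 0L) stop("gc_content: no countable (ACGT) bases")
  sum(counted %in% c("G", "C")) / length(counted)
}

#' Contig length histogram with fixed-width bins
#'
#' Bins of width `width` starting at `from`; lengths below `from` fall in
#' an initial underflow bin and the last bin is extended to the maximum.
#'
#' @param lengths Vector of contig lengths.
#' @param from First regular bin edge (bp).
#' @param width Bin width (bp).
#' @return Tibble `bin_low`, `bin_high`, `count` (`[bin_low, bin_high)`).
#' @export
length_histogram <- function(lengths, from = 200L, width = 100L) {
  top <- if (length(lengths)) max(lengths, from) else from
  edges <- c(0L, seq(from, width * (top %/% width + 1L), by = width))
  counts <- vapply(seq_len(length(edges) - 1L), function(i) {
    sum(lengths >= edges[i] & lengths < edges[i + 1L])
  }, integer(1))
  tibble::tibble(bin_low = edges[-length(edges)], bin_high = edges[-1],
                 count = counts)
}

#' Assembly summary statistics
#'
#' @param contigs Contig tibble (`id`, `seq`) or FASTA path.
#' @return Object of class `assembly_stats`: one-row tibble with
#'   `n_contigs`, `total_bp`, `gc_fraction`, `mean_len`, `sd_len`, `n50`;
#'   the contig length histogram ([length_histogram()]) is attached as
#'   attribute `"histogram"`.
#' @export
assembly_stats <- function(contigs) {
  if (is.character(contigs) && length(contigs) == 1L) {
    contigs <- read_fasta(contigs, type = "dna")
  }
  if (nrow(contigs) == 0L) stop("assembly_stats: no contigs")
  lens <- nchar(contigs$seq)
  out <- tibble::tibble(
    n_contigs = nrow(contigs),
    total_bp = sum(lens),
    gc_fraction = gc_content(contigs$seq),
    mean_len = mean(lens),
    sd_len = if (length(lens) > 1L) sd(lens) else NA_real_,
    n50 = n50(lens)
  )
  attr(out, "histogram") <- length_histogram(lens)
  class(out) <- c("assembly_stats", class(out))
  out
}
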