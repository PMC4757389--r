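# Digital normalization by median k-mer coverage.
#
# A single streaming pass: each read's canonical k-mers are looked up in
# an exact hash counter; if the median of their current counts is below
# the coverage cutoff the read is retained and its k-mers incremented,
# otherwise it is discarded without incrementing. This is the
# normalize-by-median procedure with exact (non-probabilistic) counting.

#' Canonical k-mers of a sequence
#'
#' Returns the `length - k + 1` k-mers in order, each replaced by the
#' lexicographic minimum of itself and its reverse complement; k-mers
#' containing `N` are skipped.
#'
#' @param sequence Nucleotide string.
#' @param k K-mer length (>= 1).
#' @return Character vector of canonical k-mers (possibly empty).
#' @export
#' @examples
#' canonical_kmers("TTTT", 4)  # "AAAA"
canonical_kmers <- function(sequence, k = 20L) {
  stopifnot(k >= 1L)
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0L) return(character(0))
  pmin(kmers, revcomp(kmers))
}

#' Normalize reads by median k-mer coverage
#'
#' @param reads Read tibble (`id`, `seq`, `qual`) or FASTQ path.
#' @param k K-mer length.
#' @param cutoff Coverage cutoff: a read is retained iff the median of its
#'   canonical k-mer counts (lower-middle for even counts) is `< cutoff`.
#' @param drop_short Discard reads shorter than `k` (distinct reason); if
#'   `FALSE` such reads are retained unconditionally.
#' @return Object of class `diginorm_result`: list with `reads` (retained
#'   subsequence of the input) and `report` (one-row tibble: `n_input`,
#'   `n_kept`, `n_discarded_high_coverage`, `n_discarded_too_short`,
#'   `n_distinct_kmers`).
#' @export
normalize_by_median <- function(reads, k = 20L, cutoff = 20L,
                                drop_short = TRUE) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  check_reads(reads)
  stopifnot(k >= 1L, cutoff >= 1L)
  counts <- new.env(parent = emptyenv())
  keep <- logical(nrow(reads))
  too_short <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    km <- canonical_kmers(reads$seq[i], k)
    if (length(km) == 0L) {
      too_short[i] <- TRUE
      keep[i] <- !drop_short
      next
    }
    cur <- unlist(mget(km, envir = counts, ifnotfound = 0L), use.names = FALSE)
    if (median_lower(cur) < cutoff) {
      keep[i] <- TRUE
      tab <- table(km)
      nm <- names(tab)
      prev <- unlist(mget(nm, envir = counts, ifnotfound = 0L), use.names = FALSE)
      for (j in seq_along(nm)) {
        assign(nm[j], prev[j] + as.integer(tab[[j]]), envir = counts)
      }
    }
  }
  report <- tibble::tibble(
    n_input = nrow(reads),
    n_kept = sum(keep),
    n_discarded_high_coverage = sum(!keep & !too_short),
    n_discarded_too_short = sum(too_short & !keep),
    n_distinct_kmers = length(ls(counts))
  )
  structure(list(reads = reads[keep, , drop = FALSE], report = report),
            class = "diginorm_result")
}

#' @export
print.diginorm_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<diginorm_result> %d reads in; %d kept; %d high-coverage, %d too short; %d distinct k-mers\n",
    r$n_input, r$n_kept, r$n_discarded_high_coverage,
    r$n_discarded_too_short, r$n_distinct_kmers))
  invisible(x)
}

#' Glance at a digital-normalization result
#'
#' @param x A `diginorm_result`.
#' @param ... Unused.
#' @return One-row tibble of retention counts.
#' @method glance diginorm_result
#' @export
glance.diginorm_result <- function(x, ...) x$report

#' Tidy a digital-normalization result
#'
#' @param x A `diginorm_result`.
#' @param ... Unused.
#' @return The retained read tibble.
#' @method tidy diginorm_result
#' @export
tidy.diginorm_result <- function(x, ...) x$reads
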