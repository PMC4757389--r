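# Read QC: adapter removal, quality end-trimming, and read filtering.
#
# The rules re-express the study's trimming step as explicit computation:
# 3' adapter removal, then trimming of terminal bases below Q20, then
# discarding reads shorter than 35 bp or with mean phred below 20.

#' Trim a 3' adapter from reads
#'
#' Scans 5'→3' for the first position where the remainder of the read
#' matches a prefix of the adapter over at least `min_overlap` bases with
#' a mismatch fraction at most `mismatch_rate`; that segment and
#' everything 3' of it are removed (qualities in lockstep). `N` bases
#' count as mismatches. Reads with no qualifying match are unchanged.
#'
#' @param reads Read tibble (`id`, `seq`, `qual`).
#' @param adapter Non-empty adapter sequence.
#' @param min_overlap Minimum read/adapter overlap in bases.
#' @param mismatch_rate Maximum allowed mismatch fraction in the overlap.
#' @return Read tibble with trimmed `seq`/`qual`.
#' @export
trim_adapter <- function(reads, adapter = DEFAULT_ADAPTER, min_overlap = 8L,
                         mismatch_rate = 0.125) {
  check_reads(reads)
  stopifnot(nchar(adapter) >= 1L)
  cut <- vapply(reads$seq, adapter_cut_position, integer(1),
                adapter = adapter, min_overlap = min_overlap,
                mismatch_rate = mismatch_rate, USE.NAMES = FALSE)
  keep_len <- ifelse(cut == 0L, nchar(reads$seq), cut - 1L)
  dplyr::mutate(reads,
    seq = substring(.data$seq, 1L, keep_len),
    qual = substring(.data$qual, 1L, keep_len)
  )
}

# First position p at which read[p..] matches a prefix of the adapter
# within the mismatch budget (0 = no match). Overlap is capped at the
# adapter length; a full-adapter match mid-read also trims everything 3'.
adapter_cut_position <- function(seq, adapter, min_overlap, mismatch_rate) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  if (n < min_overlap) return(0L)
  for (p in seq_len(n - min_overlap + 1L)) {
    o <- min(n - p + 1L, alen)
    mism <- count_mismatches(substring(seq, p, p + o - 1L),
                             substring(adapter, 1L, o))
    if (mism <= mismatch_rate * o) return(p)
  }
  0L
}

#' Trim low-quality bases from read ends
#'
#' Removes the maximal leading and trailing runs of bases with phred
#' quality below `q_min`; interior bases are untouched. A read whose
#' bases are all below `q_min` becomes empty.
#'
#' @param reads Read tibble.
#' @param q_min Minimum phred score kept at the ends.
#' @return Read tibble with trimmed `seq`/`qual`.
#' @export
quality_trim_ends <- function(reads, q_min = 20L) {
  check_reads(reads)
  bounds <- purrr::map(reads$qual, function(qs) {
    q <- string_to_phred(qs)
    ok <- which(q >= q_min)
    if (length(ok) == 0L) c(1L, 0L) else c(ok[1], ok[length(ok)])
  })
  from <- purrr::map_int(bounds, 1L)
  to <- purrr::map_int(bounds, 2L)
  dplyr::mutate(reads,
    seq = substring(.data$seq, from, to),
    qual = substring(.data$qual, from, to)
  )
}

#' Keep/discard decision for end-trimmed reads
#'
#' A read is discarded with reason `"length"` if shorter than `len_min`,
#' else with reason `"quality"` if its mean phred is below `q_mean_min`;
#' otherwise kept (reason `"keep"`).
#'
#' @param reads Read tibble (already end-trimmed).
#' @param q_mean_min Minimum mean phred score.
#' @param len_min Minimum read length in bp.
#' @return The tibble with a `qc_reason` column.
#' @export
filter_read <- function(reads, q_mean_min = 20, len_min = 35L) {
  check_reads(reads)
  mean_q <- purrr::map_dbl(reads$qual, function(qs) {
    q <- string_to_phred(qs)
    if (length(q) == 0L) 0 else mean(q)
  })
  dplyr::mutate(reads, qc_reason = dplyr::case_when(
    nchar(.data$seq) < len_min ~ "length",
    mean_q < q_mean_min ~ "quality",
    TRUE ~ "keep"
  ))
}

#' Run the full read-QC stage
#'
#' Applies, in order: adapter trimming, quality end-trimming, and the
#' length/mean-quality read filter. Read order is preserved.
#'
#' @param reads Read tibble (`id`, `seq`, `qual`) or path to a FASTQ file.
#' @param adapter Adapter sequence (`NULL` skips adapter trimming).
#' @param q_min End-trim quality threshold.
#' @param q_mean_min Mean-quality filter threshold.
#' @param len_min Minimum retained read length (bp).
#' @param min_overlap,mismatch_rate Adapter-matching parameters.
#' @return Object of class `qc_result`: list with `reads` (retained read
#'   tibble) and `report` (one-row tibble; see [glance.qc_result()]).
#' @export
run_qc <- function(reads, adapter = DEFAULT_ADAPTER, q_min = 20L,
                   q_mean_min = 20, len_min = 35L, min_overlap = 8L,
                   mismatch_rate = 0.125) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  check_reads(reads)
  n_input <- nrow(reads)
  trimmed <- reads
  if (!is.null(adapter)) {
    trimmed <- trim_adapter(trimmed, adapter, min_overlap, mismatch_rate)
  }
  trimmed <- quality_trim_ends(trimmed, q_min)
  flagged <- filter_read(trimmed, q_mean_min, len_min)
  retained <- dplyr::select(dplyr::filter(flagged, .data$qc_reason == "keep"),
                            -"qc_reason")
  lens <- nchar(retained$seq)
  base_q <- unlist(purrr::map(retained$qual, string_to_phred))
  bases <- unlist(strsplit(retained$seq, "", fixed = TRUE))
  acgt <- bases[bases != "N"]
  report <- tibble::tibble(
    n_input = n_input,
    n_discarded_length = sum(flagged$qc_reason == "length"),
    n_discarded_quality = sum(flagged$qc_reason == "quality"),
    n_retained = nrow(retained),
    retained_fraction = if (n_input == 0L) 1 else nrow(retained) / n_input,
    mean_retained_length = if (length(lens)) mean(lens) else NA_real_,
    sd_retained_length = if (length(lens) > 1L) sd(lens) else NA_real_,
    frac_bases_q30 = if (length(base_q)) mean(base_q >= 30L) else NA_real_,
    gc_fraction = if (length(acgt)) mean(acgt %in% c("G", "C")) else NA_real_
  )
  structure(list(reads = retained, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<qc_result> %d reads in; %d retained (%.1f%%); discarded: %d length, %d quality\n",
    r$n_input, r$n_retained, 100 * r$retained_fraction,
    r$n_discarded_length, r$n_discarded_quality))
  invisible(x)
}

#' Glance at a QC result
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return One-row tibble of QC summary statistics.
#' @method glance qc_result
#' @export
glance.qc_result <- function(x, ...) x$report

#' Tidy a QC result
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return The retained read tibble.
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) x$reads
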