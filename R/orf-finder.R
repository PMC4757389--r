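# Six-frame ORF extraction with a minimum protein length.
#
# An ORF is a maximal stop-free stretch in one of the six reading frames
# (not ATG-anchored, so 5'-partial coding regions on truncated contigs
# are admitted); `require_start` optionally anchors each stretch at its
# first Met. Coordinates are 0-based half-open on the forward strand and
# cover the protein codons only (never the stop codon).

#' Translate one reading frame of a nucleotide sequence
#'
#' Standard genetic code; stop codons render as `"*"`; codons containing
#' any non-`ACGT` base render as `"X"`. A trailing partial codon is
#' ignored.
#'
#' @param nt Nucleotide string.
#' @param frame Frame offset 0, 1 or 2.
#' @param strand `"+"` (as given) or `"-"` (reverse complement first).
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_frame("ATGAAATAA")  # "MK*"
translate_frame <- function(nt, frame = 0L, strand = "+") {
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") nt <- revcomp(nt)
  n <- nchar(nt)
  if (n - frame < 3L) return("")
  starts <- seq(frame + 1L, n - 2L, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find ORFs in contigs
#'
#' Evaluates every maximal stop-free stretch in all six frames and emits
#' those whose protein is at least `min_aa` residues. `has_start` is
#' `TRUE` when the stretch is preceded by a stop codon in its frame (or,
#' under `require_start`, begins at Met); `has_stop` when it is terminated
#' by a stop codon rather than the contig end.
#'
#' @param contigs Tibble with `id`, `seq` columns (or a single sequence
#'   string).
#' @param min_aa Minimum protein length in residues (stop excluded).
#' @param require_start Anchor each stretch at its first Met; stretches
#'   without Met are dropped.
#' @return Tibble of ORF records: `orf_id`, `contig_id`, `strand`,
#'   `frame`, `start`, `end` (0-based half-open, forward strand),
#'   `protein`, `has_start`, `has_stop`.
#' @export
find_orfs <- function(contigs, min_aa = 125L, require_start = FALSE) {
  if (is.character(contigs)) {
    contigs <- tibble::tibble(id = paste0("contig_", seq_along(contigs)),
                              seq = contigs)
  }
  stopifnot(all(c("id", "seq") %in% names(contigs)), min_aa >= 1L)
  res <- purrr::pmap(list(contigs$id, contigs$seq), function(id, seq) {
    find_orfs_one(id, seq, min_aa, require_start)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(orf_id = character(), contig_id = character(),
                          strand = character(), frame = integer(),
                          start = integer(), end = integer(),
                          protein = character(), has_start = logical(),
                          has_stop = logical()))
  }
  out
}

find_orfs_one <- function(contig_id, seq, min_aa, require_start) {
  L <- nchar(seq)
  recs <- list()
  for (strand in c("+", "-")) {
    for (frame in 0:2) {
      prot <- translate_frame(seq, frame, strand)
      if (nchar(prot) == 0L) next
      stretches <- stop_free_stretches(prot)
      for (s in stretches) {
        a <- s[1]; b <- s[2]
        has_start <- s[3] == 1L
        has_stop <- s[4] == 1L
        if (require_start) {
          sub <- substring(prot, a, b)
          m <- regexpr("M", sub, fixed = TRUE)
          if (m < 0L) next
          a <- a + as.integer(m) - 1L
          has_start <- TRUE
        }
        plen <- b - a + 1L
        if (plen < min_aa) next
        # frame coordinates (0-based half-open) on the translated strand
        fs <- frame + 3L * (a - 1L)
        fe <- frame + 3L * b
        if (strand == "+") {
          start <- fs; end <- fe
        } else {
          start <- L - fe; end <- L - fs
        }
        recs[[length(recs) + 1L]] <- tibble::tibble(
          orf_id = sprintf("%s|%s|f%d|%d-%d", contig_id, strand, frame, start, end),
          contig_id = contig_id, strand = strand, frame = frame,
          start = start, end = end,
          protein = substring(prot, a, b),
          has_start = has_start, has_stop = has_stop
        )
      }
    }
  }
  dplyr::bind_rows(recs)
}

# Maximal stop-free stretches of a frame translation. Returns a list of
# integer vectors c(first_residue, last_residue, preceded_by_stop,
# terminated_by_stop), 1-based inclusive residue positions.
stop_free_stretches <- function(prot) {
  chars <- str_chars(prot)
  n <- length(chars)
  is_stop <- chars == "*"
  out <- list()
  i <- 1L
  while (i <= n) {
    if (is_stop[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && !is_stop[j + 1L]) j <- j + 1L
    out[[length(out) + 1L]] <- c(
      i, j,
      as.integer(i > 1L),          # preceded by a stop codon
      as.integer(j < n && is_stop[j + 1L])
    )
    i <- j + 2L
  }
  out
}
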