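# FASTA/FASTQ input and output.
#
# Reads come in and go out as tibbles with columns `id`, `seq`, `qual`
# (qual stored as a phred+33 string, decoded on demand); contigs/proteins
# as tibbles with `id`, `seq`. Parsing is delegated to Biostrings; FASTQ
# writing is a deterministic four-line-per-record writer so that a fixed
# simulator seed yields byte-identical files.

#' Read a FASTQ file into a read tibble
#'
#' @param path Path to a FASTQ file (phred+33).
#' @return A tibble with columns `id`, `seq` and `qual` (phred+33 string).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(tibble::tibble(id = character(), seq = character(), qual = character()))
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(
    id = names(x) %||% as.character(seq_along(x)),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with `id`, `seq`, `qual` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rec <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- switch(type,
    dna = Biostrings::readDNAStringSet(path),
    protein = Biostrings::readAAStringSet(path)
  )
  tibble::tibble(id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with `id`, `seq` columns.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  lines <- character(0)
  if (nrow(seqs) > 0L) {
    wrapped <- lapply(seqs$seq, function(s) {
      if (nchar(s) == 0L) return("")
      starts <- seq(1L, nchar(s), by = width)
      substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    })
    lines <- unlist(purrr::map2(seqs$id, wrapped, function(id, w) c(paste0(">", id), w)))
  }
  writeLines(lines, path)
  invisible(path)
}

# Validate the read-tibble contract shared by QC/diginorm/quant.
check_reads <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad) > 0L) {
    stop("malformed read record at index ", bad[1],
         ": sequence and quality lengths differ")
  }
  invisible(reads)
}
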