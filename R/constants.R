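# Shared constants and small sequence helpers.

# The 20 standard amino acids, one-letter code.
AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

# Kyte-Doolittle hydropathy scale.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Fixed 33-nt single-end adapter constant (TruSeq-like), appended by the
# simulator when the insert is shorter than the read and removed by read QC.
DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`; `N` maps to `N`.
#'
#' @param x Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAN"))
revcomp <- function(x) {
  stri_rev <- stringi::stri_reverse(x)
  chartr("ACGTN", "TGCAN", stri_rev)
}

# Split a string into single characters.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Shannon entropy (bits) of a character vector.
shannon_entropy <- function(chars) {
  if (length(chars) == 0L) return(0)
  p <- table(chars) / length(chars)
  -sum(p * log2(p))
}

# Mean windowed Shannon entropy over windows of `window` residues; a
# stretch shorter than the window is scored as a single window.
windowed_entropy <- function(seq_str, window = 12L) {
  chars <- str_chars(seq_str)
  n <- length(chars)
  if (n == 0L) return(0)
  if (n <= window) return(shannon_entropy(chars))
  starts <- seq_len(n - window + 1L)
  mean(vapply(starts, function(s) shannon_entropy(chars[s:(s + window - 1L)]),
              numeric(1)))
}

# Lower-middle median for integer vectors: for even n the lower of the two
# central order statistics, so "median < cutoff" keeps integer semantics.
median_lower <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_integer_)
  sort(x)[(n + 1L) %/% 2L]
}

# Number of mismatching characters between two equal-length strings
# (any non-identical pair, so N mismatches everything but N).
count_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("count_mismatches: unequal lengths")
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Phred integer vector <-> phred+33 string.
phred_to_string <- function(q) intToUtf8(q + 33L)
string_to_phred <- function(s) {
  if (nchar(s) == 0L) return(integer(0))
  utf8ToInt(s) - 33L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
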