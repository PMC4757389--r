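# Homology filtering: Smith-Waterman local alignment against a reference
# panel, with Karlin-Altschul E-values. Re-expresses "retain contigs with
# at least one database match at E <= 1e-5" as explicit computation over
# a bundled (or user-supplied) protein panel.

# BLOSUM62 restricted to the 20 standard residues plus X, with X scoring
# 0 against everything.
blosum62x <- function() {
  mat <- get_blosum62()
  keep <- c(AA_STANDARD, "X")
  mat <- mat[keep, keep]
  mat["X", ] <- 0
  mat[, "X"] <- 0
  mat
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

# Protein string -> 0-based indices into blosum62x(); unknown residues
# map to X.
encode_protein <- function(protein, alphabet = c(AA_STANDARD, "X")) {
  chars <- str_chars(protein)
  idx <- match(chars, alphabet)
  idx[is.na(idx)] <- length(alphabet)
  idx - 1L
}

#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment score under affine gap costs (a gap of length
#' k costs `gap_open + k * gap_extend`), BLOSUM62 by default with `X`
#' scoring 0 against all residues. Ties are broken deterministically by
#' smallest query start, then subject start.
#'
#' @param query,subject Protein strings.
#' @param matrix Substitution matrix (rows/cols named by residue);
#'   defaults to BLOSUM62 with the X convention above.
#' @param gap_open,gap_extend Affine gap parameters.
#' @return One-row tibble: `score`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (0-based half-open spans of the optimal alignment; empty
#'   span when the score is 0).
#' @export
smith_waterman <- function(query, subject, matrix = NULL,
                           gap_open = 11, gap_extend = 1) {
  if (is.null(matrix)) matrix <- blosum62x()
  if (nchar(query) == 0L || nchar(subject) == 0L) {
    return(tibble::tibble(score = 0, q_start = 0L, q_end = 0L,
                          s_start = 0L, s_end = 0L))
  }
  alphabet <- rownames(matrix)
  res <- sw_align_cpp(encode_protein(query, alphabet),
                      encode_protein(subject, alphabet),
                      matrix, gap_open, gap_extend)
  if (res$score == 0) {
    return(tibble::tibble(score = 0, q_start = 0L, q_end = 0L,
                          s_start = 0L, s_end = 0L))
  }
  tibble::tibble(
    score = res$score,
    q_start = res$q_start - 1L, q_end = res$q_end,
    s_start = res$s_start - 1L, s_end = res$s_end
  )
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n`
#' the database (panel) residue count; no edge-effect correction. The
#' default gapped parameters are the published BLOSUM62/11/1 values.
#'
#' @param S Raw alignment score (>= 0).
#' @param m Effective query length (>= 1).
#' @param n Effective database length (>= 1).
#' @param lambda_,K Karlin-Altschul parameters.
#' @return E-value (vectorised over `S`).
#' @export
evalue <- function(S, m, n, lambda_ = 0.267, K = 0.041) {
  stopifnot(all(S >= 0), m >= 1, n >= 1)
  K * m * n * exp(-lambda_ * S)
}

#' Bit score from a raw alignment score
#'
#' @inheritParams evalue
#' @return Bit score `(lambda * S - ln K) / ln 2`.
#' @export
bit_score <- function(S, lambda_ = 0.267, K = 0.041) {
  (lambda_ * S - log(K)) / log(2)
}

#' Filter ORFs by homology to a reference panel
#'
#' Aligns every query against every panel protein with
#' [smith_waterman()]; a query is retained iff its best hit has
#' `E <= e_max`. The database length `n` is the total panel residue
#' count.
#'
#' @param orfs Tibble of queries: needs `protein` (or `seq`) and an id
#'   column (`orf_id` or `id`).
#' @param panel Reference panel tibble (`id`, `seq` as proteins), e.g.
#'   [reference_panel()], or a path to a protein FASTA.
#' @param e_max E-value retention threshold.
#' @param gap_open,gap_extend,lambda_,K Alignment/statistics parameters.
#' @return List with `retained` (subset of `orfs`) and `hits` (best hit
#'   per query: `query_id`, `subject_id`, `score`, `bit_score`, `evalue`,
#'   spans, `retained` flag).
#' @export
filter_by_homology <- function(orfs, panel = reference_panel(), e_max = 1e-5,
                               gap_open = 11, gap_extend = 1,
                               lambda_ = 0.267, K = 0.041) {
  if (is.character(panel) && length(panel) == 1L) {
    panel <- read_fasta(panel, type = "protein")
  }
  if (nrow(panel) == 0L) stop("homology panel is empty: nothing to match against")
  qcol <- if ("protein" %in% names(orfs)) "protein" else "seq"
  icol <- if ("orf_id" %in% names(orfs)) "orf_id" else "id"
  stopifnot(qcol %in% names(orfs), icol %in% names(orfs))
  n_db <- sum(nchar(panel$seq))
  mat <- blosum62x()
  if (nrow(orfs) == 0L) {
    hits <- tibble::tibble(query_id = character(), subject_id = character(),
                           score = numeric(), bit_score = numeric(),
                           evalue = numeric(), q_start = integer(),
                           q_end = integer(), s_start = integer(),
                           s_end = integer(), retained = logical())
    return(list(retained = orfs, hits = hits))
  }
  hits <- purrr::map2(orfs[[icol]], orfs[[qcol]], function(qid, qseq) {
    aligns <- purrr::map2(panel$id, panel$seq, function(sid, sseq) {
      a <- smith_waterman(qseq, sseq, matrix = mat,
                          gap_open = gap_open, gap_extend = gap_extend)
      a$subject_id <- sid
      a
    })
    aligns <- dplyr::bind_rows(aligns)
    best <- aligns[order(-aligns$score, aligns$subject_id), ][1, ]
    tibble::tibble(
      query_id = qid,
      subject_id = best$subject_id,
      score = best$score,
      bit_score = bit_score(best$score, lambda_, K),
      evalue = evalue(best$score, m = max(nchar(qseq), 1L), n = n_db,
                      lambda_ = lambda_, K = K),
      q_start = best$q_start, q_end = best$q_end,
      s_start = best$s_start, s_end = best$s_end
    )
  })
  hits <- dplyr::bind_rows(hits)
  hits$retained <- hits$evalue <= e_max
  list(retained = orfs[hits$retained, , drop = FALSE], hits = hits)
}
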