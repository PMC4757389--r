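# Pheromone domain grammar: signal peptides, complete and partial
# three-finger domains (TFDs), terminal cysteine motifs, low-complexity
# tails, and the class decision (alpha SPF / beta SPF / PPS / PMF / AFP).
#
# Domain annotations are tibbles with 0-based half-open residue spans
# (`start`, `end`), a cysteine count and positions (1-based), the
# terminal motif id for complete TFDs, and a `variant` note.
#
# Motif alphabet: C and N are literal cysteine/asparagine, X any residue.
# CC_terminal = CCXXXXCN (10-cysteine TFDs), XC_terminal = XCXXXXCN
# (8-cysteine TFDs); a site matching CC also matches XC, and CC wins.

domain_row <- function(kind, start, end, cys_positions = integer(0),
                       terminal_motif = NA_character_,
                       variant = NA_character_) {
  tibble::tibble(kind = kind, start = start, end = end,
                 n_cys = length(cys_positions),
                 cys_positions = list(cys_positions),
                 terminal_motif = terminal_motif, variant = variant)
}

empty_domains <- function() {
  tibble::tibble(kind = character(), start = integer(), end = integer(),
                 n_cys = integer(), cys_positions = list(),
                 terminal_motif = character(), variant = character())
}

#' Match a terminal cysteine motif at a residue position
#'
#' @param protein Protein string.
#' @param pos 1-based residue index of the motif's first position.
#' @param pattern `"CC_terminal"` (CCXXXXCN) or `"XC_terminal"`
#'   (XCXXXXCN).
#' @return `TRUE` iff every literal position matches; out-of-range `pos`
#'   gives `FALSE`.
#' @export
#' @examples
#' match_motif("CCAAAACN", 1, "CC_terminal")  # TRUE
match_motif <- function(protein, pos, pattern = c("CC_terminal", "XC_terminal")) {
  pattern <- match.arg(pattern)
  if (pos < 1L || pos + 7L > nchar(protein)) return(FALSE)
  win <- substring(protein, pos, pos + 7L)
  ok <- substring(win, 2L, 2L) == "C" &&
    substring(win, 7L, 7L) == "C" &&
    substring(win, 8L, 8L) == "N"
  if (pattern == "CC_terminal") {
    ok && substring(win, 1L, 1L) == "C"
  } else {
    ok
  }
}

#' Detect an N-terminal signal peptide by hydropathy
#'
#' Reports a signal peptide iff, within the first `max_search` residues,
#' some 8-residue window has mean Kyte-Doolittle hydropathy above 1.5 and
#' a candidate cleavage site lies at position 15-30. The cleavage site is
#' the smallest position `c` in that range with small residues (Ala, Gly
#' or Ser) at the -3 and -1 positions (`c - 2` and `c`); the annotated
#' span is residues 1..`c`.
#'
#' @param protein Protein string (length >= 15, else no call).
#' @param max_search Number of N-terminal residues searched.
#' @return One-row domain tibble or `NULL`.
#' @export
find_signal_peptide <- function(protein, max_search = 35L) {
  n <- nchar(protein)
  if (n < 15L) return(NULL)
  chars <- str_chars(protein)
  prefix_len <- min(max_search, n)
  kd <- unname(KD_HYDROPATHY[chars[seq_len(prefix_len)]])
  kd[is.na(kd)] <- 0
  if (prefix_len < 8L) return(NULL)
  win_means <- vapply(seq_len(prefix_len - 7L),
                      function(w) mean(kd[w:(w + 7L)]), numeric(1))
  if (!any(win_means > 1.5)) return(NULL)
  small <- c("A", "G", "S")
  for (cleave in seq(15L, min(30L, n - 1L))) {
    if (chars[cleave - 2L] %in% small && chars[cleave] %in% small) {
      return(domain_row("signal_peptide", 0L, cleave))
    }
  }
  NULL
}

#' Find complete three-finger domains
#'
#' Greedy leftmost scan for non-overlapping regions that (a) end with a
#' CC_terminal or XC_terminal motif (CC checked first at each site),
#' (b) contain, counting back from the motif's final cysteine, 10 (CC) or
#' 8 (XC) cysteines with at most `max_gap` residues between consecutive
#' cysteines, and (c) span (first counted cysteine to motif asparagine)
#' within `span_range` residues.
#'
#' @param protein Protein string.
#' @param max_gap Maximum residues between consecutive cysteines.
#' @param span_range Length-2 numeric: allowed domain span in residues.
#' @return Domain tibble (possibly 0-row) of `complete_TFD` annotations.
#' @export
find_complete_tfds <- function(protein, max_gap = 30L, span_range = c(55L, 115L)) {
  n <- nchar(protein)
  out <- empty_domains()
  if (n < 8L) return(out)
  chars <- str_chars(protein)
  cys <- which(chars == "C")
  last_end <- 0L  # 1-based position of last annotated residue
  p <- 1L
  while (p + 7L <= n) {
    # CC takes precedence at a site matching both; if its 10-cysteine
    # count-back or span fails, the site is still an XC match
    trials <- if (match_motif(protein, p, "CC_terminal")) {
      list(c("CC_terminal", 10L), c("XC_terminal", 8L))
    } else if (match_motif(protein, p, "XC_terminal")) {
      list(c("XC_terminal", 8L))
    } else {
      list()
    }
    annotated <- FALSE
    for (trial in trials) {
      motif <- trial[1]
      needed <- as.integer(trial[2])
      final_c <- p + 6L
      counted <- count_back_cysteines(cys, final_c, needed, max_gap)
      if (is.null(counted)) next
      span_start <- counted[1]
      span_len <- (p + 7L) - span_start + 1L
      if (span_len < span_range[1] || span_len > span_range[2] ||
          span_start <= last_end) next
      # up to two additional chained cysteines just upstream of the
      # canonical count are tolerated (variant note), mirroring domains
      # reported with 10-12 cysteines
      extra <- extra_upstream_cysteines(cys, span_start, max_gap)
      variant <- if (extra >= 1L && extra <= 2L) "extra_cysteines"
                 else NA_character_
      out <- dplyr::bind_rows(out, domain_row(
        "complete_TFD", span_start - 1L, p + 7L,
        cys_positions = counted, terminal_motif = motif,
        variant = variant))
      last_end <- p + 7L
      p <- p + 8L
      annotated <- TRUE
      break
    }
    if (!annotated) p <- p + 1L
  }
  out
}

# Number of cysteines chained upstream of span_start within max_gap steps.
extra_upstream_cysteines <- function(cys, span_start, max_gap) {
  upstream <- rev(cys[cys < span_start])
  count <- 0L
  anchor <- span_start
  for (pos in upstream) {
    if (anchor - pos - 1L > max_gap) break
    count <- count + 1L
    anchor <- pos
  }
  count
}

# Walk upstream from the motif's final cysteine collecting `needed`
# cysteines with inter-cysteine gaps <= max_gap; NULL if impossible.
count_back_cysteines <- function(cys, final_c, needed, max_gap) {
  upstream <- rev(cys[cys <= final_c])  # descending from final_c
  if (length(upstream) < needed) return(NULL)
  taken <- upstream[1]
  i <- 2L
  while (length(taken) < needed && i <= length(upstream)) {
    gap <- taken[length(taken)] - upstream[i] - 1L
    if (gap > max_gap) return(NULL)
    taken <- c(taken, upstream[i])
    i <- i + 1L
  }
  if (length(taken) == needed) rev(taken) else NULL
}

#' Find a partial three-finger domain
#'
#' Annotates the cysteine cluster downstream of `after`: the run starting
#' at the first cysteine past `after` and extended while consecutive
#' cysteines are at most `max_gap` residues apart. The cluster must not
#' end with a terminal motif (then it would be a complete TFD) and must
#' contain `expected_cys` cysteines; `expected_cys - 1` is tolerated with
#' the `reduced_cysteine_count` variant note.
#'
#' @param protein Protein string.
#' @param after 1-based residue index; the search starts after it.
#' @param expected_cys Expected cysteine count (6 for alpha-, 8 for
#'   beta-family partial TFDs).
#' @param max_gap Maximum residues between consecutive cysteines.
#' @return One-row domain tibble or `NULL`.
#' @export
find_partial_tfd <- function(protein, after, expected_cys, max_gap = 30L) {
  n <- nchar(protein)
  if (after >= n) return(NULL)
  chars <- str_chars(protein)
  cys <- which(chars == "C")
  cys <- cys[cys > after]
  if (length(cys) == 0L) return(NULL)
  cluster <- cys[1]
  for (i in seq_along(cys)[-1]) {
    if (cys[i] - cluster[length(cluster)] - 1L > max_gap) break
    cluster <- c(cluster, cys[i])
  }
  # a terminal motif whose final Cys lies in the cluster makes it complete
  for (cc in cluster) {
    p <- cc - 6L
    if (p >= 1L && (match_motif(protein, p, "CC_terminal") ||
                    match_motif(protein, p, "XC_terminal"))) {
      return(NULL)
    }
  }
  n_c <- length(cluster)
  if (n_c == expected_cys) {
    domain_row("partial_TFD", cluster[1] - 1L, cluster[n_c],
               cys_positions = cluster)
  } else if (n_c == expected_cys - 1L) {
    domain_row("partial_TFD", cluster[1] - 1L, cluster[n_c],
               cys_positions = cluster, variant = "reduced_cysteine_count")
  } else {
    NULL
  }
}

#' Find a cysteine-free low-complexity C-terminal tail
#'
#' Annotates the suffix starting after `after` iff it is cysteine-free,
#' at least 40 residues long, and its mean windowed Shannon entropy is at
#' most `entropy_max_bits` (windows of `window` residues; a shorter
#' suffix is scored as one window).
#'
#' @param protein Protein string.
#' @param after 1-based residue index; the tail starts after it.
#' @param window Entropy window size in residues.
#' @param entropy_max_bits Maximum mean windowed entropy (bits).
#' @param min_len Minimum tail length in residues.
#' @return One-row domain tibble or `NULL`.
#' @export
find_low_complexity_tail <- function(protein, after, window = 12L,
                                     entropy_max_bits = 2.9, min_len = 40L) {
  n <- nchar(protein)
  if (after >= n) return(NULL)
  suffix <- substring(protein, after + 1L, n)
  if (grepl("C", suffix, fixed = TRUE)) return(NULL)
  if (nchar(suffix) < min_len) return(NULL)
  if (windowed_entropy(suffix, window) > entropy_max_bits) return(NULL)
  domain_row("low_complexity_tail", after, n)
}

#' Annotate and classify one protein under the pheromone grammar
#'
#' Runs signal-peptide detection, complete-TFD search, and the downstream
#' partial-TFD and low-complexity-tail searches, then applies the class
#' decision: (1) CC-terminal complete TFD plus a cysteine-free
#' low-complexity tail of >= 40 residues is PPS; (2) complete plus
#' partial TFD is beta SPF (CC terminal) or alpha SPF (XC terminal);
#' (3) a single CC-terminal complete TFD with at most 30 residues of
#' C-terminal tail is PMF or AFP, separated by best homology-panel hit
#' (a tail longer than 8 residues sets the `extended_tail` flag);
#' (4) otherwise no call. Completeness is `complete` iff a signal peptide
#' was detected and the class's full domain set is present.
#'
#' @param protein Protein string.
#' @param panel Reference panel for the PMF/AFP tie-break (tibble with
#'   `id`, `class_label`, `seq`); ignored when `grammar_only`.
#' @param grammar_only If `TRUE`, PMF/AFP-structured proteins are
#'   labelled `"PMF_like"` without a homology tie-break.
#' @param max_gap,span_range Complete-TFD geometry parameters.
#' @return List: `class_label`, `completeness` (`"complete"`,
#'   `"partial"`, or `NA` for no call), `flags` (character vector),
#'   `domains` (domain tibble).
#' @export
classify_protein <- function(protein, panel = reference_panel(),
                             grammar_only = FALSE, max_gap = 30L,
                             span_range = c(55L, 115L)) {
  n <- nchar(protein)
  domains <- empty_domains()
  flags <- character(0)
  signal <- if (n >= 15L) find_signal_peptide(protein) else NULL
  if (!is.null(signal)) domains <- dplyr::bind_rows(domains, signal)
  tfds <- find_complete_tfds(protein, max_gap = max_gap, span_range = span_range)
  domains <- dplyr::bind_rows(domains, tfds)
  no_call <- function() list(class_label = "none", completeness = NA_character_,
                             flags = flags, domains = domains)
  if (nrow(tfds) == 0L) return(no_call())
  tfd <- tfds[1, ]
  if (!is.na(tfd$variant)) flags <- c(flags, tfd$variant)
  tfd_end <- tfd$end  # 1-based index of the motif asparagine
  # downstream annotations
  lc_tail <- find_low_complexity_tail(protein, tfd_end)
  expected_partial <- if (tfd$terminal_motif == "CC_terminal") 8L else 6L
  partial <- find_partial_tfd(protein, tfd_end, expected_partial, max_gap)
  class_label <- "none"
  full_set <- FALSE
  if (!is.null(lc_tail) && tfd$terminal_motif == "CC_terminal") {
    class_label <- "PPS"
    domains <- dplyr::bind_rows(domains, lc_tail)
    full_set <- TRUE
  } else if (!is.null(partial)) {
    class_label <- if (tfd$terminal_motif == "CC_terminal") "beta_SPF" else "alpha_SPF"
    domains <- dplyr::bind_rows(domains, partial)
    if (!is.na(partial$variant)) flags <- c(flags, partial$variant)
    full_set <- TRUE
  } else if (tfd$terminal_motif == "CC_terminal" && nrow(tfds) == 1L &&
             (n - tfd_end) <= 30L) {
    tail_len <- n - tfd_end
    if (tail_len > 8L) flags <- c(flags, "extended_tail")
    if (grammar_only) {
      class_label <- "PMF_like"
    } else {
      class_label <- pmf_afp_tiebreak(protein, panel)
    }
    full_set <- TRUE
  }
  if (class_label == "none") return(no_call())
  completeness <- if (!is.null(signal) && full_set) "complete" else "partial"
  list(class_label = class_label, completeness = completeness,
       flags = flags, domains = domains)
}

# Best Smith-Waterman hit against the PMF vs AFP panel templates; ties
# fall to PMF.
pmf_afp_tiebreak <- function(protein, panel) {
  cand <- panel[panel$class_label %in% c("PMF", "AFP"), , drop = FALSE]
  if (nrow(cand) == 0L) return("PMF_like")
  scores <- vapply(cand$seq, function(s) smith_waterman(protein, s)$score,
                   numeric(1))
  best <- cand$class_label[order(-scores, match(cand$class_label, c("PMF", "AFP")))][1]
  best
}

#' Classify a set of proteins under the pheromone grammar
#'
#' Vectorised driver over [classify_protein()].
#'
#' @param proteins Tibble with a protein column (`protein` or `seq`) and
#'   an id column (`orf_id` or `id`), or a character vector.
#' @inheritParams classify_protein
#' @return Tibble of calls: `orf_id`, `class_label`, `completeness`,
#'   `flags` (comma-separated), `n_complete_tfd`, `domains` (list column
#'   of domain tibbles).
#' @export
annotate_pheromones <- function(proteins, panel = reference_panel(),
                                grammar_only = FALSE, max_gap = 30L,
                                span_range = c(55L, 115L)) {
  if (is.character(proteins)) {
    proteins <- tibble::tibble(orf_id = names(proteins) %||%
                                 paste0("protein_", seq_along(proteins)),
                               protein = unname(proteins))
  }
  pcol <- if ("protein" %in% names(proteins)) "protein" else "seq"
  icol <- if ("orf_id" %in% names(proteins)) "orf_id" else "id"
  calls <- purrr::map(proteins[[pcol]], classify_protein, panel = panel,
                      grammar_only = grammar_only, max_gap = max_gap,
                      span_range = span_range)
  tibble::tibble(
    orf_id = proteins[[icol]],
    class_label = purrr::map_chr(calls, "class_label"),
    completeness = purrr::map_chr(calls, "completeness"),
    flags = purrr::map_chr(calls, function(x) paste(x$flags, collapse = ",")),
    n_complete_tfd = purrr::map_int(calls, function(x) {
      sum(x$domains$kind == "complete_TFD")
    }),
    domains = purrr::map(calls, "domains")
  )
}
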