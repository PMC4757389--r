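# Synthetic precursor and read generation.
#
# Pheromone precursors are built from class templates that encode the
# field's domain grammar: an N-terminal signal peptide, a complete
# three-finger domain (TFD) ending in a CCXXXXCN or XCXXXXCN cysteine
# motif, an optional partial TFD lacking the terminal motif, and a
# C-terminal tail that is either short or a cysteine-free low-complexity
# region. Filler residues between cysteines are drawn uniformly from the
# standard amino acids minus Cys, Met and Asn, so cysteine counts and
# terminal motifs occur exactly where the template places them.

# Residues used between structural positions: no Cys (would corrupt the
# cysteine grammar), no Met (no spurious internal starts), no Asn (the
# terminal motif's only Asn must be the one the template writes).
FILLER_AA <- setdiff(AA_STANDARD, c("C", "M", "N"))

# Hydrophobic core alphabet for signal peptides (all KD > 1.5).
SIGNAL_CORE_AA <- c("L", "I", "V", "F")

# Low-complexity tail alphabet (<= 4 residue types, cysteine-free).
LOW_COMPLEXITY_AA <- c("A", "G", "S", "P")

# Inter-cysteine spacing patterns, fixed per class so each synthetic
# family has its own loop geometry (this is what makes PMF and AFP
# separable by homology even though their grammar is identical).
TEMPLATE_LAYOUT <- list(
  alpha_SPF = list(signal_len = 18L, complete_tfd_cys = 8L,
                   complete_tfd_terminal = "XC_terminal", partial_tfd_cys = 6L,
                   tail_len = 8L, tail_kind = "short",
                   gaps = c(9L, 10L, 9L, 10L, 9L), link = 8L,
                   partial_gaps = c(6L, 7L, 6L, 7L, 6L)),
  beta_SPF = list(signal_len = 18L, complete_tfd_cys = 10L,
                  complete_tfd_terminal = "CC_terminal", partial_tfd_cys = 8L,
                  tail_len = 8L, tail_kind = "short",
                  gaps = c(6L, 7L, 6L, 7L, 6L, 7L), link = 6L,
                  partial_gaps = c(4L, 5L, 4L, 5L, 4L, 5L, 4L)),
  PPS = list(signal_len = 18L, complete_tfd_cys = 10L,
             complete_tfd_terminal = "CC_terminal", partial_tfd_cys = NA_integer_,
             tail_len = 63L, tail_kind = "low_complexity_cysfree",
             gaps = c(7L, 6L, 7L, 6L, 7L, 6L), link = 7L,
             partial_gaps = integer(0)),
  PMF = list(signal_len = 20L, complete_tfd_cys = 10L,
             complete_tfd_terminal = "CC_terminal", partial_tfd_cys = NA_integer_,
             tail_len = 5L, tail_kind = "short",
             gaps = c(12L, 16L, 13L, 15L, 14L, 12L), link = 8L,
             partial_gaps = integer(0)),
  AFP = list(signal_len = 20L, complete_tfd_cys = 10L,
             complete_tfd_terminal = "CC_terminal", partial_tfd_cys = NA_integer_,
             tail_len = 5L, tail_kind = "short",
             gaps = c(16L, 12L, 15L, 13L, 14L, 12L), link = 8L,
             partial_gaps = integer(0))
)

# Canonical per-class generator seeds; the reference panel and the default
# transcript pool both use these, so panel entries ARE the canonical
# precursors of each synthetic family.
CANONICAL_CLASS_SEEDS <- c(
  alpha_SPF = 101L, beta_SPF = 102L, PPS = 103L, PMF = 104L, AFP = 105L
)

# Housekeeping decoy templates shared between the reference panel and the
# default pool.
HOUSEKEEPING_TEMPLATE_SEEDS <- c(301L, 302L, 303L)
HOUSEKEEPING_TEMPLATE_LEN <- c(300L, 220L, 160L)

#' Pheromone precursor class template
#'
#' Returns the domain-grammar template of one precursor class: signal
#' peptide length, complete-TFD cysteine count and terminal motif
#' (`CC_terminal` = CCXXXXCN, `XC_terminal` = XCXXXXCN), partial-TFD
#' cysteine count (NA when the class has no partial TFD), and tail length
#' and kind.
#'
#' @param class_label One of `"alpha_SPF"`, `"beta_SPF"`, `"PPS"`,
#'   `"PMF"`, `"AFP"`.
#' @return A list of template fields (class `"pheromone_template"`).
#' @export
#' @examples
#' pheromone_template("beta_SPF")$complete_tfd_cys  # 10
pheromone_template <- function(class_label) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% names(TEMPLATE_LAYOUT)) {
    stop("invalid class_label: must be one of ",
         paste(names(TEMPLATE_LAYOUT), collapse = ", "))
  }
  tpl <- TEMPLATE_LAYOUT[[class_label]]
  tpl$class_label <- class_label
  structure(tpl, class = "pheromone_template")
}

# Motif residues for a terminal id, with fillers for the X positions
# (CCXXXXCN has four X positions, XCXXXXCN five).
motif_residues <- function(terminal, fillers) {
  stopifnot(length(fillers) == 5L)
  if (terminal == "CC_terminal") {
    c("C", "C", fillers[1:4], "C", "N")
  } else if (terminal == "XC_terminal") {
    c(fillers[1], "C", fillers[2:5], "C", "N")
  } else {
    stop("unknown terminal motif id: ", terminal)
  }
}

#' Generate a grammar-conformant precursor protein from a template
#'
#' Deterministic under `seed`. The protein is, in order: a signal peptide
#' (Met, a charged residue, a hydrophobic core, and an Ala-X-Ala cleavage
#' cassette), a complete TFD whose cysteine count and terminal motif match
#' the template, an optional partial TFD without a terminal motif, and the
#' template's tail. No cysteine occurs outside the declared domains.
#'
#' @param template A [pheromone_template()].
#' @param seed Integer seed for filler residues.
#' @return Single protein string.
#' @export
make_template_protein <- function(template, seed = 1L) {
  if (!inherits(template, "pheromone_template")) {
    template <- pheromone_template(template$class_label %||% template)
  }
  withr::with_seed(seed, {
    filler <- function(n) {
      if (n == 0L) return(character(0))
      sample(FILLER_AA, n, replace = TRUE)
    }
    sl <- template$signal_len
    signal <- c("M", "R", sample(SIGNAL_CORE_AA, sl - 5L, replace = TRUE),
                "A", "L", "A")
    # complete TFD: upstream cysteines with fixed spacing, then the motif
    n_upstream <- template$complete_tfd_cys -
      if (template$complete_tfd_terminal == "CC_terminal") 3L else 2L
    stopifnot(length(template$gaps) == n_upstream - 1L)
    tfd <- character(0)
    for (i in seq_len(n_upstream)) {
      tfd <- c(tfd, "C")
      if (i < n_upstream) tfd <- c(tfd, filler(template$gaps[i]))
    }
    tfd <- c(tfd, filler(template$link),
             motif_residues(template$complete_tfd_terminal, filler(5L)))
    # partial TFD: cysteine cluster, no terminal motif
    partial <- character(0)
    if (!is.na(template$partial_tfd_cys)) {
      stopifnot(length(template$partial_gaps) == template$partial_tfd_cys - 1L)
      partial <- filler(4L)  # cys-free linker
      for (i in seq_len(template$partial_tfd_cys)) {
        partial <- c(partial, "C")
        if (i < template$partial_tfd_cys) {
          partial <- c(partial, filler(template$partial_gaps[i]))
        }
      }
    }
    tail_res <- switch(template$tail_kind,
      none = character(0),
      short = filler(template$tail_len),
      low_complexity_cysfree =
        sample(LOW_COMPLEXITY_AA, template$tail_len, replace = TRUE),
      stop("unknown tail_kind: ", template$tail_kind)
    )
    paste(c(signal, tfd, partial, tail_res), collapse = "")
  })
}

#' Generate a decoy (non-pheromone) protein
#'
#' Cysteine-free random protein standing in for an abundant housekeeping
#' transcript (collagen, ribosomal protein, mucin, ...). Starts with Met
#' and a hydrophilic stretch so the signal-peptide heuristic rejects it.
#'
#' @param length_aa Protein length in residues.
#' @param seed Integer seed.
#' @return Single protein string.
#' @export
make_decoy_protein <- function(length_aa = 200L, seed = 1L) {
  stopifnot(length_aa >= 20L)
  withr::with_seed(seed, {
    body_aa <- setdiff(AA_STANDARD, c("C", "M"))
    paste(c("M", sample(c("D", "E", "K", "R", "S"), 9L, replace = TRUE),
            sample(body_aa, length_aa - 10L, replace = TRUE)), collapse = "")
  })
}

# Inverse genetic code: amino acid -> codons.
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a protein into a transcript
#'
#' Synonymous codons are chosen uniformly at random (deterministic under
#' `seed`); the CDS is closed by a stop codon. UTR padding is random
#' sequence, with the last three 5'-UTR bases forced to an in-frame TAA so
#' the CDS is the maximal stop-free stretch in its frame.
#'
#' @param protein Protein string (standard 20-letter alphabet).
#' @param seed Integer seed.
#' @param utr5,utr3 UTR lengths in nt (`utr5` >= 3 unless 0).
#' @return Single nucleotide string; translating frame +1 of the CDS
#'   (starting at position `utr5 + 1`) recovers `protein`.
#' @export
reverse_translate <- function(protein, seed = 1L, utr5 = 30L, utr3 = 30L) {
  aa <- str_chars(protein)
  if (length(aa) > 0L && !all(aa %in% AA_STANDARD)) {
    stop("non-standard residue in protein: ",
         paste(unique(setdiff(aa, AA_STANDARD)), collapse = ","))
  }
  stopifnot(utr5 == 0L || utr5 >= 3L, utr3 >= 0L)
  tab <- codons_by_aa()
  withr::with_seed(seed, {
    codons <- vapply(aa, function(a) {
      opts <- tab[[a]]
      opts[sample.int(length(opts), 1L)]
    }, character(1), USE.NAMES = FALSE)
    stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
    rand_nt <- function(n) {
      if (n == 0L) return("")
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }
    u5 <- if (utr5 > 0L) paste0(rand_nt(utr5 - 3L), "TAA") else ""
    paste0(u5, paste(codons, collapse = ""), stop_codon, rand_nt(utr3))
  })
}

#' Default synthetic transcript pool with ground truth
#'
#' Builds the canonical precursor of each of the five pheromone classes
#' plus five abundant housekeeping decoys, reverse-translates them, and
#' attaches true abundance weights echoing the study's expression ranks
#' (collagen-like decoys highest; beta SPF ~1477 and PMF ~1336 among the
#' pheromones; AFP moderate; alpha SPF and PPS low).
#'
#' @param seed Integer seed controlling reverse translation.
#' @return Tibble with columns `id`, `class_label` (`"decoy"` for
#'   non-pheromones), `protein`, `seq` (transcript), `weight`, `length`.
#' @export
pheromone_pool <- function(seed = 1L) {
  classes <- names(CANONICAL_CLASS_SEEDS)
  prot <- vapply(classes, function(cl) {
    make_template_protein(pheromone_template(cl), CANONICAL_CLASS_SEEDS[[cl]])
  }, character(1))
  # the first three decoys reuse the panel's housekeeping templates, so
  # they survive the homology filter and exercise the "no TFD -> none"
  # classification path; the last two have no panel homolog and model
  # contigs the homology filter removes
  decoy_spec <- tibble::tibble(
    id = c("collagen_like", "checkpoint_like", "ribosomal_like",
           "mucin_like", "ferritin_like"),
    len = c(HOUSEKEEPING_TEMPLATE_LEN, 260L, 175L),
    dseed = c(HOUSEKEEPING_TEMPLATE_SEEDS, 204L, 205L),
    weight = c(5000, 3000, 2600, 2000, 800)
  )
  decoy_prot <- purrr::map2_chr(decoy_spec$len, decoy_spec$dseed,
                                function(l, s) make_decoy_protein(l, s))
  pool <- tibble::tibble(
    id = c(paste0(classes, "_tx"), decoy_spec$id),
    class_label = c(classes, rep("decoy", nrow(decoy_spec))),
    protein = c(unname(prot), decoy_prot),
    weight = c(235, 1477, 50, 1336, 32, decoy_spec$weight)
  )
  pool$seq <- purrr::imap_chr(pool$protein, function(p, i) {
    reverse_translate(p, seed = seed * 1000L + i)
  })
  pool$length <- nchar(pool$seq)
  pool[, c("id", "class_label", "protein", "seq", "weight", "length")]
}

#' Simulate single-end reads from a transcript pool
#'
#' Read origins are drawn proportional to `weight * (length - read_len + 1)`
#' (the number of start positions a read can occupy); positions are uniform
#' within the transcript. A fraction `adapter_frac` of reads carries a
#' short insert completed to `read_len` with the 3' adapter constant.
#' Per-base phred scores follow `clamp(Normal(q_mean, q_sd), 2, 41)` and
#' substitution errors occur with the phred-implied probability.
#'
#' @param pool Tibble with `id`, `seq`, `weight` columns (see
#'   [pheromone_pool()]).
#' @param n_reads Number of reads.
#' @param read_len Read length in bp.
#' @param adapter_frac Fraction of reads with adapter read-through.
#' @param adapter Adapter sequence appended at the 3' end of short inserts.
#' @param q_mean,q_sd Per-base quality model parameters.
#' @param error_rate Override: if not `NULL`, a flat per-base substitution
#'   probability instead of the phred-implied one (0 = error-free reads).
#' @param seed Integer seed; fixed seed gives byte-identical FASTQ.
#' @return List with `reads` (tibble `id`, `seq`, `qual`) and `manifest`
#'   (tibble `read_id`, `origin_id`, `position`, `insert_len`).
#' @export
simulate_reads <- function(pool, n_reads, read_len = 50L, adapter_frac = 0,
                           adapter = DEFAULT_ADAPTER, q_mean = 34, q_sd = 4,
                           error_rate = NULL, seed = 1L) {
  stopifnot(all(pool$weight > 0), is.finite(sum(pool$weight)))
  too_short <- nchar(pool$seq) < read_len
  if (any(too_short)) {
    warning("excluding ", sum(too_short), " transcript(s) shorter than read_len")
    pool <- pool[!too_short, , drop = FALSE]
  }
  empty <- list(
    reads = tibble::tibble(id = character(), seq = character(), qual = character()),
    manifest = tibble::tibble(read_id = character(), origin_id = character(),
                              position = integer(), insert_len = integer())
  )
  if (n_reads == 0L || nrow(pool) == 0L) return(empty)
  len <- nchar(pool$seq)
  p <- pool$weight * (len - read_len + 1)
  withr::with_seed(seed, {
    origin <- sample.int(nrow(pool), n_reads, replace = TRUE, prob = p)
    has_adapter <- runif(n_reads) < adapter_frac
    insert_len <- ifelse(has_adapter,
                         sample(seq(20L, read_len - 1L), n_reads, replace = TRUE),
                         read_len)
    pos <- vapply(seq_len(n_reads), function(i) {
      sample.int(len[origin[i]] - insert_len[i] + 1L, 1L)
    }, integer(1))
    inserts <- substring(pool$seq[origin], pos, pos + insert_len - 1L)
    seqs <- ifelse(has_adapter,
                   paste0(inserts,
                          substring(adapter, 1L, read_len - insert_len)),
                   inserts)
    quals <- matrix(pmin(pmax(round(rnorm(n_reads * read_len, q_mean, q_sd)),
                              2L), 41L),
                    nrow = n_reads)
    seq_mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                      nrow = n_reads, byrow = TRUE)
    p_err <- if (is.null(error_rate)) 10^(-quals / 10) else error_rate
    err <- matrix(runif(n_reads * read_len) < p_err, nrow = n_reads)
    if (any(err)) {
      idx <- which(err)
      bases <- c("A", "C", "G", "T")
      # substitute to one of the three other bases, uniformly
      cur <- seq_mat[idx]
      pick <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), character(1))
      seq_mat[idx] <- pick
    }
    ids <- sprintf("read_%06d", seq_len(n_reads))
    list(
      reads = tibble::tibble(
        id = ids,
        seq = apply(seq_mat, 1L, paste, collapse = ""),
        qual = apply(quals, 1L, phred_to_string)
      ),
      manifest = tibble::tibble(
        read_id = ids,
        origin_id = pool$id[origin],
        position = pos,
        insert_len = insert_len
      )
    )
  })
}

#' Synthetic reference panel of pheromone templates and decoys
#'
#' The canonical precursor protein of each class (same fixed per-class
#' seeds as [pheromone_pool()]) plus housekeeping decoys; used as the
#' bundled homology panel and for the PMF/AFP tie-break.
#'
#' @return Tibble with `id`, `class_label`, `seq` (protein).
#' @export
reference_panel <- function() {
  classes <- names(CANONICAL_CLASS_SEEDS)
  prot <- vapply(classes, function(cl) {
    make_template_protein(pheromone_template(cl), CANONICAL_CLASS_SEEDS[[cl]])
  }, character(1))
  decoys <- purrr::map2_chr(HOUSEKEEPING_TEMPLATE_LEN,
                            HOUSEKEEPING_TEMPLATE_SEEDS,
                            function(l, s) make_decoy_protein(l, s))
  tibble::tibble(
    id = c(paste0(classes, "_template"), paste0("housekeeping_template_", 1:3)),
    class_label = c(classes, rep("decoy", 3L)),
    seq = c(unname(prot), decoys)
  )
}
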