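# Independent oracles and small fixture builders used across the suite.

PHEROMONE_CLASSES <- c("alpha_SPF", "beta_SPF", "PPS", "PMF", "AFP")
CLASS_SEEDS <- c(alpha_SPF = 101L, beta_SPF = 102L, PPS = 103L,
                 PMF = 104L, AFP = 105L)

canonical_protein <- function(class_label) {
  make_template_protein(pheromone_template(class_label),
                        CLASS_SEEDS[[class_label]])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_protein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, TRUE), collapse = "")
}

make_read <- function(seq, q = 40L, id = "r") {
  tibble::tibble(id = id, seq = seq,
                 qual = intToUtf8(rep(q + 33L, nchar(seq))))
}

make_reads <- function(seqs, q = 40L) {
  if (length(seqs) == 0L) {
    return(tibble::tibble(id = character(), seq = character(),
                          qual = character()))
  }
  dplyr::bind_rows(purrr::imap(seqs, function(s, i) {
    make_read(s, q, id = sprintf("r%04d", i))
  }))
}

# --- Smith-Waterman oracle: plain quadratic DP that enumerates explicit
# gap lengths instead of Gotoh's affine recurrence.
oracle_sw_score <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  m <- length(qa)
  n <- length(sa)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d <- H[i, j] + mat[qa[i], sa[j]]
      up <- max(H[1:i, j + 1] - gap_open - gap_extend * (i:1))
      lf <- max(H[i + 1, 1:j] - gap_open - gap_extend * (j:1))
      H[i + 1, j + 1] <- max(0, d, up, lf)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# --- Six-frame ORF oracle built directly on Biostrings translation:
# returns the sorted multiset of (strand, frame, protein) stretches of at
# least min_aa residues.
oracle_orfs <- function(seq, min_aa) {
  out <- list()
  for (strand in c("+", "-")) {
    nt <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (frame in 0:2) {
      if (nchar(nt) - frame < 3L) next
      sub <- substring(nt, frame + 1L,
                       frame + 3L * ((nchar(nt) - frame) %/% 3L))
      aa <- suppressWarnings(as.character(
        Biostrings::translate(Biostrings::DNAString(sub),
                              if.fuzzy.codon = "X",
                              no.init.codon = TRUE)))
      mm <- gregexpr("[^*]+", aa)[[1]]
      if (mm[1] == -1L) next
      lens <- attr(mm, "match.length")
      for (k in seq_along(mm)) {
        if (lens[k] >= min_aa) {
          out[[length(out) + 1L]] <- paste(
            strand, frame, substring(aa, mm[k], mm[k] + lens[k] - 1L),
            sep = "|")
        }
      }
    }
  }
  if (length(out) == 0L) return(character(0))
  sort(unlist(out))
}

# --- Digital-normalization oracle: recomputes all k-mer counts from the
# retained set from scratch before every decision.
oracle_diginorm <- function(reads, k, cutoff) {
  kept <- integer(0)
  for (i in seq_len(nrow(reads))) {
    km <- canonical_kmers(reads$seq[i], k)
    if (length(km) == 0L) next
    pool_kmers <- unlist(lapply(kept, function(j) {
      canonical_kmers(reads$seq[j], k)
    }))
    counts <- vapply(km, function(x) sum(pool_kmers == x), integer(1))
    srt <- sort(counts)
    med <- srt[(length(srt) + 1L) %/% 2L]
    if (med < cutoff) kept <- c(kept, i)
  }
  reads$id[kept]
}

# --- Adapter-trim oracle: enumerate every suffix/prefix overlap.
oracle_adapter_cut <- function(seq, adapter, min_overlap = 8L,
                               mismatch_rate = 0.125) {
  n <- nchar(seq)
  sa <- strsplit(seq, "")[[1]]
  aa <- strsplit(adapter, "")[[1]]
  for (p in seq_len(max(n - min_overlap + 1L, 0L))) {
    o <- min(n - p + 1L, length(aa))
    if (o < min_overlap) next
    mism <- sum(sa[p:(p + o - 1L)] != aa[1:o])
    if (mism <= mismatch_rate * o) return(p)
  }
  0L
}

# --- EM oracle: dense grid search of the two-transcript marginal
# log-likelihood.
oracle_two_tx_mle <- function(cand_sets, ell, step = 1e-4) {
  # cand_sets: list of integer vectors over {1,2}; theta is the per-read
  # origin probability, so P(read) = sum over candidates of theta_i/ell_i
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(t1) {
    th <- c(t1, 1 - t1)
    sum(vapply(cand_sets, function(cs) {
      v <- sum(th[cs] / ell[cs])
      if (v <= 0) -Inf else log(v)
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(ll)]
}

# 2% random substitutions at non-cysteine positions (cysteines untouched,
# replacements never introduce a cysteine).
mutate_noncys <- function(protein, rate = 0.02) {
  chars <- strsplit(protein, "")[[1]]
  non_cys <- which(chars != "C")
  n_mut <- max(1L, round(rate * length(non_cys)))
  pos <- sample(non_cys, n_mut)
  repl_aa <- setdiff(c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L",
                       "K", "M", "F", "P", "S", "T", "W", "Y", "V"), "C")
  chars[pos] <- sample(repl_aa, n_mut, replace = TRUE)
  paste(chars, collapse = "")
}
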