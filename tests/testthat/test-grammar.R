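# Pheromone domain grammar and classification.

test_that("terminal motif matching is literal at C and N positions", {
  expect_true(match_motif("CCAAAACN", 1L, "CC_terminal"))
  expect_false(match_motif("ACAAAACN", 1L, "CC_terminal"))
  expect_true(match_motif("ACAAAACN", 1L, "XC_terminal"))
  expect_false(match_motif("CCAAAACD", 1L, "CC_terminal"))
  # CC sites are a strict subset of XC sites
  expect_true(match_motif("CCAAAACN", 1L, "XC_terminal"))
  # out of range
  expect_false(match_motif("CCAAAACN", 2L, "CC_terminal"))
})

test_that("signal peptides are detected with the expected cleavage sites", {
  for (cl in PHEROMONE_CLASSES) {
    p <- canonical_protein(cl)
    sp <- find_signal_peptide(p)
    expect_false(is.null(sp))
    want <- if (cl %in% c("PMF", "AFP")) 20L else 18L
    expect_identical(sp$end - sp$start, want, label = cl)
  }
  # hydrophilic N-terminus is rejected
  polyd <- paste0(strrep("D", 25L), random_protein(50L))
  expect_null(find_signal_peptide(polyd))
  # too-short proteins give no call
  expect_null(find_signal_peptide("MLLLLLLIVA"))
})

test_that("complete TFDs carry the class-defining cysteine counts", {
  beta <- canonical_protein("beta_SPF")
  tb <- find_complete_tfds(beta)
  expect_identical(nrow(tb), 1L)
  expect_identical(tb$n_cys, 10L)
  expect_identical(tb$terminal_motif, "CC_terminal")
  alpha <- canonical_protein("alpha_SPF")
  ta <- find_complete_tfds(alpha)
  expect_identical(ta$n_cys, 8L)
  expect_identical(ta$terminal_motif, "XC_terminal")
  # cysteine-free protein: nothing
  expect_identical(nrow(find_complete_tfds(gsub("C", "A", beta))), 0L)
})

test_that("partial TFDs require the expected count and no terminal motif", {
  beta <- canonical_protein("beta_SPF")
  tfd <- find_complete_tfds(beta)
  pt <- find_partial_tfd(beta, tfd$end, 8L)
  expect_identical(pt$n_cys, 8L)
  expect_true(is.na(pt$terminal_motif))
  # one cysteine short: annotated with the reduced-count note
  chars <- strsplit(beta, "")[[1]]
  last_c <- max(which(chars == "C"))
  chars[last_c] <- "A"
  reduced <- find_partial_tfd(paste(chars, collapse = ""), tfd$end, 8L)
  expect_identical(reduced$n_cys, 7L)
  expect_identical(reduced$variant, "reduced_cysteine_count")
  # a downstream cluster that ends in a terminal motif is not partial
  pmf <- canonical_protein("PMF")
  sp_end <- find_signal_peptide(pmf)$end
  expect_null(find_partial_tfd(pmf, sp_end, 10L))
})

test_that("low-complexity tails demand cysteine-free low entropy", {
  pps <- canonical_protein("PPS")
  tfd <- find_complete_tfds(pps)
  tail_ann <- find_low_complexity_tail(pps, tfd$end)
  expect_identical(tail_ann$end - tail_ann$start, 63L)
  # uniform-random suffix of the same length: entropy too high
  ran <- paste0(substring(pps, 1L, tfd$end),
                withr::with_seed(51L, gsub("C", "A", random_protein(63L))))
  expect_null(find_low_complexity_tail(ran, tfd$end))
  # a single cysteine disqualifies the tail
  cystail <- paste0(substring(pps, 1L, tfd$end + 30L), "C",
                    substring(pps, tfd$end + 32L))
  expect_null(find_low_complexity_tail(cystail, tfd$end))
})

test_that("all canonical precursors and their truncations classify exactly", {
  for (cl in PHEROMONE_CLASSES) {
    p <- canonical_protein(cl)
    full <- classify_protein(p)
    expect_identical(full$class_label, cl)
    expect_identical(full$completeness, "complete")
    # 5'-truncated precursor (no signal peptide): same class, partial
    sig_len <- if (cl %in% c("PMF", "AFP")) 20L else 18L
    tr <- classify_protein(substring(p, sig_len + 1L))
    expect_identical(tr$class_label, cl, label = paste(cl, "truncated"))
    expect_identical(tr$completeness, "partial")
  }
  # housekeeping decoys never classify
  for (s in 301:303) {
    expect_identical(classify_protein(make_decoy_protein(200L, s))$class_label,
                     "none")
  }
})

test_that("grammar-only mode cannot separate PMF from AFP", {
  pmf <- canonical_protein("PMF")
  afp <- canonical_protein("AFP")
  expect_identical(classify_protein(pmf, grammar_only = TRUE)$class_label,
                   "PMF_like")
  expect_identical(classify_protein(afp, grammar_only = TRUE)$class_label,
                   "PMF_like")
  # the homology tie-break separates them
  expect_identical(classify_protein(pmf)$class_label, "PMF")
  expect_identical(classify_protein(afp)$class_label, "AFP")
})

test_that("an extended C-terminal tail past the motif is flagged", {
  pmf <- canonical_protein("PMF")
  tfd_end <- find_complete_tfds(pmf)$end
  base <- substring(pmf, 1L, tfd_end)
  extended <- paste0(base, withr::with_seed(52L, paste(
    sample(c("A", "G", "S", "T", "P", "E", "D", "Q"), 25L, TRUE),
    collapse = "")))
  res <- classify_protein(extended)
  expect_identical(res$class_label, "PMF")
  expect_true("extended_tail" %in% res$flags)
  # canonical short tail carries no such flag
  expect_false("extended_tail" %in% classify_protein(pmf)$flags)
})

test_that("CC-to-XC motif mutation flips the class only when counts match", {
  filler <- function(n, seed) withr::with_seed(seed, paste(
    sample(c("A", "G", "S", "T", "E", "D", "Q", "L", "V", "I"), n, TRUE),
    collapse = ""))
  chain <- function(gaps, seed0) {
    parts <- "C"
    for (i in seq_along(gaps)) {
      parts <- c(parts, filler(gaps[i], seed0 + i), "C")
    }
    paste(parts, collapse = "")
  }
  # 10-cysteine CC domain whose 8 nearest cysteines still span >= 55
  # residues, followed by a 6-cysteine partial cluster
  dom <- paste0(chain(c(4L, 12L, 12L, 12L, 12L, 12L), 60L), filler(8L, 70L),
                "CC", filler(4L, 71L), "CN")
  partial <- paste0(filler(4L, 72L), chain(c(6L, 7L, 6L, 7L, 6L), 80L),
                    filler(8L, 90L))
  prot <- paste0(dom, partial)
  # counts match the alpha grammar only after the mutation
  expect_identical(classify_protein(prot)$class_label, "none")
  flipped <- classify_protein(paste0(substring(prot, 1, nchar(dom) - 8L),
                                     "A",
                                     substring(prot, nchar(dom) - 6L)))
  expect_identical(flipped$class_label, "alpha_SPF")
  # beta canonical (8-cysteine partial) does not become alpha
  beta <- canonical_protein("beta_SPF")
  tfd <- find_complete_tfds(beta)
  motif_start <- tfd$end - 7L
  beta_mut <- paste0(substring(beta, 1L, motif_start - 1L), "A",
                     substring(beta, motif_start + 1L))
  expect_false(classify_protein(beta_mut)$class_label %in%
                 c("beta_SPF", "alpha_SPF"))
})

test_that("complete TFD annotations never overlap", {
  # canonical precursors carry exactly one complete TFD
  withr::with_seed(53L, {
    for (rep in 1:15) {
      cl <- sample(PHEROMONE_CLASSES, 1)
      p <- make_template_protein(pheromone_template(cl), sample.int(1e4, 1))
      expect_identical(nrow(find_complete_tfds(p)), 1L)
    }
  })
  # a two-domain construct yields two disjoint annotations
  pmf <- canonical_protein("PMF")
  tfd <- find_complete_tfds(pmf)
  dom_seq <- substring(pmf, tfd$start + 1L, tfd$end)
  two <- paste0(dom_seq, strrep("G", 10L), dom_seq)
  tfds2 <- find_complete_tfds(two)
  expect_identical(nrow(tfds2), 2L)
  expect_true(all(tfds2$start[-1] >= tfds2$end[-nrow(tfds2)]))
})

test_that("classification tolerates sparse non-cysteine substitutions", {
  withr::with_seed(54L, {
    n <- 50L
    classes <- sample(PHEROMONE_CLASSES, n, replace = TRUE)
    hits <- vapply(classes, function(cl) {
      mutated <- mutate_noncys(canonical_protein(cl), rate = 0.02)
      classify_protein(mutated)$class_label == cl
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  })
})
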