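# Read QC: adapter trimming, end-trimming, filtering, reporting.

ADAPT <- salamandr:::DEFAULT_ADAPTER

test_that("adapter trimming removes 3' adapter matches", {
  r <- make_read(paste0("AAAATTTT", ADAPT))
  expect_identical(trim_adapter(r, ADAPT)$seq, "AAAATTTT")
  # no adapter content: unchanged
  r2 <- make_read("ACGTACGTACGTACGTACGT")
  expect_identical(trim_adapter(r2, ADAPT)$seq, r2$seq)
  # 10-nt adapter prefix at the 3' end with one mismatch is removed
  pre10 <- substring(ADAPT, 1, 10)
  substr(pre10, 5, 5) <- if (substring(pre10, 5, 5) == "A") "C" else "A"
  r3 <- make_read(paste0("GGGGCCCCGGGGCCCCGGGG", pre10))
  expect_identical(trim_adapter(r3, ADAPT)$seq, "GGGGCCCCGGGGCCCCGGGG")
  # qualities trimmed in lockstep
  tr <- trim_adapter(r3, ADAPT)
  expect_identical(nchar(tr$seq), nchar(tr$qual))
})

test_that("adapter trimming matches the overlap-enumeration oracle", {
  withr::with_seed(31L, {
    for (rep in 1:100) {
      base <- random_dna(sample(20:50, 1))
      seq <- if (rep %% 2 == 0) {
        o <- sample(8:33, 1)
        paste0(base, substring(ADAPT, 1, o))
      } else base
      expected_cut <- oracle_adapter_cut(seq, ADAPT)
      got <- trim_adapter(make_read(seq), ADAPT)$seq
      want <- if (expected_cut == 0L) seq else substring(seq, 1, expected_cut - 1L)
      expect_identical(got, want)
    }
  })
})

test_that("end-trimming removes exactly the terminal low-quality runs", {
  r <- tibble::tibble(id = "r", seq = "ACGTA",
                      qual = intToUtf8(c(10, 10, 30, 30, 10) + 33L))
  out <- quality_trim_ends(r, 20L)
  expect_identical(out$seq, "GT")
  expect_identical(salamandr:::string_to_phred(out$qual), c(30L, 30L))
  # all high quality: unchanged
  hi <- make_read("ACGTACGT", 30L)
  expect_identical(quality_trim_ends(hi)$seq, hi$seq)
  # all low quality: empty read
  lo <- make_read("ACGTACGT", 5L)
  expect_identical(quality_trim_ends(lo)$seq, "")
  # interior low-quality bases are untouched
  mid <- tibble::tibble(id = "r", seq = "AACGTAA",
                        qual = intToUtf8(c(30, 30, 5, 5, 5, 30, 30) + 33L))
  expect_identical(quality_trim_ends(mid)$seq, "AACGTAA")
})

test_that("read filtering applies length-then-quality with inclusive bounds", {
  r34 <- make_read(random_dna(34L), 40L)
  r50 <- make_read(random_dna(50L), 19L)
  r35 <- make_read(random_dna(35L), 20L)
  got <- filter_read(dplyr::bind_rows(r34, r50, r35))
  expect_identical(got$qc_reason, c("length", "quality", "keep"))
})

test_that("run_qc reconciles counts and enforces the retention rules", {
  expect_identical(
    glance(run_qc(make_reads(character(0))))$n_input, 0L)
  # hand-built: 3 reads fail length after trimming, 2 fail mean quality
  # (the low-quality pair keeps Q38 ends so end-trimming leaves them long
  # while the interior drags the mean below 20)
  lowq <- intToUtf8(c(38L, 38L, rep(15L, 46L), 38L, 38L) + 33L)
  reads <- dplyr::bind_rows(
    make_reads(replicate(5, random_dna(50L)), q = 38L),         # keep
    make_reads(replicate(3, random_dna(30L)), q = 38L),         # too short
    dplyr::mutate(make_reads(replicate(2, random_dna(50L))), qual = lowq)
  )
  reads$id <- sprintf("r%02d", 1:10)
  qc <- run_qc(reads, adapter = NULL)
  g <- glance(qc)
  expect_identical(g$n_retained, 5L)
  expect_identical(g$n_discarded_length, 3L)
  expect_identical(g$n_discarded_quality, 2L)
  expect_identical(g$n_input, g$n_retained + g$n_discarded_length +
                     g$n_discarded_quality)
  expect_identical(tidy(qc)$id, sprintf("r%02d", 1:5))  # order preserved
  # all-perfect input retains everything
  perfect <- make_reads(replicate(4, random_dna(50L)), q = 40L)
  expect_identical(glance(run_qc(perfect))$retained_fraction, 1)
})

test_that("no retained read violates the length or mean-quality floor", {
  withr::with_seed(77L, {
    pool <- tibble::tibble(id = "t", seq = random_dna(400L), weight = 1)
    sim <- simulate_reads(pool, 300L, adapter_frac = 0.3, q_mean = 22,
                          q_sd = 8, seed = 13L)
    qc <- run_qc(sim$reads)
    lens <- nchar(qc$reads$seq)
    meanq <- vapply(qc$reads$qual,
                    function(q) mean(salamandr:::string_to_phred(q)),
                    numeric(1))
    expect_true(all(lens >= 35L))
    expect_true(all(meanq >= 20))
    # trimming never lengthens reads
    expect_true(all(lens <= nchar(sim$reads$seq[match(qc$reads$id, sim$reads$id)])))
    # end-trim and filter stages are idempotent on their own output
    qc2 <- run_qc(qc$reads, adapter = NULL)
    expect_identical(qc2$reads, qc$reads)
  })
})

test_that("full QC is idempotent when adapters are sequenced cleanly", {
  withr::with_seed(78L, {
    pool <- tibble::tibble(id = "t", seq = random_dna(400L), weight = 1)
    sim <- simulate_reads(pool, 200L, adapter_frac = 0.4, error_rate = 0,
                          seed = 14L)
    qc <- run_qc(sim$reads)
    qc2 <- run_qc(qc$reads)
    expect_identical(qc2$reads, qc$reads)
    expect_identical(glance(qc2)$n_retained, glance(qc)$n_retained)
  })
})

test_that("malformed read records abort with the record index", {
  bad <- tibble::tibble(id = c("a", "b"), seq = c("ACGT", "ACGT"),
                        qual = c("IIII", "III"))
  expect_error(run_qc(bad), "index 2")
})
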