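# Read mapping, EM quantification, TPM, bootstrap, summaries.

test_that("mapping finds origins, multi-maps duplications, drops noise", {
  withr::with_seed(61L, {
    c1 <- random_dna(300L)
    dup <- substring(c1, 101L, 200L)
    c2 <- paste0(random_dna(80L), dup, random_dna(80L))
    contigs <- tibble::tibble(id = c("c1", "c2"), seq = c(c1, c2))
    # error-free read from c1 outside the duplication
    r1 <- make_read(substring(c1, 1L, 50L), id = "r1")
    # read wholly inside the duplicated region
    r2 <- make_read(substring(c1, 120L, 169L), id = "r2")
    # reverse-strand read maps too
    r3 <- make_read(revcomp(substring(c1, 30L, 79L)), id = "r3")
    # unrelated read
    r4 <- make_read(random_dna(50L), id = "r4")
    res <- map_reads(dplyr::bind_rows(r1, r2, r3, r4), contigs)
    cand <- res$candidates
    expect_identical(sort(cand$contig_id[cand$read_id == "r1"]), "c1")
    expect_identical(sort(cand$contig_id[cand$read_id == "r2"]), c("c1", "c2"))
    expect_identical(sort(cand$contig_id[cand$read_id == "r3"]), "c1")
    expect_identical(res$unmapped, "r4")
  })
})

test_that("EM reduces to raw counts for uniquely mapping reads", {
  cand <- tibble::tibble(
    read_id = sprintf("r%02d", 1:30),
    contig_id = rep(c("a", "b", "c"), times = c(15, 10, 5)))
  ell <- c(a = 100, b = 200, c = 50)
  est <- em_counts(cand, ell)
  expect_equal(unname(est[c("a", "b", "c")]), c(15, 10, 5), tolerance = 1e-9)
  # single contig gets everything
  one <- em_counts(tibble::tibble(read_id = c("x", "y"), contig_id = "a"),
                   c(a = 10))
  expect_equal(unname(one), 2)
})

test_that("ambiguous mass flows to the contig with unique support", {
  cand <- dplyr::bind_rows(
    tidyr::expand_grid(read_id = sprintf("amb%03d", 1:100),
                       contig_id = c("A", "B")),
    tibble::tibble(read_id = sprintf("u%02d", 1:10), contig_id = "A"))
  est <- em_counts(cand, c(A = 100, B = 100))
  expect_gt(est[["A"]], 60)   # > 50 of the 100 ambiguous reads
  expect_equal(sum(est), 110, tolerance = 1e-6)
  # analytic fixed point: all mass on A
  expect_equal(unname(est[["A"]]), 110, tolerance = 1e-3)
})

test_that("EM matches the grid-search MLE on two-transcript instances", {
  withr::with_seed(62L, {
    for (rep in 1:5) {
      ell <- c(t1 = sample(50:200, 1), t2 = sample(50:200, 1))
      n_u1 <- sample(5:30, 1)
      n_u2 <- sample(5:30, 1)
      n_amb <- sample(10:50, 1)
      cand_sets <- c(replicate(n_u1, 1L, simplify = FALSE),
                     replicate(n_u2, 2L, simplify = FALSE),
                     replicate(n_amb, c(1L, 2L), simplify = FALSE))
      cand <- dplyr::bind_rows(purrr::imap(cand_sets, function(cs, i) {
        tibble::tibble(read_id = sprintf("r%03d", i),
                       contig_id = names(ell)[cs])
      }))
      est <- em_counts(cand, ell)
      theta1_hat <- est[["t1"]] / sum(est)
      theta1_star <- oracle_two_tx_mle(cand_sets, unname(ell))
      expect_lt(abs(theta1_hat - theta1_star), 1e-3)
    }
  })
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  cand <- dplyr::bind_rows(
    tidyr::expand_grid(read_id = sprintf("a%02d", 1:20),
                       contig_id = c("x", "y")),
    tibble::tibble(read_id = sprintf("b%02d", 1:10), contig_id = "x"),
    tibble::tibble(read_id = sprintf("c%02d", 1:5), contig_id = "z"))
  ell <- c(x = 80, y = 120, z = 60)
  loglik <- function(est) {
    theta <- est / sum(est)
    per_read <- split(cand$contig_id, cand$read_id)
    sum(vapply(per_read, function(cs) {
      log(sum(theta[cs] / ell[cs]))
    }, numeric(1)))
  }
  lls <- vapply(1:12, function(k) {
    loglik(em_counts(cand, ell, max_iter = k, tol = 0))
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("TPM follows the closed form and its invariances", {
  expect_equal(tpm(c(10, 10), c(100, 200)),
               c(2 / 3, 1 / 3) * 1e6, tolerance = 1e-9)
  expect_equal(tpm(5, 77), 1e6)
  expect_equal(tpm(c(3, 9, 1), c(10, 20, 30)),
               tpm(7 * c(3, 9, 1), c(10, 20, 30)))
  expect_identical(tpm(c(0, 0), c(10, 10)), c(0, 0))
  # sums to a million whenever any read maps
  withr::with_seed(63L, {
    for (rep in 1:20) {
      k <- sample(2:10, 1)
      v <- tpm(runif(k, 0, 50), sample(50:500, k, TRUE))
      expect_equal(sum(v), 1e6, tolerance = 1e-6 * 1e6)
    }
  })
})

test_that("bootstrap intervals are deterministic and concentrate", {
  # single contig: no variability at all
  cand <- tibble::tibble(read_id = sprintf("r%02d", 1:20), contig_id = "only")
  ci <- bootstrap_ci(cand, c(only = 100), n_boot = 30L, seed = 5L)
  expect_equal(ci$ci_low, 1e6)
  expect_equal(ci$ci_high, 1e6)
  # fixed seed reproduces intervals exactly
  cand2 <- dplyr::bind_rows(
    tibble::tibble(read_id = sprintf("a%02d", 1:30), contig_id = "p"),
    tibble::tibble(read_id = sprintf("b%02d", 1:15), contig_id = "q"))
  ell <- c(p = 120, q = 90)
  expect_identical(bootstrap_ci(cand2, ell, 40L, seed = 6L),
                   bootstrap_ci(cand2, ell, 40L, seed = 6L))
  # CI width shrinks when the read pool grows tenfold with the same shape
  big <- dplyr::bind_rows(
    tibble::tibble(read_id = sprintf("A%03d", 1:300), contig_id = "p"),
    tibble::tibble(read_id = sprintf("B%03d", 1:150), contig_id = "q"))
  w_small <- with(bootstrap_ci(cand2, ell, 60L, seed = 7L),
                  ci_high[1] - ci_low[1])
  w_big <- with(bootstrap_ci(big, ell, 60L, seed = 7L),
                ci_high[1] - ci_low[1])
  expect_lt(w_big, w_small)
})

test_that("expression summaries rank, flag, and bin correctly", {
  rec <- tibble::tibble(contig_id = c("a", "b", "c"), tpm = c(1.9, 2.0, 150))
  s <- summarize_expression(rec)
  expect_identical(sum(s$active), 2L)
  expect_identical(sum(s$highly_expressed), 1L)
  expect_identical(s$contig_id, c("c", "b", "a"))
  # deterministic tie-break by id
  ties <- summarize_expression(tibble::tibble(contig_id = c("z", "m", "a"),
                                              tpm = c(5, 5, 5)))
  expect_identical(ties$contig_id, c("a", "m", "z"))
  expect_identical(summarize_expression(rec[0, ])$contig_id, character(0))
  # histogram: unit bins to 100, then width-100 bins
  h <- tpm_histogram(c(0.5, 1.5, 99.5, 150, 450))
  expect_identical(h$bin_high[1] - h$bin_low[1], 1)
  expect_identical(sum(h$count), 5L)
  expect_identical(h$count[h$bin_low == 100], 1L)
  expect_identical(h$count[h$bin_low == 400], 1L)
})

test_that("quantification recovers simulated abundances", {
  pool <- pheromone_pool(seed = 2L)[1:5, ]
  pool$weight <- c(2, 3, 5, 8, 12)
  total_len <- sum(nchar(pool$seq))
  n_reads <- as.integer(round(40 * total_len / 50))  # 40x mean coverage
  sim <- simulate_reads(pool, n_reads, adapter_frac = 0, error_rate = 0,
                        seed = 64L)
  q <- quantify_expression(sim$reads, pool[, c("id", "seq")],
                           read_len = 50L, n_boot = 25L, seed = 65L)
  e <- tidy(q)
  truth <- setNames(pool$weight / sum(pool$weight) * 1e6, pool$id)
  est <- setNames(e$tpm, e$contig_id)[names(truth)]
  expect_gte(cor(est, truth), 0.99)
  expect_equal(sum(e$tpm), 1e6, tolerance = 1)
  expect_true(all(e$ci_low <= e$tpm + 1e-6 & e$tpm <= e$ci_high + 1e-6))
  expect_identical(sort(e$rank), 1:5)
})
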