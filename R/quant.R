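# Expression quantification: seed-and-extend read mapping, EM resolution
# of multi-mapping reads, TPM with percentile-bootstrap confidence
# intervals, ranks, and activity flags.

#' Map reads to contigs by exact k-mer seeds and ungapped extension
#'
#' A read is a candidate on every contig where a shared `seed_k`-mer
#' extends to a full-length ungapped alignment with at most
#' `max_mismatch` substitutions, on either strand.
#'
#' @param reads Read tibble (`id`, `seq`, `qual`).
#' @param contigs Tibble with `id`, `seq`.
#' @param seed_k Seed k-mer length.
#' @param max_mismatch Maximum substitutions in the full-length alignment.
#' @return List: `candidates` (tibble `read_id`, `contig_id`) and
#'   `unmapped` (character vector of read ids).
#' @export
map_reads <- function(reads, contigs, seed_k = 20L, max_mismatch = 2L) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  index <- new.env(parent = emptyenv())
  clen <- nchar(contigs$seq)
  for (ci in seq_len(nrow(contigs))) {
    if (clen[ci] < seed_k) next
    starts <- seq_len(clen[ci] - seed_k + 1L)
    kms <- substring(contigs$seq[ci], starts, starts + seed_k - 1L)
    for (p in seq_along(kms)) {
      key <- kms[p]
      prev <- if (exists(key, envir = index, inherits = FALSE)) {
        get(key, envir = index)
      } else integer(0)
      assign(key, c(prev, ci, p), envir = index)
    }
  }
  cand_read <- list()
  unmapped <- character(0)
  for (ri in seq_len(nrow(reads))) {
    rseq <- reads$seq[ri]
    rlen <- nchar(rseq)
    hits <- integer(0)
    if (rlen >= seed_k) {
      for (oriented in c(rseq, revcomp(rseq))) {
        offs <- seq_len(rlen - seed_k + 1L)
        kms <- substring(oriented, offs, offs + seed_k - 1L)
        found <- mget(kms, envir = index, ifnotfound = list(NULL))
        starts_seen <- character(0)
        for (oi in seq_along(found)) {
          v <- found[[oi]]
          if (is.null(v)) next
          for (h in seq(1L, length(v), by = 2L)) {
            ci <- v[h]; pos <- v[h + 1L]
            astart <- pos - offs[oi] + 1L
            key <- paste0(ci, ":", astart)
            if (astart < 1L || astart + rlen - 1L > clen[ci] ||
                key %in% starts_seen) next
            starts_seen <- c(starts_seen, key)
            target <- substring(contigs$seq[ci], astart, astart + rlen - 1L)
            if (count_mismatches(oriented, target) <= max_mismatch) {
              hits <- c(hits, ci)
            }
          }
        }
      }
    }
    hits <- unique(hits)
    if (length(hits) == 0L) {
      unmapped <- c(unmapped, reads$id[ri])
    } else {
      cand_read[[length(cand_read) + 1L]] <-
        tibble::tibble(read_id = reads$id[ri], contig_id = contigs$id[hits])
    }
  }
  candidates <- if (length(cand_read)) dplyr::bind_rows(cand_read) else
    tibble::tibble(read_id = character(), contig_id = character())
  list(candidates = candidates, unmapped = unmapped)
}

#' EM estimation of per-contig read counts
#'
#' Iterates responsibilities proportional to `theta_i / ell_i` over each
#' read's candidate contigs, updating `theta` as normalized expected
#' counts, until the largest `theta` change is below `tol` (or
#' `max_iter`). Expected counts are returned for every contig named in
#' `effective_lengths` (0 for contigs with no candidates).
#'
#' @param candidates Tibble `read_id`, `contig_id` (every read has >= 1
#'   candidate).
#' @param effective_lengths Named numeric vector of effective lengths.
#' @param read_weights Optional named numeric vector of per-read
#'   multiplicities (bootstrap resampling); default 1 per read.
#' @param tol,max_iter Convergence controls.
#' @return Named numeric vector of estimated counts.
#' @export
em_counts <- function(candidates, effective_lengths, read_weights = NULL,
                      tol = 1e-8, max_iter = 1000L) {
  contig_ids <- names(effective_lengths)
  stopifnot(!is.null(contig_ids), all(effective_lengths >= 1))
  est <- setNames(numeric(length(contig_ids)), contig_ids)
  if (nrow(candidates) == 0L) return(est)
  cidx <- match(candidates$contig_id, contig_ids)
  stopifnot(!anyNA(cidx))
  reads <- unique(candidates$read_id)
  ridx <- match(candidates$read_id, reads)
  w <- if (is.null(read_weights)) {
    rep(1, length(reads))
  } else {
    unname(read_weights[reads])
  }
  n_eff <- sum(w)
  if (n_eff == 0) return(est)
  nc <- length(contig_ids)
  theta <- rep(1 / nc, nc)
  inv_ell <- 1 / unname(effective_lengths)
  for (iter in seq_len(max_iter)) {
    a <- theta[cidx] * inv_ell[cidx]
    denom <- rowsum(a, ridx)[, 1]
    denom[denom == 0] <- 1
    resp <- a / denom[ridx] * w[ridx]
    counts <- rep(0, nc)
    cs <- rowsum(resp, cidx)
    counts[as.integer(rownames(cs))] <- cs[, 1]
    theta_new <- counts / n_eff
    delta <- max(abs(theta_new - theta))
    theta <- theta_new
    if (delta < tol) break
  }
  est[] <- theta * n_eff
  est
}

#' Transcripts per million
#'
#' `tpm_i = (c_i / ell_i) / sum_j (c_j / ell_j) * 1e6`; all-zero counts
#' give all-zero TPM.
#'
#' @param est_counts Numeric vector of estimated counts.
#' @param effective_lengths Numeric vector of effective lengths (>= 1).
#' @return Numeric vector of TPM values (sums to 1e6 when any count is
#'   positive).
#' @export
tpm <- function(est_counts, effective_lengths) {
  stopifnot(length(est_counts) == length(effective_lengths),
            all(effective_lengths >= 1))
  rate <- est_counts / effective_lengths
  total <- sum(rate)
  if (total == 0) return(rep(0, length(est_counts)))
  rate / total * 1e6
}

#' Percentile-bootstrap confidence intervals for TPM
#'
#' Resamples reads with replacement `n_boot` times, re-running the EM and
#' TPM computation each time, and reports percentile 2.5/97.5 bounds.
#'
#' @inheritParams em_counts
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Tibble `contig_id`, `ci_low`, `ci_high`.
#' @export
bootstrap_ci <- function(candidates, effective_lengths, n_boot = 100L,
                         seed = 1L) {
  contig_ids <- names(effective_lengths)
  reads <- unique(candidates$read_id)
  n <- length(reads)
  stopifnot(n >= 1L)
  boot_tpm <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mult <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
      wts <- setNames(mult, reads)
      cnt <- em_counts(candidates, effective_lengths, read_weights = wts)
      tpm(cnt, effective_lengths)
    }, numeric(length(contig_ids)))
  })
  boot_tpm <- matrix(boot_tpm, nrow = length(contig_ids))
  tibble::tibble(
    contig_id = contig_ids,
    ci_low = apply(boot_tpm, 1L, quantile, probs = 0.025, names = FALSE),
    ci_high = apply(boot_tpm, 1L, quantile, probs = 0.975, names = FALSE)
  )
}

#' Rank and flag an expression table
#'
#' Orders records by descending TPM (ties broken by contig id), assigns
#' ranks, and flags biological activity (TPM >= `active_min`) and high
#' expression (TPM > `high_min`).
#'
#' @param records Tibble with `contig_id` and `tpm` columns.
#' @param active_min Minimum TPM considered biologically active.
#' @param high_min TPM above which a contig is highly expressed.
#' @return The reordered tibble with `rank`, `active`,
#'   `highly_expressed` columns; the TPM histogram (see
#'   [tpm_histogram()]) is attached as attribute `"histogram"`.
#' @export
summarize_expression <- function(records, active_min = 2, high_min = 100) {
  stopifnot(all(c("contig_id", "tpm") %in% names(records)))
  out <- dplyr::arrange(records, dplyr::desc(.data$tpm), .data$contig_id)
  out <- dplyr::mutate(out,
    rank = dplyr::row_number(),
    active = .data$tpm >= active_min,
    highly_expressed = .data$tpm > high_min
  )
  attr(out, "histogram") <- tpm_histogram(out$tpm)
  out
}

#' TPM histogram with mixed bin widths
#'
#' Bin width 1 from 0 to 100 TPM and width 100 above 100 TPM (the
#' highest bin is extended to cover the maximum).
#'
#' @param tpm_values Numeric vector of TPM values.
#' @return Tibble `bin_low`, `bin_high`, `count` (bins are
#'   `[bin_low, bin_high)`).
#' @export
tpm_histogram <- function(tpm_values) {
  edges <- 0:100
  if (length(tpm_values) && max(tpm_values) >= 100) {
    top <- 100 * (floor(max(tpm_values) / 100) + 1L)
    edges <- c(edges, seq(200, max(200, top), by = 100))
  }
  counts <- vapply(seq_len(length(edges) - 1L), function(i) {
    sum(tpm_values >= edges[i] & tpm_values < edges[i + 1L])
  }, integer(1))
  tibble::tibble(bin_low = edges[-length(edges)], bin_high = edges[-1],
                 count = counts)
}

#' Quantify contig expression from reads
#'
#' Full quantification stage: maps reads ([map_reads()]), resolves
#' multi-mapping by EM ([em_counts()]), computes TPM with bootstrap
#' confidence intervals, and ranks/flags the result
#' ([summarize_expression()]). Effective length is
#' `contig_length - read_length + 1` (floor 1), with `read_length` the
#' median mapped read length unless given.
#'
#' @param reads Read tibble or FASTQ path.
#' @param contigs Contig tibble (`id`, `seq`) or FASTA path.
#' @param read_len Read length for effective lengths; default the median
#'   input read length.
#' @param n_boot Bootstrap replicates (0 skips the CI).
#' @param seed Integer seed for the bootstrap.
#' @param seed_k,max_mismatch Mapping parameters.
#' @param active_min,high_min Flag thresholds (TPM).
#' @return Object of class `quant_result`: list with `expression`
#'   (ranked tibble: `contig_id`, `est_count`, `effective_length`,
#'   `tpm`, `ci_low`, `ci_high`, `rank`, `active`, `highly_expressed`),
#'   `candidates`, `unmapped`, `read_len`.
#' @export
quantify_expression <- function(reads, contigs, read_len = NULL,
                                n_boot = 100L, seed = 1L, seed_k = 20L,
                                max_mismatch = 2L, active_min = 2,
                                high_min = 100) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (is.character(contigs) && length(contigs) == 1L) {
    contigs <- read_fasta(contigs, type = "dna")
  }
  if (is.null(read_len)) {
    read_len <- if (nrow(reads)) as.integer(round(median(nchar(reads$seq)))) else 50L
  }
  mapping <- map_reads(reads, contigs, seed_k = seed_k,
                       max_mismatch = max_mismatch)
  eff_len <- setNames(pmax(nchar(contigs$seq) - read_len + 1, 1), contigs$id)
  est <- em_counts(mapping$candidates, eff_len)
  tpm_vals <- tpm(est, eff_len)
  tab <- tibble::tibble(
    contig_id = contigs$id,
    est_count = unname(est),
    effective_length = unname(eff_len),
    tpm = tpm_vals
  )
  if (n_boot > 0L && nrow(mapping$candidates) > 0L) {
    ci <- bootstrap_ci(mapping$candidates, eff_len, n_boot = n_boot, seed = seed)
    tab <- dplyr::left_join(tab, ci, by = "contig_id")
  } else {
    tab$ci_low <- tab$tpm
    tab$ci_high <- tab$tpm
  }
  tab <- summarize_expression(tab, active_min = active_min, high_min = high_min)
  structure(list(expression = tab, candidates = mapping$candidates,
                 unmapped = mapping$unmapped, read_len = read_len),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  e <- x$expression
  cat(sprintf(
    "<quant_result> %d contigs; %d reads unmapped; %d active (TPM >= 2), %d highly expressed (TPM > 100)\n",
    nrow(e), length(x$unmapped), sum(e$active), sum(e$highly_expressed)))
  invisible(x)
}

#' Tidy a quantification result
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return The per-contig expression tibble.
#' @method tidy quant_result
#' @export
tidy.quant_result <- function(x, ...) x$expression

#' Glance at a quantification result
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return One-row tibble: contig and read totals, active/high counts,
#'   total TPM.
#' @method glance quant_result
#' @export
glance.quant_result <- function(x, ...) {
  e <- x$expression
  tibble::tibble(
    n_contigs = nrow(e),
    n_reads_mapped = length(unique(x$candidates$read_id)),
    n_reads_unmapped = length(x$unmapped),
    n_active = sum(e$active),
    n_highly_expressed = sum(e$highly_expressed),
    total_tpm = sum(e$tpm)
  )
}
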