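# End-to-end pipeline orchestration over synthetic or supplied data.
#
# Stage order mirrors the study's workflow: simulate (optional) -> read
# QC -> digital normalization -> [assembly is external; contigs come
# from file or from the simulator's truth set] -> ORF extraction ->
# homology filter -> grammar classification -> quantification -> report.
# Quantification maps the QC-filtered reads (not the normalized subset,
# which only serves assembly) back to the contigs.

#' Default pipeline configuration
#'
#' All defaults equal the pipeline's stated study parameters: adapter
#' trimming, Q20 end-trim and mean-quality filter, 35 bp minimum length,
#' k = 20 / cutoff = 20 digital normalization, 125 aa minimum ORF,
#' E <= 1e-5 homology retention, TPM activity thresholds 2 and 100.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_reads = 4000L, read_len = 50L, adapter_frac = 0.05,
    adapter = DEFAULT_ADAPTER,
    q_min = 20L, q_mean_min = 20, len_min = 35L,
    k = 20L, cutoff = 20L,
    min_aa = 125L, e_max = 1e-5,
    seed_k = 20L, max_mismatch = 2L,
    n_boot = 100L, active_min = 2, high_min = 100
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config option(s): ",
                            paste(unknown, collapse = ", "))
  utils::modifyList(cfg, dots)
}

#' Run the full pipeline
#'
#' With no `reads`, simulates a read set from `pool` (default
#' [pheromone_pool()]); contigs default to the pool's true transcripts
#' (de novo assembly is out of scope). Each stage's result is kept in
#' the returned object; a manifest records the seed and parameters.
#'
#' @param reads Read tibble or FASTQ path; `NULL` to simulate.
#' @param contigs Contig tibble or FASTA path; `NULL` to use the pool
#'   transcripts.
#' @param pool Transcript pool used for simulation (and default contigs).
#' @param panel Homology/classification reference panel.
#' @param config A [pipeline_config()].
#' @param seed Integer seed for simulation and bootstrap.
#' @param out_dir Optional directory; if given, per-stage FASTQ/FASTA/TSV/
#'   JSON outputs are written there.
#' @return Object of class `pipeline_result`: list with `pool`,
#'   `simulated`, `qc`, `diginorm`, `orfs`, `homology`, `calls`, `quant`,
#'   `assembly`, `manifest`.
#' @export
run_pipeline <- function(reads = NULL, contigs = NULL,
                         pool = pheromone_pool(seed = seed),
                         panel = reference_panel(),
                         config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  simulated <- NULL
  if (is.null(reads)) {
    simulated <- stage("simulate", simulate_reads(
      pool, n_reads = config$n_reads, read_len = config$read_len,
      adapter_frac = config$adapter_frac, adapter = config$adapter,
      seed = seed))
    reads <- simulated$reads
  } else if (is.character(reads)) {
    reads <- stage("read input", read_fastq(reads))
  }
  if (is.null(contigs)) {
    contigs <- pool[, c("id", "seq")]
  } else if (is.character(contigs)) {
    contigs <- stage("contig input", read_fasta(contigs, type = "dna"))
  }
  qc <- stage("qc", run_qc(reads, adapter = config$adapter,
                           q_min = config$q_min,
                           q_mean_min = config$q_mean_min,
                           len_min = config$len_min))
  dn <- stage("normalize", normalize_by_median(qc$reads, k = config$k,
                                               cutoff = config$cutoff))
  orfs <- stage("orfs", find_orfs(contigs, min_aa = config$min_aa))
  hom <- stage("homology", filter_by_homology(orfs, panel = panel,
                                              e_max = config$e_max))
  calls <- stage("classify", annotate_pheromones(hom$retained, panel = panel))
  quant <- stage("quantify", quantify_expression(
    qc$reads, contigs, read_len = config$read_len, n_boot = config$n_boot,
    seed = seed, seed_k = config$seed_k, max_mismatch = config$max_mismatch,
    active_min = config$active_min, high_min = config$high_min))
  assembly <- stage("report", assembly_stats(contigs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("salamandr")),
    seed = seed,
    config = config,
    n_reads_in = nrow(reads),
    n_reads_qc = nrow(qc$reads),
    n_reads_normalized = nrow(dn$reads),
    n_contigs = nrow(contigs),
    n_orfs = nrow(orfs),
    n_orfs_retained = nrow(hom$retained),
    n_calls = sum(calls$class_label != "none")
  )
  res <- structure(list(pool = pool, simulated = simulated, qc = qc,
                        diginorm = dn, orfs = orfs, homology = hom,
                        calls = calls, quant = quant, assembly = assembly,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  if (!is.null(res$simulated)) {
    write_fastq(res$simulated$reads, fp("simulated.fastq"))
    utils::write.table(res$simulated$manifest, fp("read_manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_fastq(res$qc$reads, fp("filtered.fastq"))
  jsonlite::write_json(as.list(res$qc$report), fp("qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_fastq(res$diginorm$reads, fp("normalized.fastq"))
  jsonlite::write_json(as.list(res$diginorm$report), fp("diginorm_report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(res$orfs[, setdiff(names(res$orfs), "protein")],
                     fp("orfs.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_fasta(tibble::tibble(id = res$orfs$orf_id, seq = res$orfs$protein),
              fp("orfs.fasta"))
  utils::write.table(res$homology$hits, fp("homology_hits.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$calls[, setdiff(names(res$calls), "domains")],
                     fp("pheromone_calls.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$quant$expression, fp("expression.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(attr(res$quant$expression, "histogram"),
                       fp("tpm_histogram.json"), digits = NA)
  jsonlite::write_json(res$manifest, fp("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("<pipeline_result>\n",
      sprintf("  reads: %d in -> %d after QC -> %d after normalization\n",
              m$n_reads_in, m$n_reads_qc, m$n_reads_normalized),
      sprintf("  contigs: %d; ORFs >= %d aa: %d; retained by homology: %d\n",
              m$n_contigs, m$config$min_aa, m$n_orfs, m$n_orfs_retained),
      sprintf("  pheromone calls: %d\n", m$n_calls), sep = "")
  invisible(x)
}
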