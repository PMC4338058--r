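# End-to-end orchestration: simulate (or load) -> IGRs -> signals ->
# quantify -> call -> differential expression -> targets, with a JSON run
# manifest echoing every effective parameter.

#' Default pipeline configuration
#'
#' Parameter defaults are the pipeline's canonical values: 40 bp flank
#' trimming, 120 bp minimum IGR length, a 15% expression margin over both
#' flanks, and DEG cutoffs |log2 FC| > 1 with p < 0.05.
#'
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @param control Control sample name.
#' @param trim,min_len IGR extraction parameters.
#' @param margin sRNA-calling expression margin.
#' @param log2fc_cutoff,p_cutoff DEG selection cutoffs.
#' @param promoter_threshold Promoter calling threshold.
#' @param seed_min,score_min Target-prediction parameters.
#' @param sim A [sim_config()] for the synthetic input stage (its seed is
#'   overridden by `seed`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, control = "control",
                            trim = 40L, min_len = 120L, margin = 0.15,
                            log2fc_cutoff = 1, p_cutoff = 0.05,
                            promoter_threshold = 12,
                            seed_min = 8L, score_min = 10,
                            sim = sim_config()) {
  sim$seed <- as.integer(seed)
  cfg <- list(
    seed = as.integer(seed), control = control, trim = trim,
    min_len = min_len, margin = margin, log2fc_cutoff = log2fc_cutoff,
    p_cutoff = p_cutoff, promoter_threshold = promoter_threshold,
    seed_min = seed_min, score_min = score_min, sim = sim
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' Top-level keys override [pipeline_config()] defaults; the `sim` block
#' overrides [sim_config()] defaults.
#'
#' @param path Path to a JSON config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  simargs <- raw$sim %||% list()
  raw$sim <- NULL
  cfg <- do.call(pipeline_config, c(raw, list(sim = do.call(sim_config,
                                                            simargs))))
  cfg
}

#' Run the full sRNA discovery pipeline on synthetic data
#'
#' simulate -> extract IGRs -> scan signals -> count/RPKM -> call sRNAs per
#' sample and merge -> median-normalize -> sRNA fold changes -> DEGs and
#' overlap summary -> target prediction and network statistics. All outputs
#' are returned; when `outdir` is given they are also written as text files
#' together with a `manifest.json` echoing the effective parameters.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if missing).
#' @return A list with elements `sim`, `igrs`, `signals`, `units`, `expr`
#'   (raw RPKM), `expr_norm`, `calls_per_sample`, `calls`, `folds`, `degs`,
#'   `overlaps`, `edges`, `network`, `stats`, `summary`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_genome(config$sim)
  genome <- sim$genome
  conds <- config$sim$conditions
  control <- config$control
  if (!(control %in% conds)) {
    stop("control sample '", control, "' is not among the configured ",
         "conditions: ", paste(conds, collapse = ", "), call. = FALSE)
  }

  igrs <- extract_igrs(genome, trim = config$trim, min_len = config$min_len)
  signals <- scan_igr_signals(genome, igrs,
                              promoter_threshold = config$promoter_threshold)
  units <- call_units(igrs, signals)

  alignments <- simulate_reads(sim)
  dedup_al <- lapply(alignments, dedup)
  feats <- feature_intervals(genome, igrs)
  expr <- rpkm(count_features(dedup_al, feats))

  calls_per_sample <- lapply(setNames(conds, conds), function(s) {
    call_srnas(igrs, units, expr, s, margin = config$margin)
  })
  calls <- merge_calls(calls_per_sample, expr)

  expr_norm <- median_normalize(expr)
  folds <- fold_changes(calls, expr_norm, control)
  treatments <- setdiff(conds, control)
  degs <- lapply(setNames(treatments, treatments), function(s) {
    select_degs(expr_norm, control, s,
                log2fc_cutoff = config$log2fc_cutoff,
                p_cutoff = config$p_cutoff)
  })
  overlaps <- if (length(treatments) >= 2L) {
    overlap_summary(degs, reference = treatments[length(treatments)])
  } else NULL

  windows <- extract_mrna_windows(genome)
  srna_seqs <- setNames(vapply(seq_len(nrow(calls)), function(i) {
    s <- min(calls$start[i], calls$end[i])
    e <- max(calls$start[i], calls$end[i])
    sq <- subseq0_circular(genome$sequence, s, e, genome$length)
    if (calls$strand[i] == "-") revcomp(sq) else sq
  }, character(1L)), calls$srna_id)
  edges <- predict_all_targets(srna_seqs, windows,
                               seed_min = config$seed_min,
                               score_min = config$score_min)
  network <- build_network(edges)
  stats <- coregulation_stats(network)

  res <- list(
    sim = sim, igrs = igrs, signals = signals, units = units,
    expr = expr, expr_norm = expr_norm,
    calls_per_sample = calls_per_sample, calls = calls, folds = folds,
    degs = degs, overlaps = overlaps, edges = edges, network = network,
    stats = stats, summary = summarize_genome(genome), config = config
  )
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- res$sim$genome
  seqs <- Biostrings::DNAStringSet(genome$sequence)
  names(seqs) <- genome$genome_id
  Biostrings::writeXStringSet(seqs, file.path(outdir, "genome.fa"))
  write_annotation(genome, file.path(outdir, "genes.gff3"))
  alignments <- simulate_reads(res$sim)   # seeded: same reads as the run
  for (s in names(alignments)) {
    write_alignments(alignments[[s]], file.path(outdir, paste0(s, ".bed")),
                     chrom = genome$genome_id)
  }
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(as.data.frame(res$igrs), "igrs.tsv")
  tsv(res$signals, "signals.tsv")
  tsv(res$units, "units.tsv")
  write_expression(res$expr, file.path(outdir, "expression.tsv"))
  write_expression(res$expr_norm, file.path(outdir,
                                            "expression_normalized.tsv"))
  if (nrow(res$calls)) {
    writeLines(render_catalogue(res$calls),
               file.path(outdir, "srna_catalogue.tsv"), sep = "")
  }
  tsv(res$folds, "srna_fold_changes.tsv")
  tsv(do.call(rbind, res$degs), "degs.tsv")
  if (!is.null(res$overlaps)) tsv(res$overlaps, "deg_overlaps.tsv")
  export_network(res$network, file.path(outdir, "target_edges.tsv"),
                 file.path(outdir, "network.graphml"))
  manifest <- list(
    package = "srnaseeker",
    version = as.character(utils::packageVersion("srnaseeker")),
    r_version = R.version.string,
    parameters = res$config[setdiff(names(res$config), "sim")],
    sim = res$config$sim[setdiff(names(res$config$sim), "fold_change_map")],
    n_igrs = nrow(res$igrs),
    n_srnas = nrow(res$calls),
    n_target_genes = res$stats$n_targets
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
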