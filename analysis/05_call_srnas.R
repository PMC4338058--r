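#!/usr/bin/env Rscript
# Promotes IGRs to high-confidence sRNAs: complete transcriptional unit AND
# RPKM at least 15% above both flanking genes, per sample; the final set is
# the union across samples. Compares the calls with the planted ground
# truth and writes the catalogue plus per-condition fold changes.

suppressMessages(library(srnaseeker))
indir <- "results/sim"

genome <- read_genome(file.path(indir, "genome.fa"), is_circular = TRUE)
genome <- read_annotation(file.path(indir, "genes.gff3"), genome)
igrs <- extract_igrs(genome)
units <- call_units(igrs, scan_igr_signals(genome, igrs))

samples <- c("control", "acid", "bile", "git")
al <- lapply(setNames(samples, samples), function(s) {
  dedup(read_alignments(file.path(indir, paste0(s, ".bed")), s))
})
expr <- rpkm(count_features(al, feature_intervals(genome, igrs)))

per_sample <- lapply(setNames(samples, samples), function(s) {
  call_srnas(igrs, units, expr, s, margin = 0.15)
})
message(sprintf("per-sample calls: %s",
                paste(sprintf("%s=%d", samples,
                              vapply(per_sample, nrow, 1L)), collapse = ", ")))
calls <- merge_calls(per_sample, expr)
message(sprintf("high-confidence sRNAs (union): %d", nrow(calls)))

truth <- jsonlite::fromJSON(file.path(indir, "truth.json"))
precision <- mean(calls$srna_id %in% truth$planted$igr_id)
recall <- mean(truth$planted$igr_id %in% calls$srna_id)
message(sprintf("against planted truth: precision %.2f, recall %.2f",
                precision, recall))

norm <- median_normalize(expr)
folds <- fold_changes(calls, norm, control = "control")
writeLines(render_catalogue(calls), "results/srna_catalogue.tsv", sep = "")
write.table(folds, "results/srna_fold_changes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
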