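#!/usr/bin/env Rscript
# Differential expression without replicates: median normalization, exact
# conditional binomial test on deduplicated counts, DEG selection at
# |log2 FC| > 1 and p < 0.05, and pairwise overlap (Venn) counts against
# the combined-stress condition.

suppressMessages(library(srnaseeker))
indir <- "results/sim"

genome <- read_genome(file.path(indir, "genome.fa"), is_circular = TRUE)
genome <- read_annotation(file.path(indir, "genes.gff3"), genome)
igrs <- extract_igrs(genome)
samples <- c("control", "acid", "bile", "git")
al <- lapply(setNames(samples, samples), function(s) {
  dedup(read_alignments(file.path(indir, paste0(s, ".bed")), s))
})
expr <- rpkm(count_features(al, feature_intervals(genome, igrs)))
norm <- median_normalize(expr)

treatments <- c("acid", "bile", "git")
degs <- lapply(setNames(treatments, treatments), function(s) {
  select_degs(norm, "control", s)
})
for (s in treatments) {
  message(sprintf("%s: %d up, %d down", s,
                  sum(degs[[s]]$status == "up"),
                  sum(degs[[s]]$status == "down")))
}
ov <- overlap_summary(degs, reference = "git")
for (i in seq_len(nrow(ov))) {
  message(sprintf("%s %s: %d/%d shared with %s (%.1f%%)",
                  ov$condition[i], ov$direction[i], ov$n_shared[i],
                  ov$n_condition[i], ov$reference[i],
                  100 * ov$fraction_shared[i]))
}
write.table(do.call(rbind, degs), "results/degs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ov, "results/deg_overlaps.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
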