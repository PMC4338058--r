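#!/usr/bin/env Rscript
# Quantifies expression: QC demonstration on the emitted FASTQ head, PCR
# duplicate removal on the aligned intervals, read counting over genes +
# IGRs (>= 50% of read length overlap) and RPKM.

suppressMessages(library(srnaseeker))
indir <- "results/sim"

genome <- read_genome(file.path(indir, "genome.fa"), is_circular = TRUE)
genome <- read_annotation(file.path(indir, "genes.gff3"), genome)
igrs <- extract_igrs(genome)

qc <- qc_filter(file.path(indir, "control_head.fastq"))
print(qc)

samples <- c("control", "acid", "bile", "git")
al <- lapply(setNames(samples, samples), function(s) {
  dedup(read_alignments(file.path(indir, paste0(s, ".bed")), s))
})
message(sprintf("deduplicated alignments: %s",
                paste(sprintf("%s=%d", samples, vapply(al, nrow, 1L)),
                      collapse = ", ")))

expr <- rpkm(count_features(al, feature_intervals(genome, igrs)))
write_expression(expr, "results/expression.tsv")
print(expr)
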