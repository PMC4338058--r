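#!/usr/bin/env Rscript
# Scans every IGR for sigma-70 promoters (two-box PWM, spacer 15-19) and
# rho-independent terminators (hairpin + U-tract), then decides which IGRs
# hold a complete transcriptional unit.

suppressMessages(library(srnaseeker))
indir <- "results/sim"

genome <- read_genome(file.path(indir, "genome.fa"), is_circular = TRUE)
genome <- read_annotation(file.path(indir, "genes.gff3"), genome)
igrs <- extract_igrs(genome)

signals <- scan_igr_signals(genome, igrs)
units <- call_units(igrs, signals)
message(sprintf("%d signals in %d IGRs; %d complete transcriptional units",
                nrow(signals), nrow(igrs), sum(units$complete_unit)))
write.table(signals, "results/signals.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(units, "results/units.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
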