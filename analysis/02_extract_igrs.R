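#!/usr/bin/env Rscript
# Extracts candidate intergenic regions from the simulated annotation:
# inter-gene gaps trimmed by 40 bp per side, kept at >= 120 bp, tRNA/rRNA
# carriers removed. Writes the IGR table and sequences.

suppressMessages(library(srnaseeker))
indir <- "results/sim"

genome <- read_genome(file.path(indir, "genome.fa"), is_circular = TRUE)
genome <- read_annotation(file.path(indir, "genes.gff3"), genome)
print(summarize_genome(genome))

igrs <- extract_igrs(genome, trim = 40L, min_len = 120L)
message(sprintf("%d IGRs kept (mean trimmed length %.0f bp)",
                nrow(igrs), mean(igrs$length)))
write.table(as.data.frame(igrs), "results/igrs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(igr_sequences(genome, igrs), "results/igrs.fa", sep = "")
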