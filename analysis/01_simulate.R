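#!/usr/bin/env Rscript
# Generates the synthetic study inputs: a 50 kb circular genome at 60% GC
# with 45 genes, 11 planted intergenic sRNAs (consensus promoter + strong
# terminator + expression above both flanks) and 21 decoy IGRs each
# violating exactly one calling rule; then per-condition read alignments
# (control, acid, bile, simulated GIT) with negative-binomial noise.
# Everything lands under results/sim/ as plain text.

suppressMessages(library(srnaseeker))
SEED <- as.integer(Sys.getenv("SRNASEEKER_SEED", "1"))
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_genome(sim_config(seed = SEED))
al <- simulate_reads(sim)

seqs <- Biostrings::DNAStringSet(sim$genome$sequence)
names(seqs) <- sim$genome$genome_id
Biostrings::writeXStringSet(seqs, file.path(outdir, "genome.fa"))
write_annotation(sim$genome, file.path(outdir, "genes.gff3"))
for (s in names(al)) {
  write_alignments(al[[s]], file.path(outdir, paste0(s, ".bed")),
                   chrom = sim$genome$genome_id)
}
emit_fastq(sim$genome, al$control[seq_len(min(5000, nrow(al$control))), ],
           file.path(outdir, "control_head.fastq"), seed = SEED)
jsonlite::write_json(
  list(seed = SEED,
       planted = sim$truth$planted,
       decoys = sim$truth$decoys,
       planted_edges = sim$truth$planted_edges,
       deg_plan = sim$truth$deg_plan),
  file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA
)
message(sprintf("simulated %d bp genome (seed %d): %d genes, %d planted sRNAs, %d decoys",
                sim$genome$length, SEED, sum(sim$genome$features$kind == "CDS"),
                nrow(sim$truth$planted), nrow(sim$truth$decoys)))
message(sprintf("reads per sample: %s",
                paste(sprintf("%s=%d", names(al), vapply(al, nrow, 1L)),
                      collapse = ", ")))
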