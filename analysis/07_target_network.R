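#!/usr/bin/env Rscript
# Predicts sRNA target genes by antisense seed complementarity in the
# -30..+20 start-codon window, builds the bipartite regulation network,
# reports co-regulation degree statistics and a COG category tally from
# supplied labels (here synthetic labels drawn over the standard COG
# alphabet, since COG assignment is input data, not computed).

suppressMessages(library(srnaseeker))
indir <- "results/sim"
SEED <- as.integer(Sys.getenv("SRNASEEKER_SEED", "1"))

genome <- read_genome(file.path(indir, "genome.fa"), is_circular = TRUE)
genome <- read_annotation(file.path(indir, "genes.gff3"), genome)
igrs <- extract_igrs(genome)
cat_tab <- read.delim("results/srna_catalogue.tsv", encoding = "UTF-8")

windows <- extract_mrna_windows(genome)
srnas <- setNames(vapply(seq_len(nrow(cat_tab)), function(i) {
  s <- min(cat_tab$start[i], cat_tab$end[i])
  e <- max(cat_tab$start[i], cat_tab$end[i])
  sq <- substr(genome$sequence, s + 1L, e)
  if (cat_tab$strand[i] == "-") revcomp(sq) else sq
}, character(1L)), cat_tab$srna_id)

edges <- predict_all_targets(srnas, windows, seed_min = 8L, score_min = 10)
net <- build_network(edges)
st <- coregulation_stats(net)
message(sprintf("%d edges; %d target genes, %d co-regulated by >= 2 sRNAs",
                nrow(edges), st$n_targets, st$n_coregulated_ge2))
message(sprintf("max in-degree %d (%s)", st$max_in_degree,
                paste(st$genes_at_max, collapse = ", ")))

truth <- jsonlite::fromJSON(file.path(indir, "truth.json"))
if (!is.null(truth$planted_edges) && length(truth$planted_edges)) {
  pe <- paste(truth$planted_edges$srna_id, truth$planted_edges$gene_id)
  oe <- paste(edges$srna_id, edges$gene_id)
  message(sprintf("planted antisense edges recovered: %d/%d",
                  sum(pe %in% oe), length(pe)))
}

# synthetic COG labels over the standard category alphabet (input data)
set.seed(SEED)
genes <- unique(edges$gene_id)
labelled <- sample(genes, size = floor(0.9 * length(genes)))
labels <- setNames(
  vapply(labelled, function(g) {
    paste(sample(c("E", "G", "J", "K", "M", "P", "T"),
                 sample(1:2, 1)), collapse = "")
  }, character(1)), labelled)
tally <- cog_tally(genes, labels)
print(tally)

export_network(net, "results/target_edges.tsv", "results/network.graphml")
jsonlite::write_json(
  list(n_targets = st$n_targets, n_coregulated_ge2 = st$n_coregulated_ge2,
       max_in_degree = st$max_in_degree, genes_at_max = st$genes_at_max,
       cog = list(n_with_cog = tally$n_with_cog, n_total = tally$n_total,
                  counts = as.list(tally$counts))),
  "results/network_stats.json", auto_unbox = TRUE, digits = NA
)
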