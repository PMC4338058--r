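# Fixture builders shared across test files; everything is generated in
# code at test time.

# a genome object straight from components (bypasses file I/O)
make_genome <- function(sequence, features = NULL, is_circular = FALSE,
                        genome_id = "testgenome") {
  g <- srnaseeker:::new_annotated_genome(genome_id, sequence,
                                         is_circular = is_circular)
  if (!is.null(features)) g <- srnaseeker:::set_features(g, features)
  g
}

make_features <- function(starts, ends, kinds = NULL, strands = NULL,
                          ids = NULL, products = NULL) {
  n <- length(starts)
  data.frame(
    feature_id = ids %||% sprintf("g%d", seq_len(n)),
    kind = kinds %||% rep("CDS", n),
    start = as.integer(starts), end = as.integer(ends),
    strand = strands %||% rep("+", n),
    product = products %||% sprintf("product %d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an expression_table from a wide rpkm matrix (features x samples); counts
# default to rpkm-consistent values at the given totals and lengths
make_expr <- function(rpkm_mat, lengths = NULL, totals = NULL,
                      counts_mat = NULL) {
  feats <- rownames(rpkm_mat)
  samples <- colnames(rpkm_mat)
  lengths <- lengths %||% setNames(rep(1000L, length(feats)), feats)
  totals <- totals %||% setNames(rep(1e6, length(samples)), samples)
  recs <- list()
  for (s in samples) {
    for (f in feats) {
      cnt <- if (!is.null(counts_mat)) counts_mat[f, s] else
        round(rpkm_mat[f, s] * (totals[[s]] / 1e6) * (lengths[[f]] / 1e3))
      recs[[length(recs) + 1L]] <- data.frame(
        feature_id = f, sample_id = s, count = as.integer(cnt),
        length_bp = as.integer(lengths[[f]]), rpkm = rpkm_mat[f, s],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- list(records = do.call(rbind, recs),
              total_mapped = setNames(as.integer(totals), samples))
  class(out) <- "expression_table"
  out
}

# write a small FASTQ from parallel vectors
write_fastq <- function(path, ids, seqs, quals) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
}

q33 <- function(q, n) strrep(rawToChar(as.raw(33L + q)), n)
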