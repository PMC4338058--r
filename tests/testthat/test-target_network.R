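test_that("antisense seed matching finds planted complements and applies thresholds", {
  set.seed(21)
  # plant the exact reverse complement of an sRNA segment in a window
  srna <- random_dna(120, gc = 0.5)
  seed <- substr(srna, 41, 52)               # 12 nt seed
  win <- paste0(random_dna(20, 0.5), revcomp(seed), random_dna(18, 0.5))
  wins <- data.frame(gene_id = "gA", window = win, window_offset = -30L)
  edges <- predict_targets("sr1", srna, wins, seed_min = 8, score_min = 10)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$gene_id, "gA")
  expect_gte(edges$seed_len, 12L)
  expect_gte(edges$seed_start_in_srna, 0L)
  # oracle agreement on the same pair
  best <- oracle_best_target(srna, win)
  expect_equal(edges$hybrid_score, best$score)
  expect_equal(edges$position_in_mrna, best$win_start - 30L)

  # no complementarity of length >= 8: no edge
  wins2 <- data.frame(gene_id = "gB", window = strrep("A", 50),
                      window_offset = -30L)
  expect_equal(nrow(predict_targets("sr1", strrep("A", 60), wins2)), 0L)

  # an 8 A:T-pair seed scores 8 < 10: rejected by the score threshold
  # (fillers G in both: the window's G-runs reverse complement to C-runs,
  # which cannot match the sRNA's G-runs)
  srna3 <- paste0(strrep("G", 20), "AATTAATT", strrep("G", 20))
  win3 <- paste0(strrep("G", 20), revcomp("AATTAATT"), strrep("G", 22))
  wins3 <- data.frame(gene_id = "gC", window = win3, window_offset = -30L)
  expect_equal(nrow(predict_targets("sr3", srna3, wins3)), 0L)
  # the same seed passes when the score floor is lowered
  expect_equal(nrow(predict_targets("sr3", srna3, wins3, score_min = 8)), 1L)

  # window shorter than the seed is skipped with a warning
  wins4 <- data.frame(gene_id = "gD", window = "ACGT", window_offset = -30L)
  expect_warning(out <- predict_targets("sr1", srna, wins4), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("seed matcher agrees with the brute-force oracle on random pairs", {
  set.seed(14)
  for (i in 1:40) {
    srna <- random_dna(sample(30:60, 1), gc = runif(1, 0.3, 0.7))
    win <- random_dna(sample(20:50, 1), gc = runif(1, 0.3, 0.7))
    wins <- data.frame(gene_id = "g", window = win, window_offset = -30L)
    got <- predict_targets("s", srna, wins, seed_min = 5, score_min = 6)
    best <- oracle_best_target(srna, win, seed_min = 5, score_min = 6)
    if (is.null(best)) {
      expect_equal(nrow(got), 0L, info = paste(srna, win))
    } else {
      expect_equal(got$hybrid_score, best$score, info = paste(srna, win))
    }
  }
})

test_that("mRNA windows cover -30..+20 around the start codon, strand aware", {
  seqs <- random_dna(400)
  feats <- make_features(c(100, 250), c(200, 350), strands = c("+", "-"))
  g <- make_genome(seqs, feats)
  w <- extract_mrna_windows(g)
  expect_equal(nchar(w$window), c(50L, 50L))
  # plus gene: genomic [70, 120)
  expect_equal(w$window[1], substr(seqs, 71, 120))
  # minus gene: start codon at the feature end; window revcomp of [330, 380)
  expect_equal(w$window[2], revcomp(substr(seqs, 331, 380)))
})

test_that("network statistics count distinct regulators per gene", {
  edges <- data.frame(
    srna_id = c("s1", "s2", "s3", "s4", "s1", "s2"),
    gene_id = c("ftsX", "ftsX", "ftsX", "ftsX", "gA", "gB")
  )
  net <- build_network(edges)
  expect_equal(unname(net$gene_in_degree["ftsX"]), 4L)
  st <- coregulation_stats(net)
  expect_equal(st$n_targets, 3L)
  expect_equal(st$n_coregulated_ge2, 1L)
  expect_equal(st$max_in_degree, 4L)
  expect_equal(st$genes_at_max, "ftsX")

  # empty and single-edge networks
  e0 <- edges[0, ]
  expect_equal(coregulation_stats(build_network(e0))$n_targets, 0L)
  st1 <- coregulation_stats(build_network(edges[5, ]))
  expect_equal(st1$n_targets, 1L)
  expect_equal(st1$n_coregulated_ge2, 0L)
  expect_equal(st1$max_in_degree, 1L)

  # stats are invariant under edge-list permutation, and degrees match an
  # independent adjacency recount on a random bipartite fixture
  set.seed(4)
  big <- unique(data.frame(
    srna_id = sample(paste0("s", 1:11), 300, replace = TRUE),
    gene_id = sample(paste0("g", 1:80), 300, replace = TRUE)
  ))
  n1 <- build_network(big)
  n2 <- build_network(big[sample(nrow(big)), ])
  expect_equal(n1$gene_in_degree[sort(names(n1$gene_in_degree))],
               n2$gene_in_degree[sort(names(n2$gene_in_degree))])
  recount <- table(unique(big)[, "gene_id"])
  expect_equal(unname(n1$gene_in_degree[names(recount)]),
               as.integer(recount))

  expect_error(build_network(data.frame(srna_id = "x", gene_id = "x")),
               "bipartite")
})

test_that("a fixture with published-scale degrees yields 276/48/4", {
  # 1 gene with 4 regulators, 3 with 3, 44 with 2, 228 with 1: 276 genes,
  # 48 co-regulated
  srnas <- paste0("s", 1:11)
  genes <- c("ftsX", paste0("g", 1:275))
  deg <- c(4L, rep(3L, 3), rep(2L, 44), rep(1L, 228))
  edges <- do.call(rbind, lapply(seq_along(genes), function(i) {
    data.frame(srna_id = srnas[((i + seq_len(deg[i])) %% 11) + 1],
               gene_id = genes[i])
  }))
  st <- coregulation_stats(build_network(edges))
  expect_equal(st$n_targets, 276L)
  expect_equal(st$n_coregulated_ge2, 48L)
  expect_equal(st$max_in_degree, 4L)
  expect_equal(st$genes_at_max, "ftsX")
})

test_that("COG tallies count labelled targets per category letter", {
  labels <- c(gA = "E", gB = "EG", gC = "J")
  t1 <- cog_tally(c("gA", "gB", "gC", "gD"), labels)
  expect_equal(t1$n_total, 4L)
  expect_equal(t1$n_with_cog, 3L)
  expect_equal(t1$counts[["E"]], 2L)
  expect_equal(t1$counts[["G"]], 1L)
  # multi-letter genes count once per category: sum >= n_with_cog
  expect_gte(sum(t1$counts), t1$n_with_cog)

  expect_equal(cog_tally(c("gX"), labels)$n_with_cog, 0L)

  # 248 of 276 labelled, echoing the published scale
  targets <- paste0("t", 1:276)
  lab <- setNames(rep("E", 248), targets[1:248])
  t2 <- cog_tally(targets, lab)
  expect_equal(t2$n_with_cog, 248L)
  expect_equal(t2$n_total, 276L)

  expect_warning(t3 <- cog_tally("gA", c(gA = "E?")), "unknown")
  expect_equal(t3$counts[["other"]], 1L)
})

test_that("network export writes an edge TSV and GraphML", {
  edges <- data.frame(srna_id = c("s1", "s2"), gene_id = c("gA", "gA"),
                      hybrid_score = c(12, 14), seed_len = c(8L, 9L))
  net <- build_network(edges)
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  export_network(net, tsv, gml)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 2L)
  expect_true(any(grepl("graphml", readLines(gml, n = 3), fixed = TRUE)))
})
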