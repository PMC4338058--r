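test_that("the generator is deterministic and honours its stated world", {
  cfg <- sim_config(seed = 42)
  sim1 <- simulate_genome(cfg)
  sim2 <- simulate_genome(sim_config(seed = 42))
  expect_identical(sim1$genome$sequence, sim2$genome$sequence)
  expect_identical(sim1$truth$planted, sim2$truth$planted)

  g <- sim1$genome
  expect_equal(g$length, 50000L)
  expect_true(g$is_circular)
  # realized GC within +/- 0.02 of the target at 50 kb (binomial sd bound)
  expect_lt(abs(summarize_genome(g)$gc_fraction - 0.60), 0.02)
  # 11 planted sRNAs, 9 plus / 2 minus; three decoy classes of 7
  expect_equal(nrow(sim1$truth$planted), 11L)
  expect_equal(as.integer(table(sim1$truth$planted$strand)[c("+", "-")]),
               c(9L, 2L))
  expect_equal(as.integer(table(sim1$truth$decoys$class)),
               rep(7L, 3))
  # feature complement: 45 CDS, 2 tRNA, 1 rRNA
  s <- summarize_genome(g)
  expect_equal(s$n_genes, 45L)
  expect_equal(s$n_trna, 2L)
  expect_equal(s$n_rrna, 1L)

  # a different seed gives a different genome
  expect_false(identical(sim1$genome$sequence,
                         simulate_genome(sim_config(seed = 43))$genome$sequence))
})

test_that("planted IGRs carry complete units; decoys lack exactly their element", {
  sim <- simulate_genome(sim_config(seed = 7))
  igrs <- extract_igrs(sim$genome)
  # truth and extractor agree on the IGR inventory
  expect_equal(igrs$igr_id, sim$truth$igr_features$igr_id)
  expect_equal(igrs$start, sim$truth$igr_features$start)
  expect_equal(igrs$end, sim$truth$igr_features$end)

  units <- call_units(igrs, scan_igr_signals(sim$genome, igrs))
  cu <- setNames(units$complete_unit, units$igr_id)
  us <- setNames(units$unit_strand, units$igr_id)
  tr <- sim$truth
  expect_true(all(cu[tr$planted$igr_id]))
  expect_equal(unname(us[tr$planted$igr_id]), tr$planted$strand)
  expect_true(all(cu[tr$decoys$igr_id[tr$decoys$class == "low_expression"]]))
  expect_false(any(cu[tr$decoys$igr_id[tr$decoys$class %in%
                                         c("no_promoter", "no_terminator")]]))
})

test_that("read counts follow the configured expression programme", {
  cfg <- sim_config(seed = 3)
  sim <- simulate_genome(cfg)
  al <- simulate_reads(sim)
  expect_setequal(names(al), c("control", "acid", "bile", "git"))
  # library sizes close to the configured depth
  for (s in names(al)) {
    expect_gt(nrow(al[[s]]), 0.8 * cfg$reads_per_sample)
    expect_lt(nrow(al[[s]]), 1.4 * cfg$reads_per_sample)
  }
  # duplicate fraction: dedup removes at least the injected duplicates
  dd <- dedup(al$control)
  expect_lte(nrow(dd), nrow(al$control) / 1.08)
  # dedup output equals the independent distinct-triple count
  expect_equal(nrow(dd),
               nrow(unique(al$control[, c("start", "end", "strand")])))

  # a feature forced to zero expression gets no reads
  fcm <- matrix(0, 1, 3, dimnames = list("gene05", c("acid", "bile", "git")))
  cfg0 <- sim_config(seed = 3, fold_change_map = fcm)
  sim0 <- simulate_genome(cfg0)
  al0 <- simulate_reads(sim0)
  f <- sim0$genome$features
  g5 <- f[f$feature_id == "gene05", ]
  hits <- sum(al0$acid$start < g5$end & al0$acid$end > g5$start)
  # only stray edge overlap from neighbouring features can touch it
  expect_lte(hits, 5L)
})

test_that("planted fold changes are realized within sampling noise", {
  # the strongly acid-induced planted sRNA (configured ratio 4.12) should
  # show a normalized realized ratio compatible with NB noise; the ratio's
  # log sd is ~sqrt(2 * (1/mu + disp)) ~ 0.33 here, so 3 sd is a factor 2.7
  ratios <- numeric(6)
  for (k in seq_along(ratios)) {
    sim <- simulate_genome(sim_config(seed = 100 + k))
    al <- simulate_reads(sim)
    igrs <- extract_igrs(sim$genome)
    expr <- rpkm(count_features(lapply(al, dedup),
                                feature_intervals(sim$genome, igrs)))
    norm <- median_normalize(expr)
    pl <- sim$truth$planted[order(sim$truth$planted$plant_index), ]
    id <- pl$igr_id[8]   # plant 8 carries the 4.12 acid response
    r <- norm$records
    ratios[k] <- r$rpkm[r$feature_id == id & r$sample_id == "acid"] /
      r$rpkm[r$feature_id == id & r$sample_id == "control"]
  }
  expect_true(all(ratios > 4.12 / 2.7 & ratios < 4.12 * 2.7))
  # and the mean is close on the log scale (3 standard errors)
  expect_lt(abs(mean(log(ratios)) - log(4.12)), 3 * 0.33 / sqrt(length(ratios)))
})

test_that("differential expression recovers planted DEGs and stays calibrated", {
  sens_num <- 0L; sens_den <- 0L
  fp <- 0L; null_n <- 0L
  for (seed in c(5, 6)) {
    sim <- simulate_genome(sim_config(seed = seed))
    al <- simulate_reads(sim)
    igrs <- extract_igrs(sim$genome)
    expr <- rpkm(count_features(lapply(al, dedup),
                                feature_intervals(sim$genome, igrs)))
    norm <- median_normalize(expr)
    plan <- sim$truth$deg_plan
    genes <- sim$genome$features$feature_id[sim$genome$features$kind == "CDS"]
    for (cond in names(plan)) {
      degs <- select_degs(norm, "control", cond)
      st <- setNames(degs$status, degs$feature_id)
      sens_num <- sens_num + sum(st[plan[[cond]]$up] == "up") +
        sum(st[plan[[cond]]$down] == "down")
      sens_den <- sens_den + length(plan[[cond]]$up) +
        length(plan[[cond]]$down)
      null_genes <- setdiff(genes, c(plan[[cond]]$up, plan[[cond]]$down))
      fp <- fp + sum(st[null_genes] != "ns")
      null_n <- null_n + length(null_genes)
    }
  }
  expect_gte(sens_num / sens_den, 0.9)
  expect_lte(fp / null_n, 0.05)
})

test_that("emitted FASTQ reads fail QC at the configured rate", {
  sim <- simulate_genome(sim_config(seed = 9))
  al <- simulate_reads(sim)
  sub <- al$control[1:2000, ]
  fq <- tempfile(fileext = ".fastq")
  emit_fastq(sim$genome, sub, fq, fail_fraction = 0.2, seed = 9)
  rep <- qc_filter(fq)
  expect_equal(rep$reads_in, 2000L)
  # kept fraction close to 1 - fail_fraction (binomial noise)
  expect_lt(abs(rep$fraction_kept - 0.8), 0.03)
  # surviving reads lost their Q2 ends
  expect_true(all(nchar(rep$clean$seq) ==
                    sub$end[match(rep$clean$id, sub$read_id)] -
                    sub$start[match(rep$clean$id, sub$read_id)] - 4L))
})
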