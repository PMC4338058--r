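test_that("qc_filter applies end trimming, the length rule and the Q20 rule", {
  fq <- tempfile(fileext = ".fastq")
  write_fastq(fq,
    ids = c("ok50", "len20", "q76", "trimmed"),
    seqs = c(strrep("A", 50), strrep("A", 20), strrep("A", 30),
             strrep("A", 30)),
    quals = c(
      q33(30, 50),                      # all Q30: kept
      q33(30, 20),                      # exactly 20 nt: dropped (strict >)
      paste0(q33(30, 23), q33(10, 7)),  # 23/30 = 76.7% > Q20: dropped
      paste0(q33(2, 4), q33(30, 26))    # 4 Q2 bases trimmed, 26 left: kept
    ))
  rep <- qc_filter(fq)
  expect_equal(rep$reads_in, 4L)
  expect_equal(rep$reads_clean, 2L)
  expect_equal(rep$fraction_kept, 0.5)
  expect_setequal(rep$clean$id, c("ok50", "trimmed"))
  expect_equal(nchar(rep$clean$seq[rep$clean$id == "trimmed"]), 26L)

  # a read of 21 nt passes the strict > 20 rule
  write_fastq(fq, "r21", strrep("C", 21), q33(30, 21))
  expect_equal(qc_filter(fq)$reads_clean, 1L)

  # sequence/quality length mismatch is a parse error
  writeLines(c("@r1", "ACGT", "+", "III"), fq)
  expect_error(qc_filter(fq), "length")

  # clean FASTQ written out
  write_fastq(fq, c("a", "b"), c(strrep("A", 30), strrep("A", 10)),
              c(q33(30, 30), q33(30, 10)))
  out <- tempfile(fileext = ".fastq")
  qc_filter(fq, out_path = out)
  expect_equal(length(readLines(out)), 4L)
})

test_that("dedup keeps exactly one alignment per (start, end, strand)", {
  al <- data.frame(
    read_id = paste0("r", 1:5),
    start = c(10L, 10L, 10L, 10L, 11L),
    end = c(60L, 60L, 60L, 61L, 61L),
    strand = c("+", "+", "+", "+", "+"),
    sample_id = "s1"
  )
  dd <- dedup(al)
  expect_equal(nrow(dd), 3L)           # 3 identical -> 1; 1 bp shifts kept
  expect_equal(dd$read_id, c("r1", "r4", "r5"))  # order preserved

  # 10,000 random intervals with duplicates: output size equals the number
  # of distinct triples, counted independently
  set.seed(77)
  base <- data.frame(
    start = sample(1e5, 7000, replace = TRUE), width = sample(30:50, 7000,
                                                              replace = TRUE),
    strand = sample(c("+", "-"), 7000, replace = TRUE)
  )
  big <- rbind(base, base[sample(7000, 3000, replace = TRUE), ])
  big <- big[sample(nrow(big)), ]
  al2 <- data.frame(read_id = paste0("r", seq_len(nrow(big))),
                    start = big$start, end = big$start + big$width,
                    strand = big$strand, sample_id = "s1")
  expect_equal(nrow(dedup(al2)),
               nrow(unique(big[, c("start", "width", "strand")])))

  expect_error(dedup(rbind(al, transform(al, sample_id = "s2"))),
               "single sample")
})

test_that("count_features applies the 50%-of-read-length overlap rule", {
  feats <- data.frame(feature_id = c("gA", "gB"),
                      start = c(100L, 600L), end = c(500L, 900L),
                      length_bp = c(400L, 300L), class = "gene")
  al <- data.frame(
    read_id = c("full", "edge40"),
    start = c(100L, 480L), end = c(150L, 530L),
    strand = "+", sample_id = "s1"
  )
  tab <- count_features(list(s1 = al), feats)
  counts <- setNames(tab$records$count, tab$records$feature_id)
  expect_equal(counts[["gA"]], 1L)   # 100% overlap assigned
  expect_equal(counts[["gB"]], 0L)   # edge read: 20/50 = 40% < 50%
  expect_equal(unname(tab$total_mapped["s1"]), 2L)

  # a read spanning both features with >= 50% in each is multi-assigned
  al2 <- data.frame(read_id = "straddle", start = 560L, end = 640L,
                    strand = "+", sample_id = "s1")
  tab2 <- count_features(list(s1 = al2), feats)
  expect_equal(setNames(tab2$records$count, tab2$records$feature_id)[["gB"]],
               1L)

  # random placement matches the naive O(n*m) oracle
  set.seed(31)
  feats3 <- data.frame(
    feature_id = paste0("f", 1:6),
    start = c(0L, 300L, 500L, 1200L, 2000L, 2050L),
    end = c(250L, 520L, 900L, 1900L, 2400L, 2300L),
    length_bp = 0L, class = "gene"
  )
  feats3$length_bp <- feats3$end - feats3$start
  al3 <- data.frame(
    read_id = paste0("r", 1:400),
    start = sample(0:2400, 400, replace = TRUE), strand = "+",
    sample_id = "s1"
  )
  al3$end <- al3$start + sample(20:60, 400, replace = TRUE)
  tab3 <- count_features(list(s1 = al3), feats3)
  got <- setNames(tab3$records$count, tab3$records$feature_id)
  expect_equal(got[feats3$feature_id], oracle_count(al3, feats3))
})

test_that("rpkm matches its defining identity", {
  expr <- make_expr(matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "s1")),
                    lengths = c(a = 1000L, b = 500L, c = 800L),
                    counts_mat = matrix(c(100L, 10L, 0L), 3, 1,
                                        dimnames = list(c("a", "b", "c"),
                                                        "s1")))
  expr$total_mapped <- c(s1 = 1000000L)
  out <- rpkm(expr)
  r <- setNames(out$records$rpkm, out$records$feature_id)
  expect_equal(r[["a"]], 100)   # count 100, 1 kb, 1 M mapped
  expect_equal(r[["b"]], 20)    # count 10, 0.5 kb, 1 M mapped
  expect_equal(r[["c"]], 0)     # zero count -> zero RPKM

  # linearity: doubling the count doubles RPKM at fixed totals
  expr$records$count <- expr$records$count * 2L
  out2 <- rpkm(expr)
  expect_equal(out2$records$rpkm, out$records$rpkm * 2)

  # zero total with nonzero counts is inconsistent
  bad <- expr
  bad$total_mapped <- c(s1 = 0L)
  expect_error(rpkm(bad), "total_mapped")
})

test_that("k-fold PCR duplication changes nothing after dedup", {
  set.seed(13)
  feats <- data.frame(feature_id = c("gA", "gB"),
                      start = c(0L, 700L), end = c(500L, 1200L),
                      length_bp = c(500L, 500L), class = "gene")
  al <- data.frame(
    read_id = paste0("r", 1:300),
    start = sample(0:1150, 300, replace = TRUE), strand = "+",
    sample_id = "s1"
  )
  al$end <- al$start + 50L
  base <- rpkm(count_features(list(s1 = dedup(al)), feats))
  for (k in c(2L, 5L)) {
    dup <- al[rep(seq_len(nrow(al)), k), ]
    dup <- dup[sample(nrow(dup)), ]
    again <- rpkm(count_features(list(s1 = dedup(dup)), feats))
    expect_equal(again$records$count, base$records$count)
    expect_equal(again$records$rpkm, base$records$rpkm)
  }
})
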