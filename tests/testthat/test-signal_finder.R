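PWMS <- default_sigma70_pwms()
CONSENSUS_SCORE <- 12 * log2(0.7 / 0.25)   # two perfect hexamer boxes

test_that("promoter scan finds the sigma-70 consensus with zero spacer penalty", {
  set.seed(11)
  left <- random_dna(30, gc = 0.6)
  spacer <- random_dna(17, gc = 0.6)
  seqs <- paste0(left, "TTGACA", spacer, "TATAAT", random_dna(40, gc = 0.6))
  hits <- scan_promoters(seqs, "+", PWMS$pwm35, PWMS$pwm10, threshold = 12)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$score), ]
  # consensus boxes maximize a log-odds PWM; spacer 17 has no penalty
  expect_gte(best$score, CONSENSUS_SCORE - 1e-9)
  expect_equal(best$spacer_len, 17L)
  # TSS proxy: first base after the -10 box
  expect_equal(best$position, 30L + 6L + 17L + 6L)

  # nothing callable in a homopolymer
  expect_equal(nrow(scan_promoters(strrep("A", 80), "+", PWMS$pwm35,
                                   PWMS$pwm10, threshold = 12)), 0L)
})

test_that("promoter scan recovers a planted consensus at the right offset", {
  for (seed in c(3, 17, 29)) {
    set.seed(seed)
    offset <- sample(10:60, 1)
    s <- paste0(random_dna(offset, gc = 0.6),
                "TTGACA", random_dna(17, gc = 0.6), "TATAAT",
                random_dna(30, gc = 0.6))
    hits <- scan_promoters(s, "+", PWMS$pwm35, PWMS$pwm10, threshold = 12)
    oracle <- oracle_scan_promoters(s, "+", PWMS$pwm35, PWMS$pwm10, 12)
    want <- offset + 29   # TSS proxy of the plant
    expect_true(any(abs(hits$position - want) <= 1))
    expect_equal(hits$position, oracle$position)
    expect_equal(hits$score, oracle$score, tolerance = 1e-12)
  }
})

test_that("terminator scorer reproduces the worked GC-stem example", {
  # 6 bp all-GC stem, 4 nt loop, 8 T tail:
  # hairpin 6*2 - 0.5*(4-3) = 11.5; tail 1+1+.9+.8+.7+.6+.5+.4 = 5.9
  s <- paste0("GCCGGC", "TTTT", revcomp("GCCGGC"), "TTTTTTTT")
  hits <- scan_terminators(s, "+")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$stem_len, 6L)
  expect_equal(hits$loop_len, 4L)
  expect_equal(hits$hairpin_score, 11.5)
  expect_equal(hits$tail_score, 5.9)
  expect_equal(hits$score, 11.5 + 2 * 5.9)
  expect_equal(hits$position, 16L)   # first base of the U-tract

  # same hairpin, A tail: tail score 0 < 2.5 -> no hit
  s2 <- paste0("GCCGGC", "TTTT", revcomp("GCCGGC"), "AAAAAAAA")
  expect_equal(nrow(scan_terminators(s2, "+")), 0L)

  # poly-A can form no stem
  expect_equal(nrow(scan_terminators(strrep("A", 60), "+")), 0L)
})

test_that("scanners agree with exhaustive brute-force enumeration", {
  set.seed(42)
  fixtures <- c(
    # adversarial: overlapping stems, wobble pairs, mismatch stems, near-
    # consensus promoters
    paste0("GCCGGC", "TTTT", "GCCGGC", "TTTTTTTT"),
    paste0("GCGCGCGC", "AAA", "GCGCGCGC", "TTTTTTTT"),
    paste0("GTGTGT", "TTTT", "ACACAC", "TTTTTTTT"),
    "TTGACATTTTTTTTTTTTTTTTTAT",
    strrep("GC", 12),
    replicate(40, random_dna(sample(15:45, 1), gc = 0.5)),   # > 27 nt also
    replicate(30, random_dna(sample(15:45, 1), gc = 0.7))    # covers promoters
  )
  for (s in fixtures) {
    for (strand in c("+", "-")) {
      t_fast <- scan_terminators(s, strand)
      t_slow <- oracle_scan_terminators(s, strand)
      expect_equal(t_fast$position, t_slow$position, info = s)
      expect_equal(t_fast$score, t_slow$score, tolerance = 1e-9, info = s)
      expect_equal(t_fast$hairpin_score, t_slow$hairpin_score,
                   tolerance = 1e-9, info = s)
      p_fast <- scan_promoters(s, strand, PWMS$pwm35, PWMS$pwm10, 8)
      p_slow <- oracle_scan_promoters(s, strand, PWMS$pwm35, PWMS$pwm10, 8)
      expect_equal(p_fast$position, p_slow$position, info = s)
      expect_equal(p_fast$score, p_slow$score, tolerance = 1e-9, info = s)
    }
  }
})

test_that("strand symmetry: scanning the reverse complement swaps strands only", {
  set.seed(5)
  for (i in 1:10) {
    s <- paste0(random_dna(20, 0.6), "TTGACA", random_dna(17, 0.4), "TATAAT",
                random_dna(10, 0.5), "GGCAGC", "TCAA", revcomp("GGCAGC"),
                "TTTTTTTT", random_dna(20, 0.6))
    rc <- revcomp(s)
    for (scan in list(
      function(x, st) scan_promoters(x, st, PWMS$pwm35, PWMS$pwm10, 10),
      function(x, st) scan_terminators(x, st)
    )) {
      fwd <- scan(s, "+")
      swapped <- scan(rc, "-")
      expect_equal(sort(fwd$score), sort(swapped$score), tolerance = 1e-12)
      # positions map through x -> n - 1 - x
      expect_equal(sort(fwd$position),
                   sort(nchar(s) - 1L - swapped$position))
    }
  }
})

test_that("complete-unit calls require promoter upstream of terminator, same strand", {
  sig <- function(kind, strand, pos) {
    data.frame(kind = kind, strand = strand, position = pos)
  }
  # promoter at 100, terminator at 300 on '+': complete
  u <- call_unit("x", rbind(sig("promoter", "+", 100),
                            sig("terminator", "+", 300)))
  expect_true(u$complete_unit)
  expect_equal(u$unit_strand, "+")
  # promoter only: incomplete
  expect_false(call_unit("x", sig("promoter", "+", 100))$complete_unit)
  # wrong order on '+': incomplete
  expect_false(call_unit("x", rbind(sig("promoter", "+", 300),
                                    sig("terminator", "+", 100)))$complete_unit)
  # on '-' transcription runs right to left: promoter position > terminator
  u2 <- call_unit("x", rbind(sig("promoter", "-", 300),
                             sig("terminator", "-", 100)))
  expect_true(u2$complete_unit)
  expect_equal(u2$unit_strand, "-")
  # both strands qualify: '+' wins the tie
  u3 <- call_unit("x", rbind(sig("promoter", "+", 10),
                             sig("terminator", "+", 200),
                             sig("promoter", "-", 200),
                             sig("terminator", "-", 10)))
  expect_equal(u3$unit_strand, "+")
  # signals on different strands never combine
  expect_false(call_unit("x", rbind(sig("promoter", "+", 10),
                                    sig("terminator", "-", 200)))$complete_unit)
})

test_that("planted units are recovered and promoter-free IGRs stay quiet", {
  set.seed(99)
  n_rec <- 0L
  n_fp <- 0L
  N <- 100L
  for (i in seq_len(N)) {
    planted <- srnaseeker:::build_core(0.6, TRUE, TRUE, "+")
    if (srnaseeker:::core_unit_status(planted)$complete_unit) {
      n_rec <- n_rec + 1L
    }
    bare <- srnaseeker:::build_core(0.6, FALSE, FALSE, "+")
    if (srnaseeker:::core_unit_status(bare)$complete_unit) n_fp <- n_fp + 1L
  }
  expect_gte(n_rec / N, 0.95)
  expect_lte(n_fp / N, 0.10)
})

test_that("PWM files round trip and match the consensus builder", {
  p35 <- read_pwm(system.file("extdata", "sigma70_minus35.tsv",
                              package = "srnaseeker"))
  expect_equal(unname(p35$matrix), unname(PWMS$pwm35$matrix),
               tolerance = 1e-12)
  tmp <- tempfile(fileext = ".tsv")
  write_pwm(PWMS$pwm10, tmp)
  back <- read_pwm(tmp)
  expect_equal(unname(back$matrix), unname(PWMS$pwm10$matrix),
               tolerance = 1e-12)
})
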