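# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain substr/loops, re-deriving every score from the
# documented rules.

ORACLE_PAIR <- function(x, y) {
  key <- paste0(x, y)
  if (key %in% c("GC", "CG")) return(2)
  if (key %in% c("AT", "TA")) return(1)
  if (key %in% c("GT", "TG")) return(0.5)
  -2
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# score one box against a pwm object at a 1-based offset
oracle_box_score <- function(seq, at, pwm) {
  tot <- 0
  for (j in seq_len(pwm$width)) {
    b <- substr(seq, at + j - 1, at + j - 1)
    tot <- tot + if (b %in% rownames(pwm$matrix)) pwm$matrix[b, j] else -100
  }
  tot
}

# enumerate every promoter placement, keep best spacer per -35 start, apply
# the same documented greedy best-score overlap resolution
oracle_scan_promoters <- function(seq, strand, pwm35, pwm10, threshold) {
  s <- if (strand == "-") oracle_revcomp(seq) else seq
  n <- nchar(s)
  cand <- NULL
  for (i in seq_len(max(n, 1))) {
    best <- NULL
    for (sp in 15:19) {
      end <- i + pwm35$width + sp + pwm10$width - 1
      if (end > n) next
      sc <- oracle_box_score(s, i, pwm35) +
        oracle_box_score(s, i + pwm35$width + sp, pwm10) -
        0.5 * abs(sp - 17)
      if (is.null(best) || sc > best$sc) best <- list(sp = sp, sc = sc, to = end)
    }
    if (!is.null(best) && best$sc >= threshold) {
      cand <- rbind(cand, data.frame(i = i, sp = best$sp, sc = best$sc,
                                     to = best$to))
    }
  }
  if (is.null(cand)) {
    return(data.frame(position = integer(), strand = character(),
                      score = numeric()))
  }
  cand <- cand[order(-cand$sc, cand$i), , drop = FALSE]
  picked <- NULL
  for (k in seq_len(nrow(cand))) {
    if (is.null(picked) ||
        !any(cand$i[k] <= picked$to & cand$to[k] >= picked$i)) {
      picked <- rbind(picked, cand[k, ])
    }
  }
  pos_local <- picked$i - 1 + pwm35$width + picked$sp + pwm10$width
  pos <- if (strand == "+") pos_local else n - 1 - pos_local
  out <- data.frame(position = as.integer(pos), strand = strand,
                    score = picked$sc)
  out[order(out$position), , drop = FALSE]
}

# enumerate every (start, stem, loop) hairpin candidate
oracle_scan_terminators <- function(seq, strand, params = NULL) {
  if (is.null(params)) {
    params <- list(stem_min = 4, stem_max = 15, loop_min = 3, loop_max = 10,
                   max_mismatch = 1, min_hairpin = 8, min_tail = 2.5)
  }
  s <- if (strand == "-") oracle_revcomp(seq) else seq
  n <- nchar(s)
  w <- c(1, 1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  cand <- NULL
  for (i in seq_len(max(n, 1))) {
    for (st in params$stem_min:params$stem_max) {
      for (lp in params$loop_min:params$loop_max) {
        span <- 2 * st + lp
        if (i + span - 1 > n) next
        hp <- 0; mm <- 0
        for (j in seq_len(st)) {
          ps <- ORACLE_PAIR(substr(s, i + j - 1, i + j - 1),
                            substr(s, i + span - j, i + span - j))
          hp <- hp + ps
          if (ps <= -2) mm <- mm + 1
        }
        hp <- hp - 0.5 * (lp - 3)
        tl <- 0
        for (k in 1:8) {
          p <- i + span + k - 1
          if (p <= n && substr(s, p, p) == "T") tl <- tl + w[k]
        }
        if (mm <= params$max_mismatch && hp >= params$min_hairpin &&
            tl >= params$min_tail) {
          cand <- rbind(cand, data.frame(
            i = i, stem = st, loop = lp, hp = hp, tl = tl,
            sc = hp + 2 * tl, to = min(i + span + 7, n)
          ))
        }
      }
    }
  }
  if (is.null(cand)) {
    return(data.frame(position = integer(), strand = character(),
                      score = numeric(), hairpin_score = numeric(),
                      tail_score = numeric()))
  }
  cand <- cand[order(-cand$sc, cand$i), , drop = FALSE]
  picked <- NULL
  for (k in seq_len(nrow(cand))) {
    if (is.null(picked) ||
        !any(cand$i[k] <= picked$to & cand$to[k] >= picked$i)) {
      picked <- rbind(picked, cand[k, ])
    }
  }
  pos_local <- picked$i - 1 + 2 * picked$stem + picked$loop
  pos <- if (strand == "+") pos_local else n - 1 - pos_local
  out <- data.frame(position = as.integer(pos), strand = strand,
                    score = picked$sc, hairpin_score = picked$hp,
                    tail_score = picked$tl)
  out[order(out$position), , drop = FALSE]
}

# naive O(reads x features) counting with the >= 50%-of-read-length rule
oracle_count <- function(al, features, min_frac = 0.5) {
  counts <- setNames(integer(nrow(features)), features$feature_id)
  for (r in seq_len(nrow(al))) {
    rs <- al$start[r]; re <- al$end[r]
    for (f in seq_len(nrow(features))) {
      ov <- min(re, features$end[f]) - max(rs, features$start[f])
      if (ov >= min_frac * (re - rs)) {
        counts[features$feature_id[f]] <- counts[features$feature_id[f]] + 1L
      }
    }
  }
  counts
}

# brute-force antisense matcher: try every substring of the window, check
# whether its reverse complement occurs in the sRNA
oracle_best_target <- function(srna, window, seed_min = 8, score_min = 10) {
  n <- nchar(window)
  best <- NULL
  for (a in seq_len(n)) {
    for (b in a:n) {
      len <- b - a + 1
      if (len < seed_min) next
      sub <- substr(window, a, b)
      rc <- oracle_revcomp(sub)
      if (!grepl(rc, srna, fixed = TRUE)) next
      sc <- 0
      for (ch in strsplit(rc, "")[[1]]) {
        sc <- sc + if (ch %in% c("G", "C")) 2 else 1
      }
      if (sc < score_min) next
      if (is.null(best) || sc > best$score ||
          (sc == best$score && len > best$len)) {
        best <- list(score = sc, len = len, win_start = a - 1)
      }
    }
  }
  best
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
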