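# Promoter and rho-independent terminator detection inside IGRs, and the
# "complete transcriptional unit" decision.
#
# Both scanners are deliberately transparent, deterministic stand-ins for
# the opaque external tools a practitioner might use: their role in this
# pipeline is a boolean gate (does the IGR hold a promoter / a terminator?),
# so a log-odds PWM pair for the sigma-70 -35/-10 boxes and an enumerative
# hairpin + U-tract scorer are sufficient and fully testable.

# ---------------------------------------------------------------- promoters

#' Build a position weight matrix from a consensus
#'
#' Log2-odds PWM against a uniform background (0.25 per base), built from
#' pseudocount-smoothed near-consensus counts: at each position the consensus
#' base receives weight `consensus_weight` and every other base
#' `(1 - consensus_weight) / 3`.
#'
#' @param consensus DNA string, e.g. `"TTGACA"`.
#' @param name PWM name.
#' @param consensus_weight Probability mass on the consensus base
#'   (default 0.7).
#' @return A list of class `pwm` with fields `name`, `matrix` (4 x width,
#'   rows A,C,G,T), `width`.
#' @export
pwm_from_consensus <- function(consensus, name = consensus,
                               consensus_weight = 0.7) {
  bases <- strsplit(toupper(consensus), "")[[1L]]
  stopifnot(all(bases %in% BASES))
  w <- length(bases)
  p <- matrix((1 - consensus_weight) / 3, nrow = 4L, ncol = w,
              dimnames = list(BASES, NULL))
  for (j in seq_len(w)) p[bases[j], j] <- consensus_weight
  m <- log2(p / 0.25)
  structure(list(name = name, matrix = m, width = w), class = "pwm")
}

#' Read a PWM from a tabular text file
#'
#' The file format is 4 tab-separated rows labelled A, C, G, T with one
#' numeric column per position (log2-odds scores).
#'
#' @param path Path to the PWM file.
#' @param name PWM name (defaults to the file name).
#' @return A `pwm` object.
#' @export
read_pwm <- function(path, name = basename(path)) {
  tab <- read.delim(path, header = FALSE, row.names = 1L)
  m <- as.matrix(tab)
  if (!setequal(rownames(m), BASES)) {
    stop("PWM file must have rows A, C, G, T: ", path, call. = FALSE)
  }
  m <- m[BASES, , drop = FALSE]
  if (any(!is.finite(m))) stop("PWM contains non-finite scores: ", path,
                               call. = FALSE)
  dimnames(m) <- list(BASES, NULL)
  structure(list(name = name, matrix = m, width = ncol(m)), class = "pwm")
}

#' Write a PWM to a tabular text file
#' @param pwm A `pwm` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(base = rownames(pwm$matrix), pwm$matrix)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Default sigma-70 -35 / -10 box PWMs
#'
#' Built from the canonical TTGACA / TATAAT consensus via
#' [pwm_from_consensus()]; also shipped as text files under
#' `inst/extdata/` so scores in reports are reproducible outside R.
#'
#' @return A list with elements `pwm35` and `pwm10`.
#' @export
default_sigma70_pwms <- function() {
  list(
    pwm35 = pwm_from_consensus("TTGACA", name = "sigma70_minus35"),
    pwm10 = pwm_from_consensus("TATAAT", name = "sigma70_minus10")
  )
}

# per-position PWM score track; positions with N score -100
pwm_score_track <- function(codes, pwm) {
  n <- length(codes)
  w <- pwm$width
  if (n < w) return(numeric(0L))
  m <- rbind(pwm$matrix, N = -100)
  sc <- numeric(n - w + 1L)
  for (j in seq_len(w)) {
    sc <- sc + m[cbind(codes[j:(n - w + j)], j)]
  }
  sc
}

#' Scan a sequence for sigma-70 promoters
#'
#' Slides a two-box model over the sequence: at each candidate -35 position
#' the score is `PWM35(-35 hexamer) + PWM10(-10 hexamer) + spacer_penalty`,
#' maximised over spacer lengths 15-19 bp (penalty 0 at 17, -0.5 per bp of
#' deviation). All non-overlapping local maxima scoring at least `threshold`
#' are reported; the minus strand is scanned on the reverse complement with
#' positions mapped back to forward coordinates.
#'
#' The reported `position` is a transcription start proxy: the first base
#' after the -10 box, in forward-strand coordinates of `seq` (0-based).
#'
#' @param seq DNA string (length >= 40 for a meaningful scan).
#' @param strand `"+"` to scan the given sequence, `"-"` to scan its reverse
#'   complement.
#' @param pwm35,pwm10 `pwm` objects for the -35 and -10 boxes.
#' @param threshold Minimum total score called (default 12, calibrated on
#'   synthetic GC-rich background; consensus boxes score 17.83).
#' @return A data.frame with columns `kind`, `position`, `strand`, `score`,
#'   `minus35_start`, `minus10_start`, `spacer_len` (box starts in local
#'   scanned-strand coordinates, 0-based).
#' @export
scan_promoters <- function(seq, strand = "+",
                           pwm35 = default_sigma70_pwms()$pwm35,
                           pwm10 = default_sigma70_pwms()$pwm10,
                           threshold = 12) {
  stopifnot(strand %in% c("+", "-"))
  s <- if (strand == "-") revcomp(seq) else seq
  n <- nchar(s)
  w35 <- pwm35$width
  w10 <- pwm10$width
  spacers <- 15:19
  empty <- data.frame(
    kind = character(), position = integer(), strand = character(),
    score = numeric(), minus35_start = integer(), minus10_start = integer(),
    spacer_len = integer(), stringsAsFactors = FALSE
  )
  if (n < w35 + min(spacers) + w10) return(empty)
  codes <- seq_to_int(s)
  t35 <- pwm_score_track(codes, pwm35)
  t10 <- pwm_score_track(codes, pwm10)
  cand <- NULL
  for (sp in spacers) {
    # -35 box at i (1-based), -10 box at i + w35 + sp
    imax <- n - (w35 + sp + w10) + 1L
    if (imax < 1L) next
    i <- seq_len(imax)
    tot <- t35[i] + t10[i + w35 + sp] - 0.5 * abs(sp - 17L)
    keep <- which(tot >= threshold)
    if (length(keep)) {
      cand <- rbind(cand, data.frame(i35 = keep, spacer = sp,
                                     score = tot[keep]))
    }
  }
  if (is.null(cand)) return(empty)
  # best spacer per -35 position, then greedy non-overlap on the box span
  cand <- cand[order(-cand$score, cand$i35, cand$spacer), , drop = FALSE]
  cand <- cand[!duplicated(cand$i35), , drop = FALSE]
  cand$from <- cand$i35
  cand$to <- cand$i35 + pwm35$width + cand$spacer + pwm10$width - 1L
  picked <- greedy_nonoverlap(cand$from, cand$to, cand$score)
  cand <- cand[picked, , drop = FALSE]
  m10 <- cand$i35 - 1L + w35 + cand$spacer          # 0-based -10 box start
  pos_local <- m10 + w10                            # first base after -10 box
  pos_fwd <- if (strand == "+") pos_local else n - 1L - pos_local
  out <- data.frame(
    kind = "promoter", position = as.integer(pos_fwd), strand = strand,
    score = cand$score, minus35_start = cand$i35 - 1L,
    minus10_start = as.integer(m10), spacer_len = as.integer(cand$spacer),
    stringsAsFactors = FALSE
  )
  out[order(out$position), , drop = FALSE]
}

# keep highest-scoring candidates whose [from, to] spans do not overlap
greedy_nonoverlap <- function(from, to, score) {
  ord <- order(-score, from)
  picked <- integer(0L)
  for (k in ord) {
    if (!any(from[k] <= to[picked] & to[k] >= from[picked])) {
      picked <- c(picked, k)
    }
  }
  sort(picked)
}

# -------------------------------------------------------------- terminators

# base-pair score matrix for hairpin stems: G.C 2, A.T 1, G.T wobble 0.5,
# anything else (incl. N) is a mismatch at -2
pair_score_matrix <- function() {
  m <- matrix(-2, 5L, 5L, dimnames = list(c(BASES, "N"), c(BASES, "N")))
  m["G", "C"] <- m["C", "G"] <- 2
  m["A", "T"] <- m["T", "A"] <- 1
  m["G", "T"] <- m["T", "G"] <- 0.5
  m
}

TAIL_WEIGHTS <- c(1.0, 1.0, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4)

#' Default terminator scoring configuration
#'
#' @param stem_min,stem_max Stem lengths enumerated (4-15 bp).
#' @param loop_min,loop_max Loop lengths enumerated (3-10 nt).
#' @param max_mismatch Mismatched pairs tolerated in a stem (G.U wobble is a
#'   pair, not a mismatch).
#' @param min_hairpin Hairpin score required for a call.
#' @param min_tail U-tract score required for a call.
#' @return A list of parameters for [scan_terminators()].
#' @export
terminator_config <- function(stem_min = 4L, stem_max = 15L,
                              loop_min = 3L, loop_max = 10L,
                              max_mismatch = 1L,
                              min_hairpin = 8, min_tail = 2.5) {
  list(stem_min = stem_min, stem_max = stem_max, loop_min = loop_min,
       loop_max = loop_max, max_mismatch = max_mismatch,
       min_hairpin = min_hairpin, min_tail = min_tail)
}

#' Scan a sequence for rho-independent terminators
#'
#' Enumerates candidate hairpins (stem `stem_min`-`stem_max` bp with at most
#' `max_mismatch` mismatches and no bulges, loop `loop_min`-`loop_max` nt).
#' `hairpin_score` is the sum of pair scores (G.C +2, A.T +1, G.U wobble
#' +0.5, mismatch -2) minus a loop penalty of `0.5 * (loop_len - 3)`.
#' `tail_score` weighs the Ts among the up-to-8 nt following the 3' stem with
#' weights (1, 1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4). The total score is
#' `hairpin_score + 2 * tail_score`; a hit requires `hairpin_score >=
#' min_hairpin` and `tail_score >= min_tail`. Overlapping hits are resolved
#' to the best-scoring one.
#'
#' `position` is the first base of the U-tract, in forward-strand
#' coordinates of `seq` (0-based). The minus strand is scanned on the
#' reverse complement with positions mapped back.
#'
#' @param seq DNA string.
#' @param strand `"+"` or `"-"`.
#' @param params Configuration from [terminator_config()].
#' @return A data.frame with columns `kind`, `position`, `strand`, `score`,
#'   `stem_len`, `loop_len`, `hairpin_score`, `tail_score`.
#' @export
scan_terminators <- function(seq, strand = "+", params = terminator_config()) {
  stopifnot(strand %in% c("+", "-"))
  s <- if (strand == "-") revcomp(seq) else seq
  n <- nchar(s)
  empty <- data.frame(
    kind = character(), position = integer(), strand = character(),
    score = numeric(), stem_len = integer(), loop_len = integer(),
    hairpin_score = numeric(), tail_score = numeric(),
    stringsAsFactors = FALSE
  )
  if (n < 2L * params$stem_min + params$loop_min) return(empty)
  codes <- seq_to_int(s)
  PV <- as.numeric(t(pair_score_matrix()))   # flat [(left-1)*5 + right]
  is_t <- as.numeric(codes == 4L)
  # tail score track: tail starting at 1-based position q (truncated at end)
  tail_at <- numeric(n + 1L)
  for (k in seq_along(TAIL_WEIGHTS)) {
    idx <- seq_len(n - k + 1L)
    tail_at[idx] <- tail_at[idx] + TAIL_WEIGHTS[k] * is_t[idx + k - 1L]
  }
  hits <- NULL
  for (st in params$stem_min:params$stem_max) {
    for (lp in params$loop_min:params$loop_max) {
      span <- 2L * st + lp
      imax <- n - span + 1L
      if (imax < 1L) break
      hp <- numeric(imax)
      mm <- integer(imax)
      for (j in seq_len(st)) {
        left <- codes[j:(imax + j - 1L)]
        right <- codes[(span - j + 1L):(imax + span - j)]
        ps <- PV[(left - 1L) * 5L + right]
        hp <- hp + ps
        mm <- mm + (ps <= -2)
      }
      hp <- hp - 0.5 * (lp - 3L)
      tl <- tail_at[(span + 1L):(imax + span)]
      ok <- which(mm <= params$max_mismatch & hp >= params$min_hairpin &
                    tl >= params$min_tail)
      if (length(ok)) {
        hits <- rbind(hits, data.frame(
          i = ok, stem_len = st, loop_len = lp,
          hairpin_score = hp[ok], tail_score = tl[ok],
          score = hp[ok] + 2 * tl[ok]
        ))
      }
    }
  }
  if (is.null(hits)) return(empty)
  # resolve overlaps (hairpin + tail window) to the best-scoring candidate
  hits$from <- hits$i
  hits$to <- pmin(hits$i + 2L * hits$stem_len + hits$loop_len + 8L - 1L, n)
  picked <- greedy_nonoverlap(hits$from, hits$to, hits$score)
  hits <- hits[picked, , drop = FALSE]
  pos_local <- hits$i - 1L + 2L * hits$stem_len + hits$loop_len  # 0-based
  pos_fwd <- if (strand == "+") pos_local else nchar(s) - 1L - pos_local
  out <- data.frame(
    kind = "terminator", position = as.integer(pos_fwd), strand = strand,
    score = hits$score, stem_len = hits$stem_len, loop_len = hits$loop_len,
    hairpin_score = hits$hairpin_score, tail_score = hits$tail_score,
    stringsAsFactors = FALSE
  )
  out[order(out$position), , drop = FALSE]
}

# ------------------------------------------------------------ the unit rule

#' Scan all IGRs for promoters and terminators
#'
#' Runs [scan_promoters()] and [scan_terminators()] on both strands of each
#' trimmed IGR sequence and returns one tidy signal table with positions in
#' IGR-local forward coordinates (0-based).
#'
#' @param genome An `annotated_genome`.
#' @param igrs An `igr_table`.
#' @param pwm35,pwm10 Promoter box PWMs.
#' @param promoter_threshold Promoter calling threshold.
#' @param term_params Terminator configuration.
#' @return A data.frame with columns `igr_id`, `kind`, `strand`, `position`,
#'   `score`.
#' @export
scan_igr_signals <- function(genome, igrs,
                             pwm35 = default_sigma70_pwms()$pwm35,
                             pwm10 = default_sigma70_pwms()$pwm10,
                             promoter_threshold = 12,
                             term_params = terminator_config()) {
  res <- lapply(seq_len(nrow(igrs)), function(i) {
    s <- igr_sequence(genome, igrs[i, ])
    sig <- rbind(
      scan_promoters(s, "+", pwm35, pwm10, promoter_threshold)[
        , c("kind", "position", "strand", "score")],
      scan_promoters(s, "-", pwm35, pwm10, promoter_threshold)[
        , c("kind", "position", "strand", "score")],
      scan_terminators(s, "+", term_params)[
        , c("kind", "position", "strand", "score")],
      scan_terminators(s, "-", term_params)[
        , c("kind", "position", "strand", "score")]
    )
    if (nrow(sig)) cbind(igr_id = igrs$igr_id[i], sig) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(igr_id = character(), kind = character(),
                      strand = character(), position = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Decide whether an IGR holds a complete transcriptional unit
#'
#' A complete unit requires at least one promoter and one terminator on the
#' same strand with the terminator downstream of the promoter in that
#' strand's direction of transcription (increasing coordinates on `+`,
#' decreasing on `-`). If both strands qualify the `+` strand wins.
#'
#' @param igr_id IGR identifier (copied into the result).
#' @param signals Signal table for this IGR, as one element of
#'   [scan_igr_signals()] output (columns `kind`, `strand`, `position`).
#' @return A one-row data.frame: `igr_id`, `has_promoter`, `has_terminator`,
#'   `complete_unit`, `unit_strand` (`"+"`, `"-"` or `"none"`).
#' @export
call_unit <- function(igr_id, signals) {
  has_p <- any(signals$kind == "promoter")
  has_t <- any(signals$kind == "terminator")
  strand_ok <- function(str) {
    p <- signals$position[signals$kind == "promoter" & signals$strand == str]
    t <- signals$position[signals$kind == "terminator" & signals$strand == str]
    if (!length(p) || !length(t)) return(FALSE)
    if (str == "+") any(outer(p, t, `<`)) else any(outer(p, t, `>`))
  }
  plus <- strand_ok("+")
  minus <- strand_ok("-")
  data.frame(
    igr_id = igr_id,
    has_promoter = has_p,
    has_terminator = has_t,
    complete_unit = plus || minus,
    unit_strand = if (plus) "+" else if (minus) "-" else "none",
    stringsAsFactors = FALSE
  )
}

#' Call complete transcriptional units for all IGRs
#'
#' @param igrs An `igr_table`.
#' @param signals Output of [scan_igr_signals()].
#' @return A data.frame with one row per IGR (see [call_unit()]).
#' @export
call_units <- function(igrs, signals) {
  out <- do.call(rbind, lapply(igrs$igr_id, function(id) {
    call_unit(id, signals[signals$igr_id == id, , drop = FALSE])
  }))
  rownames(out) <- NULL
  out
}
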