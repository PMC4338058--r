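# Candidate intergenic region (IGR) extraction.
#
# Gaps are computed between consecutive gene-like features (CDS and "other";
# tRNA/rRNA features do not block gaps -- they are removed by the explicit
# exclusion rule below, which would otherwise be unreachable). Each raw gap
# is trimmed by `trim` bp on both sides to strip promoters/UTRs/terminators
# belonging to the flanking ORFs, then kept only if the trimmed length is
# >= `min_len` and the trimmed interval overlaps no tRNA/rRNA feature.
# Duplicated intervals are dropped and ids IGR-1..IGR-n are assigned in
# genome order over the kept records.

#' Extract candidate intergenic regions
#'
#' Derives candidate IGRs from an annotated genome: inter-gene gaps (strand
#' agnostic) are trimmed by `trim` bp per side, filtered to a trimmed length
#' of at least `min_len` bp (a trimmed length of exactly `min_len` is kept),
#' and IGRs whose trimmed interval overlaps a tRNA or rRNA feature are
#' removed. On a circular genome the wrap-around gap between the last and
#' first gene is one IGR whose coordinates may extend past the genome length
#' (`wraps = TRUE`); on a linear genome the flankless gaps at the ends are
#' kept but flagged (`has_both_flanks = FALSE`) and are excluded from sRNA
#' calling.
#'
#' @param genome An `annotated_genome` with a non-empty feature table.
#' @param trim Bases removed from each side of a raw gap (default 40).
#' @param min_len Minimum trimmed length kept, inclusive (default 120).
#' @return A data.frame of class `igr_table` with one row per kept IGR:
#'   `igr_id`, `raw_start`, `raw_end`, `start`, `end`, `length`,
#'   `upstream_gene`, `downstream_gene`, `upstream_product`,
#'   `downstream_product`, `upstream_strand`, `downstream_strand`,
#'   `wraps`, `has_both_flanks`.
#' @export
extract_igrs <- function(genome, trim = 40L, min_len = 120L) {
  stopifnot(inherits(genome, "annotated_genome"))
  f <- genome$features
  blockers <- f[!(f$kind %in% c("tRNA", "rRNA")), , drop = FALSE]
  if (!nrow(blockers)) {
    warning("no gene-like features; returning no IGRs")
    return(empty_igr_table())
  }
  L <- genome$length

  # merge overlapping/adjacent features into occupied blocks, remembering
  # the outermost underlying feature on each side of every block
  ir <- IRanges::IRanges(start = blockers$start + 1L, end = blockers$end)
  red <- IRanges::reduce(ir)
  hit <- IRanges::findOverlaps(ir, red)
  blk <- data.frame(
    start = IRanges::start(red) - 1L,
    end = IRanges::end(red)
  )
  first_in_block <- tapply(S4Vectors::queryHits(hit),
                           S4Vectors::subjectHits(hit), min)
  last_in_block <- tapply(S4Vectors::queryHits(hit),
                          S4Vectors::subjectHits(hit), max)
  blk$first_feat <- as.integer(first_in_block[as.character(seq_len(nrow(blk)))])
  blk$last_feat <- as.integer(last_in_block[as.character(seq_len(nrow(blk)))])

  n <- nrow(blk)
  gaps <- data.frame(
    raw_start = integer(), raw_end = integer(),
    up = integer(), down = integer(),
    wraps = logical(), has_both_flanks = logical()
  )
  if (n >= 2L) {
    gaps <- data.frame(
      raw_start = blk$end[-n], raw_end = blk$start[-1L],
      up = blk$last_feat[-n], down = blk$first_feat[-1L],
      wraps = FALSE, has_both_flanks = TRUE
    )
  }
  if (genome$is_circular) {
    # wrap-around gap, represented with end > genome length
    if (blk$start[1L] + (L - blk$end[n]) > 0L) {
      gaps <- rbind(gaps, data.frame(
        raw_start = blk$end[n], raw_end = blk$start[1L] + L,
        up = blk$last_feat[n], down = blk$first_feat[1L],
        wraps = TRUE, has_both_flanks = TRUE
      ))
    }
  } else {
    if (blk$start[1L] > 0L) {
      gaps <- rbind(data.frame(
        raw_start = 0L, raw_end = blk$start[1L],
        up = NA_integer_, down = blk$first_feat[1L],
        wraps = FALSE, has_both_flanks = FALSE
      ), gaps)
    }
    if (blk$end[n] < L) {
      gaps <- rbind(gaps, data.frame(
        raw_start = blk$end[n], raw_end = L,
        up = blk$last_feat[n], down = NA_integer_,
        wraps = FALSE, has_both_flanks = FALSE
      ))
    }
  }
  if (!nrow(gaps)) return(empty_igr_table())

  gaps$start <- gaps$raw_start + as.integer(trim)
  gaps$end <- gaps$raw_end - as.integer(trim)
  gaps$length <- gaps$end - gaps$start
  gaps <- gaps[gaps$length >= min_len, , drop = FALSE]
  if (!nrow(gaps)) return(empty_igr_table())

  # exclusion rule: trimmed interval must not touch a tRNA or rRNA feature
  struct <- f[f$kind %in% c("tRNA", "rRNA"), , drop = FALSE]
  if (nrow(struct)) {
    overlaps_struct <- vapply(seq_len(nrow(gaps)), function(i) {
      s <- gaps$start[i]; e <- gaps$end[i]
      pieces <- if (e > L) {
        list(c(s, L), c(0L, e - L))
      } else {
        list(c(s, e))
      }
      any(vapply(pieces, function(p) {
        any(struct$start < p[2L] & struct$end > p[1L])
      }, logical(1L)))
    }, logical(1L))
    gaps <- gaps[!overlaps_struct, , drop = FALSE]
  }
  if (!nrow(gaps)) return(empty_igr_table())

  gaps <- gaps[!duplicated(gaps[, c("start", "end")]), , drop = FALSE]
  gaps <- gaps[order(gaps$start), , drop = FALSE]

  up_id <- ifelse(is.na(gaps$up), NA_character_, blockers$feature_id[gaps$up])
  down_id <- ifelse(is.na(gaps$down), NA_character_,
                    blockers$feature_id[gaps$down])
  out <- data.frame(
    igr_id = paste0("IGR-", seq_len(nrow(gaps))),
    raw_start = gaps$raw_start, raw_end = gaps$raw_end,
    start = gaps$start, end = gaps$end, length = gaps$length,
    upstream_gene = up_id,
    downstream_gene = down_id,
    upstream_product = ifelse(is.na(gaps$up), NA_character_,
                              blockers$product[gaps$up]),
    downstream_product = ifelse(is.na(gaps$down), NA_character_,
                                blockers$product[gaps$down]),
    upstream_strand = ifelse(is.na(gaps$up), NA_character_,
                             blockers$strand[gaps$up]),
    downstream_strand = ifelse(is.na(gaps$down), NA_character_,
                               blockers$strand[gaps$down]),
    wraps = gaps$wraps,
    has_both_flanks = gaps$has_both_flanks,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("igr_table", "data.frame")
  out
}

empty_igr_table <- function() {
  out <- data.frame(
    igr_id = character(), raw_start = integer(), raw_end = integer(),
    start = integer(), end = integer(), length = integer(),
    upstream_gene = character(), downstream_gene = character(),
    upstream_product = character(), downstream_product = character(),
    upstream_strand = character(), downstream_strand = character(),
    wraps = logical(), has_both_flanks = logical(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("igr_table", "data.frame")
  out
}

#' Forward-strand sequences of IGRs as FASTA text
#'
#' One record per IGR; the header carries the IGR id and its 1-based
#' inclusive genome coordinates (`IGR-5 genome:541-860` for internal
#' `[540, 860)`).
#'
#' @param genome An `annotated_genome`.
#' @param igrs An `igr_table` from [extract_igrs()].
#' @return Character scalar of FASTA text (empty string for no IGRs).
#' @export
igr_sequences <- function(genome, igrs) {
  if (!nrow(igrs)) return("")
  recs <- vapply(seq_len(nrow(igrs)), function(i) {
    s <- subseq0_circular(genome$sequence, igrs$start[i], igrs$end[i],
                          genome$length)
    sprintf(">%s %s:%d-%d\n%s", igrs$igr_id[i], genome$genome_id,
            igrs$start[i] + 1L, igrs$end[i], s)
  }, character(1L))
  paste0(paste(recs, collapse = "\n"), "\n")
}

# trimmed sequence of one IGR (used by the scanners)
igr_sequence <- function(genome, igr_row) {
  subseq0_circular(genome$sequence, igr_row$start, igr_row$end, genome$length)
}
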