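# Read QC, PCR-duplicate removal, feature counting and RPKM.

#' Quality-filter a FASTQ file
#'
#' Reproduces the clean-read definition used for bacterial stress
#' transcriptomes: terminal bases with quality `Q <= end_trim_q` are trimmed
#' from both ends, then a read is kept iff its trimmed length is strictly
#' greater than `min_len` nt and the fraction of its bases with quality
#' strictly greater than 20 is at least `min_frac_q20`.
#'
#' @param fastq_path Input FASTQ (Phred+33).
#' @param out_path Optional path for the clean FASTQ; `NULL` skips writing.
#' @param min_frac_q20 Minimum fraction of bases with Q > 20 (default 0.8).
#' @param min_len Reads must be longer than this after trimming
#'   (default 20, strict).
#' @param end_trim_q Quality at or below which terminal bases are trimmed
#'   (default 2).
#' @return A list of class `qc_report`: `sample_id` (file stem), `reads_in`,
#'   `reads_clean`, `fraction_kept`, and `clean` (data.frame of surviving
#'   reads: `id`, `seq`, `qual`).
#' @export
qc_filter <- function(fastq_path, out_path = NULL, min_frac_q20 = 0.8,
                      min_len = 20L, end_trim_q = 2L) {
  lines <- readLines(fastq_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L) {
    stop("FASTQ parse error: number of lines (", length(lines),
         ") is not a multiple of 4", call. = FALSE)
  }
  n <- length(lines) %/% 4L
  ids <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[1L]
    stop("FASTQ parse error: read ", bad, " (", sub("^@", "", ids[bad]),
         ") has sequence length ", nchar(seqs[bad]),
         " but quality length ", nchar(quals[bad]), call. = FALSE)
  }
  keep <- logical(n)
  out_seq <- character(n)
  out_qual <- character(n)
  for (i in seq_len(n)) {
    q <- utf8ToInt(quals[i]) - 33L
    len <- length(q)
    lo <- 1L
    hi <- len
    while (lo <= hi && q[lo] <= end_trim_q) lo <- lo + 1L
    while (hi >= lo && q[hi] <= end_trim_q) hi <- hi - 1L
    if (hi < lo) next
    q <- q[lo:hi]
    len <- length(q)
    if (len <= min_len) next
    if (mean(q > 20L) < min_frac_q20) next
    keep[i] <- TRUE
    out_seq[i] <- substr(seqs[i], lo, hi)
    out_qual[i] <- substr(quals[i], lo, hi)
  }
  clean <- data.frame(
    id = sub("^@", "", ids[keep]), seq = out_seq[keep], qual = out_qual[keep],
    stringsAsFactors = FALSE
  )
  if (!is.null(out_path)) {
    writeLines(
      as.vector(rbind(paste0("@", clean$id), clean$seq, "+", clean$qual)),
      out_path
    )
  }
  rep <- list(
    sample_id = sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq_path)),
    reads_in = n,
    reads_clean = nrow(clean),
    fraction_kept = if (n > 0L) nrow(clean) / n else 0,
    clean = clean
  )
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC %s: %d reads in, %d clean (%.1f%% kept)\n",
              x$sample_id, x$reads_in, x$reads_clean, 100 * x$fraction_kept))
  invisible(x)
}

#' Remove PCR duplicates from alignments
#'
#' Among alignments of one sample sharing an identical (start, end, strand)
#' triple exactly one (the first) is retained; input order is otherwise
#' preserved.
#'
#' @param alignments Alignment data.frame (single sample).
#' @return The deduplicated data.frame.
#' @export
dedup <- function(alignments) {
  if (!nrow(alignments)) return(alignments)
  if (length(unique(alignments$sample_id)) > 1L) {
    stop("dedup expects alignments from a single sample", call. = FALSE)
  }
  key <- paste(alignments$start, alignments$end, alignments$strand)
  out <- alignments[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the feature interval table used for counting
#'
#' Stacks annotated features (genes, tRNA, rRNA) and kept IGRs into one
#' interval table. A wrap-around IGR on a circular genome contributes two
#' pieces sharing one `feature_id`; counts are summed over pieces and the
#' length is the full IGR length.
#'
#' @param genome An `annotated_genome`.
#' @param igrs An `igr_table` (may be empty).
#' @return A data.frame: `feature_id`, `start`, `end`, `length_bp`, `class`
#'   (`gene` or `igr`).
#' @export
feature_intervals <- function(genome, igrs = empty_igr_table()) {
  f <- genome$features
  gene_tab <- data.frame(
    feature_id = f$feature_id, start = f$start, end = f$end,
    length_bp = f$end - f$start, class = "gene", stringsAsFactors = FALSE
  )
  igr_tab <- NULL
  if (nrow(igrs)) {
    pieces <- lapply(seq_len(nrow(igrs)), function(i) {
      s <- igrs$start[i]; e <- igrs$end[i]
      if (e > genome$length) {
        data.frame(feature_id = igrs$igr_id[i],
                   start = c(s, 0L), end = c(genome$length, e - genome$length),
                   length_bp = igrs$length[i], class = "igr")
      } else {
        data.frame(feature_id = igrs$igr_id[i], start = s, end = e,
                   length_bp = igrs$length[i], class = "igr")
      }
    })
    igr_tab <- do.call(rbind, pieces)
  }
  out <- rbind(gene_tab, igr_tab)
  rownames(out) <- NULL
  out
}

#' Count reads per feature and assemble an expression table
#'
#' A (deduplicated) read is assigned to every feature whose interval covers
#' at least `min_overlap_frac` of the read's length, strand-agnostic;
#' multi-assignment is allowed. The per-sample total of mapped reads is the
#' number of deduplicated alignments, not the per-feature sum.
#'
#' @param alignments Named list mapping `sample_id` to a deduplicated
#'   alignment data.frame, or a single data.frame (its `sample_id` column is
#'   used to split).
#' @param features Feature interval table from [feature_intervals()].
#' @param min_overlap_frac Minimum overlap as a fraction of read length
#'   (default 0.5).
#' @return An `expression_table`: list with `records` (data.frame
#'   `feature_id`, `sample_id`, `count`, `length_bp`, `rpkm` — `rpkm` is
#'   `NA` until [rpkm()] is applied) and `total_mapped` (named integer
#'   vector).
#' @export
count_features <- function(alignments, features, min_overlap_frac = 0.5) {
  if (is.data.frame(alignments)) {
    alignments <- split(alignments, alignments$sample_id)
  }
  feat_ir <- IRanges::IRanges(start = features$start + 1L, end = features$end)
  feat_len <- setNames(
    features$length_bp[!duplicated(features$feature_id)],
    features$feature_id[!duplicated(features$feature_id)]
  )
  feat_ids <- names(feat_len)
  recs <- lapply(names(alignments), function(sid) {
    al <- alignments[[sid]]
    counts <- setNames(integer(length(feat_ids)), feat_ids)
    if (nrow(al)) {
      read_ir <- IRanges::IRanges(start = al$start + 1L, end = al$end)
      ov <- IRanges::findOverlaps(read_ir, feat_ir)
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov)
        sh <- S4Vectors::subjectHits(ov)
        w <- IRanges::width(IRanges::pintersect(read_ir[qh], feat_ir[sh]))
        ok <- w >= min_overlap_frac * IRanges::width(read_ir)[qh]
        if (any(ok)) {
          # drop double hits of one read on the two pieces of a wrapped IGR
          hit_feat <- features$feature_id[sh[ok]]
          hit_read <- qh[ok]
          dup <- duplicated(paste(hit_read, hit_feat))
          tab <- table(hit_feat[!dup])
          counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
        }
      }
    }
    data.frame(
      feature_id = feat_ids, sample_id = sid, count = as.integer(counts),
      length_bp = as.integer(feat_len), rpkm = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- list(
    records = do.call(rbind, recs),
    total_mapped = vapply(alignments, nrow, integer(1L))
  )
  rownames(out$records) <- NULL
  class(out) <- "expression_table"
  out
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf(
    "<expression_table> %d features x %d samples (total mapped: %s)\n",
    length(unique(x$records$feature_id)), length(x$total_mapped),
    paste(sprintf("%s=%d", names(x$total_mapped), x$total_mapped),
          collapse = ", ")
  ))
  invisible(x)
}

#' Fill in RPKM values
#'
#' `RPKM = count / ((total_mapped / 1e6) * (length_bp / 1e3))`, computed per
#' (feature, sample); a zero count gives RPKM 0.
#'
#' @param table An `expression_table` from [count_features()].
#' @return The table with the `rpkm` column computed.
#' @export
rpkm <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  r <- table$records
  tot <- table$total_mapped[r$sample_id]
  if (any(tot == 0L & r$count > 0L)) {
    stop("sample with total_mapped = 0 but nonzero counts", call. = FALSE)
  }
  r$rpkm <- ifelse(r$count == 0L, 0,
                   r$count / ((tot / 1e6) * (r$length_bp / 1e3)))
  table$records <- r
  table
}

#' Write an expression table as TSV
#' @param table An `expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(table, path) {
  write.table(table$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# convenience accessor: rpkm of one feature in one sample (0 rows -> NA)
get_rpkm <- function(table, feature_id, sample_id) {
  r <- table$records
  v <- r$rpkm[r$feature_id == feature_id & r$sample_id == sample_id]
  if (length(v)) v[1L] else NA_real_
}

get_count <- function(table, feature_id, sample_id) {
  r <- table$records
  v <- r$count[r$feature_id == feature_id & r$sample_id == sample_id]
  if (length(v)) v[1L] else NA_integer_
}
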