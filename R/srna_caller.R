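# Promotion of IGRs to high-confidence sRNAs: the joint rule is a complete
# transcriptional unit AND expression at least 15% above both flanking
# genes, per transcriptome; the final set is the union over samples.

GLYPH_FWD <- "\u2192"   # right arrow
GLYPH_REV <- "\u2190"   # left arrow

strand_glyph <- function(strand) ifelse(strand == "+", GLYPH_FWD, GLYPH_REV)

#' Call sRNAs in one sample
#'
#' An IGR is called iff its unit call is complete and its RPKM is at least
#' `(1 + margin)` times the RPKM of each flanking gene in the same sample
#' (inclusive: equality at the threshold calls). IGRs missing a flank
#' (linear-genome ends) are excluded with a warning.
#'
#' @param igrs An `igr_table`.
#' @param unit_calls Output of [call_units()].
#' @param expr An `expression_table` with RPKM (normalized or not; the rule
#'   compares within one sample so scaling cancels).
#' @param sample_id Sample in which to apply the rule.
#' @param margin Required relative excess over the flanks (default 0.15).
#' @return A data.frame of calls: `srna_id`, `start`, `end` (strand
#'   polarized: on `-` calls the printed start exceeds the printed end),
#'   `strand`, `length`, `upstream_gene`, `downstream_gene`, `orientation`
#'   (3 glyphs: left flank, sRNA, right flank), `rpkm`, `rpkm_left`,
#'   `rpkm_right`, `sample_id`.
#' @export
call_srnas <- function(igrs, unit_calls, expr, sample_id, margin = 0.15) {
  stopifnot(inherits(expr, "expression_table"))
  no_flank <- !igrs$has_both_flanks
  if (any(no_flank)) {
    warning(sum(no_flank), " IGR(s) lack a flanking gene and are excluded ",
            "from sRNA calling")
    igrs <- igrs[!no_flank, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(igrs))) {
    id <- igrs$igr_id[i]
    uc <- unit_calls[unit_calls$igr_id == id, , drop = FALSE]
    if (!nrow(uc) || !uc$complete_unit) next
    r_igr <- get_rpkm(expr, id, sample_id)
    r_up <- get_rpkm(expr, igrs$upstream_gene[i], sample_id)
    r_dn <- get_rpkm(expr, igrs$downstream_gene[i], sample_id)
    if (is.na(r_igr) || is.na(r_up) || is.na(r_dn)) {
      stop("missing RPKM for IGR ", id, " or its flanks in sample ",
           sample_id, call. = FALSE)
    }
    if (r_igr >= (1 + margin) * r_up && r_igr >= (1 + margin) * r_dn) {
      strand <- uc$unit_strand
      s <- igrs$start[i]; e <- igrs$end[i]
      rows[[length(rows) + 1L]] <- data.frame(
        srna_id = id,
        start = if (strand == "+") s else e,
        end = if (strand == "+") e else s,
        strand = strand,
        length = e - s,
        upstream_gene = igrs$upstream_product[i],
        downstream_gene = igrs$downstream_product[i],
        orientation = paste0(strand_glyph(igrs$upstream_strand[i]),
                             strand_glyph(strand),
                             strand_glyph(igrs$downstream_strand[i])),
        rpkm = r_igr, rpkm_left = r_up, rpkm_right = r_dn,
        sample_id = sample_id,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_srna_calls()
  rownames(out) <- NULL
  out
}

empty_srna_calls <- function() {
  data.frame(
    srna_id = character(), start = integer(), end = integer(),
    strand = character(), length = integer(), upstream_gene = character(),
    downstream_gene = character(), orientation = character(),
    rpkm = numeric(), rpkm_left = numeric(), rpkm_right = numeric(),
    sample_id = character(), stringsAsFactors = FALSE
  )
}

#' Merge per-sample sRNA calls into the high-confidence set
#'
#' Union semantics: an IGR called in any sample is in the final set. The
#' per-sample RPKM values of each final sRNA are attached as extra columns
#' `rpkm.<sample>`. Conflicting strands for one id across samples raise an
#' error.
#'
#' @param per_sample_calls Named list mapping sample id to a [call_srnas()]
#'   data.frame, or an unnamed list (sample ids are taken from the calls).
#' @param expr Optional `expression_table` used to fill per-sample RPKMs for
#'   samples in which an sRNA was not called.
#' @return One data.frame with a single row per sRNA (catalogue schema plus
#'   `rpkm.<sample>` columns and `n_samples_called`).
#' @export
merge_calls <- function(per_sample_calls, expr = NULL) {
  all_calls <- do.call(rbind, unname(per_sample_calls))
  if (is.null(all_calls) || !nrow(all_calls)) return(empty_srna_calls())
  samples <- unique(all_calls$sample_id)
  for (id in unique(all_calls$srna_id)) {
    st <- unique(all_calls$strand[all_calls$srna_id == id])
    if (length(st) > 1L) {
      stop("sRNA ", id, " called with conflicting strands across samples: ",
           paste(st, collapse = ", "), call. = FALSE)
    }
  }
  merged <- all_calls[!duplicated(all_calls$srna_id), , drop = FALSE]
  merged <- merged[order(as.integer(sub("^IGR-", "", merged$srna_id))),
                   , drop = FALSE]
  merged$n_samples_called <- vapply(merged$srna_id, function(id) {
    length(unique(all_calls$sample_id[all_calls$srna_id == id]))
  }, integer(1L))
  for (s in samples) {
    merged[[paste0("rpkm.", s)]] <- vapply(merged$srna_id, function(id) {
      v <- all_calls$rpkm[all_calls$srna_id == id & all_calls$sample_id == s]
      if (length(v)) v[1L]
      else if (!is.null(expr)) get_rpkm(expr, id, s)
      else NA_real_
    }, numeric(1L))
  }
  merged$rpkm <- NULL
  merged$rpkm_left <- NULL
  merged$rpkm_right <- NULL
  merged$sample_id <- NULL
  rownames(merged) <- NULL
  merged
}

#' Per-condition fold changes of the called sRNAs
#'
#' Fold change is `normalized RPKM(treatment) / normalized RPKM(control)`
#' per condition; normalization must already be applied
#' ([median_normalize()]). A zero control RPKM flags the fold as infinite
#' (`is_infinite = TRUE`), to be excluded from summaries.
#'
#' @param calls Merged calls from [merge_calls()].
#' @param expr_normalized A median-normalized `expression_table`.
#' @param control Control sample id.
#' @param conditions Treatment sample ids (default: all non-control samples
#'   in the table).
#' @return A long data.frame: `srna_id`, `condition`, `fold`, `is_infinite`.
#' @export
fold_changes <- function(calls, expr_normalized, control,
                         conditions = NULL) {
  stopifnot(inherits(expr_normalized, "expression_table"))
  samples <- names(expr_normalized$total_mapped)
  if (!(control %in% samples)) {
    stop("control sample '", control, "' not in expression table",
         call. = FALSE)
  }
  if (is.null(conditions)) conditions <- setdiff(samples, control)
  rows <- list()
  for (id in calls$srna_id) {
    ctrl <- get_rpkm(expr_normalized, id, control)
    for (cond in conditions) {
      tr <- get_rpkm(expr_normalized, id, cond)
      inf <- ctrl == 0
      rows[[length(rows) + 1L]] <- data.frame(
        srna_id = id, condition = cond,
        fold = if (inf) NA_real_ else tr / ctrl,
        is_infinite = inf, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(srna_id = character(), condition = character(),
                      fold = numeric(), is_infinite = logical())
  }
  rownames(out) <- NULL
  out
}

#' Render the sRNA catalogue as TSV text
#'
#' Catalogue schema: sRNA name, start, end, strand, length, upstream gene,
#' downstream gene, orientation glyphs. Coordinates are printed strand
#' polarized (minus-strand rows print start > end) and rows are
#' deduplicated by sRNA id.
#'
#' @param calls Merged calls ([merge_calls()]) or any data.frame with the
#'   catalogue columns.
#' @return Character scalar of TSV text.
#' @export
render_catalogue <- function(calls) {
  stopifnot(nrow(calls) > 0L)
  calls <- calls[!duplicated(calls$srna_id), , drop = FALSE]
  cols <- c("srna_id", "start", "end", "strand", "length",
            "upstream_gene", "downstream_gene", "orientation")
  df <- calls[, cols, drop = FALSE]
  con <- textConnection("out", "w", local = TRUE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}
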