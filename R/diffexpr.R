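# Median normalization, replicate-free exact test, DEG selection and
# condition-overlap (Venn) summaries.

#' Median-normalize an expression table
#'
#' Scales each sample's RPKM values by `reference_median / sample_median`,
#' where the sample median is taken over that sample's features with RPKM
#' greater than zero and the reference is the geometric mean of the sample
#' medians. After scaling every sample's median over its expressed features
#' equals the reference (within 1e-9), and applying the normalization twice
#' equals applying it once.
#'
#' @param table An `expression_table` with RPKM filled in ([rpkm()]).
#' @return The table with `rpkm` rescaled per sample; scale factors are kept
#'   in `attr(, "scale_factors")`.
#' @export
median_normalize <- function(table) {
  stopifnot(inherits(table, "expression_table"))
  r <- table$records
  samples <- unique(r$sample_id)
  if (length(samples) < 2L) {
    stop("median normalization needs at least 2 samples", call. = FALSE)
  }
  med <- vapply(samples, function(s) {
    v <- r$rpkm[r$sample_id == s & r$rpkm > 0]
    if (!length(v)) {
      stop("sample '", s, "' has no feature with RPKM > 0", call. = FALSE)
    }
    median(v)
  }, numeric(1L))
  ref <- exp(mean(log(med)))
  fac <- ref / med
  r$rpkm <- r$rpkm * fac[r$sample_id]
  table$records <- r
  attr(table, "scale_factors") <- fac
  table
}

#' Exact conditional test for a two-library count contrast
#'
#' Two-sided exact test for differential expression without replicates:
#' conditional on `n = count_a + count_b`, `count_a` is
#' `Binomial(n, total_a / (total_a + total_b))` under the null of equal
#' relative expression. The p-value sums the probabilities of all outcomes
#' at most as probable as the observed one (point-probability method).
#' `n = 0` gives p = 1.
#'
#' @param count_a,count_b Feature counts in the two libraries.
#' @param total_a,total_b Library totals (mapped reads).
#' @return The two-sided p-value.
#' @export
test_de <- function(count_a, count_b, total_a, total_b) {
  stopifnot(total_a > 0, total_b > 0,
            count_a >= 0, count_b >= 0)
  n <- count_a + count_b
  if (n == 0L) return(1)
  p0 <- total_a / (total_a + total_b)
  d <- dbinom(0:n, n, p0)
  obs <- d[count_a + 1L]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

#' Select differentially expressed features for one condition
#'
#' For every feature, computes `log2fc = log2((norm_treat + c) / (norm_ctrl
#' + c))` with pseudocount `c` (RPKM units) on median-normalized values, a
#' p-value from [test_de()] on the raw deduplicated counts, and a status:
#' `up` iff `log2fc > log2fc_cutoff` and `p < p_cutoff`, `down` iff
#' `log2fc < -log2fc_cutoff` and `p < p_cutoff`, otherwise `ns` (both
#' cutoffs strict). A Benjamini-Hochberg FDR column is reported for
#' information but plays no part in the status.
#'
#' @param table A median-normalized `expression_table` (counts still raw).
#' @param control,condition Sample ids contrasted (condition vs control).
#' @param pseudocount Stabilizing constant added to both normalized values
#'   (default 0.5 RPKM).
#' @param log2fc_cutoff,p_cutoff DEG thresholds (defaults 1 and 0.05).
#' @return A data.frame: `feature_id`, `condition`, `log2fc`, `p_value`,
#'   `bh_fdr`, `status`.
#' @export
select_degs <- function(table, control, condition, pseudocount = 0.5,
                        log2fc_cutoff = 1, p_cutoff = 0.05) {
  stopifnot(inherits(table, "expression_table"))
  r <- table$records
  if (!(control %in% r$sample_id)) {
    stop("control sample '", control, "' not in expression table",
         call. = FALSE)
  }
  if (!(condition %in% r$sample_id)) {
    stop("condition sample '", condition, "' not in expression table",
         call. = FALSE)
  }
  rc <- r[r$sample_id == control, ]
  rt <- r[r$sample_id == condition, ]
  rt <- rt[match(rc$feature_id, rt$feature_id), ]
  log2fc <- log2((rt$rpkm + pseudocount) / (rc$rpkm + pseudocount))
  tot_c <- table$total_mapped[[control]]
  tot_t <- table$total_mapped[[condition]]
  p <- vapply(seq_len(nrow(rc)), function(i) {
    test_de(rt$count[i], rc$count[i], tot_t, tot_c)
  }, numeric(1L))
  status <- rep("ns", nrow(rc))
  status[log2fc > log2fc_cutoff & p < p_cutoff] <- "up"
  status[log2fc < -log2fc_cutoff & p < p_cutoff] <- "down"
  data.frame(
    feature_id = rc$feature_id, condition = condition,
    log2fc = log2fc, p_value = p, bh_fdr = p.adjust(p, "BH"),
    status = status, stringsAsFactors = FALSE
  )
}

#' Pairwise DEG overlap summary across conditions
#'
#' For each direction (`up`, `down`) and each non-reference condition,
#' counts the DEGs shared with the reference condition and reports the
#' shared fraction as `|A intersect R| / |A|`, i.e. relative to the
#' non-reference condition's own DEG count (the denominator is stated
#' explicitly in the output).
#'
#' @param results Named list mapping condition to its [select_degs()]
#'   data.frame.
#' @param reference Name of the reference condition (e.g. the combined
#'   stress treatment).
#' @return A data.frame: `condition`, `reference`, `direction`, `n_condition`,
#'   `n_reference`, `n_shared`, `fraction_shared` (of `n_condition`).
#' @export
overlap_summary <- function(results, reference) {
  stopifnot(length(results) >= 2L, reference %in% names(results))
  degs <- function(df, dir) df$feature_id[df$status == dir]
  rows <- list()
  for (cond in setdiff(names(results), reference)) {
    for (dir in c("up", "down")) {
      a <- degs(results[[cond]], dir)
      r <- degs(results[[reference]], dir)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, reference = reference, direction = dir,
        n_condition = length(a), n_reference = length(r),
        n_shared = length(intersect(a, r)),
        fraction_shared = if (length(a)) length(intersect(a, r)) / length(a)
                          else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
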