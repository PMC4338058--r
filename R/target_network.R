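# sRNA target prediction by antisense seed complementarity, the bipartite
# sRNA -> gene regulation network, and COG category tallies.
#
# The hybridization-energy model of thermodynamic target predictors is
# replaced by perfect-seed reverse-complement matching inside the canonical
# search region around the start codon (-30..+20 nt); the downstream claims
# of this module are about network structure, not thermodynamics.

#' Extract mRNA windows around start codons
#'
#' For each gene-like feature, the window spans `upstream` nt before and
#' `downstream` nt after the start codon, in mRNA sense (minus-strand genes
#' are reverse complemented). Windows truncated by the replicon end on a
#' linear genome are clipped; on a circular genome they wrap.
#'
#' @param genome An `annotated_genome`.
#' @param kinds Feature kinds to include (default CDS).
#' @param upstream,downstream Window extent around the start codon
#'   (defaults 30 and 20, a 50 nt window).
#' @return A data.frame: `gene_id`, `window` (DNA string in mRNA sense),
#'   `window_offset` (position of the window's first base relative to the
#'   start codon; `-upstream` when nothing was clipped).
#' @export
extract_mrna_windows <- function(genome, kinds = "CDS",
                                 upstream = 30L, downstream = 20L) {
  f <- genome$features[genome$features$kind %in% kinds, , drop = FALSE]
  L <- genome$length
  rows <- lapply(seq_len(nrow(f)), function(i) {
    if (f$strand[i] == "+") {
      a <- f$start[i] - upstream
      b <- f$start[i] + downstream
      if (genome$is_circular) {
        if (a < 0L) { a <- a + L; b <- b + L }
        w <- subseq0_circular(genome$sequence, a, min(b, a + (b - a)), L)
        off <- -upstream
      } else {
        off <- -(f$start[i] - max(a, 0L))
        w <- subseq0(genome$sequence, max(a, 0L), min(b, L))
      }
    } else {
      # start codon at the feature end; window in mRNA sense via revcomp
      a <- f$end[i] - downstream
      b <- f$end[i] + upstream
      if (genome$is_circular) {
        if (a < 0L) { a <- a + L; b <- b + L }
        w <- revcomp(subseq0_circular(genome$sequence, a, b, L))
        off <- -upstream
      } else {
        bb <- min(b, L)
        off <- -(bb - f$end[i])
        w <- revcomp(subseq0(genome$sequence, max(a, 0L), bb))
      }
    }
    data.frame(gene_id = f$feature_id[i], window = w, window_offset = off,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), window = character(),
                      window_offset = integer(), stringsAsFactors = FALSE)
  }
  out
}

# all maximal common substrings of length >= min_len between a and b, as
# (start_a, start_b, len) in 0-based coordinates; row-wise run DP over the
# shorter sequence so each pair costs O(min(n,m)) vector operations
maximal_common_substrings <- function(a, b, min_len) {
  av <- seq_to_int(a)
  bv <- seq_to_int(b)
  empty <- data.frame(start_a = integer(), start_b = integer(),
                      len = integer())
  swapped <- length(av) < length(bv)
  if (swapped) { tmp <- av; av <- bv; bv <- tmp }
  n <- length(av)
  m <- length(bv)
  if (n == 0L || m == 0L || m < 1L) return(empty)
  runs <- list()
  prev <- integer(n)
  for (i in seq_len(m)) {
    eq <- av == bv[i]
    cur <- (c(0L, prev[-n]) + 1L) * eq
    idx <- which(cur >= min_len)
    if (length(idx)) {
      # keep only maximal runs: not extendable to (i + 1, j + 1)
      ext <- i < m & idx < n & av[pmin(idx + 1L, n)] == bv[min(i + 1L, m)]
      idx <- idx[!ext]
      if (length(idx)) {
        runs[[length(runs) + 1L]] <- cbind(idx - cur[idx], i - cur[idx],
                                           cur[idx])
      }
    }
    prev <- cur
  }
  if (!length(runs)) return(empty)
  df <- as.data.frame(do.call(rbind, runs))
  names(df) <- if (swapped) c("start_b", "start_a", "len") else
    c("start_a", "start_b", "len")
  df[, c("start_a", "start_b", "len"), drop = FALSE]
}

seed_pair_score <- function(seed) {
  v <- strsplit(seed, "")[[1L]]
  sum(ifelse(v %in% c("G", "C"), 2, ifelse(v %in% c("A", "T"), 1, 0)))
}

#' Predict targets of one sRNA by seed complementarity
#'
#' Finds maximal perfect reverse-complement matches of length at least
#' `seed_min` between the sRNA sequence and each gene's start-codon window.
#' The hybrid score sums per-pair scores over the seed (G:C 2, A:T 1); only
#' edges with score at least `score_min` are kept, and only the best edge
#' per (sRNA, gene) pair (ties broken by seed length, then leftmost
#' position in the window) is reported.
#'
#' @param srna_id Identifier copied into the edges.
#' @param srna_seq sRNA sequence (DNA alphabet, strand of transcription).
#' @param mrna_windows Data.frame from [extract_mrna_windows()].
#' @param seed_min Minimum perfect seed length (default 8).
#' @param score_min Minimum hybrid score (default 10).
#' @return A data.frame of edges: `srna_id`, `gene_id`, `seed_start_in_srna`
#'   (0-based), `seed_len`, `hybrid_score`, `position_in_mrna` (seed start
#'   relative to the start codon).
#' @export
predict_targets <- function(srna_id, srna_seq, mrna_windows,
                            seed_min = 8L, score_min = 10) {
  empty <- data.frame(
    srna_id = character(), gene_id = character(),
    seed_start_in_srna = integer(), seed_len = integer(),
    hybrid_score = numeric(), position_in_mrna = integer(),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (i in seq_len(nrow(mrna_windows))) {
    w <- mrna_windows$window[i]
    if (nchar(w) < seed_min) {
      warning("window for gene ", mrna_windows$gene_id[i],
              " is shorter than seed_min; skipped")
      next
    }
    # an antisense seed: sRNA substring whose reverse complement sits in the
    # window <=> common substring between sRNA and revcomp(window)
    rcw <- revcomp(w)
    mcs <- maximal_common_substrings(srna_seq, rcw, seed_min)
    if (!nrow(mcs)) next
    mcs$score <- vapply(seq_len(nrow(mcs)), function(k) {
      seed_pair_score(substr(srna_seq, mcs$start_a[k] + 1L,
                             mcs$start_a[k] + mcs$len[k]))
    }, numeric(1L))
    # position of the match in the window (forward window coords)
    mcs$win_start <- nchar(w) - (mcs$start_b + mcs$len)
    mcs <- mcs[mcs$score >= score_min, , drop = FALSE]
    if (!nrow(mcs)) next
    best <- mcs[order(-mcs$score, -mcs$len, mcs$win_start), , drop = FALSE][1L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      srna_id = srna_id, gene_id = mrna_windows$gene_id[i],
      seed_start_in_srna = best$start_a, seed_len = best$len,
      hybrid_score = best$score,
      position_in_mrna = best$win_start + mrna_windows$window_offset[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Predict targets for a set of sRNAs
#'
#' @param srnas Named character vector mapping sRNA id to sequence.
#' @param mrna_windows Data.frame from [extract_mrna_windows()].
#' @param seed_min,score_min See [predict_targets()].
#' @return Row-bound edges for all sRNAs.
#' @export
predict_all_targets <- function(srnas, mrna_windows, seed_min = 8L,
                                score_min = 10) {
  out <- do.call(rbind, lapply(names(srnas), function(id) {
    predict_targets(id, srnas[[id]], mrna_windows, seed_min, score_min)
  }))
  if (is.null(out)) {
    out <- predict_targets("x", "A", mrna_windows[0, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Build the sRNA regulation network
#'
#' Bipartite graph from an edge table; degree maps are computed for both
#' vertex classes.
#'
#' @param edges Data.frame with at least `srna_id` and `gene_id` columns.
#' @return A list of class `regulation_network`: `graph` (igraph, bipartite:
#'   sRNA vertices have `type = FALSE`, genes `TRUE`), `edges`,
#'   `srna_degree` and `gene_in_degree` (named integer vectors).
#' @export
build_network <- function(edges) {
  srnas <- unique(edges$srna_id)
  genes <- unique(edges$gene_id)
  if (length(intersect(srnas, genes))) {
    stop("sRNA and gene identifiers overlap; the network must be bipartite",
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("srna_id", "gene_id"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = c(srnas, genes),
                          type = c(rep(FALSE, length(srnas)),
                                   rep(TRUE, length(genes))))
  )
  gene_in <- vapply(genes, function(gid) {
    length(unique(edges$srna_id[edges$gene_id == gid]))
  }, integer(1L))
  srna_deg <- vapply(srnas, function(sid) {
    length(unique(edges$gene_id[edges$srna_id == sid]))
  }, integer(1L))
  out <- list(graph = g, edges = edges,
              srna_degree = srna_deg, gene_in_degree = gene_in)
  class(out) <- "regulation_network"
  out
}

#' @export
print.regulation_network <- function(x, ...) {
  cat(sprintf("<regulation_network> %d sRNAs -> %d target genes, %d edges\n",
              length(x$srna_degree), length(x$gene_in_degree),
              nrow(x$edges)))
  invisible(x)
}

#' Export a regulation network
#'
#' Writes the edge list as TSV and, optionally, the graph as GraphML.
#'
#' @param network A `regulation_network`.
#' @param edges_path Path for the edge-list TSV.
#' @param graphml_path Optional path for GraphML output.
#' @return `edges_path`, invisibly.
#' @export
export_network <- function(network, edges_path, graphml_path = NULL) {
  write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  invisible(edges_path)
}

#' Co-regulation statistics of a regulation network
#'
#' @param network A `regulation_network`.
#' @return A list: `n_targets` (distinct target genes),
#'   `n_coregulated_ge2` (genes regulated by at least 2 sRNAs),
#'   `max_in_degree`, `genes_at_max` (character vector; empty for an empty
#'   network).
#' @export
coregulation_stats <- function(network) {
  d <- network$gene_in_degree
  if (!length(d)) {
    return(list(n_targets = 0L, n_coregulated_ge2 = 0L,
                max_in_degree = 0L, genes_at_max = character()))
  }
  list(
    n_targets = length(d),
    n_coregulated_ge2 = sum(d >= 2L),
    max_in_degree = max(d),
    genes_at_max = sort(names(d)[d == max(d)])
  )
}

COG_LETTERS <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1L]]

#' Tally COG categories over target genes
#'
#' COG labels are supplied data (one string of category letters per gene),
#' never computed. A gene may carry several categories and then counts in
#' each; unknown letters are bucketed as `other` with a warning.
#'
#' @param targets Character vector of target gene ids.
#' @param cog_labels Named character vector mapping gene id to category
#'   letters (e.g. `c(geneA = "EG")`). Genes absent from the map are
#'   unlabelled.
#' @return A list of class `cog_tally`: `counts` (named integer vector per
#'   category letter), `n_with_cog`, `n_total`.
#' @export
cog_tally <- function(targets, cog_labels) {
  targets <- unique(targets)
  labels <- cog_labels[targets]
  labels <- labels[!is.na(labels) & nzchar(labels)]
  letters_all <- unlist(strsplit(labels, ""))
  unknown <- setdiff(unique(letters_all), COG_LETTERS)
  if (length(unknown)) {
    warning("unknown COG category letter(s) bucketed as 'other': ",
            paste(unknown, collapse = ", "))
    letters_all[letters_all %in% unknown] <- "other"
  }
  counts <- table(letters_all)
  out <- list(
    counts = setNames(as.integer(counts), names(counts)),
    n_with_cog = length(labels),
    n_total = length(targets)
  )
  class(out) <- "cog_tally"
  out
}

#' @export
print.cog_tally <- function(x, ...) {
  cat(sprintf("COG tally: %d of %d target genes labelled\n",
              x$n_with_cog, x$n_total))
  if (length(x$counts)) {
    print(sort(x$counts, decreasing = TRUE))
  }
  invisible(x)
}
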