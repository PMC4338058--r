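# Seeded synthetic inputs: a small circular bacterial genome with annotated
# genes, planted intergenic sRNAs (consensus promoter + strong terminator +
# expression above both flanks), decoy IGRs that each violate exactly one
# calling rule, and per-condition read alignments with negative-binomial
# count noise.
#
# The generator is truth-by-construction: planted IGRs are verified to
# contain a complete transcriptional unit on the planted strand and decoy
# IGRs are rejection-sampled until they genuinely lack the element their
# class says they lack, so the ground-truth labels are correct by
# construction rather than by hope.

# Default per-condition fold changes for the 11 planted sRNAs. These
# emulate the stress responses observed for the 11 intergenic sRNAs of
# B. animalis subsp. lactis KLDS 2.0603 under acid, bile-salt and simulated
# gastrointestinal-fluid treatment (columns) relative to an untreated
# control: one sRNA strongly acid-induced (4.12x), broad mild induction
# under bile, mostly repression under the combined treatment.
PLANTED_SRNA_FOLDS <- matrix(
  c(1.63, 3.86, 0.29,
    1.26, 1.25, 0.94,
    0.98, 1.84, 0.59,
    0.70, 1.05, 1.25,
    2.15, 3.26, 0.33,
    0.90, 1.44, 0.26,
    1.11, 1.24, 0.86,
    4.12, 1.55, 0.65,
    0.96, 1.99, 0.47,
    1.92, 1.76, 0.50,
    2.50, 1.19, 0.63),
  ncol = 3L, byrow = TRUE,
  dimnames = list(NULL, c("acid", "bile", "git"))
)

#' Simulation configuration
#'
#' Defaults describe a 50 kb circular genome at 60% GC (the GC content of
#' the B. animalis subsp. lactis chromosome this generator miniaturizes)
#' with 45 genes, 11 planted sRNAs and 21 decoy IGRs (7 per violation
#' class), sequenced at 50,000 reads per sample under four conditions.
#'
#' @param seed Integer seed; every random choice flows from it.
#' @param genome_len Genome length in bp.
#' @param gc GC fraction of the background sequence.
#' @param n_genes Number of gene-like (CDS) features.
#' @param n_planted_srnas Planted true sRNAs (each with consensus promoter,
#'   strong terminator, expression 3x both flanks).
#' @param n_decoys_per_class Decoys per violation class (`no_promoter`,
#'   `no_terminator`, `low_expression`).
#' @param conditions Sample names; the first is the control.
#' @param reads_per_sample Expected sequenced fragments per sample.
#' @param nb_dispersion Negative-binomial dispersion of per-feature counts
#'   (variance = mu + dispersion * mu^2).
#' @param duplicate_fraction Fraction of reads duplicated exactly (PCR).
#' @param read_len_range Read lengths drawn uniformly from this range
#'   (post-trim lengths; variable lengths keep coincidental position
#'   collisions from being confused with PCR duplicates).
#' @param fold_change_map Optional feature x condition fold-change matrix
#'   overriding the defaults (rownames = feature ids).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_len = 50000L, gc = 0.60,
                       n_genes = 45L, n_planted_srnas = 11L,
                       n_decoys_per_class = 7L,
                       conditions = c("control", "acid", "bile", "git"),
                       reads_per_sample = 50000L, nb_dispersion = 0.05,
                       duplicate_fraction = 0.1,
                       read_len_range = c(36L, 50L),
                       fold_change_map = NULL) {
  cfg <- list(
    seed = as.integer(seed), genome_len = as.integer(genome_len), gc = gc,
    n_genes = as.integer(n_genes),
    n_planted_srnas = as.integer(n_planted_srnas),
    n_decoys_per_class = as.integer(n_decoys_per_class),
    conditions = conditions,
    reads_per_sample = as.integer(reads_per_sample),
    nb_dispersion = nb_dispersion,
    duplicate_fraction = duplicate_fraction,
    read_len_range = as.integer(read_len_range),
    fold_change_map = fold_change_map
  )
  class(cfg) <- "sim_config"
  cfg
}

rand_dna <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# overwrite positions [at, at + nchar(motif)) of a char vector (0-based at)
write_motif <- function(seqv, at, motif) {
  m <- strsplit(motif, "")[[1L]]
  seqv[(at + 1L):(at + length(m))] <- m
  seqv
}

# the planted promoter/terminator arrangement inside a 220 nt trimmed core,
# expressed in local plus-strand coordinates of the core
PLANT_LAYOUT <- list(
  core_len = 220L,
  prom35_at = 5L,       # TTGACA
  prom10_at = 28L,      # TATAAT after a 17 bp spacer
  term_at = 150L,       # stem(6) loop(4) stem(6) then TTTTTTTT
  term_stem = "GGCAGC",
  term_loop = "TCAA",
  seed_at = 60L,        # 10 nt later embedded (revcomp) in a target gene
  seed_len = 10L
)

# build one 220 nt core on random background with the requested elements
build_core <- function(gc, with_promoter, with_terminator, strand) {
  lay <- PLANT_LAYOUT
  core <- rand_dna(lay$core_len, gc)
  if (with_promoter) {
    core <- write_motif(core, lay$prom35_at, "TTGACA")
    core <- write_motif(core, lay$prom10_at, "TATAAT")
  }
  if (with_terminator) {
    term <- paste0(lay$term_stem, lay$term_loop, revcomp(lay$term_stem),
                   "TTTTTTTT")
    core <- write_motif(core, lay$term_at, term)
  }
  s <- paste(core, collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

core_unit_status <- function(core_seq, promoter_threshold = 12,
                             term_params = terminator_config()) {
  sig <- rbind(
    scan_promoters(core_seq, "+", threshold = promoter_threshold)[
      , c("kind", "position", "strand", "score")],
    scan_promoters(core_seq, "-", threshold = promoter_threshold)[
      , c("kind", "position", "strand", "score")],
    scan_terminators(core_seq, "+", term_params)[
      , c("kind", "position", "strand", "score")],
    scan_terminators(core_seq, "-", term_params)[
      , c("kind", "position", "strand", "score")]
  )
  call_unit("core", sig)
}

# rejection-sample a core until the unit call matches what the class needs
sample_core <- function(gc, class, strand, max_tries = 100L) {
  for (k in seq_len(max_tries)) {
    core <- build_core(
      gc,
      with_promoter = class %in% c("planted", "low_expression",
                                   "no_terminator"),
      with_terminator = class %in% c("planted", "low_expression",
                                     "no_promoter"),
      strand = strand
    )
    uc <- core_unit_status(core)
    ok <- if (class %in% c("planted", "low_expression")) {
      uc$complete_unit && uc$unit_strand == strand
    } else {
      !uc$complete_unit
    }
    if (ok) return(core)
  }
  stop("could not realize a '", class, "' IGR core in ", max_tries,
       " tries; background too signal-rich", call. = FALSE)
}

#' Simulate an annotated genome with planted sRNAs and decoy IGRs
#'
#' Lays out `n_genes` genes (500-800 bp, random strands, ATG start codons)
#' separated by gaps of known role: planted sRNA gaps (300 bp raw, so the
#' 40 bp trim leaves a 220 bp IGR carrying a consensus promoter, a strong
#' GC-stem terminator and an 8 nt U-tract on the planted strand), decoy
#' gaps missing exactly one required element, gaps containing a tRNA/rRNA
#' feature (to exercise the exclusion rule), sub-threshold short gaps, and
#' plain gaps. Left-over genome length is absorbed by the wrap-around gap
#' of the circular chromosome. Two of the planted sRNAs lie on the minus
#' strand.
#'
#' @param cfg A [sim_config()].
#' @return A list: `genome` (an `annotated_genome`), `truth` (ground-truth
#'   list: `planted`, `decoys`, `igr_features`, `base_expression`,
#'   `fold_change`, `planted_edges`), `config`.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lay <- PLANT_LAYOUT
  n_planted <- cfg$n_planted_srnas
  n_decoy <- 3L * cfg$n_decoys_per_class
  n_struct <- 3L   # gaps holding a tRNA/tRNA/rRNA feature
  n_short <- 4L
  n_special <- n_planted + n_decoy + n_struct + n_short
  n_gaps <- cfg$n_genes - 1L   # internal gaps; the wrap gap is extra
  if (n_special > n_gaps) {
    stop("infeasible packing: ", n_special, " special gaps but only ",
         n_gaps, " internal gaps; increase n_genes", call. = FALSE)
  }

  roles <- c(rep("planted", n_planted),
             rep(c("no_promoter", "no_terminator", "low_expression"),
                 each = cfg$n_decoys_per_class),
             rep("structural", n_struct),
             rep("short", n_short),
             rep("plain", n_gaps - n_special))
  roles <- sample(roles)

  gene_len <- sample(500:800, cfg$n_genes, replace = TRUE)
  gap_len <- ifelse(roles == "short", sample(100:190, n_gaps, replace = TRUE),
                    300L)
  used <- sum(gene_len) + sum(gap_len)
  leftover <- cfg$genome_len - used
  if (leftover < 200L) {   # wrap-around gap must survive trimming + filter
    stop("infeasible packing: layout needs ", used + 200L,
         " bp but genome_len is ", cfg$genome_len,
         "; increase genome_len", call. = FALSE)
  }

  # planted strands: two minus-strand sRNAs, the rest plus
  planted_idx <- which(roles == "planted")
  planted_strand <- rep("+", n_planted)
  if (n_planted >= 4L) planted_strand[c(3L, 7L)] <- "-"
  decoy_strand <- sample(c("+", "-"), n_gaps, replace = TRUE)

  seqv <- rand_dna(cfg$genome_len, cfg$gc)
  feats <- list()
  planted_rows <- list()
  decoy_rows <- list()
  igr_feature_rows <- list()

  pos <- 0L
  struct_seen <- 0L
  planted_seen <- 0L
  gene_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  gene_start <- integer(cfg$n_genes)
  for (k in seq_len(cfg$n_genes)) {
    gene_start[k] <- pos
    gid <- sprintf("gene%02d", k)
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = gid, kind = "CDS", start = pos, end = pos + gene_len[k],
      strand = gene_strand[k],
      product = sprintf("hypothetical protein %02d", k),
      stringsAsFactors = FALSE
    )
    if (gene_strand[k] == "+") {
      seqv <- write_motif(seqv, pos, "ATG")
    } else {
      seqv <- write_motif(seqv, pos + gene_len[k] - 3L, "CAT")
    }
    pos <- pos + gene_len[k]
    if (k == cfg$n_genes) break

    role <- roles[k]
    gs <- pos
    ge <- pos + gap_len[k]
    trim_s <- gs + 40L
    trim_e <- ge - 40L
    if (role == "structural") {
      struct_seen <- struct_seen + 1L
      kind <- if (struct_seen <= 2L) "tRNA" else "rRNA"
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = sprintf("%s%d", tolower(kind), struct_seen),
        kind = kind, start = gs + 110L, end = gs + 190L,
        strand = sample(c("+", "-"), 1L),
        product = paste(kind, "feature"), stringsAsFactors = FALSE
      )
    } else if (role %in% c("planted", "no_promoter", "no_terminator",
                           "low_expression")) {
      strand <- if (role == "planted") {
        planted_seen <- planted_seen + 1L
        planted_strand[planted_seen]
      } else {
        decoy_strand[k]
      }
      core <- sample_core(cfg$gc,
                          class = if (role == "planted") "planted" else role,
                          strand = strand)
      seqv <- write_motif(seqv, trim_s, core)
      if (role == "planted") {
        planted_rows[[length(planted_rows) + 1L]] <- data.frame(
          plant_index = planted_seen, start = trim_s, end = trim_e,
          strand = strand, left_gene = sprintf("gene%02d", k),
          right_gene = sprintf("gene%02d", k + 1L), stringsAsFactors = FALSE
        )
      } else {
        decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
          class = role, start = trim_s, end = trim_e, strand = strand,
          left_gene = sprintf("gene%02d", k),
          right_gene = sprintf("gene%02d", k + 1L), stringsAsFactors = FALSE
        )
      }
    }
    if (role != "short") {
      igr_feature_rows[[length(igr_feature_rows) + 1L]] <- data.frame(
        role = role, start = trim_s, end = trim_e, stringsAsFactors = FALSE
      )
    }
    pos <- ge
  }
  # wrap-around gap: remainder of the genome after the last gene
  igr_feature_rows[[length(igr_feature_rows) + 1L]] <- data.frame(
    role = "wrap", start = pos + 40L, end = cfg$genome_len - 40L,
    stringsAsFactors = FALSE
  )

  features <- do.call(rbind, feats)
  genome <- new_annotated_genome("simgenome", paste(seqv, collapse = ""),
                                 is_circular = TRUE, features = features)
  genome <- set_features(genome, features)

  planted <- do.call(rbind, planted_rows)
  decoys <- do.call(rbind, decoy_rows)
  igr_features <- do.call(rbind, igr_feature_rows)
  # structural-gap IGRs are removed by the tRNA/rRNA rule, shorts by length
  igr_features <- igr_features[igr_features$role != "structural",
                               , drop = FALSE]
  igr_features <- igr_features[order(igr_features$start), , drop = FALSE]
  igr_features$igr_id <- paste0("IGR-", seq_len(nrow(igr_features)))
  planted$igr_id <- igr_features$igr_id[match(planted$start,
                                              igr_features$start)]
  decoys$igr_id <- igr_features$igr_id[match(decoys$start,
                                             igr_features$start)]

  truth <- list(planted = planted, decoys = decoys,
                igr_features = igr_features)
  truth <- add_expression_truth(truth, genome, cfg)
  truth <- add_planted_edges(truth, genome, cfg)
  genome$sequence <- paste(truth$seqv %||% strsplit(genome$sequence, "")[[1L]],
                           collapse = "")
  truth$seqv <- NULL
  list(genome = genome, truth = truth, config = cfg)
}

# base (control) expression per feature and the fold-change matrix
add_expression_truth <- function(truth, genome, cfg) {
  f <- genome$features
  base <- numeric(0L)
  for (i in seq_len(nrow(f))) {
    base[f$feature_id[i]] <- switch(
      f$kind[i],
      CDS = exp(rnorm(1L, log(50), 0.5)),
      tRNA = 30,
      rRNA = 500,
      exp(rnorm(1L, log(50), 0.5))
    )
  }
  ig <- truth$igr_features
  flank_base <- function(left, right) {
    c(base[[left]], base[[right]])
  }
  for (i in seq_len(nrow(ig))) {
    id <- ig$igr_id[i]
    role <- ig$role[i]
    base[id] <- if (role == "planted") {
      p <- truth$planted[truth$planted$igr_id == id, ]
      3 * max(flank_base(p$left_gene, p$right_gene))
    } else if (role %in% c("no_promoter", "no_terminator")) {
      d <- truth$decoys[truth$decoys$igr_id == id, ]
      3 * max(flank_base(d$left_gene, d$right_gene))
    } else if (role == "low_expression") {
      d <- truth$decoys[truth$decoys$igr_id == id, ]
      0.4 * min(flank_base(d$left_gene, d$right_gene))
    } else {
      2   # faint background transcription in plain/wrap gaps
    }
  }

  conds <- setdiff(cfg$conditions, cfg$conditions[1L])
  fold <- matrix(1, nrow = length(base), ncol = length(conds),
                 dimnames = list(names(base), conds))
  if (!is.null(cfg$fold_change_map)) {
    fcm <- cfg$fold_change_map
    fold[rownames(fcm), colnames(fcm)] <- fcm
  } else {
    # planted sRNAs: stress-response profile of the 11 reference sRNAs
    pl <- truth$planted[order(truth$planted$plant_index), ]
    for (i in seq_len(nrow(pl))) {
      for (cc in intersect(conds, colnames(PLANTED_SRNA_FOLDS))) {
        fold[pl$igr_id[i], cc] <- PLANTED_SRNA_FOLDS[
          ((i - 1L) %% nrow(PLANTED_SRNA_FOLDS)) + 1L, cc]
      }
    }
    # a handful of genes with strong (|log2 FC| = 2) responses, with
    # overlapping membership across conditions so DEG Venn counts are
    # non-trivial. Genes flanking a low-expression decoy are exempt: if a
    # decoy's flanks dropped 4x under stress the decoy would honestly
    # satisfy the 15% rule in that sample and stop being a decoy.
    lowexp <- truth$decoys[truth$decoys$class == "low_expression", ]
    protected <- unique(c(lowexp$left_gene, lowexp$right_gene))
    elig <- setdiff(genome$features$feature_id[
      genome$features$kind == "CDS"], protected)
    if (length(elig) < 17L) {
      stop("too few genes free of decoy adjacency for the DEG plan",
           call. = FALSE)
    }
    deg_plan <- list(
      acid = list(up = elig[1:4], down = elig[11:14]),
      bile = list(up = elig[3:6], down = elig[13:16]),
      git = list(up = elig[c(2:5, 7)], down = elig[c(12:15, 17)])
    )
    for (cc in intersect(conds, names(deg_plan))) {
      fold[deg_plan[[cc]]$up, cc] <- 4
      fold[deg_plan[[cc]]$down, cc] <- 0.25
    }
    truth$deg_plan <- deg_plan[intersect(conds, names(deg_plan))]
  }
  truth$base_expression <- base
  truth$fold_change <- fold
  truth
}

# embed reverse-complement seeds of planted sRNAs into the start-codon
# windows of plus-strand flanking genes; returns truth with planted_edges
add_planted_edges <- function(truth, genome, cfg) {
  lay <- PLANT_LAYOUT
  seqv <- strsplit(genome$sequence, "")[[1L]]
  f <- genome$features
  edges <- list()
  used_genes <- character()   # one embedded seed per gene: adjacent plants
                              # must not overwrite each other's seed
  for (i in seq_len(nrow(truth$planted))) {
    p <- truth$planted[i, ]
    srna_seq <- substr(genome$sequence, p$start + 1L, p$end)
    if (p$strand == "-") srna_seq <- revcomp(srna_seq)
    seed <- substr(srna_seq, lay$seed_at + 1L, lay$seed_at + lay$seed_len)
    # choose an unclaimed plus-strand flank gene to write the complement into
    cand <- c(p$right_gene, p$left_gene)
    gene <- NULL
    for (g in setdiff(cand, used_genes)) {
      row <- f[f$feature_id == g, ]
      if (row$strand == "+") { gene <- row; break }
    }
    if (is.null(gene)) next
    used_genes <- c(used_genes, gene$feature_id)
    at <- gene$start + 8L   # inside the -30..+20 window, in the gene body
    seqv <- write_motif(seqv, at, revcomp(seed))
    edges[[length(edges) + 1L]] <- data.frame(
      srna_id = p$igr_id, gene_id = gene$feature_id, seed = seed,
      position_in_mrna = 8L, stringsAsFactors = FALSE
    )
  }
  truth$planted_edges <- do.call(rbind, edges)
  truth$seqv <- seqv
  truth
}

#' Simulate per-condition read alignments
#'
#' For each feature (genes, tRNA/rRNA and the IGR-level intervals of the
#' ground truth) and condition, a count is drawn from a negative binomial
#' with mean `base_expression * fold_change * length_kb * depth`, where the
#' depth factor scales expected totals to `reads_per_sample`. Reads are
#' intervals of 36-50 nt placed uniformly within the feature on a random
#' strand; a `duplicate_fraction` of reads is then duplicated exactly (PCR).
#' Alignments never cross the origin of the circular genome (features are
#' laid out so none wraps).
#'
#' @param sim Output of [simulate_genome()].
#' @return Named list mapping condition to an alignment data.frame
#'   (`read_id`, `start`, `end`, `strand`, `sample_id`).
#' @export
simulate_reads <- function(sim) {
  genome <- sim$genome
  truth <- sim$truth
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  f <- genome$features
  ivs <- rbind(
    data.frame(feature_id = f$feature_id, start = f$start, end = f$end,
               stringsAsFactors = FALSE),
    data.frame(feature_id = truth$igr_features$igr_id,
               start = truth$igr_features$start,
               end = truth$igr_features$end, stringsAsFactors = FALSE)
  )
  ivs$len <- ivs$end - ivs$start
  base <- truth$base_expression[ivs$feature_id]
  conds <- cfg$conditions
  control <- conds[1L]
  out <- list()
  for (cond in conds) {
    fold <- if (cond == control) rep(1, nrow(ivs))
            else truth$fold_change[ivs$feature_id, cond]
    mu_raw <- base * fold * (ivs$len / 1000)
    mu <- mu_raw * cfg$reads_per_sample / sum(mu_raw)
    counts <- rnbinom(nrow(ivs), size = 1 / cfg$nb_dispersion, mu = mu)
    rows <- lapply(which(counts > 0L), function(i) {
      n <- counts[i]
      len <- sample(cfg$read_len_range[1L]:cfg$read_len_range[2L], n,
                    replace = TRUE)
      len <- pmin(len, ivs$len[i])
      start <- ivs$start[i] +
        floor(runif(n) * (ivs$len[i] - len + 1L))
      data.frame(start = as.integer(start),
                 end = as.integer(start + len),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    al <- do.call(rbind, rows)
    if (is.null(al)) {
      al <- data.frame(start = integer(), end = integer(),
                       strand = character(), stringsAsFactors = FALSE)
    }
    n_dup <- floor(cfg$duplicate_fraction * nrow(al))
    if (n_dup > 0L) {
      al <- rbind(al, al[sample(nrow(al), n_dup, replace = TRUE),
                         , drop = FALSE])
    }
    al <- al[sample(nrow(al)), , drop = FALSE]
    al$read_id <- sprintf("%s_r%06d", cond, seq_len(nrow(al)))
    al$sample_id <- cond
    rownames(al) <- NULL
    out[[cond]] <- al[, c("read_id", "start", "end", "strand", "sample_id")]
  }
  out
}

#' Emit a FASTQ file for simulated alignments
#'
#' Read sequences are taken from the genome (reverse complemented for
#' minus-strand reads). A `fail_fraction` of reads receives low qualities
#' (Q = 15 throughout) so they fail the 80%-of-bases-over-Q20 rule; the
#' rest get Q = 35 with the two terminal bases at Q = 2 to exercise end
#' trimming.
#'
#' @param genome An `annotated_genome`.
#' @param alignments One sample's alignment data.frame.
#' @param path Output FASTQ path.
#' @param fail_fraction Fraction of reads built to fail QC (default 0.1).
#' @param seed Seed for choosing the failing reads.
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(genome, alignments, path, fail_fraction = 0.1,
                       seed = 1L) {
  set.seed(seed)
  n <- nrow(alignments)
  fails <- runif(n) < fail_fraction
  lines <- character(4L * n)
  for (i in seq_len(n)) {
    s <- subseq0(genome$sequence, alignments$start[i], alignments$end[i])
    if (alignments$strand[i] == "-") s <- revcomp(s)
    len <- nchar(s)
    q <- if (fails[i]) {
      strrep(rawToChar(as.raw(33L + 15L)), len)
    } else {
      mid <- strrep(rawToChar(as.raw(33L + 35L)), max(len - 4L, 0L))
      lowq <- rawToChar(as.raw(33L + 2L))
      paste0(lowq, lowq, mid, lowq, lowq)
    }
    lines[4L * i - 3L] <- paste0("@", alignments$read_id[i])
    lines[4L * i - 2L] <- s
    lines[4L * i - 1L] <- "+"
    lines[4L * i] <- q
  }
  writeLines(lines, path)
  invisible(path)
}
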