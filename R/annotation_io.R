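# Genome / annotation / alignment I/O and genome summary statistics.
#
# An annotated_genome is a list:
#   genome_id   character scalar (first token of the FASTA header)
#   sequence    character scalar over {A,C,G,T,N}
#   length      integer, nchar(sequence)
#   is_circular logical
#   features    data.frame(feature_id, kind, start, end, strand, product)
#               with kind in {CDS, tRNA, rRNA, other}, 0-based half-open
#               coordinates, sorted by start.

FEATURE_KINDS <- c("CDS", "tRNA", "rRNA", "other")

new_annotated_genome <- function(genome_id, sequence, is_circular = TRUE,
                                 features = empty_features()) {
  g <- list(
    genome_id = genome_id,
    sequence = sequence,
    length = nchar(sequence),
    is_circular = is_circular,
    features = features
  )
  class(g) <- "annotated_genome"
  g
}

empty_features <- function() {
  data.frame(
    feature_id = character(), kind = character(),
    start = integer(), end = integer(),
    strand = character(), product = character(),
    stringsAsFactors = FALSE
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf(
    "<annotated_genome> %s: %s bp (%s), %d features\n",
    x$genome_id, format(x$length, big.mark = ","),
    if (x$is_circular) "circular" else "linear", nrow(x$features)
  ))
  invisible(x)
}

#' Read a genome sequence from FASTA
#'
#' Loads the first record of a FASTA file as an [annotated genome][read_annotation]
#' with an empty feature table. The sequence is upper-cased and RNA `U` is
#' converted to `T`. Multi-record files trigger a warning and only the first
#' record is used (single-replicon pipeline).
#'
#' @param fasta_path Path to a FASTA file with at least one record.
#' @param is_circular Treat the replicon as circular (bacterial chromosome)?
#' @return An `annotated_genome` with empty features.
#' @export
read_genome <- function(fasta_path, is_circular = TRUE) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(fasta_path),
    error = function(e) stop("not a valid FASTA file: ", fasta_path,
                             " (", conditionMessage(e), ")", call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", fasta_path, call. = FALSE)
  }
  if (length(set) > 1L) {
    warning("FASTA has ", length(set), " records; using the first only")
  }
  seq <- toupper(as.character(set[[1L]]))
  seq <- chartr("U", "T", seq)
  bad <- gsub("[ACGTNRYSWKMBDHV]", "", seq)
  if (nchar(bad) > 0L) {
    stop("sequence contains non-IUPAC characters: ",
         paste(unique(strsplit(bad, "")[[1L]]), collapse = ""), call. = FALSE)
  }
  genome_id <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  new_annotated_genome(genome_id, seq, is_circular = is_circular)
}

#' Attach a GFF3 annotation to a genome
#'
#' Reads a GFF3 file and converts its 1-based inclusive coordinates to the
#' internal 0-based half-open convention (`start_internal = start_gff - 1`,
#' `end_internal = end_gff`). The GFF type column is mapped to the feature
#' kind: `CDS`, `tRNA` and `rRNA` keep their names, everything else becomes
#' `other` (`gene`/`region`/`source` container lines are dropped to avoid
#' double-counting a CDS and its parent gene). Features are sorted by start.
#'
#' @param gff_path Path to a GFF3 file.
#' @param genome An `annotated_genome` from [read_genome()].
#' @param drop_types GFF type values ignored entirely (container lines).
#' @return The genome with its `features` table filled in.
#' @export
read_annotation <- function(gff_path, genome,
                            drop_types = c("gene", "region", "source",
                                           "exon", "chromosome")) {
  stopifnot(inherits(genome, "annotated_genome"))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  keep <- !(as.character(gr$type) %in% drop_types)
  gr <- gr[keep]
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids <- ifelse(is.na(ids) | ids == "",
                paste0("feat", seq_along(gr)), ids)
  kind <- as.character(gr$type)
  kind[!(kind %in% c("CDS", "tRNA", "rRNA"))] <- "other"
  product <- gr$product
  if (is.null(product)) product <- rep("", length(gr))
  product[is.na(product)] <- ""
  feats <- data.frame(
    feature_id = ids,
    kind = kind,
    start = GenomicRanges::start(gr) - 1L,   # GFF 1-based -> internal 0-based
    end = GenomicRanges::end(gr),            # inclusive -> half-open
    strand = as.character(GenomicRanges::strand(gr)),
    product = as.character(product),
    stringsAsFactors = FALSE
  )
  feats$strand[!(feats$strand %in% c("+", "-"))] <- "+"
  set_features(genome, feats)
}

# validate + sort + attach a feature table
set_features <- function(genome, feats) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (nrow(feats)) {
    bad <- feats$start < 0L | feats$end > genome$length |
      feats$start >= feats$end
    if (any(bad)) {
      stop("feature(s) outside genome bounds [0, ", genome$length, "): ",
           paste(feats$feature_id[bad], collapse = ", "), call. = FALSE)
    }
    if (!all(feats$kind %in% FEATURE_KINDS)) {
      stop("unknown feature kind(s): ",
           paste(setdiff(feats$kind, FEATURE_KINDS), collapse = ", "),
           call. = FALSE)
    }
    feats <- feats[order(feats$start, feats$end), , drop = FALSE]
    rownames(feats) <- NULL
  }
  genome$features <- feats
  genome
}

#' Write a feature table back to GFF3
#'
#' Inverse of [read_annotation()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive GFF3 (`start_gff = start + 1`,
#' `end_gff = end`), so a read/write round trip reproduces coordinates
#' exactly.
#'
#' @param genome An `annotated_genome` with features.
#' @param gff_path Output path.
#' @return `gff_path`, invisibly.
#' @export
write_annotation <- function(genome, gff_path) {
  stopifnot(inherits(genome, "annotated_genome"))
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = genome$genome_id,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand
  )
  gr$type <- f$kind
  gr$ID <- f$feature_id
  gr$product <- f$product
  gr$phase <- ifelse(f$kind == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(gff_path)
}

#' Summarize a genome
#'
#' Length, GC fraction (N excluded from the denominator), feature counts by
#' kind and the coding fraction (union length of CDS features over genome
#' length). GC is returned as a fraction in `[0, 1]`; format as percent only
#' for display.
#'
#' @param genome An `annotated_genome`.
#' @return A list of class `genome_summary` with fields `length_bp`,
#'   `gc_fraction`, `n_genes`, `n_trna`, `n_rrna`, `coding_fraction`.
#' @export
summarize_genome <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  counts <- Biostrings::letterFrequency(
    Biostrings::DNAString(genome$sequence), letters = c("A", "C", "G", "T")
  )
  acgt <- sum(counts)
  gc <- if (acgt > 0) (counts[["C"]] + counts[["G"]]) / acgt else NA_real_
  f <- genome$features
  cds <- f[f$kind == "CDS", , drop = FALSE]
  coding <- if (nrow(cds)) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = cds$start + 1L, end = cds$end)
    ))) / genome$length
  } else 0
  out <- list(
    length_bp = genome$length,
    gc_fraction = gc,
    n_genes = sum(f$kind %in% c("CDS", "other")),
    n_trna = sum(f$kind == "tRNA"),
    n_rrna = sum(f$kind == "rRNA"),
    coding_fraction = coding
  )
  class(out) <- "genome_summary"
  out
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Genome summary: %s bp, GC %.2f%%, %d genes, %d tRNA, %d rRNA, ",
           "coding %.1f%%\n"),
    format(x$length_bp, big.mark = ","), 100 * x$gc_fraction,
    x$n_genes, x$n_trna, x$n_rrna, 100 * x$coding_fraction
  ))
  invisible(x)
}

#' Read aligned reads from a BED6 file
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Strandless lines (`.` in column 6) default to `+` with a warning; counting
#' downstream is unstranded anyway. Malformed lines raise an error naming the
#' line number.
#'
#' @param bed_path Path to a BED6 file (chrom, start, end, name, score,
#'   strand).
#' @param sample_id Sample label attached to every alignment.
#' @return A data.frame with columns `read_id`, `start`, `end`, `strand`,
#'   `sample_id`.
#' @export
read_alignments <- function(bed_path, sample_id) {
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(read_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      sample_id = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L)) {
    stop("BED parse error at line ", which(nf < 6L)[1L],
         ": expected 6 tab-separated columns, got ", nf[nf < 6L][1L],
         call. = FALSE)
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1L],
         ": invalid interval (", m[bad[1L], 2L], ", ", m[bad[1L], 3L], ")",
         call. = FALSE)
  }
  strand <- m[, 6L]
  if (any(strand == ".")) {
    warning(sum(strand == "."), " strandless BED line(s) defaulted to '+'")
    strand[strand == "."] <- "+"
  }
  if (!all(strand %in% c("+", "-"))) {
    stop("BED parse error at line ", which(!(strand %in% c("+", "-")))[1L],
         ": strand must be '+', '-' or '.'", call. = FALSE)
  }
  data.frame(
    read_id = m[, 4L], start = start, end = end, strand = strand,
    sample_id = sample_id, stringsAsFactors = FALSE
  )
}

#' Write alignments as BED6
#'
#' @param alignments Data.frame as returned by [read_alignments()].
#' @param bed_path Output path.
#' @param chrom Chromosome name for column 1.
#' @return `bed_path`, invisibly.
#' @export
write_alignments <- function(alignments, bed_path, chrom = "chr") {
  df <- data.frame(
    chrom = chrom, start = alignments$start, end = alignments$end,
    name = alignments$read_id, score = 0L, strand = alignments$strand
  )
  write.table(df, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}
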