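# Internal coordinate convention: 0-based, half-open [start, end), forward
# strand of the single replicon. GFF/BED conversion happens only in
# annotation_io. Sequences are plain upper-case character strings over
# {A,C,G,T,N}.

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over the IUPAC DNA alphabet
#'   (case-insensitive).
#' @return Character scalar, the reverse complement.
#' @export
#' @examples
#' revcomp("TTGACA")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  # chartr + codepoint reversal is ~100x faster than S4 dispatch here and
  # this sits on the scanners' hot path
  intToUtf8(rev(utf8ToInt(chartr(
    "ACGTRYSWKMBDHVNacgtryswkmbdhvn",
    "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", seq
  ))))
}

# DNA string -> integer codes A=1 C=2 G=3 T=4 N/other=5 (fast scan indexing)
seq_to_int <- function(seq) {
  codes <- integer(256)
  codes[] <- 5L
  codes[utf8ToInt("A")] <- 1L
  codes[utf8ToInt("C")] <- 2L
  codes[utf8ToInt("G")] <- 3L
  codes[utf8ToInt("T")] <- 4L
  codes[utf8ToInt(seq)]
}

# substring by internal 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# substring that may run past the end of a circular genome (wrap-around IGR)
subseq0_circular <- function(seq, start, end, genome_len) {
  if (end <= genome_len) return(subseq0(seq, start, end))
  paste0(subseq0(seq, start, genome_len), subseq0(seq, 0L, end - genome_len))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
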