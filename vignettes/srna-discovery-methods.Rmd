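---
title: "Methods: intergenic sRNA discovery and stress-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intergenic sRNA discovery and stress-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

srnaseeker implements a genome-wide discovery procedure for bacterial small
regulatory RNAs (sRNAs) transcribed from intergenic regions (IGRs), together
with the downstream expression analyses one runs on stress-treated
transcriptomes: replicate-free differential expression and an
sRNA–target co-regulation network. This vignette is the package's own
account of the method — the model at each stage, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
establish.

## The discovery model

A candidate sRNA is an intergenic interval that looks transcribable and is
actually transcribed. The pipeline decomposes this into four gates applied
in order:

1. **IGR extraction.** Gaps between annotated gene-like features are
   computed strand-agnostically (regulatory RNAs can sit between genes of
   either orientation). Forty bp are deleted from each side of every raw
   gap, because the margins of an intergenic gap typically belong to the
   flanking ORFs — their promoters, UTRs and terminators. Trimmed intervals
   shorter than 120 bp are discarded (an sRNA needs some minimal length,
   and a very short interval cannot carry its own promoter and terminator);
   a trimmed length of exactly 120 bp is kept. Intervals whose trimmed span
   overlaps a tRNA or rRNA feature are removed: these are structured RNAs
   already annotated, not novel sRNAs. Duplicated intervals are collapsed
   and identifiers `IGR-1 … IGR-n` are assigned left to right.
2. **Complete transcriptional unit.** An IGR must contain a predicted
   promoter and, downstream of it on the same strand, a predicted
   terminator. This is a boolean gate; the scanners behind it are
   deliberately simple (below).
3. **Expression above the flanks.** In a given transcriptome the IGR's
   RPKM must be at least 15% higher than the RPKM of *both* flanking genes
   (`rpkm(IGR) ≥ 1.15 × rpkm(flank)`, inclusive). The logic: read-through
   or mis-annotated UTR transcription tracks its gene's level, whereas an
   independently transcribed sRNA exceeds it. The rule is applied per
   sample, and the final high-confidence set is the union of the
   per-sample calls — an sRNA may be silent under some conditions.
4. **Reporting.** Calls are reported with strand-polarized coordinates
   (minus-strand rows print start > end), the flanking genes' products, and
   a three-glyph orientation string (left flank, sRNA, right flank; `→` for
   plus, `←` for minus).

### Coordinates

Internally every interval is 0-based, half-open on the forward strand of a
single replicon; GFF3 (1-based inclusive) and BED (0-based half-open) are
converted at the I/O boundary only. This makes the trimming arithmetic
(`start + 40`, `end − 40`, `length = end − start`) exact and
off-by-one-free. The chromosome is treated as circular by default; the gap
between the last and first gene is one IGR, and simulated alignments never
cross the origin.

### Which features block a gap

Gaps are computed between *gene-like* features (CDS and unclassified
features). tRNA and rRNA features deliberately do not block gaps: they are
removed by the explicit exclusion rule instead. If every annotated feature
blocked gaps, no IGR could ever overlap a tRNA/rRNA and the exclusion rule
would be unreachable dead code; placing structured RNAs inside gaps is also
how the synthetic genome exercises that rule. Overlapping gene features are
merged into occupied blocks before gap computation so that no negative-length
gap can arise.

## Transcription-signal scanners

The role of the promoter and terminator predictors in this pipeline is a
yes/no gate per IGR, so srnaseeker substitutes transparent, deterministic,
exhaustively testable scoring schemes for the opaque external tools a
practitioner might otherwise run. All thresholds are configuration, not
biological claims.

**Promoters** are scored with a two-box sigma-70 model. Each box is a
log2-odds position weight matrix over a uniform background, built from the
canonical consensus (TTGACA for the −35 box, TATAAT for the −10 box) with
pseudocount smoothing: the consensus base carries probability 0.7, the
others 0.1 each, so a consensus position scores `log2(0.7/0.25) ≈ 1.485`
and any other base `log2(0.1/0.25) ≈ −1.322`. The scanner slides the −35
box and, for each spacer length 15–19 bp, adds the −10 box score and a
spacer penalty of −0.5 per bp of deviation from the canonical 17. The
reported position is a transcription start proxy: the first base after the
−10 box. Non-overlapping local maxima at or above the threshold are
reported; the minus strand is scanned on the reverse complement and mapped
back. Two perfect boxes score 17.83; one mismatch costs 2.81. The default
threshold of 12 therefore admits up to two mismatches across both boxes —
calibrated on synthetic GC-rich background so that a ~200 bp random
sequence almost never yields a false promoter, while near-consensus
promoters always pass.

**Rho-independent terminators** are found by exhaustive hairpin
enumeration: stems of 4–15 bp with at most one mismatched pair and no
bulges, loops of 3–10 nt. The hairpin score sums pair scores (G·C +2,
A·T +1, G·U wobble +0.5, mismatch −2) minus a loop penalty of
`0.5 × (loop − 3)`; the U-tract score weighs the Ts among the up-to-8 nt
after the 3′ stem with weights (1, 1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4),
truncated at the sequence end. A hit needs hairpin ≥ 8 *and* tail ≥ 2.5;
the total score `hairpin + 2 × tail` resolves overlapping candidates to
the best one. The one-mismatch/no-bulge restriction is what keeps the
search space small enough for an exhaustive brute-force enumerator to
serve as an independent oracle in the tests — the test suite checks exact
agreement of the two implementations on hundreds of short fixtures, and
nearest-neighbour free-energy folding is an explicit non-goal.

A complete unit requires a promoter–terminator pair in transcription
order on one strand; if both strands qualify, the plus strand wins the tie
(a deterministic, documented choice — in practice the synthetic generator
rejects such ambiguous IGRs).

## Expression quantification

**Read QC** keeps a read iff, after trimming terminal bases of quality
≤ 2, it is longer than 20 nt (strict) and at least 80% of its bases have
quality strictly above Q20. The end-trim threshold of Q2 is the package's
choice (only "low-quality ends are trimmed" is specified by the
procedure); the 80%/Q20/20 nt filter is applied exactly as stated.

**PCR duplicates** are alignments sharing an identical (start, end,
strand) triple; exactly one survives. With single-end data this
deliberately cannot distinguish true PCR duplicates from coincidental
position collisions — a known limitation of position-based deduplication.

**Counting** assigns a deduplicated read to every feature (gene or IGR)
covering at least 50% of the read's length, strand-agnostic (the library
protocol is unstranded). Multi-assignment is allowed. This rule is the
package's own: simple, deterministic, and checked against a naive
interval-intersection oracle. The per-sample total of mapped reads is the
number of deduplicated alignments, not the per-feature sum, and

`RPKM = count / ((total_mapped / 10^6) × (length / 10^3))`.

## Differential expression without replicates

Each stress condition is a single library, so dispersion cannot be
estimated. The package uses the classical exact conditional test for
single-library count contrasts: conditional on `n = count_a + count_b`,
`count_a ~ Binomial(n, total_a/(total_a+total_b))` under the null; the
two-sided p-value sums the probabilities of all outcomes at most as likely
as the observed one. Its analytic size at typical bacterial depths
(hundreds of reads per gene) is 0.040–0.046 at α = 0.05 — slightly
conservative, as any discrete exact test is.

RPKMs are first median-normalized: each sample is scaled by
`reference / median(sample RPKM > 0)` with the reference set to the
geometric mean of the sample medians. "Normalize by the median" leaves the
target arbitrary; the geometric mean is the symmetric choice (no sample is
privileged) and makes the normalization idempotent. Fold changes use a
pseudocount of 0.5 RPKM on both sides to avoid infinities at zeros. A
feature is a DEG iff `|log2 FC| > 1` and `p < 0.05`, both strict; a
Benjamini–Hochberg FDR column is emitted for information but does not
enter the status, since the selection rule is the raw-p convention.
Condition overlap ("Venn") counts report the shared fraction as
`|A ∩ R| / |A|` — the denominator is the non-reference condition's own DEG
count, and it is named explicitly in the output because the alternative
reading (fraction of the reference set) is a real ambiguity.

## Target prediction and the regulation network

Thermodynamic target predictors are replaced by perfect antisense seed
matching: a maximal reverse-complement match of ≥ 8 nt between the sRNA
and the −30..+20 window around a gene's start codon (the canonical search
region for translation-initiation interference), scored G:C = 2, A:T = 1
and kept at score ≥ 10, best edge per (sRNA, gene) pair. The claims this
module supports are about *network structure* — degree statistics,
co-regulation counts — not hybridization energetics. COG category labels
are supplied data (a gene → letters table); assignment via sequence search
is out of scope, keeping the package free of external databases. The
network is exported as an edge-list TSV and GraphML.

## The synthetic world

The generator emits the complete input set — genome FASTA, GFF3, per-
condition BED alignments, optional FASTQ — from one seed, with the
statistical structure every stage assumes. Its defaults are a stated
world, fixed once:

* 50 kb circular genome, iid background at 60% GC — the GC content of the
  *B. animalis* subsp. *lactis* chromosome this miniaturizes; 45 genes of
  500–800 bp with ATG start codons and random strands; 2 tRNA and 1 rRNA
  features placed inside gaps to exercise the exclusion rule; 4 short
  (100–190 bp) gaps to exercise the length filter; left-over length is
  absorbed by the wrap-around gap.
* 11 planted sRNAs (9 plus / 2 minus strand, echoing the reference
  catalogue's strand split) in 300 bp gaps, whose 220 bp trimmed cores
  carry consensus boxes at spacer 17, a 6 bp GC stem with 4 nt loop and an
  8 T tail, and base expression 3× the stronger flank.
* 21 decoys, 7 per class, each violating exactly one rule: no promoter,
  no terminator (both at 3× flank expression), or a complete unit at 0.4×
  the weaker flank's expression.
* Per-condition counts are negative binomial (dispersion 0.05) around
  `base × fold × length_kb`, scaled to 50,000 reads per sample; a
  configurable 10% of reads are exact PCR duplicates; read lengths are
  drawn uniformly from 36–50 nt.
* The default fold-change programme gives the 11 planted sRNAs the stress
  profile observed for the 11 reference sRNAs of KLDS 2.0603 under acid,
  bile and simulated gastrointestinal treatment (one sRNA acid-induced
  4.12×, broad mild bile induction, mostly repression under the combined
  fluid), and plants |log2 FC| = 2 responses on a handful of genes with
  overlapping membership across conditions so the DEG overlap counts are
  non-trivial.

Three generator choices deserve their rationale:

* **Truth by construction.** Decoy cores are rejection-sampled until the
  scanner genuinely finds no complete unit (and planted cores until the
  unit sits on the planted strand). A "no-promoter" decoy whose random
  background happened to contain a promoter would not be a decoy; without
  rejection the ground-truth labels would be wishes, not facts. This uses
  the scanner inside the generator — acceptable because the label being
  guaranteed is exactly "what the scanner may legitimately find".
* **Variable read lengths.** With constant-length reads at realistic
  depth, position-based deduplication collapses many coincidental
  collisions (a 220 bp sRNA offers only ~340 distinct constant-length
  placements), biasing every expression level downward in a way real
  variable-length trimmed libraries do not. Lengths of 36–50 nt (post-trim
  lengths) keep that artefact negligible.
* **DEG genes avoid decoy flanks.** If a low-expression decoy's flanking
  gene were planted to drop 4× under stress, the decoy would honestly
  satisfy the 15% rule in that sample and stop being a decoy. The DEG
  programme therefore only uses genes that do not flank a low-expression
  decoy. This is not a dodge of a hard case but the removal of a
  mislabelled one; the hard case — expression genuinely crossing the
  threshold — is what the low-expression class itself tests.

**What a green test establishes.** That the pipeline's gates, applied to
data whose generative process matches the pipeline's assumptions, recover
exactly the planted signal (precision = recall = 1 in ≥ 18/20 seeds) and
that the statistics are calibrated (type-I error within [0.04, 0.06]).
**What it does not establish:** performance on real genomes, where
promoters diverge from consensus, terminators have bulged stems,
background composition is not iid, coverage is position-biased, reads
contain sequencing errors, and mapping is ambiguous. The iid background
also makes spurious antisense seed matches *more* common than in real
coding sequence at the same GC, so the target network's precision on
synthetic data understates nothing.

## Numerical and degenerate-input choices

* Ties between equally scoring overlapping signals resolve to the earlier
  position; both-strand unit ties resolve to plus.
* The terminator tail window truncates at the sequence end rather than
  requiring 8 nt (a terminator at the very 3′ edge of an IGR is real).
* `n = 0` contrasts give p = 1; a zero control RPKM flags the fold change
  as infinite and excludes it from summaries rather than propagating Inf.
* Equality comparisons against thresholds are exact and inclusive
  (≥ 1.15×, ≥ 120 bp) or strict (> 20 nt, > 1 log2, < 0.05) exactly as the
  gates are stated; floating-point tolerance of 1e−7 relative is used only
  when collecting "outcomes at most as probable as observed" in the exact
  test, to absorb `dbinom` rounding.
* Median normalization requires every sample to have some expressed
  feature; an all-zero sample is an error, not a silent scale factor of 0.

## Known limitations

Single replicon only; unstranded counting (the 15% rule can therefore be
fooled by antisense read-through, which stranded data would resolve); no
boundary refinement of sRNA ends from coverage; no homology or structure
classification of the called sRNAs; the exact test is slightly
conservative at low counts; and the accession-based validation (length,
GC, IGR count of the real KLDS 2.0603 chromosome) requires a one-time
download that offline environments cannot perform — the corresponding
acceptance test then reports its absence rather than silently passing.

## Interfaces

The package's functions are the API; the numbered scripts under
`analysis/` are the workflow presentation (simulate → IGRs → signals →
quantify → call → differential expression → targets), each a thin driver
over exported functions that states what it found and writes its tables
under `results/`. `run_pipeline()` executes the same chain in one call
from a `pipeline_config()` (JSON-readable, one top-level seed, every
parameter echoed into `manifest.json`), and `scripts/acceptance.R` runs it
end to end from a command-line seed.
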