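---
title: "Models and methods behind vnarseq"
author: "vnarseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vnarseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vnarseq)
```

`vnarseq` analyses the IgNAR antibody system of cartilaginous fish: the
cluster-organised germline loci, the rearranged vNAR repertoire, and the
cysteine-pattern diversity of vNAR single domains. This vignette explains
the models the package implements, the parameters that matter, what the
simulators do and do not emulate, and the design decisions taken where
more than one defensible convention exists.

## 1. RSS scanning

Somatic V(D)J recombination is guided by recombination signal sequences:
a conserved heptamer (canonically `CACAGTG`), a spacer, and a conserved
nonamer (canonically `ACAAAAACC`). In shark IgNAR clusters three spacer
classes occur, 12, 22 and 23 bp. `findRSS()` reports every window, on
both strands, where a heptamer within `heptamerBudget` mismatches
(default 2) is separated by an allowed spacer from a nonamer within
`nonamerBudget` mismatches (default 3). Three conventions are fixed
deliberately:

* **`N` counts as a mismatch, never a wildcard.** Assembly gaps cannot
  manufacture motif hits; any other non-ACGTN character invalidates the
  window outright.
* **The scan is definitionally exhaustive.** The implementation is a
  direct window scan in C++, and the test suite verifies exact
  equivalence against an independently written vectorised Hamming oracle
  on randomly seeded genomes up to 10 kb.
* **Deduplication keeps the lowest-mismatch motif** when several rows of
  the motif table match the same (contig, start, strand, spacer) window.

The default motif table holds only the canonical pair. Real loci carry
degenerate variants; the table is an ordinary data frame argument and can
be extended row by row, which changes recall but never the scan
semantics. Which spacer class goes with which segment kind is not fixed
by the scanner at all — minus-strand hits simply are RSS in the opposite
orientation, and interpretation is left to segment annotation.

## 2. Germline segment search and cluster assembly

`scanSegments()` is a seed-and-extend local search: exact seed words
(default 12-mers, every 6th offset) anchor candidate windows, and each
window is aligned with affine-gap Smith–Waterman scoring (match 2,
mismatch −3, gap open −5, extend −2 — ordinary nucleotide BLAST-like
weights). A hit is kept when alignment identity (matches over alignment
columns) reaches `minIdentity` and at least half the reference is
covered. Overlapping hits of the same segment kind collapse to the
highest identity, ties broken leftmost-then-plus-strand so output is
deterministic. References shorter than twice the seed length — in
practice the 9-bp D segments — are matched directly with at most one
mismatch instead.

A 9-bp sequence is not uniquely mappable in a genome-sized background,
so D evidence is interpreted in context at assembly time:
`assembleClusters()` retains an RSS-less D hit only within `dContext`
(default 2 kb) of a non-D segment on the same contig and strand. A D
inside a cluster but without flanking RSS is flagged *pre-joined*
(germline-fused); an isolated RSS-less D is discarded as a chance match.
D hits with RSS evidence are always kept.

Clusters are formed per contig and strand by a gap rule (`maxGap`,
default 50 kb — generous relative to intra-cluster spacing yet far below
the distance separating shark IgNAR clusters), named `IgNAR1, IgNAR2,
...` in genomic order, and classified *complete* exactly when they
contain one V, three D, one J, five C, one Sec and one Tm segment,
non-overlapping and in genomic order along the segment strand. Exported
segment names follow the locus convention (`IGNARV1`, `IGNARJ1`,
`IGNARD1-2`, ...), and the exported TSV carries coordinates, strand, RSS
spacers, CDR3 anchor positions and completeness, round-tripping
losslessly through `importGermline()`.

## 3. Two-stage read annotation

Reads are first orientation-canonicalised by a k-mer vote against the V
references (12-mers, forward versus reverse complement), so annotation is
invariant to reverse-complemented input.

**Primary stage.** Every read is scored against every germline V and J
with the same affine Smith–Waterman weights, in a batch C++ kernel; the
top `topK` (default 3) candidates per side survive, provided the best
reaches `minScore` (default 40, i.e. twenty matched bases).

**Secondary stage.** Because germline paralogues are highly similar,
local score alone is not trusted for the final call. Each close candidate
(within `scoreMargin` of the best) is re-aligned with an end-free global
alignment: leading and trailing gaps are free in *both* sequences,
because the read continues past the segment into the junction and the
germline end may have been trimmed by recombination; the endpoint is the
maximum over all cells, so the alignment is one contiguous stretch with
no interior resets. The junction-side boundary is then extended
base-by-base while the read matches the germline, attributing to the
germline the maximal span it can explain. The final call maximises
identity, then alignment length, then database order — all deterministic.

The junction between the refined V end and J start is searched for D
segments by near-exact matching: the longest contiguous germline-D
substring of at least `dMinLength` (6) bp with at most `dMaxMismatch` (1)
mismatches, ties broken toward fewer mismatches, database order, then
leftmost position. Two consequences of the extension convention are worth
stating plainly. First, when a few junction bases happen to match the
germline, the V and J boundary attributions can meet or even cross; this
is an attribution tie, not an error — the calls themselves are anchored
deep inside the segments — so the junction truncates and only *crossed
CDR3 anchors* fail QC as overlapping calls. Second, the same mechanism
can reattribute one or two genuine D bases to V or J, eroding a short D
below the 6-bp rule; D calls are therefore the one annotation field that
is near-perfect rather than exact on noise-free data (the suite asserts
at least 90% agreement with simulator truth there, and exact agreement
for V, J and CDR3).

**CDR3.** Anchor codon positions are data, not code: the germline table
stores, per V, the codon start of the FR3b canonical cysteine and, per J,
the codon start of the FR4 tryptophan motif. The anchors are mapped onto
the read through the refined alignment; the CDR3 is the interval from the
codon after the V anchor to the codon before the J anchor, translated in
the V frame. A read is in frame when the two anchors are a multiple of
three apart, and productive when additionally no stop codon occurs from
the V anchor through the J anchor codon. Reads whose anchors are not
covered fail QC with reason `anchor not covered`; every input read
appears in exactly one output row.

## 4. Repertoire statistics

Clonotypes are keyed by (V call, J call, CDR3 amino-acid sequence), and
by default only productive pass-QC rearrangements enter statistics —
read-level and clonotype-level weighting are both exposed where the
distinction matters (`vjPairMatrix`), and `shannonIndex` reports Pielou
evenness alongside H so read-weighted values are comparable across
samples of different richness.

* Shannon–Wiener: H = −Σᵢ pᵢ ln pᵢ, natural log. 0 for a single
  clonotype, ln k for k uniform clonotypes (both asserted to 1e-9).
* Wu–Kabat positional variability: distinct residues divided by the
  frequency of the most common residue, gaps excluded; an invariant
  column scores exactly 1, an uncovered column is missing.
* Clonotype overlap: shared keys over the smaller repertoire's key count
  (symmetric, 1 for nested repertoires); Jaccard as an option.
* `topNCumulative`, `uniqueRatio` (both the distinct-fraction and the
  occurs-once definitions are reported), and `clonotypeTracking`, whose
  per-time-point columns (tracked clonotypes plus an explicit "other"
  mass) each sum to 1.

## 5. vNAR typing

Typing runs off a region-labelled global alignment (BLOSUM62, gap open
10, extend 0.5) to a shipped *synthetic* reference frame of 90 aa with
regions FR1(20) · CDR1(8) · FR2(10) · HV2(8) · FR3a(10) · FR3b(12) ·
CDR3(12) · FR4(10); the reference FASTA and region table under
`inst/extdata/` are plain files and can be replaced to re-key the
package to another numbering. Inserted residues take the neighbouring
variable-region label at framework/CDR boundaries, otherwise the
preceding label, so a CDR3 insertion lengthens CDR3 without disturbing
framework labels. Sequences below 50% framework identity are excluded as
unalignable rather than mistyped.

The classification rules (editable YAML, `defaultTypeRules()`):
every named type requires the canonical FR1+FR3b cysteine pair and no
stray cysteines (HV2/FR3a, or extra copies in FR1/FR3b). Type I adds FR2
and FR4 cysteines with an even count (≥2) in CDR3 and none in CDR1; type
II has exactly one CDR1 cysteine and at least one in CDR3; type III is
the type II pattern plus a conserved CDR1 tryptophan (checked before II);
type IV is the canonical pair alone. Everything else is "new" — a class,
not an error, since real libraries contain patterns outside the named
taxonomy. The suite verifies by enumeration over cysteine placements that
the rules partition, and that classification is invariant to
substitutions that touch neither cysteine nor tryptophan.

## 6. The simulators and what they (don't) emulate

All generators derive independent RNG streams from one master seed, so a
fixed `SimConfig` reproduces byte-identical FASTA/FASTQ/TSV output.

**Genome.** The default layout plants seven clusters: 1, 2, 5 and 6
complete, 3/4/7 incomplete (missing V, J, and V+D+J respectively), with
the third D of clusters 2, 5 and 6 planted without RSS (pre-joined).
Spacer classes default to 23 bp downstream of V, 12 bp on both sides of
D and 22 bp upstream of J so all three classes occur; the true
kind-to-spacer assignment in shark loci is not settled, and every site is
configurable. RSS are planted with exactly the configured heptamer and
nonamer mismatch counts. One guarantee is engineered in: the 9-bp D
sequences occur nowhere except where planted — generated germline
sequences are redrawn and the assembled background is scrubbed (single
base flips outside planted features) until no 1-mismatch near-match of
any D remains on either strand. Without this, planted-truth recovery at
the 9-bp information limit would be ill-defined. Inter-cluster gaps
default to 60 kb so the assembly gap rule separates clusters.

**Repertoire.** Clones are drawn once: a V–J pair from the configured
pair-probability table (defaults: within-cluster pairs of the four
expressed clusters at 96 / 2 / 1.5 / 0.5%), a uniformly chosen D,
geometric trims (capped), Poisson N-insertions, and a clone-level
somatic hypermutation pattern (default 1%). Junctions are frame-adjusted
by default (`force_in_frame`), emulating mRNA-derived amplicons; stop
codons in the junction still render a clone unproductive. Clone sizes
follow a discrete power law over ranks, default exponent 0.6 over 10,000
clones — a diverse pre-immunisation blood repertoire whose top-100
clonotypes carry roughly 16% of reads. Reads sample clones with
replacement and acquire per-base sequencing error (default 0.1%) and
constant Q30 qualities; optional flanking PCR primers can be added.
Because reads are cluster-sampled through clones, the sampling variance
of a read-weighted share estimate is p(1−p)(Σ w² + 1/n) under the
configured clone weights w — the test suite uses three sigma of exactly
this design variance, computed from the configuration, when checking
parameter recovery. `simulateTimeCourse()` shares one clone set across
time points and multiplies chosen clones' weights per time point to
programme clonal expansion.

Not modelled: PCR amplification bias and chimeras, platform-specific
error/quality profiles (qualities are constant), insertion/deletion
sequencing errors, clone-internal SHM lineages (mutations are shared by
a whole clone), and allelic variation of germline segments. Passing
parameter-recovery tests therefore demonstrates correctness of the
algorithms under a clean generative model, not robustness to every
artefact of real libraries.

**Library.** vNAR amino-acid sequences are built on the reference frame:
frameworks carry the reference residue with 5% substitution, CDR1/HV2
are partially randomised (60% / 50%), CDR3 length is 5 + Poisson(9)
clamped to [3, 32] (lengths stay on the conventional 0–40 profile axis),
and cysteines/tryptophans are then placed to realise each sequence's
drawn type — random residues exclude C and W, so the planted pattern is
the complete pattern and truth labels are exact. The default mixture is
79.0% II, 18.8% new, 1.9% IV, with the 0.3% remainder split 0.2/0.1
between the rare types I and III; the four-cysteine share within types
II/III is set to 0.745/0.791 so the marginal four-cysteine fraction is
74.5%. "New" sequences are drawn from three concrete off-taxonomy
variants (lone FR2 cysteine; doubled CDR1 cysteine; missing FR1
canonical cysteine). The configured unique fraction (default 83.8%) is
realised exactly: round(u·n) distinct sequences plus resampled
duplicates, shuffled.

## 7. Numerical and engineering choices

* Alignment kernels (batch local scoring, end-free refinement with
  traceback, D-segment search) are integer-arithmetic C++ (Rcpp); the
  amino-acid alignments for typing go through
  `Biostrings::pairwiseAlignment`. All tie-breaks are specified
  (identity → length → database order; leftmost, plus strand), so every
  stage is deterministic given its inputs.
* Coordinates are 1-based closed throughout, the GRanges convention;
  exported GFF3 is 1-based as the format requires.
* Translation uses the standard code with ambiguous codons rendered `X`;
  `N` never matches in any alignment kernel.
* Degenerate inputs have defined behaviour: empty genomes warn and
  return empty hit sets, empty read sets return empty samples, empty
  clonotype tables are errors ("empty sample"), and `n` beyond the
  clonotype count saturates `topNCumulative` at 1 with a message.
* Problem sizes in the shipped tests were chosen to exercise every
  statistic at meaningful scale on a single CPU: mining on a ~400 kb
  seven-cluster genome, truth recovery at 10,000 reads, pairing-share
  and library-mixture recovery at 50,000, with smaller property-based
  checks throughout.

## 8. Known limitations

* The two-stage aligner assumes amplicons that run V→junction→J in one
  orientation; paired-end merging, UMIs and barcode demultiplexing are
  out of scope.
* Allele-level germline resolution (distinguishing near-identical
  paralogues from somatic mutation) is limited by the base-by-base
  extension convention; calls are reported with identities so downstream
  filtering is possible.
* The typing reference frame is synthetic and single; typing against a
  species-specific numbering requires swapping the two files under
  `inst/extdata/`.
* Shannon indices are read-weighted by default and therefore depend on
  sequencing depth; evenness is reported to ease comparison, but
  cross-study comparisons should fix a common depth or rarefy.
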