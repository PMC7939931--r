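---
title: "Methods: how sangerkit processes Sanger chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how sangerkit processes Sanger chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sangerkit)
```

This vignette is the package's account of its own methods: the algorithms,
the parameters that matter, the numerical conventions, and the design
decisions taken where more than one reasonable choice existed. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The pipeline

A run proceeds in five stages: (1) group read files into contigs, either by
the filename convention (`<contig>_F.ab1` / `<contig>_R.ab1`, configurable
regular expressions) or by a three-column CSV (`reads,direction,contig`);
(2) load each read — for ABIF input the bases are re-called from the
processed traces and quality-trimmed; (3) assemble each contig: orient,
align, call the consensus, and derive the Hamming matrix, read dendrogram
and (with an amino-acid reference) indel/stop-codon tables; (4) align the
contig consensi and estimate a BIONJ tree; (5) write FASTA outputs, a JSON
state file and the HTML report.

The central assumption is the standard Sanger model: one trace peak per
called base, four dye channels, Phred-scaled per-base error probabilities
`p = 10^(-Q/10)`, and contigs formed from a small number of forward and
reverse reads of a single template. Quality scores inform trimming only;
the consensus is not quality-weighted.

## ABIF input and output

ABIF is a tagged binary container: magic `ABIF`, 2-byte version, and
28-byte big-endian directory entries; payloads of at most 4 bytes live
inline in the entry's offset field. The reader extracts the *processed*
trace channels `DATA` 9–12 — mapped to bases through the instrument's
`FWO_` channel order — rather than the raw channels 1–4, because
chromatogram display and peak-ratio calls conventionally operate on
processed traces. `PBAS`/`PLOC`/`PCON` are taken from tag number 1 with a
fallback to 2; unknown tags are preserved as raw bytes and never
interpreted. The fixture writer emits version 101 files containing exactly
the tags the reader needs; round-trip identity is asserted on every
simulated read, and a hand-assembled byte-literal fixture pins the
big-endian layout independently of the writer.

## Trimming

Two methods, selected by `trim_method`:

* **M1, modified Mott** (default): per-base score `s_i = cutoff - p_i`;
  keep the contiguous segment maximising `sum(s_i)` when that maximum is
  positive, else trim everything, reported as the empty window `(0, 0)`.
  Ties break toward the smallest start, then the largest end.
  `trim_cutoff` is an error probability; its default `1e-4` (Q40) mirrors
  the defaults documented for Phred-style trimming.
* **M2, sliding window**: window means `m_j` over `window = 10` bases;
  the kept segment starts at the first window with `m_j >=
  quality_cutoff` (default 20) and is cut at the first base of the first
  subsequent failing window, with no per-base refinement inside that
  window. This simpler cut point is exactly reproducible by a brute-force
  window scan, which the tests exploit.

Both trimmers are property-tested against exhaustive oracles (every
contiguous segment for M1; a direct window scan for M2) on 1,000 random
quality vectors. One caveat discovered while formalising the tests: the
intuitive claim "the kept region's mean *Phred score* is at least the full
read's" is not a theorem under these definitions — M2's cut can discard a
high-quality tail, and M1 guarantees improvement in mean *error
probability*, which convexity does not transfer to mean Q. The tests
therefore assert the provable forms: Mott never increases mean error
probability, and M2's start window passes while its cut window fails.

Trim coordinates are 0-based half-open internally; reports and HTML show
1-based inclusive positions. A quality of 0 (p = 1) is legal and can never
fall inside a kept Mott segment because `cutoff < 1`.

## Base calling and secondary peaks

At each `PLOC` peak position the primary base is the channel with the
maximal intensity, ties broken in fixed A < C < G < T order; an all-zero
column calls `N`. If the second-highest channel reaches `secondary_ratio`
times the highest, the secondary sequence records the two-base IUPAC code.
The default ratio 0.33 is the conventional one-third heterozygote
threshold and is exposed as a parameter. Secondary-peak summaries can be
restricted to the trim window (`within_trim_only`); both views are exposed
because either convention is defensible — full-read counts flag dirty
reactions, trimmed counts flag credible heterozygosity.

## Assembly and consensus

Reverse reads are reverse-complemented before alignment, so all MSA rows
are in forward orientation and ungap exactly to the trimmed, oriented
reads. Two reads are aligned with global Needleman–Wunsch (match +2,
mismatch −1, linear gap −2; IUPAC codes match when their base sets
intersect); more reads go through progressive alignment: pairwise
p-distances, an average-linkage (UPGMA) guide tree, and profile–profile NW
merges. Traceback prefers diagonal, then a gap in the second sequence,
then the first, making output deterministic; merge orientation is
canonicalised by sorted member sequences, so the column structure is
invariant to input order. Reads whose trimmed length falls below
`min_read_length = 20` are excluded and reported, never silently dropped.

The consensus is per-column over non-gap characters: a base whose fraction
exceeds `majority_threshold = 0.5` wins; otherwise the IUPAC code of all
bases at fraction ≥ `ambiguity_min_fraction = 0.25`. Columns that are more
than half gaps are omitted so that single-read primer overhangs do not
enter the contig. Hamming distances are computed on the contig's multiple
alignment (columns where both rows are non-gap and differ); whether the
original tooling used pairwise or multiple alignments is not documented,
so the MSA convention is fixed here and stated. The read dendrogram uses
UPGMA — deterministic and exact on ultrametric inputs — via
`stats::hclust(method = "average")`.

## Indels, stop codons and frameshift correction

With an amino-acid reference, the strand is chosen by translating all six
frames and scoring each against the reference with protein NW (BLOSUM62,
linear gap −4). A codon-aware dynamic program then aligns the nucleotide
read directly to the amino-acid reference with moves for codon match
(3 nt ↔ 1 aa), whole-codon insertion/deletion (penalty −8) and 1–2-base
frameshift moves (penalty −12); end gaps are free, so the reading-frame
offset emerges from the DP and partial reads incur no spurious end indels.
The penalties are the package's own calibration: frameshifts must cost
more than a codon gap (they are rarer and more consequential) but less
than two codon gaps, so single-base errors are still bridged rather than
split. Gap runs become indel records, frameshifting when the length is not
a multiple of three; stop codons (TAA/TAG/TGA) are reported by codon index
in the chosen frame, excluding a terminal stop aligned at the reference's
end. Correction deletes frameshifting insertions and pads frameshifting
deletions with `N` (placed at the end of the partial codon); in-frame
columns are never touched and the operation is idempotent, which the tests
verify by re-analysis.

## Contig alignment, distances and the tree

Contig consensi are aligned with the same progressive machinery;
translation mode aligns the in-frame translations (requiring an amino-acid
reference to fix the frame) and expands amino-acid columns back to codon
triplets. Distances default to the p-distance, with JC69
(−(3/4)·ln(1 − (4/3)p), undefined at p ≥ 0.75 — an explicit error naming
the offending pair) as an opt-in; the original tooling does not document
its model, so the simplest one is the default.

The tree is BIONJ: standard NJ agglomeration minimising
`(r−2)·d(i,j) − S_i − S_j` with branch lengths
`b_i = d(i,j)/2 + (S_i−S_j)/(2(r−2))`, reduction
`d(u,k) = λ(d(i,k)−b_i) + (1−λ)(d(j,k)−b_j)` with the variance-weighted λ
clipped to [0, 1], and variance updates
`V(u,k) = λV(i,k) + (1−λ)V(j,k) − λ(1−λ)V(i,j)`; λ fixed at 1/2 gives
classical NJ (`mode = "nj"`). Ties in the criterion resolve to the lowest
index pair, making output deterministic. Negative branch-length estimates
are clamped to zero and counted in the `clamped_branches` attribute.
Consistency is tested by exact topology recovery and path-length
reproduction (within 1e-9) on additive matrices from random trees, plus a
cross-check against an independent BIONJ implementation. The tree is a
quality-control view of contig coherence and is deliberately not offered
as a best-practice phylogeny — no bootstrap, no model selection.

Newick output uses six significant digits and single-quotes labels
containing metacharacters (doubling embedded quotes); parsing delegates to
a standard parser after a structural pre-check that reports the character
offset of the first imbalance. The writer is the package's own because the
standard writer rewrites labels containing spaces, which would break the
quote/round-trip contract.

## State, outputs and report

The analysis state is a versioned JSON document (`format:
"sangerkit-state"`, `version: "1.0"`) holding all parameters, per-read
sequences, qualities, trim windows and secondary-peak calls, the read and
contig alignments, tables, distances, the tree as Newick, and file
provenance. JSON was chosen over R-native serialization for
language-neutral reproducibility; traces are not embedded (they are bulky
and exactly recoverable from the recorded ABIF paths, which `load_state`
re-reads when present). Save → load → save reproduces the file byte for
byte, and two pipeline runs on the same inputs produce byte-identical
state and FASTA outputs — the report contains no timestamps for the same
reason. The HTML report is static (index → contig pages → read pages, all
sequences taken from the same objects that the FASTA writers use);
chromatograms are SVG drawn directly by the package, with 5′/3′ trimmed
regions red-hatched and an Okabe–Ito-derived palette available for
color-vision-deficient users.

## The simulator: what it does and does not emulate

`simulation_spec()` defaults describe the study conditions used throughout
the tests: 8 contigs × (1 forward + 1 reverse read), 600-base templates
derived from a common ancestor (10 substitutions per contig, so contigs
are homologous and alignable, as in a barcoding experiment), a Q50 quality
plateau with 20-base ramps down to Q5 at both ends (so every default read
gives both trimmers nontrivial work), Gaussian peaks at 12-sample spacing
with σ = 3 and low Gaussian baseline noise, and a substitution-only error
model (indel injection is an explicit option used by the coding-sequence
tests). Files are laid out in two subdirectories with the
contig-plus-direction naming convention, with a matching grouping CSV and
a JSON manifest of injected truth.

What it does not emulate: dye blobs, mobility shifts, peak-width drift,
polymerase slippage and other physical artifacts of real
electropherograms. Passing tests therefore demonstrate the pipeline's
contracts — grouping, trimming semantics, assembly correctness, detection
of injected features, determinism — not robustness to every pathology of
real traces.

Problem sizes in the default test and acceptance runs were chosen to probe
each property at the smallest scale that exercises it: 1,000 random
quality vectors (length ≤ 200) per trimmer oracle, 100 simulated reads for
ABIF round-trips, 100 contigs of four 300-base reads at 1% error for
consensus accuracy, 100 random 4–12-leaf trees for BIONJ, and the full
16-read fixture for end-to-end runs.

## Known limitations

FASTA input disables trace-dependent features (trimming, base re-calling,
secondary peaks, chromatograms); affected functions raise a distinct
capability error rather than guessing. Consensus calling is not
quality-weighted. The codon-aware DP assumes a single reading frame per
read (no chimeras) and the standard genetic code (the code table is a
single internal constant, straightforward to generalise). Linear gap
penalties can, on repetitive sequence, split an indel into co-optimal
fragments that an affine model would keep together.
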