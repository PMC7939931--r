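# sangerkit

Scriptable processing of Sanger sequencing data in R: from raw ABIF
chromatogram files (or FASTA) through quality trimming, secondary-peak
detection and contig assembly, to aligned contigs, a quality-control
phylogenetic tree, FASTA outputs and a static hierarchical HTML report.

Sanger sequencing remains the workhorse for single-fragment sequencing,
barcoding and validation work, but its processing is often locked inside
point-and-click tools. sangerkit is for anyone who wants that workflow as
reproducible code: load a directory of `.ab1` trace files, and one function
call trims every read, assembles forward/reverse read pairs into consensus
contigs, aligns the contigs and builds the tree — with every parameter
recorded in a versioned JSON state file.

## What it computes

* **Base calling** — at every peak the primary base is the channel with the
  highest intensity; a secondary base is called where the second channel
  reaches a configurable fraction of the primary (default 1/3), yielding
  IUPAC codes for likely heterozygous or mixed positions.
* **Trimming** — two algorithms. The modified Mott algorithm keeps the
  contiguous segment maximising ∑ (cutoff − p_i), where p_i = 10^(−Q_i/10)
  is the per-base error probability (default cutoff 10⁻⁴). The
  sliding-window method cuts where a 10-base window's mean Phred quality
  first falls below 20. Both are checked against brute-force oracles.
* **Assembly** — reverse reads are reverse-complemented, trimmed reads are
  aligned (Needleman–Wunsch; progressive profile alignment for >2 reads)
  and a per-column consensus is called: majority base if its fraction
  exceeds 0.5, otherwise the IUPAC code of all bases at ≥ 0.25, omitting
  columns that are more than half gaps.
* **Contig comparison** — progressive alignment of consensus sequences,
  p or JC69 (−(3/4)·ln(1 − (4/3)p)) distances, and a BIONJ tree
  (variance-weighted neighbor joining; classical NJ available). The tree is
  a quality-control device, not a publication phylogeny.
* **Coding-sequence checks** — given an amino-acid reference, a codon-aware
  alignment reports indels (flagging frameshifts), stop codons by codon
  index, and can correct frameshifts (deleting 1–2-base insertions, padding
  deletions with `N`).
* **Simulation** — a chromatogram simulator (Gaussian peaks, quality ramps,
  injected errors/secondary peaks/indels, valid ABIF output) provides
  ground truth for every test in the package.

## Worked example

```r
library(sangerkit)

# simulate a two-plate experiment: 8 contigs x (1 forward + 1 reverse read)
root <- file.path(tempdir(), "demo")
write_fixture_tree(simulation_spec(seed = 1), root)

set <- sanger_alignment(dir = root)   # group, trim, assemble, align, tree
set
#> <sanger_contig_set> 8 contig(s), 16 read(s); MSA width 570

glance(set)
#> # A tibble: 1 × 4
#>   n_contigs n_reads msa_width mean_distance
#>       <int>   <int>     <int>         <dbl>
#> 1         8      16       570        0.0312

set$contigs$contig01$reads[[1]]
#> <sanger_read> contig01_F (forward, abif)
#>   600 bases; trim [15, 585); mean Q 48.5; 0 secondary peak(s)
```

The 16 simulated reads group into 8 contigs; each 600-base read loses its
low-quality 20-base ramps to Mott trimming (kept window `[15, 585)`), the
two reads of each contig agree perfectly (Hamming distance 0), and the
aligned consensi differ by about 3% (`mean_distance`), reflecting the
simulated divergence between contig templates. `write_outputs(set, "all",
out)` writes the trimmed reads, consensus contigs and aligned contigs as
FASTA; `generate_report(set, report_config(out))` renders the HTML report
(alignment → contig → read pages, chromatograms hatched red where
trimmed); `save_state(set, "state.json")` records everything for exact
re-runs.

The same workflow is available from the shell:

```sh
Rscript inst/cli/sangerkit.R simulate --out demo --seed 1
Rscript inst/cli/sangerkit.R align --dir demo --out results --write all --report
```

## Limitations

FASTA input carries no trace data, so trimming, base re-calling,
secondary-peak detection and chromatogram plotting are unavailable for it.
Per-base manual editing is out of scope — edit reads in an external viewer
and feed the result back as FASTA.
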