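---
title: "Models and methods behind msrrbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind msrrbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement this package models

Multiplexed single-cell RRBS (msRRBS) profiles CpG methylation of many
single cells in one sequencing library. Each cell's genome is digested
with MspI (which cuts C^CGG and is insensitive to CpG methylation, so
it enriches CpG-dense regions regardless of methylation state); a
cell-specific barcode adapter is ligated directly onto the native CG
overhangs; all cells are then pooled into a single bisulfite
conversion. Bisulfite deaminates unmethylated cytosine to uracil (read
as T) while 5-methylcytosine stays C, so after sequencing, a C at a
reference cytosine means "methylated" and a T means "converted, hence
unmethylated".

The downstream consequence of the chemistry is fully captured by the
read layout, and that layout is what this package simulates and
inverts:

```
read 1:  [4-bp marker][6-bp cell barcode][bisulfite-converted insert][read-through][adapter]
read 2:  the same structure over the reverse complement of the molecule
```

Because library inserts (default 30-200 bp) are usually shorter than
the 150-bp reads, the 3' end of each mate runs through the opposite
end's barcode and marker (as their reverse complement) and into the
sequencing adapter. The fill-in chemistry uses methylated dCTP, so the
marker and barcode are read out unconverted.

# The forward simulator

`simulate_reads()` composes five sub-models:

* **Fragment universe.** `digest_mspi()` places a cut after the first C
  of every CCGG, so fragments tile each chromosome exactly; MspI's
  recognition geometry guarantees no CpG dinucleotide spans a cut, so
  fragment-local CpGs are exactly the genome's CpGs.
  `select_inserts()` applies the library's size window (30-200 bp by
  default; the 30-400 and 30-600 windows correspond to the wider
  library sizes).
* **Per-cell methylomes.** `simulate_cell_methylome()` draws one
  methylation probability per CpG from a two-Beta archetype: CGI CpGs
  from Beta(1, 9) (mean 0.1) and background CpGs from Beta(6, 2)
  (mean 0.75). This reproduces the canonical mammalian pattern —
  hypomethylated islands in a methylated background and a
  hypomethylation valley at transcription start sites — which is the
  feature the cohort analytics need. Non-CpG cytosines are always
  unmethylated, matching their near-zero levels in mammalian cells.
* **Molecules.** Each read pair samples a fragment uniformly; per
  molecule, CpG states are Bernoulli draws from the cell's
  probabilities. Both strands of the digested duplex carry adapters,
  and by default each molecule is sequenced from the original-top or
  original-bottom strand with probability 0.5 (`ob_fraction`); the
  proportion is a modeling choice, as the chemistry does not fix it.
* **Conversion and errors.** Unmethylated C converts to T with
  probability 1 − `conversion_failure` (default failure 0.004, i.e. a
  99.6% conversion rate); methylated C converts with probability
  `overconversion` (default 0). Substitution errors are injected
  uniformly at `error_rate` (default 0.001) with flat Phred strings at
  the matching quality; indels and quality-profile realism are out of
  scope.
* **Spike-in control.** A deterministic synthetic 48,502-bp random
  sequence (`lambda_control_genome()`, seeded, regenerated at run
  time) stands in for the unmethylated lambda-DNA spike-in; it is
  simulated fully unmethylated through the same path at
  `spike_frac` = 0.1 of the pool, which at the desk-scale pool sizes
  used here yields tens of thousands of control cytosine observations
  for the conversion-rate estimator. Only its cytosine positions
  matter to any test. PhiX is not modeled: it carries no
  marker/barcode and is removed upstream of this pipeline.

Truth tables record cell, fragment, species, strand and per-molecule
conversion outcomes for every emitted pair, which is what makes exact
round-trip testing possible.

What the generator does *not* emulate: real MspI fragment-length
biology (fragment lengths come from random-sequence CCGG spacing, not
a real genome's CpG-island structure), PCR amplification bias and
chimeras, end-repair artifacts (msRRBS ligates native CG overhangs, so
fragment-end CpGs carry true methylation and no end-filled positions
are masked), quality-score degradation along the read, and indels.
Passing round-trips therefore validate the processing rules, not
performance on real libraries.

# The inverse pipeline

**Demultiplexing** (`demultiplex()`) follows the protocol's exact
rules: bases 1-4 must equal the marker (or are skipped in the
random-marker mode), bases 5-10 are the barcode, no mismatches are
tolerated, and a pair whose mean barcode Phred on either mate falls
below Q20 is removed entirely (counted as quality-filtered, separate
from unassigned). Both mates must agree on the barcode — the
conservative reading where the protocol reads barcodes from both
mates. With whitelist Hamming distance >= 3 (the packaged lexicode
designer guarantees it; at length 6 it holds 109 barcodes, covering
the protocol's 96), a single sequencing error can never reassign a
pair to the wrong cell, only drop it.

**Trimming** (`trim_reads()`) removes the 10 structural bases and
scans each mate's 3' side for the read-through (reverse complement of
the 10-bp prefix, one substitution tolerated for full-length hits;
exact-match 3' overlaps down to 4 bp) or the adapter stub. Like any
overlap-based trimmer, chance matches occasionally shave a few extra
bases; pairs below 20 retained bases are dropped, and clean pairs =
assigned − dropped.

**Alignment** (`build_bs_index()`, `align_pairs()`) works in MspI
fragment space rather than against the whole genome. This is the key
desk-scale design: msRRBS reads begin at MspI cut sites by
construction, so read 1 anchors at one fragment end and read 2 at the
other, and the only freedom is the fragment, the strand, and how much
of the fragment each mate covers. Matching is three-letter: read 1 is
C-to-T collapsed and looked up in a 20-mer seed table over the
C-to-T-converted top strand and the converted bottom strand; full
verification counts only non-bisulfite mismatches (reference C read
as T is free on the converted strand) with a per-mate cap of 2. Ties
are ambiguous and excluded, mirroring unique-only reporting. Because
the mapping space is the fragment catalog, mapping rates here are not
numerically comparable to whole-genome mapping rates from real
libraries, and the package never claims they are.

**Methylation calling** (`pileup_calls()`) reconstructs each
molecule's strand sequence from the two mates. Where the mates
overlap — for msRRBS inserts that is usually the whole molecule — a
base is counted only when the mates agree; discordant positions are
discarded as sequencing error. This consensus is the main numerical
safeguard of the caller: a single T-to-C miscall would otherwise
inflate apparent methylation by about `error_rate`/3 (0.033 percentage
points at the defaults), visibly biasing the non-CpG background above
its 0.4% conversion-failure floor, whereas requiring agreement pushes
the error term to the product of both mates' error rates. CpG
observations from bottom-strand molecules are merged onto the
plus-strand C (destranding, the CGmap-ecosystem convention; a flag
keeps strands separate, and summing the two strands reproduces the
merged counts exactly). Non-CpG observations accumulate per
chromosome into CHG/CHH totals. The conversion rate is estimated on
the spike-in control over all cytosine contexts, since the control is
fully unmethylated. Cell QC applies the inclusive >= 0.2 M detected
CpG sites rule, with the threshold configurable for desk-scale
genomes.

# Cohort analytics and differential methylation

`merge_callsets()` sums counts and serves both pseudo-bulk merging
across cells and "silicon-merging" across library size windows; it is
associative and commutative, so window levels of a merged set equal
the count-weighted combination of member windows. Window levels
(0.2-kb and 50-kb in common use) are coverage-weighted
(Σmeth/Σtotal), not means of site levels — the bulk convention.
Pairwise Pearson correlations apply a per-site coverage floor to both
members (presets 3/5/10/15/20 for bulk comparisons; 1 for single
cells) and need at least 3 shared sites. Metagene profiles scale gene
bodies into bins with fixed-width flanks, orienting minus-strand
genes. Saturation downsamples *clean read pairs* (so unmapped pairs
consume depth, as on a sequencer) and re-calls methylation per
replicate. Embeddings drop windows missing in more than 80% of cells,
mean-impute the remainder (tSNE-like methods need complete input) and
delegate to `prcomp`, `cmdscale` or `Rtsne`.

Differential methylation uses the single-cell criteria verbatim:
per-CpG two-sided Mann-Whitney U tests between cell groups (the
per-CpG reading; the alternative per-window reading is not
implemented), then chains of significant same-direction sites with
gaps under 100 bp become DMRs when they hold >= 3 CpGs and span
>= 50 bp. The MWU p-value is exact for n + m <= 20 — the null
distribution of U is enumerated over all group-label assignments of
the observed values, handling ties by midranks, with tail doubling
for two-sidedness — because base R's `wilcox.test` falls back to a
normal approximation under ties, and single-cell levels are full of
ties. Larger samples use the tie-corrected normal approximation with
continuity correction. Raw p < 0.05 is the default significance rule
as specified (a Benjamini-Hochberg option exists but is off);
opposite-direction significant sites break a chain, since a DMR has
one direction. A consequence worth knowing: at desk-scale CpG
densities (a site every ~16 bp) the chance of three same-direction
null sites clustering within the gap limit is non-negligible, so a
handful of false-positive DMRs per 50-kb genome is expected behavior
of the stated criteria, not a bug.

# Numerical choices and conventions

* Coordinates are 1-based closed inside the package (the R/Bioconductor
  convention); BED output is 0-based half-open and CGmap output
  1-based, so both external conventions are preserved.
* The CGI scanner is Gardiner-Garden-style: a 200-bp window at step 1
  must satisfy GC >= 0.5 and observed/expected CpG >= 0.6 with
  expected = (#C x #G)/length; overlapping qualifying windows merge,
  and a merged region failing re-validation is greedily trimmed one
  base at a time from whichever end improves the binding criterion
  most (ties trim the left end). N bases count as neither C nor G.
* Shores are the 2-kb CGI flanks minus CGI bases; shelves the next
  2 kb minus CGI and shore bases — per-base precedence
  CGI > shore > shelf, implemented with interval arithmetic and
  verified against a per-base painter.
* Promoters are strand-aware TSS − 1500/+500 windows; the "containing
  CGIs" clause of the printed definition is recorded as a boolean
  `contains_cgi` attribute rather than a filter, because the sentence
  admits both readings and the attribute preserves both.
* Element dedup is by (chrom, start, end) ignoring strand — the
  "identical genomic coordinates" rule.
* Degenerate inputs: empty chromosomes are skipped with a warning;
  fragments containing N are retained and flagged; a cell with zero
  unique alignments gets NA species fractions; a site covered in
  fewer than 3 cells per group yields a missing DMC record, not an
  error.

# Desk-scale problem sizes

The package's own test and verification workloads run on synthetic
genomes of 20-100 kb, pools of 4-16 cells at 250-5,500 pairs per
cell, and DMR experiments with 20 planted 200-bp blocks on a 50-kb
genome at 10x coverage — sizes chosen so every property can be
verified exhaustively against oracles while exercising every code
path, including the spike-in at >= 50,000 control cytosine
observations. Real-genome-scale alignment is explicitly out of scope.

# Known limitations

Fragment-space alignment cannot place reads from outside the MspI
universe (contamination simply goes unmapped); the simulator's
uniform fragment sampling ignores PCR and size-selection efficiency
gradients; flat quality strings mean the caller cannot
quality-weight bases (consensus substitutes for it); and hemimethylation
is invisible because molecule CpG states are drawn once per duplex.

```{r example}
library(msrrbs)
fx <- make_fixture("tiny", seed = 1, dir = tempdir())
cfg <- msrrbs_config(out_dir = tempdir(), simulate = TRUE, seed = 1)
manifest <- run_pipeline(cfg)
manifest$conversion_rate
```
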