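---
title: "Methods: time-resolved ribosome profiling analysis with ribotime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved ribosome profiling analysis with ribotime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotime)
library(data.table)
```

## Scope and model of the data

`ribotime` analyses paired ribosome-profiling (ribo-seq) and mRNA-seq
libraries collected along a stress time course — the canonical design is
two biological replicates at 0, 20, 40 and 60 minutes. All coordinates
are transcript-space, 0-based and half-open. A transcript is partitioned
into the 5′ leader `[0, cds_start)`, the annotated coding ORF (acORF)
`[cds_start, cds_end)`, and the 3′ UTR `[cds_end, length)`. `cds_end` is
exclusive and **includes the stop codon**, so acORF densities use a
denominator that contains the stop codon; this is stated here once and
holds everywhere.

The package works from transcriptome-space alignments (SAM or a 4-column
TSV). It deliberately does not do genome-space exon arithmetic: a read
is counted once per gene no matter how many of that gene's isoforms it
hits, which reproduces the intent of exon-union counting without genomic
coordinates. The ~2% difference between exon-union and
longest-transcript counting reported for real catalogues cannot be
measured in this transcript-space setting and is not emulated.

## Footprint processing

Adapter trimming removes the longest read suffix exactly matching a
prefix of the adapter (minimum overlap 5 nt, no mismatches). This is a
deterministic simplification of heuristic trimmers; it is exact on
synthetic data and appropriate for the clean reads the generator emits.
Reads equal to the spike-in oligo or contained in a user-supplied
contaminant FASTA (the stand-in for an rRNA index) are removed, and a
`PreprocessStats` accounting (input = retained + each removal class) is
kept throughout.

The ribosomal A-site of a footprint is placed 17 nt downstream of the 5′
end for lengths 29–33 nt and 18 nt for lengths 34–35 nt; reads outside
29–35 nt are discarded. Reads whose inferred A-site would fall past the
transcript end (possible near the 3′ terminus) are discarded with a
counter — a convention this package chooses explicitly. When a read maps
to several positions of one transcript, the mapping whose A-site falls
in the highest-priority region wins (acORF > 5′ leader > 3′ UTR), ties
going to the 5′-most position. Gene-level locations are then counted:
weight 1, 1/2 or 1/3 for one, two or three gene-level locations; more
than three discards the read. mRNA-seq reads carry no A-site: the 5′ end
is the position, the only length filter is ≥ 20 nt, and counting is over
the whole transcript. These mRNA conventions are package choices where
the upstream protocol is silent.

## Quantification and normalization

Region counts are weighted sums of A-sites per gene and region.
Libraries are rescaled **to the smallest library** of their group
(ribo-seq and mRNA-seq separately, both replicates together): counts in
sample *k* are multiplied by `min(x[i])/x[k]`. The reciprocal form,
which would inflate every library to a scale above the largest one's,
appears in some descriptions of this normalization; the direction makes
no difference to any fold-change-based result, only to the absolute
scale of reported counts, and the scale-to-minimum form is the
dimensionally coherent one. Translation efficiency is
`(ribo acORF + 1)/(mRNA total + 1)` on normalized counts; pseudocount 1
is the package default wherever ratios are formed.

## The binned Z-score DE caller

For a contrast of time *t* against 0 min, each replicate yields
per-gene `log2` fold changes. Genes are ranked by their expression floor
— the minimal relevant count across the two compared samples (ribo
acORF counts for ribo DE, mRNA totals for mRNA DE, the minimum of all
four for TE) — and grouped into consecutive bins of 300; a trailing bin
of fewer than 50 genes merges into its predecessor. Within each bin
`Z = (lfc − mean)/sd`, so every bin is standardized exactly (mean 0,
SD 1). A gene is called increased when `(Z1+Z2)/2 > T` and decreased
when `(Z1+Z2)/2 < −T`, strictly.

The threshold is chosen from the empirical discordant-sign estimate:
false positives at `T` are the genes with `(|Z1|+|Z2|)/2 > T` whose
replicate Z-scores disagree in sign, and the estimated FDR is FP divided
by the number of called genes (defined 0 when nothing is called, capped
at 1 — FP need not be a subset of the calls, so the raw ratio can exceed
1). Scanning the observed `(|Z1|+|Z2|)/2` values downward from the
maximum, the selected `T` is the smallest value on the plateau where the
estimate stays at or below the target (default 10%); if no value
qualifies, the maximum is returned with a warning. Thresholds are
computed per (signal, contrast) pair. One analytical consequence worth
knowing: on data with *no* true changes the discordant and concordant
tails are symmetric, the estimate is near 1 at every threshold, and the
procedure correctly calls (almost) nothing rather than chasing the
target.

The robustness filter asks whether a call survives removal of its
strongest pause sites: per sample, the reads at the 3 highest-density
acORF codons of each transcript (ties 5′-most) are removed, counting,
normalization and the full caller are re-run, and `robust` records
whether the gene is still called in the same direction. Peaks are found
per sample because pauses are condition-specific. A gene covered at
fewer than 3 codons loses everything and is non-robust by construction.

## Metagene profiles and queuing peaks

A transcript enters the metagene when it is the longest isoform of its
gene, has ≥ 100 alignments, is longer than 600 nt, and has both flanks
(5′ leader and 3′ UTR) longer than 45 nt. Offsets are footprint **5′
ends** relative to the first nucleotide of the start or stop codon
(switchable to A-sites via the profile builder if needed). Each
transcript's window is normalized by its own average density (window
alignments per nt — "average gene density" is defined over the window)
before position-wise averaging; per-codon values are the sum of the
three nucleotide offsets of each codon. The start-anchored window spans
−45 … +150 nt and the stop-anchored window −150 … +45 nt by default; the
downstream extent is configurable since no canonical value exists.

Ribosomes queued behind slow termination sit at multiples of the
exclusion footprint (~33 nt) upstream of the stall, which appears in the
stop-anchored metagene as peaks spaced 33 nt = 11 codons. Peak detection
takes the `n` highest strict local maxima over a ±2-codon window among
codon offsets upstream of the stop and reports the median spacing; the
±2 window is this package's choice (the peaks were originally read off
visually).

## Profile similarity

Pairwise similarity of two samples on one transcript is the Pearson
correlation of unique-read (unambiguously aligned), codon-resolution
acORF profiles of the gene's longest transcript, computed only when both
samples exceed one footprint per nucleotide of average acORF density.
Depth matching subsamples the deeper read set without replacement to the
shallower set's size (default 10 repeats, seeded, restoring the caller's
RNG state) and averages the correlations.

## Readthrough, uORF and periodicity screens

**Leaky termination.** Transcripts with a pooled weighted 3′ UTR read
count strictly greater than 20 (ambiguous alignments included) are
candidates. The downstream ORF runs from `cds_end` to the next in-frame
stop (excluded); absence of such a stop flags the record and ends the
dORF at the transcript end. Readthrough efficiency per sample is dORF
density over acORF density (alignments per nt of ORF). Stop identity and
the +4 nucleotide are reported for sequence-context tables.

**5′-leader effect.** Genes whose maximal per-sample leader count
reaches 10 weighted reads are treated as leader-translated — a
package-chosen operational predicate — and their acORF fold-change
distribution is compared with all others by the two-sample Wilcoxon
rank-sum test.

**Center-of-density shift.** For each coding transcript with more than
64 alignments, nucleotide A-site profiles of all time points are
compressed to the coordinates covered in *every* time point. The center
is the minimal compressed index whose strictly-upstream cumulative count
exceeds the count at-or-after it (falling back to the last index). The
at-or-after reading of "downstream" is adopted deliberately: the
alternative (excluding the coordinate itself) shifts the center by at
most one index and neither reading changes any ranking produced here.
The shift `(center_t − center_0)/n_covered` is averaged across
replicates and transcripts are ranked most-negative-first (density
moving 5′-ward); the screen returns the top 200 by default. The screen
needs real coverage: coordinates covered at all four time points are
rare below roughly one read per nucleotide, which is why the bundled
analyses run it at the depth of production libraries rather than at toy
depth.

**Triplet periodicity.** Only 31-nt unique reads are used (the length
with the strongest phasing). 5′ ends over the first 50 acORF codons are
classified by `(pos − cds_start) mod 3`; transcripts covering fewer than
50 distinct coordinates are excluded. "First 50 coordinates" is read as
the first 50 codons and the exclusion's "coordinates" as distinct
covered nucleotides — both switchable (`coordinate_unit`), since the
phrase is ambiguous. The typical third-subcodon fraction is ~20%; the
distortion flag fires above 0.35, a conservative package-chosen margin
over that baseline, replacing what was originally a manual call.

## The synthetic generator

`sim_config()` encodes the study conditions: 2 replicates × 4 time
points × {ribo, mRNA}, log-normal gene expression, negative-binomial
counts (size 20) so replicate Z-scores behave realistically, footprint
lengths 29–35 nt peaked at 31, and 5′-end subcodon frames (0.60, 0.20,
0.20) giving the ~20% third-subcodon baseline. Planted classes occupy
disjoint gene subsets: mRNA-level changes (ribo follows, TE flat),
ribo-occupancy and TE changes (4-fold at the last time point, ramping
linearly), uORF induction (leader ×10, acORF ×0.5 at 60 min, reads
confined to a planted upstream ORF), leaky UGA-C stops emitting the
configured fraction of in-frame dORF footprints, and single-codon pauses
(×50 dwell under stress). Termination is modelled as a stop-codon dwell
multiplier plus geometric stacking of queued footprints at hard 33-nt
exclusion, present under control conditions and decaying to zero across
the time course — matching the observation that stacking disappears
under stress. Multimapping is simulated at the assignment level: decoy
mappings land in the **coding region** of other transcripts (paralogous
CDS-to-CDS hits), and a fraction of genes carries a 5′-truncated second
isoform whose shared region duplicates mappings within the gene.
Everything is reproducible byte-for-byte from `(config, seed)`.

What the generator does *not* emulate: sequence errors and base
qualities, genuine sequence-homology multimapping, rRNA contamination
beyond an optional contaminant list, UTR secondary structure, or
isoform-specific expression. Passing tests on this generator therefore
demonstrate the correctness of the statistical machinery under the
stated generative assumptions, not performance on any particular real
library.

## Problem sizes and numerical choices

The bundled tests and the acceptance script use sizes chosen so each
analysis operates in its informative regime: the FDR calibration uses
10,000 genes × 2 replicates at count level; queuing uses 500 transcripts
with a strong stall (stop dwell ×20, mean queue 2) — the regime in which
the peaks were originally visible; periodicity pools >50,000 31-nt
reads; the uORF screen uses ~3,000 reads per transcript per sample
(production-library depth, see above) over 40 genes; pause similarity
uses ~4,000 reads per transcript over 30 genes. Ties are broken
deterministically everywhere (5′-most position, lexicographic
identifiers); subsampling and simulation are seeded; zero-variance and
zero-density cases are excluded with explicit reasons rather than
propagating NaN; empty-library normalization and sub-2-gene bins are
hard errors.

## Known limitations

- The caller assumes exactly the two-replicate design for its
  discordant-sign estimate; more replicates generalize the mean but the
  FP estimator still uses the first two.
- Transcript-space counting cannot see reads that would align only to
  unannotated exon unions.
- The readthrough screen requires transcript sequences; without them it
  refuses rather than guessing dORF boundaries.
- Real multimapping follows sequence homology; the assignment-level
  simulation exercises the weighting arithmetic, not an aligner.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 200, seed = 1)
sim <- simulate_experiment(cfg)
res <- run_pipeline(sim)
res$de$ribo_60[label != "unchanged"]
queue_peak_spacing(res$metagene_stop)
res$periodicity$pooled
```
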