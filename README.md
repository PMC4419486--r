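# ribotime

Time-resolved ribosome profiling (ribo-seq) paired with mRNA-seq can
show, at codon resolution, how a cell reprograms translation within
minutes of a stress such as oxygen and glucose deprivation. `ribotime`
is an R package for exactly this kind of experiment — typically two
biological replicates sampled along a short time course — covering the
full path from raw footprints to biological calls:

- **Footprint processing** — adapter/spike-in/contaminant filtering with
  full read accounting; A-site assignment at 17 nt downstream of the 5′
  end for 29–33-nt reads and 18 nt for 34–35-nt reads (reads outside
  29–35 nt discarded); within-transcript resolution by region priority
  (acORF > 5′ leader > 3′ UTR); gene-level multimapper weighting
  (1, 1/2, 1/3; more than three locations discarded).
- **Quantification** — weighted per-gene counts for the 5′ leader,
  annotated coding ORF (acORF) and 3′ UTR; rescaling of every library to
  the smallest one of its group; translation efficiency
  TE = (ribo acORF + 1)/(mRNA total + 1).
- **Differential expression** — the binned local Z-score caller: genes
  ranked by minimal expression, bins of 300, per-bin standardization,
  calls at |(Z₁+Z₂)/2| > T, with T chosen so the empirical
  discordant-sign false-discovery estimate
  FP = #{(|Z₁|+|Z₂|)/2 > T, Z₁Z₂ < 0} stays at or below the 10% target,
  plus a robustness filter that re-runs the caller after deleting each
  transcript's three highest-density codons per sample.
- **Profile analytics** — metagene profiles of footprint 5′ ends at
  initiation and termination with detection of ribosome **queuing
  peaks** (stacked ribosomes at ~33-nt exclusion spacing appear 11
  codons apart upstream of the stop); depth-matched pairwise Pearson
  similarity of codon-resolution profiles.
- **mRNA-specific screens** — stop-codon readthrough (3′ UTR reads > 20,
  efficiency = downstream-ORF density / acORF density), the effect of 5′
  leader translation on acORF fold changes (Wilcoxon rank-sum),
  center-of-density shifts on compressed profiles for uORF-induction
  candidates (transcripts with > 64 reads), and triplet-periodicity
  distortion of 31-nt footprints over the first 50 acORF codons.
- **A seeded synthetic generator** — annotation, sequences and
  alignments for the full design with planted fold changes, uORF
  induction, leaky UGA-C stops, site-specific pauses, termination
  queuing, phased 5′ ends and multimapping, plus a machine-readable
  truth table. Every analysis in the package is exercised against this
  ground truth.

## Worked example

```r
library(ribotime)

cfg <- sim_config(n_genes = 100, seed = 7)   # 2 reps x 0/20/40/60 min
sim <- simulate_experiment(cfg)
res <- run_pipeline(sim)

de <- res$de$ribo_60                          # ribo occupancy, 60 vs 0 min
attr(de, "threshold"); attr(de, "fdr")
de[label != "unchanged"][order(-abs(mean_z))][1:5]
```

```
T = 0.933, estimated FDR = 0.053
   gene_id log2_fc_rep1 log2_fc_rep2    mean_z     label
1:  g00040     1.196322     2.907129  2.769871 increased
2:  g00059    -2.433796    -2.370501 -2.709677 decreased
3:  g00015     1.171791     2.590668  2.572188 increased
4:  g00083     2.251967     1.224777  2.522712 increased
5:  g00008    -1.657070    -2.872700 -2.470640 decreased
```

The threshold T is the smallest value keeping the discordant-sign FDR
estimate at or below 10% (here 5.3% at T = 0.933); the five strongest
calls are all planted genes (`sim$truth` labels them `ribo_de_*`,
`te_de_*` and `mrna_de_up`). Termination queuing and the footprint frame
distribution come straight off the same result bundle:

```r
queue_peak_spacing(res$metagene_stop)
#> 11 codons, peaks at codon offsets -28, -17, -6
res$periodicity$pooled
#>    f1    f2    f3
#> 0.601 0.195 0.204
```

Stacked ribosomes behind slow termination sit 33 nt apart, i.e. 11
codons between metagene peaks; ~20% of 31-nt footprint 5′ ends fall on
the third subcodon position, the baseline against which periodicity
distortion is flagged.

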