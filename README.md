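# t6aribo

Codon-resolved ribosome occupancy, footprint simulation, and related
translation metrics for studying loss of the t6A tRNA modification.

## The problem

t6A (N6-threonylcarbamoyladenosine) is deposited at position 37 of
cytoplasmic tRNAs whose anticodons end in U (tRNA-NNU) and is required for
efficient decoding of the 16 codons with adenosine in the first position
(ANN codons). When the modification is lost — e.g. by knocking down OSGEP,
the catalytic subunit of the KEOPS complex — ribosomes dwell longer with
ANN codons in the A site, translation stalls, misfolded protein
accumulates, and downstream innate-immune signalling is triggered.
Detecting that codon-specific dwell signal in ribosome-profiling data, and
quantifying the associated stalling, tRNA binding and spatial immune
phenotypes, requires a chain of small but exacting computations. This
package implements that chain as tested, reusable R functions, aimed at
computational biologists analysing ribo-seq (and companion RIP-seq /
spatial transcriptomics) experiments in transcriptome coordinates.

## What it computes

**Ribosome profiling core.** Ribosome-protected fragments (RPFs) of
27–33 nt are length-filtered; the P-site offset Δ (displacement from a
read's 5′ end to the first nucleotide of the P-site codon) is calibrated
as the mode of the start-codon meta-profile of d = cds_start − 5′ end;
reads in frames {0, −1} are retained and resolved to E/P/A-site codon
indices plus the three flanking codons downstream of the A site. The
headline statistic is the occupancy ratio

    O(c, s) = f_s(c) / mean( f_F1(c), f_F2(c), f_F3(c) )

i.e. the frequency of codon c at ribosomal site s ∈ {E, P, A} divided by
its mean frequency over the three downstream flanking codons, which act
as a within-library codon-usage control. Under neutral elongation
O(c, s) ≈ 1; a codon whose decoding is slowed by a factor w shows
O(c, A) elevated in proportion to w. Occupancies are aggregated per
codon, per class (ANN/CNN/GNN/UNN by first base), per gene, and compared
between conditions as log2 fold changes, with Kruskal–Wallis rank tests
for gene-subpool contrasts.

**Stalling.** Per gene, mean mapped reads per codon location m = R/L,
compared between conditions as log2((m_kd + α)/(m_ctr + α)) with the
control as reference, and gene sets compared by a two-sided Mann–Whitney
U test (exact for small samples).

**Simulator.** A seeded RPF generator with per-codon A-site dwell
weights, configurable P-site displacement, frame noise, per-gene coverage
and an initiation-peak component. It emits SAM/FASTA/TSV plus a ground
truth sufficient to predict every statistic above analytically, which is
how the pipeline is tested end to end.

**Auxiliary metrics.** tRNA isodecoder percentages and anticodon-group
(NNU/NNA/NNG/NNC) differential binding from RIP-seq counts with seeded
depth subsampling; spatial-transcriptomics spot QC (≥ 100 transcripts),
top-quartile T-cell enrichment, per-spot minimum Euclidean distance to
enriched spots and the signature–proximity Spearman correlation; the
aggregation propensity factor APF = 100·(MFI_ko − MFI_control)/MFI_ko;
and differential-expression signature selection (log2FC > 0.5,
p < 0.05).

## Worked example

Simulate a knockdown-like library in which every ANN codon carries a
2-fold A-site dwell weight, then run the pipeline:

```r
library(t6aribo)

cfg <- sim_config(n_transcripts = 100, n_reads = 200000, seed = 1)
tx  <- generate_transcriptome(cfg)
kd  <- simulate_footprints(tx, class_dwell_model("ANN", 2), cfg)

reads  <- filter_by_length(kd$reads)                         # 27-33 nt
offset <- infer_psite_offset(build_start_metaprofile(reads, tx))
offset
#> [1] 15

asn <- assign_sites(reads, tx, offset)                       # frames {0, -1}
occ <- occupancy(site_frequencies(asn, tx))
subset(class_summary(occ, "codon")$summary, site == "A")
#>    class site  n    q1 median    q3
#> 9    ANN    A 16 1.569  1.586 1.602
#> 10   CNN    A 16 0.777  0.791 0.804
#> 11   GNN    A 16 0.786  0.795 0.804
#> 12   UNN    A 13 0.782  0.794 0.801
```

The calibration recovers the simulator's true 15 nt P-site offset. At the
A site the median ANN occupancy (1.586) is twice the median of the other
classes (≈ 0.793), recovering the simulated 2-fold dwell; the absolute
values sit around 2/S and 1/S with S = (2·16 + 45)/61, because
frequencies are normalised within the site. The UNN row has n = 13: the
three stop codons are excluded from occupancy throughout.

A shell entry point wrapping the same functions is installed at
`inst/scripts/t6a.R` (subcommands `simulate`, `psite`, `occupancy`,
`subpool`, `stalling`, `rip-trna`, `spatial`, `apf`, `signature`), and
serialises each run's resolved configuration to `run_config.json`.

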