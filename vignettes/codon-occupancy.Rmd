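---
title: "Codon-resolved ribosome occupancy: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-resolved ribosome occupancy: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the statistical model behind each stage, the parameters that matter and
their defaults, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## Coordinate model

Everything runs in transcript space. A transcript is a nucleotide string
with 0-based, half-open CDS bounds; codon index 0 is the start codon, and
codon k occupies nucleotides `cds_start + 3k .. cds_start + 3k + 2`.
U is normalised to T on ingestion so there is a single internal alphabet;
anticodons are displayed with U. Transcripts violating the CDS invariants
(bounds, multiple-of-3 length, a configurable minimum of 10 codons) are
dropped with a warning rather than aborting the run — real annotations
are dirty, and the dropped count is recorded for audit. Genome
coordinates, splicing and strand are deliberately out of scope: reads are
assumed already aligned to a coding transcriptome, and isoform-to-gene
collapsing is left to `gene_id` (per-gene statistics sum isoforms).

## P-site calling

An elongating ribosome protects a 27–33 nt fragment whose 5′ end sits a
fixed displacement Δ upstream of the P-site codon. The pipeline
calibrates Δ from data: the meta-profile histograms
d = cds_start − five_prime over reads near start codons (window
d ∈ [5, 45] nt by default, chosen to exclude degenerate displacements),
and Δ is the modal d — ribosomes captured at initiation hold the start
codon in the P site, so their 5′ ends pile up exactly Δ nt upstream of
it. Ties break toward the smaller d, with a warning. The offset is
global per sample; per-read-length calibration is a non-goal since a
single fixed displacement is the operative convention here (default
fallback 15 nt).

With Δ applied, `raw = (five_prime + Δ − cds_start) mod 3` labels the
reading frame: residue 0 is frame 0, residue 1 is frame +1, and residue
2 is called frame −1 (5′ end one nucleotide downstream of in-frame).
Frames {0, −1} are retained by default; frame −1 reads are snapped
*forward* to the nearest codon start. Which physical shift "frame −1"
denotes is genuinely ambiguous, so both the label mapping and the
retained set are arguments, not assertions. E/P/A are consecutive codons
(e = p − 1, a = p + 1) and the three flanking codons a+1..a+3 are
resolved from transcript coordinates rather than from the trimmed read
sequence — equivalent for frequency counting, and it avoids flank
truncation on 27–29 nt reads. Reads whose sites leave the CDS or touch
the stop codon are rejected, with per-reason counts.

## The occupancy statistic

For each site s ∈ {E, P, A, F1, F2, F3} the pipeline counts codon
identities over accepted reads and normalises to frequencies over the 61
sense codons (stop codons are excluded from numerator and denominator
everywhere; flanks near stops are already excluded upstream). The
occupancy ratio is

O(c, s) = f_s(c) / mean(f_F1(c), f_F2(c), f_F3(c)).

The flanking codons sit outside the tRNA-binding sites, so their codon
composition reflects library-wide codon usage; dividing by the flank mean
cancels usage and leaves a per-codon dwell signal. Codons with zero
flank mean are reported missing (NA), never infinite; no smoothing is
applied by default, but a `pseudocount` argument exists for sparse
per-gene tables. Because frequencies are normalised within each site, a
class-wide 2-fold A-site dwell appears as an ANN/non-ANN median ratio of
2 (at roughly 2/S vs 1/S with S = Σ_c u_c w_c), not as ANN occupancy
exactly 2.

Per-gene occupancy repeats the computation on each gene's reads alone,
with a default minimum of 32 accepted reads per gene (variance control;
the threshold is configurable because no principled universal value
exists). Aggregation to classes supports two units — per-gene class
means and per-codon values — as a flag, since box plots of such data are
legitimately drawn either way. One numerical caveat is documented rather
than "fixed": O is a ratio of estimated frequencies, so at low per-gene
coverage it carries a small positive bias of order 1/(flank counts);
tests of the per-gene null therefore use well-covered genes
(≥ ~1500 reads/gene), where the bias is ≈ 1%.

Subpool contrasts (`subpool_compare`) take a named gene set and a
size-matched random control drawn *without replacement* from the
remaining genes under a caller-supplied seed (the sampling scheme for
such controls is otherwise unspecified), then apply Kruskal–Wallis rank
tests per class and site, plus across classes within each pool. The
two-group Kruskal–Wallis is equivalent to a Wilcoxon test; the
chi-square approximation it uses is standard.

## Stalling

A gene's stalling value is m = R/L: mapped reads per location, where a
location is an A-site codon position in the CDS. This is a declared
replacement for genome-space data-driven binning: since values are pooled
into a per-gene average anyway, per-codon locations preserve the
semantics while staying in transcript space. Replicates are averaged at
the m level with equal weights before the fold change
log2((m_kd + α)/(m_ctr + α)), control as reference. The pseudocount α
defaults to 1 and is added directly to m so that zero-coverage genes are
defined (e.g. m_ctr = 0, m_kd = 3 gives log2 4 = 2); note that α = 1 is
deliberately conservative and attenuates fold changes when m is small —
recovery analyses on well-covered simulations pass a small α (0.01)
instead, which is safe there because every gene has m > 0.

Gene sets are compared by a two-sided Mann–Whitney U test: exact when
the smaller set has ≤ 8 members and there are no ties, otherwise a
tie-corrected normal approximation; the method used is recorded in the
output. The test suite checks the exact path against a full enumeration
over all C(n_a + n_b, n_a) labelings.

## The simulator and what passing tests mean

`simulate_footprints` is the ground-truth engine for all of the above.
Each footprint picks a transcript with probability proportional to
coverage × length, then an A-site codon position uniformly over eligible
positions re-weighted by the dwell weight w of the codon found there.
Eligible positions keep the E site and all three flanks inside the CDS
and additionally exclude the first 2 and last 5 codons, avoiding
initiation/termination artifacts. The 5′ end is placed Δ nt upstream of
the P-site codon, optionally jittered ±1 nt with probability
`frame_noise_rate` (half each direction — hence frame +1 rejections
converge to r/2). Dwell acts only at the A site, as a single-codon
multiplicative weight: that is where codon–anticodon decoding happens and
where the modification-loss effect is localised, and it yields the
closed-form predictions the recovery tests assert —
empirical A-site codon frequency u_c·w_c/Σ u·w, hence
O(c, A)/O(c′, A) → w_c/w_c′, with E/P occupancies staying at 1. A
per-gene dwell override lets a subpool of genes carry the effect inside
one dataset for the gene-set contrasts.

A fraction `init_fraction` (default 0.10) of footprints are drawn from
initiation-stage ribosomes with the start codon in the P site. This is
the package's own addition: elongation-only sampling would leave the
meta-profile without a unique mode at Δ (the eligibility rule keeps
elongating P sites ≥ codon 1), whereas real libraries carry a strong
initiation peak, which is precisely what offset calibration relies on.
These reads are later rejected by site assignment (E site outside the
CDS), so they calibrate the offset without touching occupancy.

Generators for the auxiliary inputs follow the same contract —
deterministic given the seed, conservation of requested totals, and
closed-form expectations recorded as ground truth: multinomial
isodecoder counts with a group-level effect multiplier, and jittered
spot grids where the T-cell score decays exponentially with distance to
the nearest focus and the signature score couples linearly to the same
field.

What the simulator does *not* emulate: sequencing error, UTR
translation, multi-mapping, ligation/fragment bias, UMIs, per-read-length
offset heterogeneity, and any real noise structure of the biological
data (no noise model is published for it; the generator's noise levels
are conventions). Passing recovery tests therefore demonstrates that the
pipeline's arithmetic inverts its own generative model at realistic
depths — not that it is robust to every artefact of real libraries.

## Study-condition defaults and problem sizes

Defaults mirror the pipeline constants: read lengths 27–33 nt, Δ = 15 nt,
frames {0, −1}, RIP-seq subsampling to 1,000,000 reads, spot QC at ≥ 100
transcripts, top-quartile enrichment, signature thresholds
log2FC > 0.5 and p < 0.05 (strict, as printed; inclusive variants by
flag, and the p column is raw by default with a selector for adjusted).
The reference simulation scenario (`annA2` in the CLI) uses 200 genes,
uniform sense-codon usage, CDS lengths 100–200 codons, 30 nt UTRs, and a
2-fold ANN A-site dwell in the perturbed condition. Test problem sizes
were chosen so each statistical assertion has comfortable power at
desk scale: 10^5 reads for offset recovery, 2×10^5 for the occupancy
null (mean |O − 1| < 0.05), 5×10^5 for codon-level dwell recovery within
10%, 50-vs-50 gene subpools at ~750 reads/gene for the rank-test
contrast, and 100-seed / 200-seed null calibrations for the subpool and
gene-set tests.

For two-condition stalling simulations the recorded truth is the
expected per-gene read count (coverage × length, normalised within the
condition, times the condition's read total). Because coverage vectors
are renormalised, realising an exact per-gene density ratio k requires
scaling the perturbed condition's read total by the ratio of
normalisation constants; the recovery tests do exactly that and assert
median log2FC within log2(k) ± 0.1.

## Spatial and RIP-seq choices

The spot QC boundary is inclusive: "fewer than 100" removed means
exactly 100 is retained. Quartiles use the linear-interpolation
percentile (R type 7), inclusive at the cut, so at least ⌈n/4⌉ spots are
always enriched; constant scores enrich everything with a warning.
Distances are raw-coordinate Euclidean with no spot-diameter or
hexagonal-grid adjustment — units are unspecified in such data and the
downstream Spearman correlation is scale-invariant. The sign convention
is recorded in the output: proximity association means *negative*
correlation with distance. `module_score` is a declared simplification
of control-bin module scoring (CP10K → log1p → mean over the set →
z-score across spots, with the z-score standing in for background
subtraction); it is not claimed to reproduce any reference tool
numerically, and the library-size totals can be supplied explicitly so
the score does not depend on which genes the matrix happens to contain.

Isodecoder differential binding reports both log2 of group percentage
ratios (pseudocount 0.01 percentage points) and raw percentage-point
differences, because the y-axis transform of such plots is typically not
fully specified; the percentage arithmetic is labelled as such. Note that
percentages renormalise: doubling one group's mass necessarily pushes the
untargeted groups' shares down, so coherent opposite-sign shifts in the
other groups are expected, not an artefact.

## Known limitations

* Occupancy inference assumes a single global P-site offset; libraries
  with strong length-dependent offsets need external pre-shifting.
* The frequency-ratio estimator is biased upward at very low coverage;
  use the per-gene read threshold (and, if needed, the pseudocount)
  rather than interpreting sparse per-gene tables directly.
* No multiple-testing correction is applied across codons or genes; the
  implemented contrasts are single-comparison designs and are flagged as
  such.
* Soft-clips beyond leading/trailing removal, periodicity scoring beyond
  the modal rule, and dwell inference by model fitting are out of scope.
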