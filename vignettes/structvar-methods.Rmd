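---
title: "Differential RNA structurome analysis with structvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential RNA structurome analysis with structvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structvar)
```

# The problem

Chemical structure probing of the icSHAPE family reads out RNA secondary
structure one nucleotide at a time: flexible (unpaired) bases acquire
adducts that terminate reverse transcription, so the per-base RT-stop rate
in a treated library, relative to a DMSO control, measures accessibility.
Comparing reactivity profiles between conditions — for example successive
stages of early embryogenesis, spanning the maternal-to-zygotic transition
(MZT) — identifies *structurally variable regions*: spans whose structure
changes. Where such regions fall on RNA-binding-protein (RBP) motifs in
3'UTRs, a structural switch can gate protein binding and hence transcript
fate; the package's last stage quantifies that linkage between binding-site
structural switching and maternal mRNA decay.

`structvar` implements this workflow end to end on tabular inputs
(read mapping is upstream and out of scope), together with a seeded
synthetic-data generator that plants ground truth, so every statistical
stage of the pipeline is testable without any sequencing data.

All coordinates, everywhere, are 0-based half-open in transcript space.

# Reactivity model

For one transcript, condition and stage, replicate RT-stop and coverage
("base density") counts are summed (`combine_replicates()`), and the
combined stop counts are normalized in sliding windows
(`normalize_rtstops()`): windows of 200 nt step by 30 nt, and within each
window the counts are divided by the mean of the 90th–95th nearest-rank
percentile band, scaled by 100, so most values land in [0, 100]. A base
covered by several windows gets the mean of its window contributions. Two
layout details matter:

* Every window has full size: the last window is anchored at the 3' end
  (`[L - 200, L)`) rather than letting a nest of short suffix windows
  accumulate. Short windows have tiny percentile bands (2–3 order
  statistics) that a single locally elevated feature can dominate, which
  throws "shadow" differences onto neighbouring bases when profiles are
  compared across stages. Transcripts shorter than one window are
  normalized as a single short window rather than dropped.
* A window whose normalizer is 0 contributes the invalid marker, not 0:
  absence of signal is not evidence of structure.

Reactivity (`compute_reactivity()`) is

$$ r_i = \frac{\max(0,\; T_i - \alpha\, C_i)}{\max(d_i, 1)} $$

with window-normalized treated and control signals $T_i$, $C_i$,
background factor $\alpha = 0.25$, and treated base density $d_i$. Raw
values are rescaled per transcript by the mean of their 90th–95th
nearest-rank percentile band and clipped to $[0, 1]$. Bases with zero
density, and transcripts whose scaling normalizer is 0, become invalid
(`NA`). Transcripts with mean raw RT stop `< 2` or mean density `< 200` in
the treated library are discarded before normalization
(`filter_transcripts()`; thresholds inclusive, treated library only — the
report flags the convention). All of these constants live in
`reactivity_params()` and can be overridden.

Percentile convention: nearest rank, i.e. the band from the
`ceiling(p_lo/100 * n)`-th to the `ceiling(p_hi/100 * n)`-th order
statistic inclusive. Nothing interpolates.

# Differential structure

`replicate_noise_quantiles()` calibrates the difference cutoffs: between
replicate reactivity profiles it reports the fraction of bases with
absolute difference below 0.2 and of 10-nt sliding windows with mean
difference below 0.05. On deeply covered synthetic libraries both
fractions are ≥ 0.99, comfortably inside the calibration bounds that
motivate the cutoffs.

`call_variable_nucleotides()` reports bases valid in both stages with
|Δreactivity| > 0.2. `window_scan()` tiles each transcript into disjoint
10-nt windows from position 0 (trailing partial windows dropped), keeps
windows with ≥ 80% jointly valid bases, and runs a two-sided paired
t-test on the per-base differences. Windows with mean difference > 0.05
and p < 0.05 are *less structural* at the later stage; < −0.05 with
p < 0.05, *more structural*. No multiple-testing correction is applied at
this stage by design — the compound effect-size-plus-p cut is the
published procedure and is conservative on nulls (its false-call rate is
below the nominal p cutoff). Degenerate windows: identical nonzero
differences give p = 0 (the t statistic diverges); identical zero
differences give p = 1.

`build_regions()` drops stable windows, extends the rest by 10 nt,
merges overlapping or book-ended intervals *within* each class (merging
across opposite directions would destroy the annotation downstream steps
need), and partitions each merged interval left-to-right into 30-nt bins,
keeping the final partial bin. `hot_regions()` clusters regions from
different stage comparisons that overlap by ≥ 1 nt (transitively) on the
same transcript and class, reporting the merged footprint with `n_way`,
the number of distinct comparisons sharing it.

`assign_segment()` assigns a region to 5'UTR, CDS or 3'UTR when one
segment covers ≥ 51% of it (exact ties are unassigned), and
`segment_enrichment()` compares observed counts against expectations from
the 150:1250:460 average segment-length ratio, with a per-segment Fisher
test on observed versus rounded-expected counts. Because the reference
row of that table has no sampling variance and exact conditional tests
are discrete, these p-values are conservative (null type-I error well
below nominal) and their null distribution is *not* uniform; treat them
as a screening statistic, with the enrichment ratio as the primary
readout.

# Motif scanning and enrichment

`motif_model()` stores a position probability matrix over ACGU (T is
accepted and converted; scanning is sense-strand only, as mRNA probing
has no antisense strand). Scoring is log2 odds against a 0-order
background, after adding a pseudocount (default 1e-4) to every
probability; `pseudo = 0` makes off-consensus letters unmatchable.
Motifs must be at least 4 columns wide — below that the score-tail table
degenerates into a handful of values and threshold scanning is
meaningless.

`score_pvalue_table()` computes exact tail probabilities
$P(\text{score} \ge t)$ by dynamic-programming convolution of the
per-position score distributions on an integer grid: scores are quantized
with step `eps = range/granularity` (default granularity 1000), and the
*same* quantized scores drive both the table and the scanner, so scan
p-values are exact for the scores actually assigned, not approximations.
Words containing a forbidden letter carry their probability mass at minus
infinity and can never reach a finite threshold. Against exhaustive
enumeration over all 4^w words the table agrees to better than 1e-9 for
every motif width used in the tests.

`scan_regions()` reports every offset with tail probability below the
threshold (default 0.001); windows containing N are skipped.
`sample_background_regions()` draws fixed-length background regions
uniformly over all allowed start positions on the given transcripts,
excluding the test regions (hard-asserted), optionally restricted to
3'UTRs to match a 3'UTR test set. `motif_enrichment()` counts *regions*
with at least one hit (not hits) into the 2×2 table a/b/c/d and reports
the ratio (a/b)/(c/d) with a two-sided Fisher test;
`enrich_motifs()` runs a motif collection with a shared background
estimated from the union of test and reference sequences (overridable)
and Benjamini–Hochberg correction across motifs. The number of background
regions defaults to the test-set size, mirroring one shuffle per input
region. `kmer_enrichment()` is a deliberately simple exhaustive k-mer
diagnostic, not a motif-discovery method.

# Binding sites, structural groups and decay

`truncation_to_sites()` turns iCLIP crosslink-induced truncation
positions into ±20-nt sites, keeping (by default) those whose center lies
in the 3'UTR. `metaprofile()` averages valid reactivity at each offset in
−20..+20 around site centers; the 60% validity rule (sites kept only when
more than 60% of their bases are valid) is exposed as `min_valid_frac`.
`unbound_controls()` builds the sequence-matched structural baseline: all
motif occurrences on the same transcripts whose spans avoid every bound
site (asserted).

`classify_site_structure()` groups each site by a two-sided paired t-test
across its span between stages: group I (more structural later; mean
reactivity drops by more than 0.05, p < 0.05), group II (mirror image),
otherwise unchanged. Sites with fewer than 3 jointly valid bases are
flagged and left unchanged — a paired t-test needs variance. Whether the
site mean should use the full 41-nt window or only the motif span is not
fixed by the procedure; the full span is used.

Expression: `rpkm()`/`rpkm_table()` compute per-replicate RPKM and
average across replicates; `de_test()` is an exact binomial
two-proportion test of each gene's counts between two libraries, with
fold changes on library-normalized rates (a deliberate stand-in for an
external differential-expression package; externally computed fold
changes and FDRs can be fed straight into `classify_genes()`).
`classify_genes()` applies the literal thresholds: maternal decay
(RPKM > 1 early, log2FC > log2 1.2 early-over-late, FDR < 0.05), maternal
stable (RPKM > 1 early, log2FC < log2 1.2, FDR < 0.05), zygotic
(RPKM < 1 early, > 1 late). Taken literally the stable rule admits
strongly up-regulated genes; `symmetric_stable = TRUE` adds the lower
bound, but the literal rule is the default because the intent is not
ours to guess. `stability_association()` compares the fold-change
distributions of group I versus group II genes with a two-sided Wilcoxon
rank-sum test (the groups are disjoint transcripts, so a signed-rank test
has no pairing to use) and reports each group's composition across gene
classes.

# The synthetic-data generator

`sim_config()`/`make_transcriptome()`/`simulate_rtstops()`/
`simulate_expression()`/`emit_fixture()` generate the full input stack
with planted ground truth. What it emulates:

* transcripts ~1860 nt with 5'UTR:CDS:3'UTR near 150:1250:460;
* hairpin stems (two 15-nt paired arms around a 10-nt loop, ~12 per kb)
  defining the paired/unpaired state;
* a Gamma(2, 2) per-base accessibility multiplier, fixed in the ground
  truth and shared across stages, replicates and both libraries. This is
  the generator's model of biological base-to-base variability and RT
  bias; it spreads reactivities over (0, 1) instead of piling all
  unpaired bases at the top of the normalization band, and it cancels in
  stage comparisons, which is exactly how shared biological structure
  behaves in real comparisons;
* RT stops as Binomial(coverage, rate) draws on Poisson(5000) coverage,
  with rates 0.08 (unpaired), 0.02 (paired) and 0.01 (control) times the
  multiplier. The deep default coverage is deliberate: the 200× density
  filter threshold is a floor for retaining a transcript, not a typical
  depth, and recovering planted switches at low false discovery rates
  requires window-level technical noise well below the 0.05 effect-size
  cutoff. At this depth the replicate-noise quantiles (99.8% of bases
  below 0.2; 99.6% of windows below 0.05) sit inside the calibration
  bounds that motivate the cutoffs, on the clean side;
* switch sites: 21-nt spans in 3'UTRs around a planted U-rich motif
  (UUUGUUU consensus, 10% per-base mutation) whose pairing state flips
  between stages, half gaining and half losing structure. The accessible
  state elevates the stop rate by `switch_delta` times the transcript's
  90th–95th percentile rate band, which the normalization maps back to a
  reactivity shift of ≈ `switch_delta` (0.3 by default, measured ±0.30);
* bound sites (iCLIP truncations at their centers) are unpaired at the
  bound stage; unbound control sites carry the same motif but stay
  paired, and are co-hosted on bound transcripts so the control
  construction can find them;
* expression: log-normal baselines, negative binomial counts
  (size 100, ~10% CV — replicates model draws from a pooled embryo
  batch; a larger dispersion would make the fold-change classifier, not
  the coupling, the limiting factor of the linkage analysis), decay genes
  scaled by 2^−1 at the late stage, zygotic genes near-zero early, and
  the structure–stability coupling: genes whose site gains structure are
  decay-class with probability 0.6, genes whose site loses structure are
  stable-class with probability 0.6.

What it does *not* model: real sequence composition, thermodynamic
folding, adduct chemistry and ligation bias, positional coverage decay,
genuine iCLIP noise (truncations sit exactly at planted centers), or
isoforms. Passing tests therefore demonstrate statistical correctness of
the pipeline under its own assumptions, not performance on real
libraries.

Default problem sizes are desk-scale by design: fixtures use 40
transcripts; the null-calibration experiment uses 500 transcripts at
200× coverage; recovery runs pool 10 seeded 40-transcript cohorts; the
coupling experiment uses 1300 genes with 600 per structural group. The
acceptance script (`scripts/acceptance.R`) re-runs all of these from a
single seed and writes the resulting quantities as JSON.

# Numerical choices and degenerate inputs

* Nearest-rank percentiles everywhere; inclusive thresholds for the
  transcript filter; inclusive band ends.
* Zero-variance paired t-tests: p = 0 for a nonzero constant difference,
  p = 1 for all-zero differences.
* Wilcoxon tests use the normal approximation; an all-ties comparison
  reports p = 1.
* The PWM score grid keeps quantized integers far from overflow even for
  single-word consensus matrices whose finite score range is 0.
* Interval merging treats book-ended intervals as mergeable within the
  region builder (they arose from one evidence cluster) but requires
  ≥ 1 nt overlap for cross-comparison sharing.
* Writers emit a `# structvar <version>` header; reactivity values are
  written at 6 significant digits with `NULL` marking invalid bases.
* Manifests record parameters and input/output digests but no
  timestamps, so identical inputs and seeds reproduce byte-identical
  output trees.

# Known limitations

The segment-level Fisher p-values are conservative screening statistics
(see above). The exact binomial DE test ignores biological
overdispersion and will overstate significance on real replicated data —
it exists to make the classification thresholds operable on synthetic
data, and real analyses should supply externally computed fold changes
and FDRs. The region caller inherits the local-normalization property
that strong local signal changes can slightly perturb neighbouring
windows through shared normalizers; full-size windows keep this effect
below the effect-size cutoff at the generator's depths, but very shallow
libraries will show it.
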