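# structvar

Differential RNA structurome analysis from icSHAPE probing data.

In icSHAPE-style chemical probing, flexible (unpaired) nucleotides acquire
adducts that terminate reverse transcription, so per-base RT-stop counts in
a treated library, against a DMSO control, measure RNA structural
accessibility. `structvar` implements the comparative analysis of such data
across conditions or developmental stages — for example across the
maternal-to-zygotic transition of early embryogenesis:

* **Reactivity** — per-nucleotide reactivity in [0, 1] from RT-stop and
  base-density counts: replicate combination, 200-nt/30-nt sliding-window
  normalization against the 90th–95th nearest-rank percentile band,
  background subtraction `max(0, T − 0.25·C)/density`, per-transcript
  winsorized scaling, and the average-stop ≥ 2 / density ≥ 200 transcript
  filter. Replicate-noise quantiles calibrate the difference cutoffs.
* **Differential structure** — structurally variable nucleotides
  (|Δreactivity| > 0.2), disjoint 10-nt windows tested with a two-sided
  paired t-test under the compound cut |Δ̄| > 0.05 and p < 0.05, 10-nt
  flank extension with per-class merging and 30-nt re-binning into
  variable regions, n-way "hot" regions shared across comparisons, and
  segment enrichment against the 150:1250:460 5'UTR:CDS:3'UTR length
  ratio (bedtools-style 0.51 majority assignment).
* **Motif regulome** — PWM scanning with *exact* score-tail p-values
  (dynamic-programming convolution on a quantized score grid shared with
  the scanner; FIMO-style threshold 0.001, sense strand only), matched
  background-region sampling excluding the test regions, and region-level
  (a/b)/(c/d) Fisher enrichment with BH correction.
* **Binding sites and decay** — iCLIP truncations extended ±20 nt into
  3'UTR binding sites, structural metaprofiles against sequence-matched
  unbound controls, site grouping into "more structural" / "less
  structural" between stages (paired t-test, ±0.05, p < 0.05), RPKM and
  maternal-decay / maternal-stable / zygotic gene classes, and the
  Wilcoxon linkage between site structural switching and mRNA decay.
* **Synthetic data** — a seeded generator that plants hairpin structure,
  per-base accessibility heterogeneity, stage-dependent structural
  switches at U-rich motif sites, iCLIP-like truncations and
  structure-coupled expression decay, with the ground truth serialized
  for testing.

All coordinates are 0-based half-open in transcript space. Input formats
are plain text: a TSV transcript table (+ FASTA), long-format RT-stop
TSVs, icSHAPE-style `.out` reactivity files (`NULL` marks invalid bases),
BED-like region files in transcript coordinates, MEME-minimal motifs and
long-format count tables.

## Worked example

Simulate a two-stage probing study with planted structural switches, then
run the differential analysis:

```r
library(structvar)

cfg <- sim_config(seed = 7)                      # 40 transcripts, 16 switch sites
truth <- make_transcriptome(cfg)
simA <- simulate_rtstops(truth, cfg, "A")        # 4 h.p.f.-like stage
simB <- simulate_rtstops(truth, cfg, "B")        # 6 h.p.f.-like stage

reactA <- reactivity_pipeline(simA$treated, simA$control)
reactB <- reactivity_pipeline(simB$treated, simB$control)

windows <- window_scan_set(reactA$profiles, reactB$profiles)
table(windows$klass)
#> less_structural more_structural          stable
#>              20              21            7540

regions <- build_regions(windows, setNames(truth$transcripts$length,
                                           truth$transcripts$transcript_id))
regions <- assign_segments(regions, truth$transcripts)
segment_enrichment(table(regions$segment))
#>   segment observed  expected      ratio     fisher_p
#> 1    5UTR        0  2.741935 0.00000000 2.388060e-01
#> 2     CDS        2 22.849462 0.08752941 1.247036e-07
#> 3    3UTR       32  8.408602 3.80562660 2.080328e-09

sites <- truncation_to_sites(truth$truncations, truth$transcripts)
groups <- classify_site_structure(reactA$profiles, reactB$profiles, sites)
table(groups$group)
#>         I        II unchanged
#>         8         8         8
```

The 16 planted switch sites (half gaining, half losing structure) come
back as 41 variable windows concentrated in 3'UTRs — the 3'UTR enrichment
ratio of 3.8 with Fisher p ≈ 2e-9 mirrors where the switches were planted
— and the 24 binding sites split into 8 more-structural (group I), 8
less-structural (group II) and 8 constitutively accessible (unchanged)
sites, exactly matching the planted directions.

`run_pipeline(fixture_dir, out_dir)` wires all stages together over an
on-disk dataset (see `emit_fixture()`), writing reactivity `.out` files,
window/region BEDs, enrichment tables, metaprofiles, gene classes, the
association report and a JSON manifest with parameter and digest
provenance; reruns with the same seed are byte-identical.

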