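# oligotag

High-throughput DNA barcoding of individually tagged aquatic oligochaete
specimens, for abundance-based assessment of sediment quality in streams and
lakes.

## The problem

Aquatic oligochaetes (Tubificinae, Naidinae, Enchytraeidae, Lumbriculidae,
…) are standard bioindicators of sediment quality, but identifying them
morphologically to species level is hard and often impossible for immature
specimens. Bulk eDNA metabarcoding loses per-specimen abundance, which the
oligochaete indices need. The alternative implemented here sequences each
sorted specimen individually: every specimen's COI amplicon (313 bp) is PCR
tagged with a unique combination of 8-nucleotide forward/reverse tags, all
specimens of a site are pooled into one paired-end (2×250) library, and
reads are demultiplexed back to specimens exactly. One barcode per specimen
preserves true abundances, so the classical indices apply unchanged.

`oligotag` implements the full analysis as tibble-first, pipe-friendly R:

- **Read processing** — mean-Q30 quality filter (and removal of reads with
  ambiguous bases), exact dual-tag demultiplexing (zero mismatches in tag or
  primer; IUPAC degeneracy in primers honoured), quality-weighted ungapped
  pair merging.
- **Barcode determination** — per-specimen dereplication, de novo two-parent
  chimera removal, greedy 97% OTU clustering, dominant-OTU barcode with a
  minimum read count.
- **Lineage assignment** — Kimura two-parameter distance
  `d = -½·ln((1−2P−Q)·√(1−2Q))` to a local COI reference database; a
  barcode is assigned to its nearest reference when `d` is below the
  species threshold (default 10%, with per-genus overrides: 8% for *Nais*
  and *Uncinais*), with an optional secondary database fallback; leftover
  barcodes cluster into new lineages and can be placed to family/subfamily
  level on a bootstrapped neighbour-joining tree.
- **Indices** — the stream IOBS, `IOBS = 10·S/T` (S = taxa richness, T = %
  of the dominant tubificid hair-setae group), and the lake percentage of
  sensitive taxa, each with its five-class quality scale.
- **Concordance** — ordinary least-squares regressions of genetic (y) on
  morphological (x) metric values (natural-log transform for the IOBS),
  R², slope and Pearson p, plus quality-class agreement tables.
- **Synthetic data** — reference databases with known divergence structure
  (including cryptic species pairs), site communities along a pollution
  gradient, tagged paired-end reads with substitution errors and chimeras,
  and a coarsened "morphological observer", all with ground truth, so the
  whole pipeline is testable end to end.

## Worked example

```r
library(oligotag)

fa <- system.file("extdata", "synthetic_refdb.fasta", package = "oligotag")
tr <- system.file("extdata", "synthetic_refdb_traits.tsv", package = "oligotag")
db <- load_reference_db(fa, tr)
db
#> COI reference database: 10 lineages
#>   default threshold: 0.1
#>   genus overrides: Nais=0.08, Uncinais=0.08
#>   sensitive taxa: 4

profiles <- study_design(db, n_stream = 1, n_lake = 0, seed = 2)
cfg <- pipeline_config(db, profiles, specimens_per_site = 33, seed = 42,
                       out_dir = tempfile())
rep <- run_site(cfg, "stream01")
rep$genetic_index
#> # A tibble: 1 × 7
#>   site_id      S     T  iobs quality_class metric value
#>   <chr>    <int> <dbl> <dbl> <ord>         <chr>  <dbl>
#> 1 stream01     7  9.09   7.7 very_good     iobs     7.7
```

All 33 specimens were sequenced and assigned (`rep$stats$success_rate` is
1): 7 lineages were detected among them (S = 7), the dominant tubificid
hair-setae group holds 9.09% of specimens (T), so IOBS = 10·7/9.09 = 7.7 —
"very good" sediment quality (tubificid dominance is low and richness
high). `rep$assignments` lists each specimen's barcode, K2P distance to its
best reference and assignment route; `autoplot()` on a
`concordance_regression()` fit and `plot_quality_classes()` on a study
summary draw the standard figures.

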