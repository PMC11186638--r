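# asartools

Tools for finding and characterizing candidate **ASAR** loci — very long
(>50 kb) strand-specific, contiguously transcribed intergenic noncoding RNAs
("transcribed loci", TLs) that control replication timing of their parent
chromosome — and for quantifying the two signals that define them:
RNA-binding-protein (RBP) occupancy from eCLIP, and replication-timing
asynchrony between chromosome homologs from BrdU quantification.

The package is aimed at analysts who have (or simulate) three kinds of
desk-scale inputs:

* **stranded aligned-read intervals** (BED6, score column = MAPQ, optional
  7th duplicate-flag column) plus an optional gene annotation (GTF/BED);
* **eCLIP and size-matched control reads** (BED6) or ENCODE-style
  **narrowPeak** peak tables;
* **homolog measurement tables** (TSV: cell, chromosome pair, homolog A/B,
  BrdU area and mean intensity, optional DAPI, group).

## The methods in brief

**TL calling** — after removing duplicates and MAPQ ≤ 20 reads and masking
genic reads, stranded reads separated by ≤ 1 kb merge into contigs, contigs
separated by ≤ 7 kb merge into loci, and loci ≥ 50 kb are reported
(`call_transcribed_loci()`).

**eCLIP window enrichment** — per 10 kb window
`ratio_i = log2((n_eclip_i + 1) / (s * n_ctrl_i + 1))`, z-scored across the
window family (population sd), one-sided upper-tail normal p, and
Benjamini–Hochberg FDR; a window is significant at q ≤ 0.05
(`eclip_window_enrichment()`). narrowPeak peaks are kept when peak p ≤ 0.05
and fold enrichment ≥ 2 (`filter_peaks()`), and the densest peak cluster
(e.g. a ~7 kb RBP domain) is located with `find_peak_dense_domain()`.

**Replication asynchrony** — per homolog, signal = BrdU area × mean
intensity; per cell, the B/A ratio; groups are compared against a reference
with a tie-corrected Kruskal–Wallis test (`summarize_asynchrony()`).

A synthetic-data layer (`gen_read_set()`, `gen_paired_counts()`,
`gen_peak_table()`, `gen_homolog_table()`) produces all inputs with ground
truth, seeded and byte-reproducible.

## Worked example

```r
library(asartools)

# 1. simulate a chromosome with two planted loci and call them back
sim <- gen_read_set(tl_sim_config(
  chrom_length = 2e6,
  planted_tls = list(c(3e5, 3.9e5, "+"), c(8e5, 9.5e5, "-")),
  background_rate = 0.05, seed = 42))
call_transcribed_loci(sim$reads)
#>   seqnames  start    end  width strand n_reads n_stage1_contigs
#> 1     chr6 300001 390000  90000      +     181                1
#> 2     chr6 800001 950000 150000      -     301                1
```

Both planted loci come back with exact boundaries (the data.frame view shows
1-based GRanges coordinates; BED output is 0-based: 300000–390000 and
800000–950000), with per-locus read and contig provenance.

```r
# 2. window enrichment: plant fold-4 and fold-6 windows among 200 nulls
cnt <- gen_paired_counts(enrich_sim_config(n_windows = 200, base_rate = 20,
  planted = list(c(12, 4), c(40, 6)), seed = 7))
st <- zscore_fdr(window_log2_enrichment(cnt$eclip, cnt$control))
subset(st, significant)
#>    log2_ratio zscore pvalue qvalue significant
#> 12     1.6947 3.6424  1e-04 0.0135        TRUE
#> 40     1.9087 4.0960  0e+00 0.0042        TRUE
```

Exactly the two planted windows survive FDR control.

```r
# 3. peak filtering and asynchrony scoring
pk <- gen_peak_table(n = 200, n_pass = 60, seed = 11)
length(filter_peaks(pk$peaks))   # 60 — the planted passing subset, exactly

sync  <- gen_homolog_table(homolog_sim_config(10, mean_ratio = 1.0,
  noise_cv = 0.1, group_label = "empty_vector", seed = 1))
async <- gen_homolog_table(homolog_sim_config(10, mean_ratio = 1.5,
  noise_cv = 0.1, group_label = "ASAR_del", seed = 2))
summarize_asynchrony(rbind(sync$table, async$table),
                     reference_group = "empty_vector")
#>          group n_cells median_ratio   q05  q25  q50  q75  q95    H df p_vs_reference
#> 1 empty_vector      10         1.02 0.804 1.02 1.02 1.08 1.17   NA NA             NA
#> 2     ASAR_del      10         1.53 1.201 1.40 1.53 1.62 1.76 13.2  1       0.000285
```

The synchronous reference sits at a median B/A ratio of ~1.0; the group with
a planted 1.5× delayed homolog is recovered at 1.53 and differs from the
reference at p = 2.85e-4 (Kruskal–Wallis, df = 1).

## Command line

A launcher is installed at
`system.file("scripts", "asartools", package = "asartools")`:

```sh
asartools call-tls --reads reads.bed --genes genes.gtf --out tls.bed
asartools eclip-windows --eclip eclip.bed --control ctrl.bed --regions regions.bed --out windows.tsv
asartools filter-peaks --peaks peaks.narrowPeak --out kept.narrowPeak
asartools rbp-domain --peaks kept.narrowPeak --gap 1000 --min-peaks 5
asartools rt-asynchrony --measurements table.tsv --reference empty_vector --out summary.tsv
asartools run --config config.yaml --seed 1 --out-dir out/
```

Exit codes: 0 success, 2 config error, 3 input error, 4 degenerate data.
`run` writes a manifest with md5 checksums; identical (config, seed) runs are
byte-identical.

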