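# hybridpop

Population-genomic tools for dissecting **homoploid hybrid speciation
(HHS)** — the formation of a hybrid species without a change in ploidy.
The package is written for studies of a diploid hybrid taxon with a
paternal-like parent (`P1`), a maternal-like parent (`P2`), a hybrid
cohort (`HYB`) and an outgroup, genotyped by whole-genome resequencing and
profiled by allele-resolved RNA-seq across tissues and stress conditions.

It provides, as one pipeline or as composable tibble-in/tibble-out
functions:

* **Sliding-window scans** (20 kb / 5 kb): nucleotide diversity
  π = Σ 2p̂q̂·n/(n−1) / L, Hudson's Fst as a ratio of averages with
  per-site numerator (p₁−p₂)² − p₁q₁/(n₁−1) − p₂q₂/(n₂−1) and denominator
  p₁q₂ + p₂q₁, reduction of diversity ROD = 1 − π_target/π_control,
  z-score standardisation and top-1% sweep-candidate calling.
* **ABBA/BABA introgression test**: Patterson's
  D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA) from population allele frequencies,
  with a delete-one block-jackknife Z.
* **Diagnostic-SNP discovery and allele-specific expression (ASE)**:
  parental fixed-discordant SNPs (> 80% within-parent consistency, ≥ 3
  heterozygous hybrids), gene-level gating (exonic span, no opposing
  directions), exact binomial / beta-binomial allelic-imbalance tests
  (|log2FC| > 1, BH-adjusted p < 0.05), and the
  consistent / direction-shifting / non-directional classification.
* **HKA scan for positively selected genes (PSGs)**: per-gene
  polymorphism (within P1+HYB) versus fixed differences (per-site Hudson
  Fst > 0.95 against P2) contrasted with the genome-wide background by a
  1-df chi-square; retention at p < 0.01; ranking by fixed nonsynonymous
  differences (top 2.5%); biparental-inheritance confirmation from hybrid
  heterozygosity.
* **Inversion genotyping and LD contrast**: per-sample
  heterozygous / P1-homozygous / P2-homozygous calls across declared
  inversion regions from diagnostic-site genotypes, and distance-matched
  composite r² inside inversions versus collinear background
  (Haploview-style filters: MAF ≥ 0.05, genotyping ≥ 0.6, HWE p ≥ 0.001,
  ≤ 50 kb).
* **A seeded synthetic-data generator** (Balding–Nichols populations,
  planted introgression, sweeps, PSGs, inversion genotypes and allelic
  bias) with machine-readable ground truth, so every stage is testable
  end to end without any external data.

Standard formats in, tibbles out: VCF (via vcfR), GFF3/BED gene models,
TSV labels and allele-count tables; results ship with
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate a default study (2 chromosomes × 1 Mb, 20 000 SNPs, 28 + 10 + 14
samples, F = 0.3, introgression f = 0.2, planted sweeps/PSGs/inversions
and allelic bias) and run every stage:

```r
library(hybridpop)

ds  <- simulate_dataset(sim_config(seed = 1))
res <- run_pipeline(ds)
res$report
#> # A tibble: 14 × 3
#>    metric                   value     n
#>    <chr>                    <dbl> <dbl>
#>  1 diagnostic_precision    0.916   1204
#>  2 diagnostic_recall       1       1007
#>  3 sweep_candidate_hit     1         23
#>  4 sweep_mean_rod_in_sweep 0.852     17
#>  5 ase_sensitivity         1         62
#>  6 ase_class_accuracy      1         62
#>  7 ase_empirical_fdr       0         62
#>  8 ase_direction_accuracy  1        126
#>  9 psg_recall              0.8       10
#> 10 psg_precision           1          8
#> 11 inversion_accuracy      1         28
#> 12 d_statistic             0.0617 10000
#> 13 d_z                     8.91      20
#> 14 ld_r2_difference        0.0363    10
```

Reading the report: the pipeline rediscovered essentially all planted
parental-diagnostic SNPs (recall 1.00; precision 0.92 against the set of
truly fixed-discordant sites), flagged the planted 100-kb sweep among its
top-1% ROD candidates with window ROD ≈ 0.85 (planted diversity reduction
r = 0.1 predicts ≈ 0.9), recovered the planted ASE genes with perfect
direction assignment and zero empirical FDR, recalled 8/10 planted PSGs
with no false positives, called all 28 hybrid × inversion genotypes
correctly, measured D = 0.062 with jackknife Z = 8.9 for the planted
introgression, and found r² elevated by 0.036 inside the heterozygous
inversion relative to distance-matched collinear background.

Individual stages compose with the pipe:

```r
gm <- assign_sites_to_genes(ds$gm, ds$genes) |> filter_variants()
scan <- sweep_scan(gm, ds$labels)          # windowed pi/Fst/ROD + candidates
autoplot(scan)

glance(res$dstat)
#> # A tibble: 1 × 7
#>    abba  baba      D      se     Z n_sites n_blocks
#>   <dbl> <dbl>  <dbl>   <dbl> <dbl>   <int>    <int>
#> 1  273.  241. 0.0617 0.00692  8.91   10000       20

res$classification
#> <aseg_classification> 222 genes tested, 62 ASEGs
#> # A tibble: 4 × 2
#>   class                  n
#>   <chr>              <int>
#> 1 consistent            21
#> 2 direction_shifting    19
#> 3 non_directional       22
#> 4 not_aseg             160
```

`write_dataset()` exports a simulated study as VCF + GFF3 + TSV + BED +
truth JSON; the file formats round-trip through `read_vcf()`,
`read_gene_models()`, `read_labels()`, `read_allele_counts()` and
`read_truth()`.

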