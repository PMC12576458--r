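---
title: "Methods: population-genomic dissection of a homoploid hybrid species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic dissection of a homoploid hybrid species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridpop)
```

hybridpop implements the computational core of a population-genomic study of
homoploid hybrid speciation (HHS): a diploid hybrid species formed without a
change in ploidy from a paternal-like population (`P1`) and a maternal-like
population (`P2`), carrying both parental haplotypes at many loci. The
package answers four linked questions on diploid genotype and
allele-resolved expression data: Is there differentiation and introgression
consistent with a hybrid origin? Which genomic windows show selective
sweeps? Which genes express their two parental alleles unequally, and how
does that bias respond to tissue and stress condition? And which genes show
the polymorphism-versus-divergence signature of positive selection while
demonstrably carrying one allele from each parent?

Everything operates on a `geno_matrix` — diploid genotype codes 0/1/2/NA
for biallelic sites by samples — plus a sample-to-population label table,
gene models, and a gene x sample x tissue x condition table of
allele-resolved read counts. All user-facing functions take data frames (or
the `geno_matrix`) and return tibbles.

## Variant substrate and filters

`read_vcf()` converts biallelic GT records to genotype codes; multiallelic
records are skipped (the diagnostic-SNP logic downstream assumes biallelic
sites), and `./.` becomes a missing call. Coding-effect labels
(synonymous / nonsynonymous / noncoding) are consumed from INFO annotations,
never recomputed: effect prediction belongs to dedicated annotators.
`filter_variants()` applies the standard resequencing-panel filter — minor
allele frequency strictly above 0.05 computed from non-missing diploid
calls, missing-call fraction strictly below 0.20. Both inequalities are
strict, which makes the filter deterministic at the boundary. An optional
`min_depth` mask in `read_vcf()` covers designs that require a per-call
read-depth floor (e.g. 8x for transcriptome-derived calls); absent a DP
field all calls pass.

Internal coordinates are 1-based inclusive (VCF/GFF3 native); BED input is
converted at the boundary. Sites inside two overlapping genes are assigned
to the smaller gene span (then lexicographic id) — a deterministic
tie-break favouring the more specific model.

## Windowed diversity, differentiation and sweep candidates

`sweep_scan()` tiles chromosomes with 20-kb windows advancing by 5 kb
(`make_windows()`), then per window computes:

* **Nucleotide diversity** $\pi = \sum_s 2\hat p_s \hat q_s\, n_s/(n_s-1) / L$,
  the unbiased per-bp heterozygosity over the population's non-missing
  haplotypes. This equals the mean pairwise haplotype difference, which the
  test suite verifies against a direct pairwise oracle.
* **Hudson's Fst**, as a ratio of averages:
  per-site numerator $(p_1-p_2)^2 - p_1q_1/(n_1-1) - p_2q_2/(n_2-1)$ and
  denominator $p_1q_2 + p_2q_1$ are summed across the window before the
  ratio is taken. Ratio-of-averages windowing is markedly more stable than
  averaging per-site ratios, and Hudson's estimator is robust to unequal
  sample sizes. Negative windowed estimates are legitimate noise around
  zero and are retained.
* **Reduction of diversity** $\mathrm{ROD} = 1 - \pi_{target}/\pi_{control}$,
  oriented so that diversity loss in the target population is positive.
  Only the ratio is prescribed by the method; the orientation is this
  package's choice so that sweeps feed the same one-tailed top-quantile
  rule as Fst.

`zscore_candidates()` standardises a window statistic with the population
standard deviation and flags the `ceiling(0.01 m)` largest z-scores
(boundary ties all included) — the "top 1%" rule. Selection is one-tailed:
only large positive departures are sweep-like.

## ABBA/BABA introgression test

`d_statistic()` computes Patterson's D from population allele frequencies
for the taxon order (P1, P2, P3, outgroup), with the alternate allele
polarised by the outgroup frequency:

$$D = \frac{\sum (1-p_1)p_2p_3(1-p_4) - \sum p_1(1-p_2)p_3(1-p_4)}
           {\sum (1-p_1)p_2p_3(1-p_4) + \sum p_1(1-p_2)p_3(1-p_4)}$$

Positive D means excess derived-allele sharing between P2 and P3.
`block_jackknife_z()` assigns sites to contiguous genomic blocks,
recomputes D with each block deleted, and uses the delete-one variance
$\frac{B-1}{B}\sum_i (D_{(i)} - \bar D_{(\cdot)})^2$ to form $Z = D/SE$.
Frequencies (not sampled haplotypes) and a configurable block count are
used because neither is dictated by the method itself; defaults (20 blocks
at the desk-scale genome) keep blocks much larger than local LD.

## Diagnostic SNPs and allele-specific expression

Parent-of-origin assignment in a hybrid requires sites where the parents
are fixed for opposite homozygotes. Four criteria gate a gene into the ASE
test set:

(a) fixed homozygous discordance between the parental populations —
modal genotypes are opposite homozygotes; (b) the fraction of non-missing
parental samples carrying that homozygote exceeds 0.8 in each population
(`find_diagnostic_sites()`); (c) at least 3 hybrid samples are
heterozygous at the site (`genotype_hybrids()`); (d) the gene's qualifying
sites span at least one exon and do not show opposing hybrid allelic
imbalances (`assemble_gene_diagnoses()`). "Opposing" means strict sign
conflict of per-site hybrid P1-read fractions around 0.5; an exactly
balanced site is concordant with anything. Genes failing (d) never reach
the imbalance test.

`ase_test()` sums replicate counts per gene x tissue x condition cell,
computes `log2((P1 + 0.5)/(P2 + 0.5))` (the 0.5 pseudocount guards zero
counts; thresholds apply to the pseudocounted value), and tests the summed
P1 count against a balanced binomial at 0.5. Paired allele counts within a
sample share one library, so the 0.5-null binomial is the natural exact
test; when the replicate-level method-of-moments intraclass correlation
exceeds 0, a symmetric beta-binomial with the matched overdispersion
replaces it, so replicate inconsistency cannot masquerade as imbalance.
P-values are Benjamini-Hochberg adjusted across all tested cells
(`bh_fdr()`), and a cell is biased only when `|log2fc| > 1` and
`padj < 0.05`.

`classify_asegs()` partitions tested genes: **consistent** (significant in
*all* observed cells, one direction), **direction_shifting** (significant
toward P1 somewhere and toward P2 somewhere else), **non_directional**
(significant in a strict subset of cells, one direction), **not_aseg**
otherwise. The stricter reading of "consistent" — all cells significant
rather than all significant cells agreeing — is deliberate: it is the only
reading that makes the three ASE classes disjoint and exhaustive, and the
generator plants classes under exactly these definitions.
`bias_binomial_test()` is the one-tailed exact binomial used for
genome-wide direction dominance.

## HKA scan and positively-selected genes

For each gene, `hka_scan()` counts polymorphic SNPs within the pooled
hybrid + paternal group and fixed differences — SNP sites whose per-site
Hudson Fst between that group and the maternal population strictly exceeds
0.95 — and contrasts the gene's (polymorphic, fixed) counts against the
genome-wide background (focal gene excluded) with a 1-df Pearson
chi-square. This 2x2 contrast is the minimal faithful
polymorphism-versus-divergence test; the classic multi-locus HKA
likelihood is deliberately out of scope. Retention is direction-agnostic
at p < 0.01, with the excess direction reported, and expected cells below
1 flagged.

`select_psgs()` ranks genes by fixed *nonsynonymous* differences, keeps
the top 2.5% (ties included; a gene must carry at least one), intersects
with the retained set, and finally requires evidence of biparental
inheritance: more than half of the hybrid samples heterozygous at one or
more of the gene's fixed-difference sites. The union-over-sites form is a
considered choice: requiring majority heterozygosity *per site* is
arithmetically incompatible with that site having passed Fst > 0.95 while
the hybrids are pooled into the test group (majority-het hybrids alone
push the pooled minor-allele frequency above the ~5% that the threshold
tolerates, for any cohort where hybrids are more than about a quarter of
the paternal panel). Heterozygosity at *some* fixed site captures the
intended evidence — the gene still segregates a maternal allele in the
hybrid — without that contradiction.

## Inversion genotyping and the LD contrast

Within a declared inversion region, `genotype_inversion_region()` computes
for each sample the fractions of its non-missing diagnostic-site genotypes
that are heterozygous, P1-homozygous or P2-homozygous and calls the class
whose fraction reaches 0.8 (else `ambiguous`; fewer than 20 usable sites
makes the region uncallable). The threshold is deliberately conservative
relative to the near-1 fractions that intact heterozygous inversions
produce (> 94% heterozygosity, > 98% paternal-like homozygosity in the
motivating observations), and is configurable. Only diagnostic sites are
used — ordinary heterozygosity would dilute the signal with sites that
carry no parent-of-origin information.

`ld_contrast()` compares composite (phase-free) r² — squared Pearson
correlation of genotype dosages over jointly non-missing samples — inside
inversions against collinear background sampled from the same chromosomes
and matched in total span, after Haploview-style site filters
(MAF >= 0.05, genotyping rate >= 0.6, Hardy-Weinberg p >= 0.001, pairs
within 50 kb). Means are compared over distance bins populated on both
sides, so the contrast is distance-matched and LD decay cannot confound
it. D' is not computed; r² carries the suppressed-recombination signal.

## The synthetic-data generator

`sim_config()` + `simulate_dataset()` generate complete studies with
machine-readable truth. Design choices, with defaults:

* **Genome**: 2 chromosomes x 1 Mb, 20 000 SNPs, ~400 two-exon gene
  models — a desk-scale stand-in for an ~11-chromosome, ~230-Mb genome
  that keeps every stage exercised in seconds.
* **Populations**: Balding-Nichols drift — parental frequencies are
  Beta-distributed around an ancestral frequency drawn from a symmetric
  Beta(0.8, 0.8), with divergence `F_div = 0.3` chosen to reproduce the
  parental-contrast differentiation (windowed Hudson Fst recovers it; see
  the parameter-recovery test). Cohort sizes 28 / 10 / 14 / 4
  (P1 / P2 / HYB / OUT) are half the motivating study's proportions. An
  explicit coalescent would add realism (linked genealogies, LD decay) the
  tested statistics do not require.
* **Hybrids**: each hybrid draws a per-site ancestry pair — both alleles
  from P1 (0.75), one from each parent (0.20), both from P2 (0.05) — an
  ancient, paternally backcrossed hybrid rather than an F1. The weights
  follow the motivating system's paternal-dominant nuclear contribution
  and modest genome-wide heterozygosity excess. Planted diagnostic sites
  (5% of sites; parents forced to opposite fixation) are heterozygous in
  every hybrid up to the genotype error rate (0.005, uniform re-draw).
* **Inversions**: declared regions with per-sample planted classes
  (default 8 heterozygous / 3 P1 / 3 P2 carriers); inside a region the
  planted class fixes the ancestry pair at every site, which is exactly
  the non-recombining haplotype structure the LD contrast detects.
* **Sweeps**: within swept regions the target population's frequency
  collapses to a Bernoulli draw of itself with probability `1 - r`
  (default r = 0.1), scaling expected heterozygosity by r, hence window
  ROD near `1 - r = 0.9`.
* **PSGs**: planted genes receive 12 parental fixed differences (2/3
  nonsynonymous); hybrids are heterozygous at each such site with
  probability 0.15 and P1-homozygous otherwise — rare retained maternal
  alleles on a paternal background, which keeps per-site Fst above 0.95
  while most hybrids remain heterozygous at *some* site of the gene
  (expected fraction `1 - 0.85^12 ~ 0.86`), so planted genes pass the
  inheritance check for the right reason. The default plants 10 PSGs among
  ~400 genes, matching the 2.5% selection fraction.
* **Expression**: totals are negative-binomial (mean 100, dispersion 0.1)
  per gene x replicate x tissue x condition over the 2 x 3 x 3 default
  design (shoot/root, 0/200/400 mM NaCl, 3 replicates); the P1 count is
  binomial with the planted cell-level P1-read probability
  (`theta = 0.8` for biased cells). Classes realise the classifier's
  definitions exactly: consistent genes hold theta in every cell,
  direction-shifting genes cross 0.5 between cells, non-directional genes
  are biased in a third of cells.
* **Four-taxon sites**: frequencies are generated directly on the species
  topology (((P1,P2),P3),O) with Balding-Nichols drift on the internal
  branch (F = 0.2) and tips (F = 0.1); with probability `f` (default 0.2)
  a site's genealogy instead couples P2 with P3. Site patterns, not
  genealogies, are simulated — sufficient for calibrating D and its
  jackknife Z; blocks are contiguous runs.

Determinism: every generator output is a pure function of the config
including its seed; regeneration writes byte-identical files.

What the generator does **not** emulate: linkage and recombination maps
(sites are exchangeable given their frequencies, except for the planted
inversion coupling), mapping and genotype-calling artefacts beyond a
uniform error rate, reference bias in allele-resolved counts, and library
composition effects across tissues. Passing recovery tests therefore show
that the estimators and decision rules are implemented correctly and are
calibrated under their own assumptions — not that the pipeline is robust
to every artefact of real sequencing data.

## Numerical and degenerate-case conventions

Missing calls are excluded site-wise from every frequency; sites with
fewer than 2 usable haplotypes in a population are skipped. A window with
an all-zero Fst denominator, a D test with no informative sites, a
jackknife with zero SE, an empty LD side, a gene with no sites, and an
all-equal z-score input are all flagged (`NA` plus an explicit
flag/warning) rather than silently zeroed. The two-sided exact p-value is
twice the smaller tail, capped at 1 — monotone in the observed count and
identical in spirit for the binomial and beta-binomial branches.
Top-fraction selections use `ceiling` and include boundary ties, so
results are invariant to within-tie ordering.

## Scale of the shipped test problems

The packaged tests run the default 20 000-site study end to end, 200
null-replicate and 100 power-replicate D studies at 10 000 sites, 2 000
gene HKA calibrations at 30 000 sites, a 1 000-gene expression recovery,
50 sweep replicates and 20 LD-contrast replicates — sizes chosen so the
whole suite completes in a few minutes while each Monte-Carlo criterion
retains enough replicates to be meaningful.

## Worked example

```{r example, eval = FALSE}
library(hybridpop)

ds <- simulate_dataset(sim_config(seed = 1))
res <- run_pipeline(ds)
res$report

# or stage by stage:
gm <- assign_sites_to_genes(ds$gm, ds$genes) |> filter_variants()
scan <- sweep_scan(gm, ds$labels)
autoplot(scan)

diag <- find_diagnostic_sites(gm, ds$labels) |>
  genotype_hybrids(gm, ds$labels)
ase <- ase_test(ds$counts)
classify_asegs(ase)
```

## Known limitations

The HKA contrast tests each gene against a pooled background, so a handful
of extreme genes slightly contaminate every other gene's background (the
focal gene is excluded; others are not). Per-site Fst-defined fixed
differences conflate low within-group frequency with fixation when sample
sizes are small. The beta-binomial fallback estimates one intraclass
correlation per cell from as few as 3 replicates, which is noisy;
overdispersion across tissues is not shared. Inversion genotyping presumes
the declared breakpoints are correct — discovery is out of scope. None of
the estimators model linked selection or demography; candidate windows are
outliers, not formal hypothesis tests.
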