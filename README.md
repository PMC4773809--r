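# ptcpopgen

Population-genetic analysis of premature termination codons (PTCs) in
multi-sample sequencing cohorts.

A PTC — a stop codon (TAA/TAG/TGA) created inside an open reading frame
upstream of the native stop — truncates the protein and, when the stop
falls far enough upstream of the last exon–exon junction, usually triggers
nonsense-mediated decay (NMD). Segregating PTC alleles are natural human
"knockouts": their frequencies and geographic differentiation carry
signatures of drift and selection. `ptcpopgen` is for population
geneticists who want a tested, reproducible pipeline from a multi-sample
VCF to per-variant and per-gene PTC statistics:

* **Stop-gain classification** against transcript ORFs (BED12 + FASTA,
  both strands), with site-quality filters on total read depth, number of
  covered individuals, and mean read position of variant alleles.
* **Ancestral polarization** by majority consensus over primate outgroup
  alleles (chimpanzee, gorilla, orangutan, human reference), and the
  derived allele frequency `DAF = 100 · n_a / (n_A + n_a)` per population
  and pooled, with a configurable DAF selection threshold (default >1%).
* **Consequence geometry**: for a PTC at codon *k* of an ORF of *L*
  amino-acid codons, retained residues *k* − 1, truncation percentage
  100·(*L* − (*k* − 1))/*L*, and the 50-nt last-junction NMD rule.
* **Differentiation statistics** per locus: Weir–Cockerham θ (F_ST) from
  the diploid variance components *a*, *b*, *c*; Nei G_ST; Hedrick's
  G′_ST = G_ST(k − 1 + H_S)/((k − 1)(1 − H_S)); Jost's
  D = (k/(k − 1))(H_T − H_S)/(1 − H_S); exact Hardy–Weinberg tests; and
  percentile-bootstrap CIs from resampling individuals within populations
  (B = 1000 by default).
* **Outliers and structure**: OLS regression of θ on DAF or
  heterozygosity with internally studentized residuals (flag > +2) and a
  95th-percentile rule; population × variant DAF matrices; PCA; UPGMA
  clustering with Newick export; per-group and per-category DAF totals.
* **Archaic overlap** ("virtual genotyping"): the fraction of PTC derived
  alleles observed in Neanderthal/Denisovan allele tables.
* A **Balding–Nichols simulator** (population frequencies
  `Beta(p(1−F)/F, (1−p)(1−F)/F)` around an ancestral frequency `p`,
  genotypes in HWE within populations, optional hierarchical super-groups,
  injected stop-gains with recorded truth) so the entire pipeline is
  testable without external data.

## Worked example

Simulate a 4-population cohort (50 diploids each, F = 0.1, 200 loci of
which half are genuine stop-gains), run every stage, and inspect:

```r
library(ptcpopgen)

cfg <- pipeline_config(
  simulate = TRUE,
  sim = sim_config(n_populations = 4, samples_per_population = 50,
                   n_loci = 200, differentiation_F = 0.1,
                   archaic_carrier_fraction = 0.25, seed = 42),
  daf_threshold = 1, out_dir = "ptc_run")
manifest <- run_pipeline(cfg)
#> [..] classify: 100 rows        <- the 100 injected stop-gains, no decoys
#> [..] daf_threshold: 96 rows    <- pooled DAF > 1%
#> [..] archaic: 22 rows

stats <- read.delim("ptc_run/locus_stats.tsv")
summary(stats$theta)
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> -0.00744  0.02352  0.06172  0.07806  0.11463  0.38867
```

Per-locus θ centers near the simulated F = 0.1 (slightly negative values
are expected for undifferentiated loci; the estimator is not truncated).
The annotated call table carries the consequence metrics:

```r
ann <- read.delim("ptc_run/ptc_annotated.tsv")
median(ann$truncation_pct)   # 47 — uniform placement removes ~half the protein
sum(ann$nmd)                 # 47 of 96 PTCs lie >50 nt upstream of the last junction
```

Hardy–Weinberg and outlier checks:

```r
print(hwe_exact_test(64, 32, 4))
#> HWE exact test: obs (64/32/4), q = 0.2000, p-value = 1

ro <- regress_outliers(stats$daf_total / 100, stats$theta)
sum(ro$outlier)           # 4 loci with studentized residual > +2
sum(ro$above_percentile)  # 5 loci above the 95th percentile of theta
```

The run directory also contains `gene_daf.tsv` (per-gene DAF sums),
`pca_scores.tsv`, `dendrogram.nwk`, `archaic_overlap.tsv` (22 of 96
derived alleles seen in an archaic genome here, matching the simulated 25%
carrier fraction), and `manifest.json` with input checksums, seeds and
stage row counts. A thin CLI wrapper with `simulate` and `all` subcommands
is installed at `inst/cli/ptc-popgen.R`.

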