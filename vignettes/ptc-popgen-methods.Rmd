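---
title: "Methods: population genetics of premature termination codons"
author: "ptcpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics of premature termination codons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcpopgen)
```

# Scope and model

`ptcpopgen` analyses segregating premature termination codons (PTCs):
single-nucleotide substitutions that convert a sense codon, upstream of
the native stop, into TAA/TAG/TGA. The pipeline runs from a multi-sample
diploid VCF, transcript models (BED12 + reference FASTA) and a population
panel to per-variant and per-gene population-genetic summaries. Only SNV
stop-gains are in scope: frameshifts, splice-site variants and indels are
deliberately excluded, because the derived-allele-frequency machinery and
the truncation geometry are defined per substituted codon.

## Stop-gain classification

A variant overlapping a transcript's CDS is substituted into the spliced
CDS (complemented for minus-strand transcripts). It is a PTC call iff the
substitution converts an in-frame non-stop codon at index
$k \le L$ (with $L$ the ORF length in amino-acid codons, excluding the
terminal stop) into a stop. A change inside the native terminal stop is
not premature and yields no call; a mismatch between the VCF reference
allele and the genome, or between the genome and the transcript model, is
a hard integrity error rather than a silent skip. Multi-allelic VCF
records are split and each alt allele evaluated independently.

Site-quality filtering precedes classification and mirrors conventional
exome QC on the three site metrics carried in INFO fields: total read
depth (default ≥ 10 reads), number of individuals with coverage (default
≥ 0.8 × samples), and the mean position fraction of variant alleles along
a read (default within [0.1, 0.9]; variants concentrated at read ends are
alignment-artifact prone). The defaults are conventional values, not
calibrated constants — the contract is the filter semantics, and every
threshold is configurable. In strict mode (default) a missing metric
fails its filter; a permissive mode passes it. The filter report
preserves conservation (retained + removed = input) with per-filter
attribution.

## Polarization and derived allele frequency

The ancestral allele at each site is the majority vote among the
available outgroup alleles — chimpanzee, gorilla, orangutan and the human
reference, equally weighted — requiring at least two informative genomes;
ties, insufficient coverage, or a consensus matching neither ref nor alt
leave the site *unresolved*, which is a value (such sites are excluded
downstream with a logged count), not an error. Weighting the human
reference equally with the three non-human primates is a design decision
recorded in output metadata; the consensus rule is deliberately
conservative and deterministic.

The derived allele frequency is
$\mathrm{DAF} = 100 \cdot n_a / (n_A + n_a)$ with $n_A$ ancestral and
$n_a$ derived allele counts. Missing genotypes reduce the denominator
(no imputation). Pooled DAF therefore equals the sample-size-weighted
mean of per-population DAFs — an identity the tests check numerically.
Variant selection applies a strict inequality on pooled DAF (default
> 1%). Gene-level totals are the *sums* of member-variant DAFs, kept raw
(a capped copy is provided for reporting): a gene whose individual PTCs
each sit below the threshold can still pass at the gene level, which is
why variant-level and gene-level selections are offered separately.
Functional-category totals are likewise uncapped sums and can exceed
100% by construction.

## Truncation geometry and NMD

For a PTC at codon $k$ of an ORF of $L$ amino-acid codons: retained
residues $k-1$, position percentage $100(k-1)/L$, truncation percentage
$100(L-(k-1))/L$. A PTC at codon 1 is position 0% / truncation 100%.
Under uniform placement the expected truncation tends to $50 + 50/L$
percent, so the median sits just above 50% — the basis of the ~50%
acceptance check.

NMD susceptibility uses the canonical 50-nt last-junction rule: flagged
iff the transcript has ≥ 2 exons and the last base of the PTC codon lies
strictly more than 50 nt upstream (spliced coordinates) of the final
exon–exon junction. The threshold is a named parameter and the rule used
is recorded in outputs; measuring from the last base of the PTC codon and
breaking the tie strictly (exactly 50 nt → not flagged) are documented
decisions.

## Differentiation statistics

Per-locus F_ST uses the Weir–Cockerham variance-component estimator for
diploid biallelic data: components $a$ (among populations), $b$ (among
individuals within populations), $c$ (within individuals), and
$\hat\theta = a/(a+b+c)$. Negative estimates are reported, not truncated;
globally monomorphic loci are undefined (missing). Across loci the
*multi-locus* estimate is the ratio of summed components
$\sum_\ell a_\ell / \sum_\ell (a_\ell+b_\ell+c_\ell)$ — the combination
the original estimator prescribes and the one F recovery is validated
with. The arithmetic mean of per-locus ratios is also reported per locus
but is downward-biased when many loci segregate at low frequency, which
is why it is not the headline estimate.

The G_ST family is computed from within- and total expected
heterozygosity. With `corrected = TRUE` (default), $H_S$ is the
unweighted mean of per-population unbiased gene diversities
$\frac{2n_i}{2n_i-1} 2 p_i q_i$ and
$H_T = 1 - \bar p^2 - \bar q^2 + H_S/(2k\tilde n)$ with $\tilde n$ the
harmonic mean sample size (Nei/Chesser-style corrections; the
Chao-corrected variants used by some software are intentionally not
replicated). Then $G_{ST} = (H_T - H_S)/H_T$, Hedrick's
$G'_{ST} = G_{ST}(k-1+H_S)/((k-1)(1-H_S))$ and Jost's
$D = \frac{k}{k-1}\,(H_T-H_S)/(1-H_S)$. A consequence of the small-sample
correction is that for *identical* populations $H_T - H_S$ is slightly
negative at finite $n$ (order $1/n$), so corrected G statistics center on
zero without being exactly zero; the plug-in forms (`corrected = FALSE`)
satisfy the exact closed-form identities (identical populations → 0;
populations fixed for alternate alleles → 1) and are retained for that
reason. Both are exposed and both behaviours are asserted in the tests.

Hardy–Weinberg testing is the exact conditional test: given the observed
allele counts, all genotype tables of matching heterozygote parity are
enumerated and the probabilities of tables as or less probable than the
observed one are summed. The exact test was chosen over the chi-square
because PTC derived homozygotes are typically rare and expected counts
small; it is conservative by construction, which the calibration check
(rejection ≤ α at HWE) reflects. Expected genotype frequencies
$(p^2, 2pq, q^2)$ are emitted for plotting against observed spectra.

Bootstrap confidence intervals resample individuals with replacement
*within* populations (the locus-level resampling unit), recompute the
statistic B times (default 1000) and take the percentile interval.
Intervals are seeded and bit-reproducible; if the statistic is undefined
in more than half the replicates the interval is reported missing with a
diagnostic. Cohort DAF comparisons use the two-sided paired Wilcoxon
signed-rank test: for ≤ 16 informative pairs the exact permutation
distribution of the positive-rank sum is enumerated (tied ranks handled
by mid-ranks — the reason a hand-rolled enumeration is needed at small
n), otherwise the tie-corrected normal approximation.

## Outliers and structure

Outlier detection regresses per-locus θ on a predictor (pooled DAF by
default, heterozygosity as an alternative; which regressor was used is
recorded in output metadata) by ordinary least squares and flags loci
with *internally studentized* (leverage-corrected) residuals above +2 —
one-sided, since only unusually differentiated loci are of interest. An
independent flag marks loci strictly above the 95th percentile of raw θ
(linear-interpolation percentile). When the fit is essentially perfect
(residual variance at numerical-noise level) residuals are defined as
zero so that degenerate inputs produce no spurious flags; a constant
predictor leaves the regression undefined but still computes percentile
flags. Flags are invariant under affine rescaling of the predictor.

Structure summaries operate on the population × variant DAF matrix
(row order = panel order; unobserved entries zero with a recorded mask):
PCA on the column-centered matrix without unit-variance scaling (DAFs
share units), populations as observations; hierarchical clustering with
Euclidean distance and average linkage (UPGMA), exported as Newick. The
distance/linkage choices are defaults recorded in output metadata, not
reconstructions of any particular prior analysis.

## Archaic overlap

"Virtual genotyping" counts a PTC as detected in an archaic genome iff
its derived allele is among that genome's observed alleles at the site;
the union over Neanderthal and Denisovan is the headline count. The
default denominator is the *total* PTC set, with an assayable-only mode
(sites covered in at least one archaic genome) available, since either
convention is defensible. Archaic read-level processing is intentionally
externalized: the interface is a precomputed allele table ("." = no
coverage, distinct from an observed-ancestral-only site).

# The synthetic-data generator

The generator exists so that every downstream stage has a ground truth.
Population allele frequencies follow the Balding–Nichols model: an
ancestral derived-allele frequency $p$ per locus (uniform on a
configurable range, default 0.01–0.5 — a stand-in spectrum, not an
empirical claim), population frequencies
$p_i \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$, degenerating to
$p_i = p$ at $F = 0$, and genotypes $\mathrm{Binomial}(2, p_i)$ — HWE
within populations by construction. Balding–Nichols was chosen because
its $F$ is exactly the quantity the Weir–Cockerham estimator targets,
enabling parameter-recovery validation. With `n_groups > 1` a group
frequency is drawn first (at `group_F`) and population frequencies are
nested within it, emulating continental structure for the
clustering/PCA checks. Missing genotypes are injected at a configurable
rate (default 0).

Synthetic transcripts have in-frame CDSs (ATG start, single terminal
stop, no internal stops) split over 1–5 exons on alternating strands of
one synthetic chromosome; coordinates are 1-based in VCF and 0-based
half-open in BED12. Injected variants are genuine single-substitution
stop-gains at known codons, mixed 1:1 by default with decoy
(synonymous/missense) substitutions so classification has true
negatives. Note one geometric consequence: codon 1 of any ORF is ATG,
which is at least two substitutions from any stop, so a stop-gain can
never be placed there — explicit placement at such a codon is a
placement error by design. Outgroup genomes carry the true ancestral
allele independently with probability `outgroup_concordance`; the
archaic table carries the derived allele at a configurable fraction of
loci, with the carrier set recorded in truth.

What the generator does *not* emulate: linkage disequilibrium and
recombination, demographic history (bottlenecks, migration, admixture),
sequencing-read error processes, and site-frequency spectra shaped by
selection. Passing the validation suite therefore demonstrates
correctness of the estimators and plumbing under idealized sampling — it
does not certify behaviour on real cohorts with LD, cryptic relatedness
or batch effects.

# Validation design and problem sizes

The validation suite (and `scripts/acceptance.R`, which recomputes the
same quantities from scratch at any seed) uses these fixed designs:

* **F recovery** — 4 populations × 100 diploids × 2,000 loci at
  F = 0.10 and 0.30; multi-locus θ expected within ±0.02/±0.03. The
  ratio-of-sums estimator is used (see above).
* **Closed forms** — populations fixed for alternate alleles (θ, G_ST,
  G′_ST, D all 1); literally identical populations (plug-in forms all
  exactly 0); 2,000 undifferentiated loci (F = 0: |mean θ| < 0.01 and
  corrected G-family means within 0.01 of 0).
* **HWE calibration** — 5,000 loci, q ~ U(0.05, 0.5), n = 200;
  rejection at α = 0.05 must not exceed 0.06.
* **Classifier exactness** — 50 injected stop-gains + 50 decoys across
  both strands, written to VCF/BED12/FASTA and reloaded; precision =
  recall = 1 with identical codon indices.
* **Truncation geometry** — uniform placement over 10,000 simulated
  ORFs of 100–400 codons; median truncation in [48%, 52%].
* **Outlier recovery** — 100 replicates of 500 background loci at
  F = 0.05 plus one planted locus at F = 0.5, in 14 populations × 25
  diploids (14 matching a typical continental panel division); the
  planted sweep locus draws its ancestral frequency from U(0.2, 0.8),
  since a population-restricted sweep is by nature a moderate-to-high
  frequency phenomenon and differentiation outliers concentrate at
  moderate/high DAF. The residual rule must flag it in ≥ 95% of
  replicates.
* **Structure recovery** — 12 populations in 4 super-groups
  (between-group F = 0.3, within 0.02, 250 loci); the 4-cluster UPGMA
  cut must reproduce the groups exactly (adjusted Rand = 1) and PCA
  variance explained must be non-increasing.
* **Bootstrap** — B = 1000 within-population resampling; same seed →
  bit-identical intervals containing the point estimate; degenerate
  data → zero-width interval.

These sizes keep the full suite within a couple of minutes on one CPU
while leaving Monte-Carlo error well below the tolerances.

# Numerical and degenerate-input choices

* θ undefined (a+b+c = 0) is missing, never 0; negative θ is reported.
* HWE enumeration works in log-space and normalizes, so large counts do
  not overflow; the observed-table comparison uses a 1e-7 relative slack
  to absorb rounding.
* Percentiles use R's default linear interpolation (type 7) with strict
  exceedance.
* Perfect regression fits (residual SD ≤ 1e-10 × data scale) define all
  studentized residuals as zero.
* The DAF of a locus with zero called alleles is an error at the
  single-locus level and missing in per-population matrices (masked
  zeros in the DAF matrix, with the mask kept as an attribute).
* The genome-wide average PTC allele frequency (~0.16%) is carried as a
  reporting constant in the pipeline configuration; it is an input, not
  something this package estimates.

# Known limitations

Single-transcript genes only (no isoform-aware consequence selection);
biallelic statistics only; no haplotype-based selection scans; ancestral
inference is site-wise consensus, not alignment-based probabilistic
reconstruction; archaic input is a precomputed allele table, not BAM
pileups. These match the intended scope: a desk-scale, fully testable
reimplementation of the PTC population-survey analysis chain.
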