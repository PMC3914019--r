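# lowcovcall

Simulation and evaluation of variant calling for low-coverage whole-genome
sequencing (WGS) of family cohorts, at desk scale.

Low-coverage WGS (roughly 1–15× mean depth) trades per-sample read depth
for sample count. Whether that trade is worth making hinges on the
genotype caller: with only a handful of reads per site, a caller that uses
only one sample's reads is weak, a caller that pools the cohort to
estimate each site's allele frequency does better, and a caller that
additionally exploits linkage disequilibrium — copying each sample's
genome as a mosaic of the other samples' haplotypes — does best on
genotype accuracy while finding fewer of the rarest variants. This package
is for method developers and teaching: it rebuilds that entire comparison
as reproducible simulation, with every statistic implemented from first
principles and tested against independent oracles.

## What it implements

**Simulation** — multi-generation pedigrees with two-population admixed
founders, half-sib/avuncular structure and cryptic relatedness; founder
haplotypes with distance-decaying LD via a mosaic-of-seed-haplotypes
process; gene dropping; Poisson read pileups with base error; and an
exome-chip-style genotype set with realistic artifacts (A/B allele flips,
duplicate samples, missingness, monomorphic markers).

**Callers** — three classes, all fed pileup counts only (pedigree
information never enters a caller):

* single-sample: per sample-site maximum-likelihood genotype from
  binomial read likelihoods, phred-gap quality gate;
* multi-sample: per-site allele frequency by EM under Hardy–Weinberg,
  site flagged by a phred likelihood ratio against q = 0, genotypes as
  posterior modes under the cohort prior;
* LD-aware: cohort-evidence site discovery followed by iterative diploid
  Li–Stephens haplotype-copying refinement (exact forward–backward in
  compiled code, forward-filter backward-sampling of haplotypes, round
  averaging).

**Evaluation** — marker QC (duplicate discordance > 3 pairs, exact
Hardy–Weinberg test at p < 10⁻¹⁰, flipped-marker concordance < 2% across
all samples); per-sample concordance C_S = N_m/N_v against chip genotypes
with missing calls read as homozygous reference; per-sample
false-positive rate; frequency-binned site discovery with the
single-sample model `1 − (1 − p)^f` fitted by maximum likelihood; the
log10 identity statistic `Σ [−PL(GT_chip)/10 + log10 f_GT]` for
sample-swap detection; pedigree kinship by the exact recursion; moment
estimation of empirical kinship; greedy weakly-related subset selection;
and best linear unbiased (kinship-corrected, GLS) allele frequencies.

## Worked example

One call runs the whole study — simulate, call with all three methods,
QC, evaluate, match identities, estimate kinship and corrected
frequencies:

```r
library(lowcovcall)
res <- run_experiment(default_config(seed = 1))

round(100 * sapply(res$concordance, function(x) median(x$concordance, na.rm = TRUE)), 1)
#> single  multi     ld
#>   91.2   92.5   96.3

round(sapply(res$fpr, function(x) median(x$fpr, na.rm = TRUE)), 4)
#> single  multi     ld
#> 0.0240 0.0180 0.0074

res$site_finding$multi
#>            bin n_sites n_found  fraction mean_carriers
#> 1        MAC=1      23      14 0.6086957      1.000000
#> 2        MAC=2      24      21 0.8750000      1.875000
#> 3    (0,0.001]       0       0        NA            NA
#> 4 (0.001,0.01]       0       0        NA            NA
#> 5  (0.01,0.05]     105     104 0.9904762      6.085714
#> 6   (0.05,0.5]     694     694 1.0000000     42.883285

res$discovery_fit
#> discovery_model_fit: p = 0.8285 (per-carrier find probability), 846 sites

res$match
#> match_matrix: 100 wgs x 105 chip samples; 0 mismatch flag(s)

res$blue
#> frequency_estimate: 1000 sites; rms(BLUE - naive) = 0.0231; clipped 0; failed 0
```

Reading the numbers: median per-sample concordance at chip variant sites
rises from 91.2% (single-sample) through 92.5% (multi-sample) to 96.3%
(LD-aware), while the LD-aware caller also has the smallest median
false-positive rate (0.0074) — the accuracy ordering low-coverage studies
report. The cost shows in the lowest frequency bin: at chip minor-allele
count 1 the cohort callers find 61% of sites, versus 99–100% of common
sites; the fitted per-carrier discovery probability p = 0.83 summarises
the single-sample curve. Identity matching pairs all 100 sequencing
samples with their chip counterparts (the 105 chip samples include 5
duplicates) with no mismatch flags, and the kinship-corrected allele
frequencies differ from naive prevalence by 2.3% rms on this heavily
related 100-sample cohort.

Individual pieces are plain functions on plain objects —
`simulate_pileups()`, `call_ld_aware()`, `hmm_posteriors()`,
`hwe_exact_test()`, `blue_frequencies()`, `match_samples()`, … — see the
help pages and the methods vignette (`vignettes/low-coverage-calling.Rmd`)
for the models, parameter meanings and design decisions.

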