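---
title: "Models and methods: evaluating variant callers on simulated low-coverage cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: evaluating variant callers on simulated low-coverage cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lowcovcall` re-creates, at desk scale, the standard evaluation of
genotype calling from low-coverage whole-genome sequencing (WGS) of a
family cohort: three caller classes — single-sample, multi-sample with a
cohort allele-frequency prior, and LD-aware haplotype-copying refinement —
are run on simulated read pileups and compared against an exome-chip-style
genotype set, together with the population-genetic side analyses such a
study carries (kinship verification, sample-swap detection, and
kinship-corrected allele frequencies). This vignette documents the models,
the parameters that matter, and the design decisions, in the package's own
terms.

## The simulation chain

**Pedigree.** `generate_pedigree()` builds a multi-generation cohort from
a founder generation drawn from two ancestral populations (A and B, with a
configurable admixture fraction). Mating pairs form at random within the
previous generation, avoiding unions that share a parent; with probability
`p_remate` (default 0.2) an individual takes a second mate, which creates
half-sib and avuncular structures. When a generation admits no valid new
pairing (all members are siblings), established couples reproduce again,
so small pedigrees stay connected without introducing extra founders. The
sequenced cohort of an experiment is the first `n_samples` pedigree
members in storage order (founders first), which yields a mixture of
founders, their children and grandchildren — the cryptic-relatedness
texture of a community family study.

**Haplotypes and LD.** Linkage disequilibrium is induced by a
mosaic-copying process rather than a coalescent simulator:
`simulate_founder_haplotypes()` draws a small panel of seed haplotypes
from per-site Beta-distributed allele frequencies and builds each founder
haplotype as a mosaic of the seeds, switching template with probability
`switch_rate` (default 0.01) per adjacent-site interval. Adjacent sites
tend to be copied from the same seed, so pairwise r² decays with
inter-site distance — the only property the LD-aware caller needs.
Per-site allele flips at `mutation_rate` add private variation. A fraction
`rare_site_fraction` of sites carries an all-reference seed panel, so its
variation comes only from these flips: those sites populate the
singleton/doubleton discovery bins, and where no flip lands they remain
monomorphic, which is what gives the chip its realistic monomorphic
component. The defaults (`mutation_rate = 0.006`,
`rare_site_fraction = 0.5` in `default_config()`) were chosen so that the
simulated chip, like a real first-generation exome array, is heavy in
low-frequency content: at the default 100 samples × 1000 sites this
yields roughly 20–50 markers each at minor-allele counts 1 and 2. These
are marker-level rates for a sparse marker panel, not per-base-pair
mutation rates.

**Transmission.** `gene_drop()` performs standard gene dropping: each
non-founder receives one recombinant gamete per parent (template switching
at `recomb_rate` per interval), with no mutation, so founder-monomorphic
sites stay monomorphic and familial allele sharing matches the pedigree
kinship in expectation.

**Sequencing.** `simulate_pileups()` reduces sequencing to its sufficient
statistic for genotype calling: per sample-site, the read total is
Poisson at the sample's mean depth, each read copies one of the two true
haplotypes uniformly, and reports the wrong allele with probability
`base_error` (default 0.005). Per-sample mean depths are drawn uniformly
on [1, 15], matching the wide low-coverage spread such studies report
(most samples between roughly 3× and 12×). There are no reads, qualities,
mapping artifacts, or indels; pileup counts are the atomic evidence.

**Chip.** `simulate_chip()` applies, in order: symmetric genotyping error
(default 5 × 10⁻⁴, the scale of a validated array product — at much higher
rates, sporadic errors at monomorphic sites masquerade as singleton
markers and dominate the lowest frequency bin), missingness, A/B allele
flips on a fraction of polymorphic markers (default 0.005, storing
`2 − g`; heterozygotes are flip-invariant), and duplicate samples
re-genotyped with independent error draws.

## The three callers

All callers see pileup counts only; pedigree information never enters any
caller, by interface.

**Genotype likelihoods.** Per-read independent binomial with symmetric
error ε: `L(D|RR) = C(n,a) εᵃ(1−ε)ʳ`, `L(D|RA) = C(n,a) 0.5ⁿ`,
`L(D|AA) = C(n,a)(1−ε)ᵃεʳ`. PL values follow the VCF convention
(`round(−10·log10 L)`, min-normalised, capped at 255), which keeps
identity matching format-faithful.

**Single-sample** (`call_single_sample()`): maximum-likelihood genotype
under a flat prior, ties broken toward the lower dosage (reference-first,
as real callers do). Call quality is the phred gap between best and
second-best genotype; calls below `min_call_quality` (default 4, echoing
low-coverage emission-confidence settings) or at zero depth are missing.
Missing calls are interpreted downstream as homozygous reference.

**Multi-sample** (`call_multi_sample()`): per site, the alternate-allele
frequency q is fitted by EM on the expected alternate dosage under
Hardy–Weinberg, maximising `∏ᵢ Σ_g HWE(g;q)·Lᵢ(D|g)`; EM is initialised at
the flat-prior mean dosage and its observed-data likelihood is
non-decreasing by construction. A site is flagged variant when the
phred-scaled likelihood ratio of q̂ against q = 0 reaches
`min_site_quality` (default 4). Genotypes at flagged sites are posterior
modes under the HWE(q̂) prior, zero-depth samples receiving the prior
mode; unflagged sites are reference for everyone. A flagged site can
therefore carry all-reference genotypes, as with cohort callers that emit
a site record on cohort evidence alone.

**LD-aware** (`call_ld_aware()`): a two-stage pipeline, the shape such
callers actually sit in. Stage 1 is cohort-evidence site discovery — the
same likelihood-ratio statistic as the multi-sample caller, at the same
default threshold. Stage 2 is iterative haplotype-copying refinement in
the MaCH/Thunder family: haplotypes are initialised from single-sample
maximum-likelihood genotypes with random phase; in each round every
sample, in random order, is re-estimated by an exact forward–backward
pass of the diploid Li–Stephens HMM against up to `n_templates`
haplotypes drawn from the other samples' current haplotypes, and its
haplotype pair is re-sampled from the joint posterior path
(forward-filter backward-sample). Genotype posteriors are averaged over
the final half of `n_rounds` and the posterior mode gives the genotype.
Sites failing stage-1 discovery are reference calls for every sample: an
LD-aware caller never emits a variant its discovery stage missed, which
is the structural reason this caller class under-finds rare sites while
leading on genotype concordance.

The HMM state is an *ordered* template pair; each copied haplotype
independently switches to a uniformly chosen template (including the
current one) with probability `recomb_switch` per interval. This
factorised transition collapses the H²-state sums to row/column
marginals, making forward–backward O(sites × H²); the inner loops are
compiled (Rcpp) and draw from R's RNG, so a fixed seed fixes every call.

**Choice of `template_error`.** The copying-error parameter sets the odds
a sampled haplotype explains a mismatching read. Its default is 0.003 —
deliberately *below* the read error 0.005. At the acceptance odds
`1/(2e)`, a copying error at or above the read error lets a single
alternate read overcome the haplotype prior, making the LD caller *more*
permissive at singletons than the multi-sample caller — inverting the
defining trade-off of the caller class. Keeping the copying error below
the read error encodes the modelling fact that template haplotypes
(backed by many reads across samples) are cleaner evidence than an
individual read.

## Evaluation statistics

**Marker QC** (`filter_markers()`), in order: (1) duplicate discordance —
markers discordant in more than `dup_max_discordant` (default 3)
duplicate pairs; (2) Hardy–Weinberg — exact conditional test p below
10⁻¹⁰ on a weakly related subset (by default the greedy pedigree-kinship
< 0.1 subset); (3) flipped markers — per-marker concordance with a call
set, computed across **all** samples with a non-missing chip genotype
(missing calls read as hom-ref), below 2%. Counting all samples rather
than alternate carriers is what makes the filter specific to the flip
artifact: a flipped marker turns its hom-ref majority into mismatches
(2 − g ≠ g for homozygotes) and collapses to ~the het fraction, while a
rare marker the caller merely missed still matches at its hom-ref
majority and survives. The practical corollary, visible in simulation, is
that flips on common, het-rich markers evade the 2% rule — on a real chip
the flagged markers are the low-frequency ones. Monomorphic markers are
excluded from concordance but retained for the false-positive-rate
denominator (both conventions are reported).

**Concordance** (`sample_concordance()`): per sample,
`C_S = N_{S,m}/N_{S,v}` over surviving non-monomorphic markers, where
`N_{S,v}` counts chip genotypes with at least one alternate allele and
`N_{S,m}` those the caller matches exactly, missing calls reading as
hom-ref. Chip-missing genotypes are excluded from both counts (the chip
is not imputed). Samples with no chip alternate genotypes are undefined,
not zero. Depth strata for reporting are <5×, 5–10×, >10×.

**False-positive rate** (`false_positive_rate()`): the fraction of a
sample's non-reference calls that the chip genotypes as hom-ref;
undefined (not 0) when the sample has no non-reference calls.

**Site finding** (`site_finding()`): a chip variant site is found by a
caller if the caller flags it variant, regardless of genotype agreement.
Sites are binned by chip minor-allele frequency with dedicated bins at
minor-allele counts 1 and 2 and configurable edges above (defaults 0.001,
0.01, 0.05, 0.5); empty bins report NA, never 0.

**Discovery model** (`fit_discovery_model()`): if a single-sample caller
finds a variant in any carrier independently with probability p, a site
with f carriers is found with probability `1 − (1−p)^f`. f defaults to
the number of samples carrying at least one alternate allele (each
carrier is "an independent chance"); the maximum-likelihood p comes from
scalar optimisation on (0, 1).

**Identity matching** (`match_samples()`): the statistic
`M = ∏ L{D|GT_chip}·f_GT` is computed in log10 throughout (the raw
product underflows at realistic marker counts), with the likelihood read
off PL triples and `f_GT` the chip genotype-class frequency (per class,
not per allele), floored at 10⁻⁴ so empty classes cannot contribute −∞.
Pairs are compared on the per-marker-normalised statistic so different
marker subsets are comparable; raw sums are also kept. Ties (duplicate
chip samples) are reported, never silently broken, and flagged mismatches
are reported, not adjudicated.

**Kinship and corrected frequencies.** `pedigree_kinship()` is the
standard recursion in generation order (exact binary rationals in
doubles); `empirical_kinship()` is the centred-dosage moment estimator
`φ̂ᵢⱼ = ½·mean_s (gᵢ−2q)(gⱼ−2q)/(2q(1−q))` with a minor-allele-frequency
floor (default 0.01; low-frequency sites destabilise the denominator) and
pairwise deletion of missing genotypes. `blue_frequencies()` computes the
best linear unbiased (GLS) frequency `(1'Φ⁻¹x)/(1'Φ⁻¹1)` with `x = g/2`
per site over the non-missing samples, inverting the kinship submatrix
exactly per missingness pattern (cached by pattern) rather than imputing;
estimates are clipped to [0, 1] with clipping counted, and singular
submatrices are recorded as per-site failures, not errors. Pedigree
kinship is the default input, matching how such corrections are run in
practice; an empirical matrix is accepted.

One exact property worth knowing: with pedigree kinship and no missing
data, the GLS weights put all mass on founders (descendant genotypes are
linear in founder alleles under the covariance model), so the BLUE equals
the founder-subset prevalence and its correction correlates *perfectly*
with the unrelated-subset deviation in simulation. The much weaker
correlation seen in real data reflects genotype error, missingness and
cryptic relatedness, none of which the idealised check carries.

## What the generator does and does not emulate

The simulator reproduces the features the statistics are sensitive to:
pedigree relatedness with half-sib/avuncular structure, two-population
admixture with divergent founder frequencies, distance-decaying LD, a
wide per-sample depth spread, read error, and chip artifacts (flips,
duplicates, missingness, monomorphic markers). It deliberately omits
read-level reality: alignment and mapping error, base-quality
miscalibration, GC and reference bias, indels, and non-autosomes. Passing
tests therefore demonstrate correctness of the statistical machinery and
reproduction of the qualitative caller trade-offs under the stated
generative model — not performance claims about any real cohort, where
error processes are correlated in ways the binomial pileup model is not.

## Numerical choices

- Genotype argmax ties break toward the lower dosage, everywhere.
- PL integers are min-normalised and capped at 255; infinite phred values
  (zero likelihoods) hit the cap.
- EM stops at |Δq| < 10⁻⁸ or 200 iterations; the all-flat degenerate case
  returns the initialisation (0.5) by construction.
- The forward pass is normalised per site; the backward pass is rescaled
  against the forward scale so products stay O(1); posteriors are
  renormalised per site and sum to 1 within 10⁻¹².
- The HWE exact test enumerates heterozygote counts in log space
  (lgamma), normalises by log-sum-exp, and includes ties within a 10⁻⁹
  relative band when summing configurations at or below the observed
  probability.
- A site whose cohort likelihood ratio is exactly 0 (no reads anywhere)
  is never flagged, even at threshold 0.
- Per-stage seeds derive from the master seed by a stage-name hash
  (`stage_seed()`), all below 2³¹, so stages re-run identically in
  isolation.

## Problem sizes

The bundled checks run the full comparison on one seeded cohort of 100
samples × 1000 SNP sites (depths uniform on [1, 15], base error 0.005) —
large enough that the caller orderings and depth trends are stable, small
enough to run in about a minute; identity matching uses ten cohorts of 20
samples × 2000 markers at ≥2×; the BLUE study uses 200 gene-dropped
site-replicates of a three-generation fixture pedigree at founder
frequency 0.2, with recombination 0.5 making sites independent drops.
These sizes are the package's reference configuration; every parameter is
exposed in `default_config()`.

## Known limitations

- The LD caller is an iterative-resampling approximation: no per-round
  re-estimation of error/crossover parameters, no consensus phasing, no
  convergence diagnostics beyond round-averaging.
- The multi-sample flag is a profile-likelihood ratio under HWE, not the
  exact allele-count posterior of production cohort callers; at singleton
  sites it is accordingly conservative.
- Desk-scale cohorts are far more related than a 600+-sample community
  study (more than half the default cohort are close relatives of other
  members), so kinship-corrected frequency corrections are larger here
  (rms of a few percent) than the sub-percent corrections a large cohort
  shows.
- Exact per-pattern kinship inversion is O(n³) per distinct missingness
  pattern; heavy chip missingness on large cohorts would need the
  mean-imputation shortcut the package intentionally avoids.

```{r example}
library(lowcovcall)
res <- run_experiment(default_config(seed = 1))
sapply(res$concordance, function(x) median(x$concordance, na.rm = TRUE))
res$site_finding$multi
res$discovery_fit
```
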