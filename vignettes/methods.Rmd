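---
title: "Models and numerical conventions in flockdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical conventions in flockdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flockdiv)
```

`flockdiv` quantifies genetic diversity and population structure in
pedigreed, partially genotyped livestock populations. This vignette is the
package's own account of the models it implements, the defaults it chose
where the field leaves room, and what its validation does and does not
demonstrate.

## Pedigree representation

A pedigree is a data frame of animal/sire/dam records with sex, birth year
and flock. Construction (`ped_table()`) validates the structure — unique
ids, no id used as both sire and dam, an acyclic parent graph (Kahn's
algorithm; a cycle is reported by naming a member), and parents born
strictly before offspring where both years are known — and stores records
in topological order, the precondition for every recursive computation.
Parents that appear only in the parent columns are materialized as founder
records with sex inferred from their role. Unknown parents are encoded
`"0"` in files and `NA` internally.

## Inbreeding, relatedness, and coancestry

Individual inbreeding F is computed by the Meuwissen–Luo algorithm: writing
the additive relationship matrix as A = T D T′ (T the gene-flow matrix, D
the Mendelian-sampling variances d_j = 0.5 − 0.25(F_s + F_d), with 0.75 −
0.25 F for one known parent and 1 for founders), F_i is half the inner
product of the sire's and dam's ancestor-contribution vectors weighted by
D. The trace touches only the ancestors of each animal, so cost grows with
total ancestor count rather than the square of pedigree size. An animal
with an unknown parent is assigned F = 0: the unrecorded side is assumed
unrelated, the conventional choice for breed pedigrees traced "until all
ancestors are unknown".

Average relatedness (AR, twice the mean coancestry of an animal with the
whole pedigree including itself) is the mean of a row of A. It is obtained
without forming A from the same decomposition: u = T′1 by one backward
pass, then v = T(Du) by one forward pass gives the row sums. The identical
machinery yields mean coancestries between arbitrary groups
(1′_g A 1_h terms), which is how flock-level Wright's FST
((f̄ − f̃)/(1 − f̃), flock means weighted by size) and Nei's minimum
distance ((f_ii + f_jj)/2 − f_ij) are computed for whole pedigrees. Self
pairs are included in all group means, so a flock's mean self-coancestry
term (1 + F)/2 enters f̄ — the convention of the classical pedigree
software this analysis style comes from; the population mean f̃ is the
full pairwise mean over all animals. The rate ΔF between successive
cohorts is (F̄_g − F̄_{g−1})/(1 − F̄_{g−1}) with cohorts of one
generation-interval width anchored at the earliest birth year (the exact
cohorting convention is not standardized; this one is deterministic and
documented), and the trend test is an ordinary least-squares regression of
ΔF on cohort index.

## Founders, ancestors, and the conservation index

Expected founder contributions q_k are accumulated by halving each
reference animal's contribution up through its parents. Unknown parents of
non-founders become distinct *phantom founders*, so Σq_k = 1 holds exactly
and f_e = 1/Σq_k² is well defined even for ragged pedigrees.

The effective number of ancestors uses the greedy marginal-contribution
procedure: in each round the expected contributions are recomputed with all
previously selected ancestors acting as absorbing pseudo-founders (flow
reaching them is credited to them, not to their parents), each candidate's
value is further multiplied by one minus the fraction of its own genome
already explained by the selected set (a forward pass with selected
ancestors set to 1), and the maximum is selected. Ties break to the older
birth year — with unknown years sorting oldest — then the lexically
smaller id, making selection fully deterministic. Selection stops when the
cumulative explained contribution reaches 1 or the best marginal falls
below 1e-10. n_50 is the smallest prefix whose cumulative contribution
reaches 0.5; a 1e-9 slack guards against accumulated rounding at exactly
one half. The per-animal genetic conservation index is the same f_e
computed on the animal's own ancestry.

## Effective population size

Six pedigree estimators transform an estimate of ΔF into Ne = 1/(2ΔF):
ordinary least-squares regressions of F on maximum, complete, and
equivalent complete generations; regression of F on birth year scaled by
the generation interval L; the mean individual increase
ΔF_i = 1 − (1 − F_i)^(1/(t_i − 1)) over animals with equivalent complete
generations t > 1; and the log regression of ln(1 − F̄_g) on generation
number with Ne = −1/(2s). The seventh uses pairwise coancestries:
Δc_jk = 1 − (1 − c_jk)^(2/(g_j + g_k)) averaged over pairs. All
regressions are OLS (the methods this mirrors say "regression" without
qualification). Degenerate inputs — non-positive slopes, a pedigree with
no inbreeding, t ≤ 1 everywhere — return a *flagged* result carrying a
reason rather than a silent NA or a negative Ne; a numerically-zero slope
(|s| < 1e-12) counts as degenerate. Pair sets beyond 5 × 10⁶ are
subsampled with a recorded seed, since whole-breed pair counts are
otherwise intractable (restricting the reference to a recent cohort is the
usual practical remedy).

The genomic estimator is the linkage-disequilibrium method: the mean
squared dosage correlation over marker pairs on *different* chromosomes
(physical linkage would otherwise inflate r²), corrected for sample size S
by the expected no-LD value 1/S + 3.19/S² (S ≥ 30; the small-sample
coefficients 0.0018 + 0.907/S + 4.44/S² otherwise), inverted through
Ne = (1/3 + √(1/9 − 2.76 r̂²))/(2 r̂²) for the random-mating case. A
non-positive corrected r² is reported as an unbounded (flagged) estimate.
The confidence interval is a delete-one jackknife over individuals applied
to the corrected r², transformed through the monotone Ne formula; missing
dosages are mean-imputed once before correlation.

## Genotype quality control

`qc_pipeline()` reproduces the three-variant design used with
medium-density panels: after removing animals with unknown parentage (when
a pedigree is supplied) and animals with call rate < 0.90, autosomal
markers with call rate > 0.90 are kept; LD pruning (pairwise r² > 0.5
within 50-marker windows advancing by 5) gives the **full** set used for
MAF spectra, ROH and HBD (where fixed alleles are informative); removing
MAF < 0.01 from the full set gives the **reduced** set used for
heterozygosity, GRM, FST, PCA and LD-method Ne; removing MAF < 0.01 from
the *unpruned* markers gives the **LD** set used for decay curves. The
pruning rule — remove the lower-MAF member of the worst over-threshold
pair, ties to the later position — is deterministic, unlike
variance-inflation-driven orderings; window and step are configurable
because published analyses rarely print them. The report's removed and
retained counts close exactly at every stage and are tested to do so.

## Runs of homozygosity and the HBD model

ROH detection follows the sliding-window scheme: 50-SNP windows advance one
marker at a time; a window tolerating at most one heterozygous and one
missing call is *compliant* (for a 50-SNP window this is in effect a ~3%
allowance wide enough to absorb array-typical genotyping error); each SNP
is scored by the fraction of covering windows that are compliant and joins
a run when the score strictly exceeds 0.05. Maximal eligible stretches are
split at inter-marker gaps above 250 kb and kept as segments at ≥ 30 SNPs
and ≥ 1 Mb. Window scoring erodes a few SNPs at true tract edges — the
test suite asserts core recovery, and the detector is verified identical
to an exhaustive window-enumeration oracle on 500-SNP fixtures. F_ROH is
the summed segment length over the marker-covered autosome length (per
chromosome, last minus first position), decomposed into the 1–6, >6–12,
>12–24 and >24 Mb classes that proxy inbreeding age; the components sum to
the total exactly. Chromosomes shorter than one window are skipped and
recorded.

F_HBD comes from a deliberately minimal two-state hidden Markov model with
a single rate: the HBD state emits a heterozygote only through genotyping
error e and a homozygote in proportion to its allele frequency; the
non-HBD state emits Hardy–Weinberg probabilities; over a map distance d
Morgans the chain resets with probability 1 − exp(−R·d) into the prior
(ρ, 1 − ρ). Multi-class mixtures that partition HBD by segment age exist,
but the single-rate model has the same posterior semantics
(F_HBD = mean posterior HBD probability) while remaining fully specified
and cheap. Defaults: R = 20/Morgan (≈ 5 cM expected segments, i.e.
inbreeding within the last few generations), ρ = 0.05, e = 0.002;
optionally R is chosen per animal by likelihood over a log-spaced grid
(2⁰…2⁹). The forward–backward recursion is scaled per marker; forward and
backward total log-likelihoods are asserted to agree within 1e-8, and
allele frequencies are clamped to [1e-6, 1 − 1e-6] so fixed markers cannot
produce degenerate emissions. Missing genotypes are uninformative
(emission 1 in both states).

## GRM, heterozygosity, and structure

The VanRaden method-1 GRM is Z Z′/(2Σp(1−p)) with Z centered by 2p and
missing dosages mean-imputed (centered to zero); F_GRM = G_ii − 1. Allele
frequencies default to the analyzed sample — which is why F_GRM can be
strongly negative for animals less homozygous than the sample average —
with an option to supply base-population (founder) frequencies in
simulations. F_IND applies (H_E − H_O)/H_E per animal, with the animal's
own heterozygosity against the population H_E; Nei's non-biased
heterozygosity multiplies each marker's 2p(1−p) by 2n/(2n−1), and group
F_IS = 1 − H_O/Hnb is computed within groups.

Genomic flock differentiation uses the two-population Weir–Cockerham
variance components per marker, combined across markers as a ratio of sums
(not a mean of ratios), with negative estimates retained; markers
monomorphic across a pair carry no information and contribute zero
components. The bootstrap resamples markers with replacement (100
replicates by default) for percentile intervals; flocks with fewer than
two genotyped animals are excluded with a warning. PCA eigendecomposes the
VanRaden GRM of each subsample; because frequencies come from the
subsample itself the GRM is doubly centered, scores average zero, and the
percentage of variance uses the non-negative eigenvalue spectrum. Flocks
above the cap (default 30) are subsampled without replacement per
replicate; flocks at or under the cap enter complete.

## The simulator: what it emulates, and what it does not

`simulate_pedigree()` produces discrete generations dressed with
overlapping birth years (±1 year jitter around generation midpoints,
clamped after the parents' years), several flocks with offspring assigned
to the dam's flock, ram migration at a configurable rate, a progeny cap
per sire with a least-used fallback, and alternating offspring sexes
within flocks so no flock loses its rams by chance. Defaults (50 founder
rams, 200 founder ewes, 8 generations, 3 offspring per dam, 8 flocks, 10%
migration, 3-year spans) sketch a mid-size national flock book; they are
plausibility choices, not calibrated claims about any particular program,
since flock-size and mating-structure distributions of real programs are
not public.

`simulate_genotypes()` drops founder haplotypes through the pedigree.
Marker positions sit on a jittered regular grid — array-like spacing
matters because the ROH gap rule (250 kb) would shred runs under uniform
random placement, where spacing is exponential and long gaps are routine.
Founder allele frequencies are Beta(0.5, 0.5) truncated to [0.01, 0.5],
the U-shaped-then-filtered spectrum typical of a medium-density array
after its design MAF filter. Recombination is Haldane (no interference):
between adjacent markers the transmitted haplotype switches with
probability (1 − exp(−2d))/2, and a fresh 50/50 draw starts each
chromosome. Founder-origin labels travel with alleles, so true
autozygosity — the fraction of loci where an animal's homologs carry the
same founder-haplotype label — is exact. Genotyping error flips each
allele independently (symmetric, default 0.1%), and missingness (default
0.5%) is applied last, after truth is recorded.

Not emulated: selection on phenotypes, mutation, sex chromosomes,
chromosome-specific linkage maps, genotyping batch effects, and family
structure in missingness. Consequently, passing tests demonstrate that the
estimators recover truth under drift, inbreeding, and neutral transmission
— not that they are robust to selection-driven allele-frequency change or
array artefacts.

A statistical point the validation respects: conditional on one realized
pair of parents, the IBD sharing of their offspring deviates persistently
from the pedigree expectation (a full-sib pair may happen to inherit the
same grandparental haplotypes). Gene-dropping consistency is therefore
checked across *replicate genomes* — fresh founder haplotypes each time —
whose mean autozygosity must match pedigree F within ±0.02.

## Validation scales

The test suite checks Meuwissen–Luo F and AR against a brute-force tabular
relationship matrix to 1e-10 on 100 random pedigrees of 50–250 animals;
closed forms (full-sib line 0.25/0.375/0.5/0.59375, parent–offspring 0.25,
N balanced founders giving f_e = f_a = N and GCI = N) exactly; gene-drop
consistency over 200 replicate genomes; correlation of F_ROH and F_HBD
with exact truth (≥ 0.8) at 2,000 markers and 200 animals; recovery of a
simulated effective size of 50 by all seven pedigree estimators (medians
within [25, 100] over 20 replicates) and by the LD method (within a factor
of two in ≥ 80% of replicates at S = 50); ROH detection identical to
exhaustive enumeration on 500-SNP fixtures; Weir–Cockerham FST equal to 1
for fixed alternative alleles, covering 0 for arbitrary splits of one
population, and consistent with the drift expectation 1 − exp(−t/(2Ne))
after ten generations at Ne = 100; HMM forward/backward identities and an
independent log-space dynamic-programming oracle to 1e-8; and
Hardy–Weinberg null behaviour (|mean F_IND| < 0.01, mean F_HBD < 0.05) on
10,000 markers. These sizes keep the complete suite within a few minutes
on a single CPU while leaving each check statistically comfortable; the
acceptance script analyses a ~4,900-animal, six-flock population with
2,000 markers and 300 genotyped animals end to end.

## Known limitations

* The pedigree algorithms are pure R; whole-breed pedigrees (10⁵ animals)
  are fine for F, AR and group coancestries (linear passes), but the
  per-animal ancestor trace makes F computation noticeably slower than
  compiled implementations on very deep, highly inbred pedigrees.
* GCI materializes a sparse founder-proportion vector per animal; for very
  large pedigrees with many founders this is memory-heavy.
* The LD-method Ne assumes random mating and unlinked pairs; the
  inter-chromosomal restriction enforces the latter but residual
  admixture or overlapping generations bias it like any other use of the
  method.
* The single-rate HBD model cannot separate recent from ancient
  autozygosity the way multi-class models do; F_HBD is a total.
* The QC pruning rule is deterministic but not identical to
  variance-inflation-ordered pruning in existing tools, so marker lists
  (not downstream statistics) can differ slightly from theirs.
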