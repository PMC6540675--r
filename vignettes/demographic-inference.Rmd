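---
title: "Population-genetic diversity, differentiation and coalescent ABC demographic inference with gcpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic diversity, differentiation and coalescent ABC demographic inference with gcpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gcpop analyses co-dominant microsatellite genotypes and aligned
mitochondrial sequences for a single species sampled across locations,
and infers single-population demographic history by approximate Bayesian
computation (ABC) over seven piecewise-constant effective-size
scenarios.  This vignette explains the models and estimators, the
defaults and why they were chosen, what the synthetic-data generator
does and does not emulate, and the package's known limitations.

## Estimators

**Microsatellite diversity.**  Per population the package reports the
mean number of alleles per locus, observed heterozygosity, Nei's
unbiased expected heterozygosity (the small-sample correction
$2n/(2n-1)$ applied per locus), and the multilocus inbreeding
coefficient $F_{IS}$ from Weir–Cockerham variance components, with the
$b$ and $c$ components summed over alleles and loci before the ratio is
formed.  Hardy–Weinberg equilibrium is tested by shuffling the pooled
alleles of a population among its individuals at each locus; the
statistic is $|f|$ and p-values use the add-one permutation estimator
$(1+\#\{perm \ge obs\})/(1+B)$, which cannot return zero.  Linkage
disequilibrium between locus pairs is tested by a likelihood-ratio
statistic comparing EM-estimated two-locus gametic frequencies (phase
unknown; at most 1,000 iterations, log-likelihood tolerance $10^{-8}$,
initialized at the product of single-locus frequencies) against linkage
equilibrium, with the null generated by permuting one locus' genotypes
among individuals.

**Rarefaction.**  Allelic richness at $g$ gene copies is the exact
hypergeometric expectation
$A_r(g) = \sum_i [1 - \binom{N-N_i}{g}/\binom{N}{g}]$ per locus;
private allelic richness multiplies, for each allele, the probability of
presence in a rarefied sample of the focal population by the
probability of absence from rarefied samples of every other population.
Loci where any population has fewer than $g$ non-missing copies are
dropped from both means in all populations, so the per-location means
stay locus-matched.  The default $g = 16$ copies corresponds to the
smallest location in the study design (eight diploid genotypes).

**Differentiation.**  Pairwise $F_{ST}$ is Weir–Cockerham's $\theta$
(components summed over alleles and loci; negative estimates are
reported as computed and clipped at zero only in the display matrices).
Jost's $D_{est}$ uses the Nei–Chesser unbiased $H_S$ and $H_T$ per
locus, $D = [(\hat H_T - \hat H_S)/(1-\hat H_S)]\cdot n/(n-1)$ with
$n = 2$ demes, combined across polymorphic loci by arithmetic mean
(harmonic available by flag).  Note that with the unbiased estimators
$D_{est}$ is only asymptotically zero for identical allele-frequency
vectors; the plug-in version would be exactly zero.  $\Phi_{ST}$ is a
one-level AMOVA on the matrix of pairwise nucleotide differences
(pairwise deletion of ambiguous sites by default, complete deletion by
flag), with negative among-group variance components truncated at zero,
so identical compositions yield exactly 0 and fixed haplotype
differences yield exactly 1.  Significance for all three metrics comes
from permuting individuals (or sequences) between the pair of
populations; the FDR family is all pairs of one metric on one dataset
(Benjamini–Hochberg).

**Sequence statistics.**  Haplotype diversity is the unbiased
$h = \frac{n}{n-1}(1 - \sum p_i^2)$ with Nei's sampling variance;
nucleotide diversity is the mean number of pairwise differences divided
by the alignment length.  A caveat worth knowing: programs that exclude
gap- or N-containing columns report $\pi$ over the *net* number of
sites, which can shift the last printed digit relative to the full
alignment length (for the eight-sequence 6:2 worked example at 2,452
sites the exact value is 0.000175).  Tajima's $D$ uses the standard
$a_1,\dots,e_2$ constants and is undefined at $S=0$.  Fu's $F_s$
computes $S' = P(K \ge H_{obs})$ under the Ewens sampling distribution
with unsigned Stirling numbers of the first kind: an exact
double-precision table is used for $n \le 60$ and a log-domain
recurrence beyond (cached; stable for the sample sizes real datasets
reach), and $F_s = \ln(S'/(1-S'))$.  Significance for both statistics
comes from constant-size coalescent simulation conditioned on
$\theta = \bar k$ of the observed data (the convention of the software
family the statistics originate from), one-sided toward negative values
as expansion is the alternative of interest; a two-sided option exists
for $D$.  The conventional 0.02 significance threshold for $F_s$ is
noted in the report.

**Parsimony networks.**  The connection limit is the largest $j$ with
$P_j = \prod_{i=0}^{j-1}(1-i/L) \ge 0.95$: under uniform placement of
mutations over $L$ sites, $P_j$ is the probability that a $j$-step path
involves $j$ distinct sites (no superimposed change), a coalescent-free
simplification of the original statistical-parsimony estimator.  It
keeps the estimator's qualitative behaviour — $P_1 = 1$, monotone
decreasing in $j$, limit non-decreasing in $L$ — and gives a limit of
15 steps at $L = 2452$, comfortably above the one-to-two-step
separations seen in weakly structured mitochondrial data.  Networks are
built by joining haplotype clusters in increasing distance order up to
the limit, inserting $d-1$ single-step intermediate nodes per join;
ties are broken deterministically (larger cluster sample count, then
lexicographic haplotype order) so the construction is exactly
reproducible.  Ancestrality inference is deliberately not performed;
node sizes carry the frequencies.

## The demographic model and ABC engine

Seven piecewise-constant scenarios describe the history of one
population: recent ($t_1$) or ancient ($t_2$) decline or expansion
(scenarios 1–4), an expansion or bottleneck phase between generation 5
and $t$ (scenarios 5–6, the end fixed at five generations before
present), and constant size (scenario 7).  Sizes are diploid effective
sizes; mtDNA coalesces at rate $\binom{k}{2}/(N/4)$ per generation
(maternal haploid inheritance at even sex ratio) and autosomal loci at
$\binom{k}{2}/(2N)$.

Priors (overridable, stored with every reference table):
$N_0,N_1,N_b,N_e \sim U[10,10^4]$ diploid individuals — the upper bound
is implied by posterior 97.5% quantiles near $10^4$ in the source
analysis; $t_1 \sim U[5,500]$ and $t_2 \sim U[10^3, 5\times10^5]$
generations (stated ranges); $t \sim U[10, 10^3]$, wide enough to cover
the reported 97.5% quantile of 913.  Scenario inequalities are enforced
by rejection.  Mutation: a generalized stepwise microsatellite model
with mean rate $\bar\mu \sim U[10^{-4},10^{-3}]$ per locus per
generation, per-locus rates Gamma(shape 2) scaled to $\bar\mu$,
geometric step parameter $P \sim U[0.1,0.3]$, and 40 contiguous allele
states with reflecting bounds; sequences evolve under HKY85
($\kappa = 10$, mtDNA-like base frequencies) with
$\mu \sim U[10^{-8},10^{-7}]$ per site per generation.  These are the
defaults of the simulation-software family this engine mirrors.

The summary panel is fixed and ordered: microsatellites — mean allele
number, mean unbiased $H_E$, mean allele-size variance, mean M-ratio
(alleles / (range + 1)); sequences — $H$, $S$, $h$, $\pi$, Tajima's $D$
(imputed as 0 with an appended 0/1 indicator when $S = 0$, keeping
vectors fixed-length).  Distances are Euclidean after dividing each
statistic by its median absolute deviation over the whole table
(standard-deviation fallback for degenerate columns).

Model choice retains the closest 1% of rows, projects the normalized
statistics by linear discriminant analysis, and fits an
Epanechnikov-weighted multinomial logistic regression of scenario id on
the projections, evaluated at the observed point; the direct estimate
is the scenario composition of the 500 closest rows (capped at the
retained count, so a degenerate one-row retention gives that row's
scenario probability 1).  Parameter posteriors use the classical
local-linear adjustment: parameters are logit-transformed to their
prior bounds, regressed on the centred normalized statistics with
Epanechnikov weights, adjusted to the observed point, back-transformed,
and summarized by weighted median and 2.5/97.5% quantiles.  A singular
design falls back to the unadjusted rejection posterior with a warning.
Validation utilities simulate pseudo-observed datasets for posterior
error rates, and a predictive check reports each observed statistic's
quantile within each scenario's simulated marginal (flagging < 0.005 or
> 0.995).

Reference tables are generated in seeded chunks of 1,000 rows, so
serial and chunked execution produce identical tables, and the whole
pipeline is bit-reproducible from one seed.

## What the generator emulates, and what it does not

`make_fixture()` reproduces the study-shaped data: by default either
the island configuration (167 diploids × 27 loci; 39 sequences ×
2,452 bp) or a small "desk" preset (30 × 10; 15 × 600 bp) for fast
runs.  `make_multipop_fixture()` labels one panmictic coalescent sample
by location (the weak-structure regime) or simulates fully independent
populations (for differentiation power checks).  The generator does not
emulate genotyping artifacts (null alleles, allelic drop-out, binning
error), migration at intermediate rates, or linked loci; passing tests
on fixtures therefore demonstrates correctness of the estimators and
the inference machinery under the model, not robustness to those
real-data complications.

## Problem sizes and numerical choices

The validation experiments in the test suite use a reference table of
$10^4$ rows per scenario at the island sampling configuration, 20
fixed-parameter bottleneck pods ($N_1 = N_0 = 5000$, $N_b = 50$,
$t = 300$) for recovery and coverage, and 500 prior-drawn pods for the
posterior error rate; parameter posteriors at this table size retain
5% of the scenario's rows (500), since the classical 1% would leave
only 100.  A note on scale: at the desk preset the same strong
bottleneck produces nearly monomorphic panels (mean allele number
about 1.5), and all small-recent-size scenarios become almost
indistinguishable — scenario recovery collapses toward prior mass.
The island-scale configuration restores discrimination, which is why
the validation experiments run at that scale.  Even there, prior draws
with weak (N_b close to N_0, N_1) or short (t near 10 generations)
bottlenecks are intrinsically confusable with the decline and
constant-size scenarios, so the posterior error rate over prior-drawn
pods remains substantially higher at a $10^4$-row table than the error
a $10^6$-row table yields; the package reports the measured value
rather than targeting a literature figure.

Other numerical conventions: permutation p-values use the add-one
estimator; monomorphic loci have HWE p = 1 by convention; the EM for
gametic frequencies flags non-convergence and reports the best
likelihood reached; rarefaction uses log-binomials to avoid overflow;
weighted quantiles are of the left-continuous inverse-CDF type;
Epanechnikov weights degenerate to uniform when all retained distances
are zero.

## Limitations

The ABC model is single-population; spatial structure, migration and
linked loci are out of scope.  The statistical-parsimony probability
uses the simplified non-homoplasy estimator described above, not the
original cladogram-estimation refinements.  Dest's unbiased estimator
is not exactly zero under identical compositions (see above).  The
sequence mutation process is an event-based HKY85 approximation that
draws the number of events from the mean rate rather than integrating
base-specific rates; at mitochondrial divergence levels the difference
is negligible but it is not an exact GTR simulator.
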