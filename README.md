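# gcpop

Population-genetic analysis and coalescent ABC demographic inference for
a single species genotyped at microsatellite loci and sequenced at
mitochondrial markers — the setting of large marine vertebrates such as
sharks, where structure is weak, samples are hard-won, and the question
of interest is whether the population went through a bottleneck.

The package covers, in one coherent toolchain:

* **Diversity** — allele counts, observed and Nei-unbiased expected
  heterozygosity, Weir–Cockerham *F*<sub>IS</sub>, permutation tests for
  Hardy–Weinberg equilibrium and (EM likelihood-ratio) linkage
  disequilibrium, and exact-hypergeometric rarefied allelic and private
  allelic richness *A*<sub>r</sub>(*g*), *A*<sub>rp</sub>(*g*).
* **Differentiation** — pairwise Weir–Cockerham
  θ (*F*<sub>ST</sub>), Jost's *D*<sub>est</sub> (Nei–Chesser unbiased
  estimators), and AMOVA Φ<sub>ST</sub> on pairwise nucleotide
  differences, each with permutation p-values and Benjamini–Hochberg FDR
  per matrix.
* **Sequence statistics** — haplotype/nucleotide diversity with sampling
  SDs, Tajima's *D* and Fu's *F*<sub>s</sub> (exact Ewens/Stirling
  evaluation) with significance from a constant-size coalescent null
  conditioned on θ = k̄.
* **Statistical-parsimony haplotype networks** with a 95% connection
  limit and deterministic construction, exported as GraphML.
* **Demographic ABC** — a compiled coalescent simulator of seven
  piecewise-constant effective-size scenarios (declines, expansions, a
  bottleneck or expansion phase ending five generations ago, constant
  size) under a generalized stepwise microsatellite model and HKY85
  sequences; reference tables; scenario choice by rejection and by
  LDA-transformed, Epanechnikov-weighted multinomial logistic
  regression; local-linear regression-adjusted parameter posteriors
  (*N*<sub>0</sub>, *N*<sub>1</sub>, *N*<sub>b</sub>, *t*); posterior
  error rates and predictive checks.
* **Synthetic data with known truth** (`make_fixture()`,
  `make_multipop_fixture()`) and an end-to-end pipeline
  (`run_pipeline()`) emitting delimited reports and a JSON manifest,
  bit-reproducible from one seed.

The central model-fitting interface is `abc_fit(genotypes, sequences,
table)`, which returns a classed object with `print`, `summary`,
`coef`, `predict`, `plot` and `simulate` methods.

## Worked example

Simulate a strong-bottleneck dataset with known truth
(*N*<sub>1</sub> = *N*<sub>0</sub> = 5000 diploids, *N*<sub>b</sub> = 50
from generation 300 to 5), build a small reference table, and fit:

```r
library(gcpop)

fx <- make_fixture(6, params = c(N0 = 5000, N1 = 5000, Nb = 50, t = 300),
                   preset = "desk", seed = 42)
diversity_stats(fx$genotypes, "RUN", rarefaction_g = 16)
#> Population RUN: N = 30, 10 loci (rarefied to g = 16 copies)
#>   Na = 1.80  Ho = 0.193  He = 0.158  FIS = -0.225
#>   Ar(16) = 1.58 (0.24)  Arp(16) = 1.58 (0.24)

tab <- build_reference_table(n_per_scenario = 1000, seed = 1)
fit <- abc_fit(fx$genotypes, fx$sequences, tab)
summary(fit)
#> Scenario choice:
#>  scenario direct logistic ...
#>         6 0.1286   0.8763
#> Selected scenario: 6 (logistic), 2 (direct)
#>
#> Parameter posterior:
#>    Median 2.5% quantile 97.5% quantile
#> Nb   77.0          17.1          314.2
#> t   650.2         108.4          975.2
#> ...
#> Predictive check: 4 of 70 scenario x statistic marginals flag the observation
```

The low heterozygosity and allele counts are the bottleneck's signature;
the logistic posterior concentrates on the bottleneck scenario and the
95% credible interval for *N*<sub>b</sub> (17–314) covers the generating
value 50.  `coef(fit)` returns the posterior medians,
`predict(fit, newdata)` classifies further datasets, and
`simulate(fit, nsim)` draws posterior-predictive summary panels.

A shell entry point for the pipeline lives at `inst/cli/gcpop.R`:

```sh
Rscript inst/cli/gcpop.R run --config config.yaml
```

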