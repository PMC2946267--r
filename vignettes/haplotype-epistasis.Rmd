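---
title: "Modelling haplotype-haplotype epistasis with adaptively penalized logistic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling haplotype-haplotype epistasis with adaptively penalized logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapepi)
```

## The problem

Case-control association studies routinely interrogate single SNPs, but many
disease signals live in *interactions* between genomic regions — including,
in perinatal genetics, interactions between the maternal and the fetal
genome. Single-SNP interaction scans capture only part of the variation in a
gene; haplotypes (the ordered alleles along one chromosome copy) carry more.
`hapepi` models the interaction between two *haplotype blocks* of two SNPs
each, estimating interpretable genetic effects rather than only testing for
association.

Two obstacles shape the method. First, with two blocks there are 81 possible
genotype combinations but far fewer subjects per cell than a saturated model
would need; second, unphased genotypes do not always identify the haplotype
pair. The model answers the first with a *composite diplotype* reduction and
a sparsity-inducing penalty, and the second with an EM treatment of phase
ambiguity.

## Composite diplotypes and the risk haplotype

For one block, the four haplotypes are `[11], [12], [21], [22]` (allele 1 =
major, 2 = minor, one digit per SNP). One haplotype is singled out as the
*risk haplotype* `H`; all others are collapsed into `H̄`. Every subject then
carries 2, 1 or 0 copies of `H` — the composite diplotypes `HH`, `HH̄`,
`H̄H̄`. This reduction is what keeps the parameter count fixed (eight genetic
effects) no matter how polymorphic the region is.

Of the nine unphased two-SNP genotypes, eight imply a unique haplotype pair.
The double heterozygote 12/12 is compatible with two configurations,
`[11][22]` and `[12][21]`; under Hardy-Weinberg equilibrium the first has
conditional probability

$$\phi = \frac{p_{11}p_{22}}{p_{11}p_{22} + p_{12}p_{21}}$$

given the genotype. Whichever configuration contains the risk haplotype
contributes a single copy (`HH̄`), the other none (`H̄H̄`), so the 12/12
genotype is a two-component mixture with weights determined by `phi`. Block
haplotype frequencies are estimated once, from all subjects pooled, by the
standard EM for the double-heterozygote split, and held fixed; `phi` is
computed from them. (Control-only estimation is available via
`freq_from = "controls"`; pooling is the default because the mixture prior
describes genotype structure, not disease risk, and pooled estimates are more
precise. The package treats this as a configuration choice, not a finding.)

## The genetic model

With composite diplotypes for blocks $s$ and $t$, the nine cell means follow
the Cockerham orthogonal partition

$$\mu_{st} = \mu + a_s x_s + a_t x_t + d_s z_s + d_t z_t +
  i_{aa} x_s x_t + i_{ad} x_s z_t + i_{da} z_s x_t + i_{dd} z_s z_t,$$

with additive scores $x = 1, 0, -1$ and dominance scores
$z = -\tfrac12, \tfrac12, -\tfrac12$ for 2, 1, 0 risk copies. The eight
coefficients $\beta = (a_s, a_t, d_s, d_t, i_{aa}, i_{ad}, i_{da}, i_{dd})$
are the additive and dominance main effects and their four interactions. At
allele frequency one half the columns are exactly orthogonal (the package
tests this); at general frequencies they are merely well-behaved, and no
orthogonality is assumed anywhere.

The binary phenotype enters through a logistic model,
$\operatorname{logit} P(y_i = 1) = x_{ig}\beta + x_{ie}\gamma$, where
$\gamma$ holds the intercept and any covariates. Covariates are adjusted for
but never penalized.

## Adaptive L1 penalty and its tuning

The coefficients are estimated by minimizing

$$L' = -2L + \lambda \sum_{j=1}^{8} w_j\,|\beta_j|,$$

an adaptive LASSO with data-dependent weights $w_j = 1/|\hat\beta_j|$, where
$\hat\beta$ is the unpenalized maximum-likelihood fit (phase-weighted by the
same EM machinery, computed by damped Newton iteration). Adaptive weighting
is what gives the estimator its oracle property: strong effects are penalized
lightly, noise effects heavily. Numerical guardrails: $|\hat\beta_j|$ is
floored at $10^{-3}$ (weights capped at 1000), and if the unpenalized fit
separates or fails to converge, a ridge-stabilized reference fit (quadratic
coefficient $10^{-4}$) supplies the weights, with a warning.

$\lambda$ runs over 50 log-spaced values (20 in the fast simulation studies)
from $\lambda_{\max}$ — the smallest value at which all eight effects stay
zero, computed from the null-model score — down to $\lambda_{\max}/1000$,
warm-starting each fit from its predecessor. Each candidate is scored by
$\mathrm{BIC} = -2L + d\log n$ with $d$ the number of nonzero genetic effects
plus all unpenalized parameters; the minimum wins and ties go to the sparser
(larger-$\lambda$) model.

## Phase ambiguity and the EM loop

Subjects are grouped by which blocks are double-heterozygous: neither (M1),
only $s$ (M2), only $t$ (M3), both (M4). Ambiguous subjects contribute
mixture terms; the complete-data log-likelihood weights each candidate
configuration by an indicator the E-step replaces with its posterior
expectation,

$$E(c_{ji}) = \frac{\phi_j\,\pi_1^{y_i}(1-\pi_1)^{1-y_i}}
  {\phi_j\,\pi_1^{y_i}(1-\pi_1)^{1-y_i} + (1-\phi_j)\,\pi_0^{y_i}(1-\pi_0)^{1-y_i}}.$$

For M4 subjects the package weights the four joint cells by their joint
posterior (whose margins are exactly the printed conditional expectations);
using products of the margins instead would not be a valid EM and can
increase the objective. The M-step minimizes the penalized objective at fixed
weights; the loop alternates until the largest coefficient change falls below
$10^{-6}$ (at most 200 iterations, flagged if exceeded). The observed-data
penalized objective is recorded each iteration and is non-increasing — the
test suite audits this on every fitted model.

## The Gauss-Seidel maximum-violator solver

The M-step objective is convex but has kinks at zero. The solver works one
coordinate at a time, driven by the first-order conditions: writing
$F_j = \partial(2L)/\partial\beta_j$, optimality requires $F_j = 0$ for
unpenalized coordinates, $F_j = \pm w_j\lambda$ on the active signs, and
$|F_j| \le w_j\lambda$ at zero. Each coordinate's *violation* measures its
distance from these conditions; the algorithm repeatedly brings the worst
violator among the zero coefficients into the active set, then cleans the
active set by its own worst violators, until every violation is below
$10^{-5}$. A single-coordinate update is an exact scalar solve: the
subgradient test decides whether the coordinate stays at the kink, otherwise
bracketed Newton solves $F_j(b) = \pm w_j\lambda$ on the appropriate side.

Two numerical choices matter in practice. Internally the solver standardizes
columns to unit weighted root-mean-square — an exact reparameterization,
mapped back on exit — because the raw codes ($x = \pm 1$ against
$z_s z_t = \pm\tfrac14$) differ enough in scale to slow one-coordinate
descent badly. And probabilities are clipped to $[10^{-12}, 1-10^{-12}]$
before logs, with a separation flag raised when any $|\eta| > 30$. The update
cap is 10,000 coordinate moves; exceeding it is an error carrying the
residual violation, which in the pipeline only arises for the unpenalized
reference fit on quasi-separated data — precisely the case the ridge
fallback handles.

## Risk-haplotype selection and permutation p-values

Every haplotype of each block is a candidate risk haplotype: all $4\times4$
ordered pairs are fitted end-to-end (mapping, `phi`, adaptive weights,
$\lambda$ path) and compared by BIC; ties break lexicographically so results
are deterministic. Empirical p-values for the selected effects come from
phenotype permutations: each permutation re-runs weights and the full
$\lambda$ path with the risk pair held fixed at the observed winner, and
effect $j$ scores a hit when its permuted estimate is nonzero;
$p_j = \#\text{hits}/n_{\text{perm}}$ (1000 by default). Re-searching the
risk pair inside each permutation is available (`re_search = TRUE`) but
roughly 16 times slower; holding the selected model fixed matches the usual
reading of "permute and refit the model". Across many scanned block pairs no
multiplicity correction is applied by default; `bonferroni_adjust()` is
provided.

A selected interaction has a direct epidemiological reading:
`risk_group_odds()` groups the nine composite-diplotype cells by their
interaction code and reports odds ratios $\exp(\text{code}\times\beta)$
against the zero-code reference — for an additive-by-dominance effect the
three groups have log-odds $\mu$, $\mu - i_{ad}/2$ and $\mu + i_{ad}/2$.

## What the simulator emulates

`simulate_epistasis_data()` reproduces the structure the model assumes: two
independent blocks, haplotypes drawn i.i.d. under Hardy-Weinberg equilibrium
with per-SNP minor allele frequencies 0.3 and 0.4 and within-block linkage
disequilibrium $D = 0.02$ (haplotype frequencies 0.44/0.26/0.16/0.14), a
designated risk pair (default `[11]`, `[11]`), and phenotypes drawn from the
logistic model at scenario-specific effect vectors (`S0` null through `S4`
main-plus-interaction, magnitude 0.8) with the intercept calibrated by root
finding so the expected case fraction is one half. Phase is discarded from
the observable output but kept in a `truth` slot so tests can run the
pipeline in oracle-phase mode.

What it deliberately does not emulate: linkage between the two blocks,
population structure, genotyping error, missingness, covariate confounding,
or deviation from HWE. Passing simulation tests therefore demonstrates
correctness of the estimator under its own assumptions, not robustness to
real-data violations of them.

`run_scenario_study()` wraps the Monte-Carlo design: per scenario and sample
size it simulates, fits (fixed true risk pair or full search) and tabulates
per-effect selection proportions — false selection rates under `S0`,
selection power elsewhere. The conventional design uses 200 replicates and
the 50-point path with the risk search. The package's own studies use a
20-point path and the fixed true risk pair; the null-scenario
false-selection study keeps the full 200 replicates (at 50 the proportions
are multiples of 0.02, too coarse to resolve a 5% level across eight
parameters), while the power and recovery studies use 50 replicates so a
full run stays in the minutes range on one core. These sizes are the
package's chosen study conditions; replicate seeds derive from one base
seed, so every study is exactly reproducible.

## Degenerate inputs and edge behaviour

* A block where every subject is 12/12 leaves the frequencies
  non-identifiable (only $p_{11}p_{22}+p_{12}p_{21}$ is determined); the
  symmetric solution is returned, flagged and warned about.
* $p_{12} = 0$ or $p_{21} = 0$ forces $\phi = 1$: the E-step then fixes
  $E(c) = 1$ regardless of coefficients.
* Subjects with any missing genotype among the four SNPs are dropped with a
  message before fitting.
* $\lambda = \infty$ is used internally for the null fit; the penalty term is
  defined as 0 when all genetic effects are zero, keeping BIC finite.
* A permutation replicate that fails to fit counts as a non-hit (and is
  warned about), keeping $p_j = \#\text{hits}/n_{\text{perm}}$ exact.

## Known limitations

Blocks are limited to two SNPs; for larger blocks only the combinatorial
accounting (`count_block_states()`) is provided — a three-SNP block has 7
phase-ambiguous genotypes and two such blocks give 16 mixture cells, which
the same likelihood architecture would carry but this package does not fit.
The genome-scan entry point is a plain iterator over user-defined block
pairs, not a windowing engine, and no standard errors are reported for
penalized estimates (permutation p-values are the supported inference).
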