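---
title: "Linking rates of molecular and phenotypic evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking rates of molecular and phenotypic evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratelink)
```

## The problem

Classical comparative tests for genotype–phenotype associations regress a
trait's *value* on a gene's strength of molecular selection (dN relative to
dS). Such tests only detect genes whose protein-coding change pushed the
trait consistently in one direction. A gene that drove both increases and
decreases — or that acted to *suppress* change — is invisible to them.

`ratelink` implements an association test that is agnostic to
directionality: it asks whether the *rate* of phenotypic evolution along
the branches of a phylogeny covaries with the *rate* of protein-coding
evolution of a candidate gene. Three per-species quantities are combined:

* `R_phen` — the root-to-tip sum of rate-scaled branch lengths
  (time × posterior-median rate scalar) from a variable-rates model of the
  trait; a species' accumulated amount of phenotypic-rate change.
* `R_dN`, `R_dS` — root-to-tip sums of branch-wise non-synonymous and
  synonymous rates from a codon model of the gene.

Two Bayesian phylogenetic regressions (PGLS with Pagel's lambda) then
separate level effects from rate effects:

1. `testes ~ R_dN + R_dS + body` — a *directional* (level) association;
2. `R_phen ~ R_dN + R_dS + testes + body` — a *rate* association.

The joint pattern of significance and sign classifies a gene as a
bidirectional or directional rapid driver, a moderator (plain or
directional), a directional non-rapid driver, or unassociated.

## The variable-rates regression model

Log testes mass is regressed on log body mass with a separate intercept
and slope per clade. The residual evolves by Brownian motion with
covariance `sigma2_b * V(r)`, where `V(r)` is the phylogenetic covariance
of the tree after each branch length `t_b` is multiplied by a scalar
`r_b >= 0`; branches outside the scaled set have `r_b = 1`.

Priors (not stated by the upstream method descriptions; chosen here to be
weakly informative and fully testable by recovery):

* coefficients: flat (a ±100 uniform box in marginal-likelihood runs);
* `sigma2_b`: scale-invariant `1/sigma2` (log-uniform box in
  marginal-likelihood runs);
* number of scaled branches: uniform on `0..B` via reversible jump;
* log scalars: Normal(0, 1.5²).

The sampler is Metropolis-within-Gibbs with a collapsed reversible-jump
step: for scalar-set moves the coefficients and `sigma2_b` are integrated
out analytically (flat and scale-invariant priors give a closed-form
marginal), so birth/death/perturb proposals are judged by their marginal
merit; the coefficients and `sigma2_b` are then drawn from their exact
conditionals. Collapsing matters in practice: judging scalar moves at a
fixed `sigma2_b` lets the chain wander into a mode where an inflated
background rate absorbs genuine branch-rate heterogeneity. Birth values
are proposed from a wider Normal(0, 2.2²) than the prior (corrected in the
acceptance ratio) so that large scalars such as r = 16 are reachable.

The rate-scaled (`rt`) tree multiplies each branch length by the posterior
median of its scalar, counting unscaled samples as r = 1. Branch identity
is the sorted set of tip labels below the branch, which survives
serialization and pruning.

Marginal likelihoods come from a stepping-stone sampler with temperatures
at Beta(0.40, 1) quantiles and log-sum-exp accumulation; the Bayes factor
is reported as `BF = 2 (log m1 - log m0)` with positive values favouring
the variable-rates model. (The widespread formula written as
`-2 log_e[m1/m0]` yields the opposite sign for the same comparison; the
convention here keeps reported support positive, as in published
applications.) The defaults (100 stones × 10⁴ iterations) are desk-scale;
the published analyses of this model family use 500 stones of 10⁶
iterations, which is a configuration choice, not a code path.

## The codon model

MG94xREV: codon substitution rates are nonzero only between codons
differing at a single nucleotide position; the rate is the GTR
exchangeability of the nucleotide pair times the position-specific F3x4
frequency of the target nucleotide, times a synonymous (`dS_b`) or
non-synonymous (`dN_b`) branch rate. Equilibrium frequencies are F3x4 with
zero-frequency nucleotides floored at 1e-6. No site-to-site rate
variation is modelled. Gaps and ambiguous codons are missing data
(partial likelihood 1). The genetic code is the universal code's 61 sense
codons.

Two nested fits:

* **global** — one shared dN/dS ratio omega; per-branch time-scales
  absorb the synonymous rate (alpha fixed to 1, so `dS_b = t_b`,
  `dN_b = omega t_b`); `5 + 1 + E` parameters.
* **local** — free `(dS_b, dN_b)` per branch with shared
  exchangeabilities; branch lengths are absorbed into the rates (the
  estimates are time-independent); `5 + 2E` parameters.

The likelihood-ratio statistic `D = 2 (lnL_local - lnL_global)` is
referred to chi-squared with `df = E - 1`. Under null simulations the
empirical D distribution matches this reference closely (the test suite
checks the rejection rate; a 40-replicate pilot gave mean D 14.9 against
df 16 with a Kolmogorov–Smirnov p of 0.57).

Optimization is coordinate ascent: Nelder–Mead over the five free
exchangeabilities (AG fixed to 1), Brent or Nelder–Mead per branch against
per-edge likelihood contexts, iterated to a log-likelihood tolerance
(default 1e-4). Edge sweeps are exact and incremental: edges are visited
in preorder while "up" partials carry already-updated transition matrices
and cached per-edge contributions carry the rest, so each edge optimizes
against the current state of every other edge at the cost of one postorder
pass per sweep. Transition matrices use the symmetrized eigendecomposition
of the reversible generator; in the global model all branches share one
generator up to scale, so a single decomposition serves every branch and
every candidate length. The local fit is seeded from the global fit,
which also enforces the nesting inequality numerically. By default the
exchangeabilities are re-optimized only in the global fit and inherited by
the local fit (both models contain them; this is a fitting-order choice
that roughly halves runtime with no measurable effect on D in null
calibrations).

The branch-wise dN and dS estimates are carried as branch lengths of two
rate trees. These are rooted on the outgroup, the outgroup is dropped,
and root-to-tip sums give `R_dN` and `R_dS` per species. All sums and
masses enter the regressions as log10 values (sums are floored at 1e-8
before logging).

## Bayesian PGLS with Pagel's lambda

Residual covariance `sigma2 * V(lambda)` where `V(lambda)` multiplies the
off-diagonal entries of the time-tree covariance by `lambda` in `[0, 1]`.
Priors: coefficients flat, `sigma2` scale-invariant, `lambda` uniform.
Coefficients and `sigma2` are drawn from exact conditionals; `lambda`
moves by a reflected random walk. A one-time spectral reduction of the
lambda family (`V(lambda) = D^{1/2}(lambda W + (1-lambda) I) D^{1/2}`)
makes each lambda evaluation O(np), so desk-scale chains take well under a
second.

Significance is summarized by `p_x`, the fraction of a coefficient's
posterior on the minority side of zero, with samples exactly at zero
counted as crossing (conservative); `p_x < 0.05` is read as significant.
The published description of the chain ("1 million iterations, sampling
every 500 thousand") would retain about two samples and is presumed a
typo; the defaults here retain 1,000 thinned samples.

## The synthetic benchmark

The generator emulates the study's three inputs: a time-calibrated
phylogeny (pure-birth, rescaled to 300 Myr), a trait table (clade-specific
testes/body allometries with a Brownian phylogenetic residual), and
per-gene codon alignments evolved under MG94xREV along the same tree plus
an outgroup.

Default conditions (one-time choices, in units a comparative biologist
would recognise):

* 64 taxa, 300 Myr depth, five clades with allometric slopes near 0.7 and
  intercepts within 0.1 log10 g of each other;
* body mass Brownian rate 0.01 log10-g²/Myr from a 100 g root;
* residual background rate `sigma2_b` = 0.001 log10-g²/Myr; a planted
  rate burst multiplies it by 16 on the fast-branch set;
* codons: 300; GTR exchangeabilities with transition/transversion bias;
  synonymous rate 0.0025/Myr; baseline omega 0.2; every branch's rates
  are additionally jittered by a log-normal with sd 0.5 — like the
  control genes in real data, *every* simulated gene shows
  branch-to-branch rate variation, association or not.

The fast-branch set can be independent terminal branches (`"tips"`, the
default: many phylogenetically unconfounded bursts, each individually
detectable), a single deep clade (`"clade"`, the x16 recovery scenario),
disjoint subclades, or scattered branches. The clade burst deliberately
leaves the clade's stem unscaled: a x16 stem makes the entire clade's
trait level drift as one enormous excursion, which reads as a directional
(level) effect rather than a rate effect. Three designs that do *not*
work at desk scale -- and why -- are worth recording: a single clade-wide
burst is exactly the signal Pagel's lambda discounts (a clade-aligned
covariate carries about one effective degree of freedom in PGLS);
scattered internal branches and shallow subclades leave variance
signatures too weak for the variable-rates model to recover; and
suppressing a few branches barely moves a root-to-tip *sum*, so moderator
genes cannot be planted by slowing gene branches down.

Genes couple to the phenotype through two channels:

* **realized-rate coupling** (`rate_coupling`): terminal branches are
  classed as realized-fast when their squared standardized trait
  increment exceeds 9 (a 3-sigma excursion). Positive coupling `c`
  multiplies non-synonymous rates on realized-fast terminals by `1 + c`
  (drivers); negative coupling applies the boost to every branch off the
  realized-fast species' paths instead, so moderator genes accumulate
  protein change exactly where the phenotype stagnated, averaged over
  many branches rather than riding one terminal's rate jitter. Coupling
  to the *realized* speed rather than the latent planted set is the fair
  test of the pipeline: the variable-rates model can only ever see
  realized changes.
* **directional coupling** (`gamma`): rates are multiplied by
  `exp(gamma z_b)` with `z_b` the signed standardized increment, so
  root-to-tip dN tracks the final trait value.

A set-based variant (multiply `dN_b` by `1 + c` on the planted fast set,
or on branches off every planted fast path) is also provided.

The six benchmark archetypes are built from these channels
(`benchmark_archetypes()`); their effect sizes were fixed once by pilot
power runs of the full pipeline at the benchmark scale (48 taxa,
150 codons, burst scalar 36 on a quarter of the terminals -- the published
analyses' sample sizes, roughly 100-600 sequences and 2,036 trait
species, are far beyond desk scale, and these conditions are the smallest
at which all three estimation stages retain useful power). Pilot
recovery rates over eight replicates were 7/8, 8/8, 6/8, 5/8, 7/8 and
7/8 across the six archetypes. The pilot script is shipped under
`inst/scripts/pilot-calibration.R`.

What passing benchmarks do **not** show about real data: alignments here
are error-free, orthology is perfect, the trait model is exactly the
fitted model (no measurement error, no non-Brownian tails), and the
planted couplings are stylized. The benchmark validates the inference
machinery, not the biology of any particular gene.

## Numerical choices

* Phylogenetic covariances get a relative jitter of 1e-10 × mean
  diagonal before Cholesky factorization; singular matrices raise an
  error that reports the reciprocal condition number.
* Transition-matrix reconstruction clips tiny negative entries to zero
  and renormalizes rows.
* Pruning partials are rescaled per site pattern when they fall below
  1e-200, with log scale factors carried alongside.
* Log branch rates are bounded in [-14, 3] during optimization.
* Ties at exactly zero in `p_x` count as crossing.
* All samplers and simulators are deterministic functions of an integer
  seed; identical seeds give byte-identical outputs.

## Desk-scale problem sizes

The package's validation studies are sized for a single CPU: likelihood
oracles use 2–6 taxa; LRT calibration uses 10 taxa × 100 codons over
dozens of replicates; omega recovery uses 12 taxa × 200 codons; the
sigma2_b coverage study uses 24-taxon trees; the end-to-end benchmark uses
48 taxa × 120 codons with short chains. These sizes are stated here as
the package's own validation choices; all are configurable upward, and
the full-scale published settings (10⁹ MCMC iterations, 500-stone
stepping stones, hundreds of taxa) are reachable through the same
configuration objects.

## Known limitations

* Whole-clade (node) rate scalars are not modelled — branch scalars only.
* No site-to-site rate variation in the codon model (by design).
* The local codon model estimates 2 parameters per branch; on very short
  alignments the chi-squared reference for D becomes approximate.
* PGLS assumes a homoscedastic Brownian residual; under extreme planted
  rate bursts the directional (level) test is mildly anti-conservative,
  which is visible in the benchmark as occasional spurious directional
  labels for purely rate-coupled genes.
* Leave-one-species-out reruns hold the molecular and phenotypic rate
  estimates fixed by default (re-estimation per exclusion is available
  but costly).
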