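# ratelink

Detecting genotype–phenotype associations across species — regardless of
the direction of phenotypic change.

## The problem

Comparative tests that regress a trait's *value* on a gene's strength of
molecular selection (dN relative to dS) can only find genes that pushed
the trait consistently up or consistently down. A gene that drove both
increases and decreases, or that acted to *suppress* change, leaves no
directional signal. `ratelink` implements a rate-based test: it asks
whether the *rate* of phenotypic evolution along each branch of a
phylogeny covaries with the *rate* of protein-coding evolution of a
candidate gene, and classifies genes accordingly.

For species *i* with root-to-tip path *P(i)* on a time tree with branch
lengths *t_b*:

* a Bayesian **variable-rates regression** of log₁₀ testes mass on log₁₀
  body mass (clade-specific allometries) estimates a background Brownian
  rate σ²_b and branch-specific rate scalars *r_b* in its phylogenetic
  residual (reversible-jump MCMC; support for rate heterogeneity is a
  stepping-stone Bayes factor). The phenotypic rate path sum is
  *R*_phen(*i*) = Σ_{b∈P(i)} *t_b* · median(*r_b*);
* an **MG94xREV codon model** with free per-branch synonymous and
  non-synonymous rates (the *local* model) is compared with a shared-rate
  *global* model by a likelihood-ratio test *D* = 2(lnL_local −
  lnL_global); the branch estimates give *R*_dN(*i*) = Σ_{b∈P(i)} dN_b
  and likewise *R*_dS;
* two Bayesian **PGLS** regressions with Pagel's λ separate level from
  rate effects: (i) testes ~ *R*_dN + *R*_dS + body, and (ii) *R*_phen ~
  *R*_dN + *R*_dS + testes + body. Significance is *p*_x, the minority
  fraction of a coefficient's posterior across zero.

The joint sign/significance pattern maps each gene onto a six-way
taxonomy: bidirectional or directional rapid driver, moderator,
directional moderator, directional non-rapid driver, or no association.

A rate-coupled simulator (`simulation_scenario()`,
`generate_benchmark()`) produces trees, trait tables and codon alignments
with known planted couplings, and is the package's test harness.

## Worked example

Simulate a benchmark bundle, estimate phenotypic rates, and run the
association pipeline on a planted driver gene:

```r
library(ratelink)

scenario <- simulation_scenario(n_taxa = 32, ncodons = 120, r_scalar = 36,
                                fast_prob = 0.5)
bench <- generate_benchmark(tempfile("bench"), seed = 42,
                            scenario = scenario)

design <- regression_design(bench$traits, bench$ingroup_tree)
vr <- varrates_mcmc(design, bench$ingroup_tree,
                    varrates_config(iterations = 3e4, samples = 500),
                    seed = 42)
rt <- median_rate_tree(vr)

res <- run_gene_association(
  file.path(bench$dir, "gene_bidirectional_rapid_driver.fasta"),
  bench$traits, bench$tree, rt$tree, outgroup = "Outgroup",
  gene = "driver42", seed = 42)
res
tidy(res)
```

Output (seed 42):

```
<gene_association> driver42
  N_taxa = 32; LRT D = 297.1 (df 62, p = 2.07e-32)
  classification: bidirectional_rapid_driver

# A tibble: 9 x 6
  gene     model         term              estimate     sd   p_x
1 driver42 testes ~ R_dN (Intercept)        -2.03   0.587  0.002
2 driver42 testes ~ R_dN R_dN                0.336  0.651  0.285
3 driver42 testes ~ R_dN R_dS               -0.887  2.01   0.331
4 driver42 testes ~ R_dN body_mass_log10     1.04   0.133  0
5 driver42 R_phen ~ R_dN (Intercept)         2.89   0.0814 0
6 driver42 R_phen ~ R_dN R_dN                0.332  0.0613 0
7 driver42 R_phen ~ R_dN R_dS                0.0813 0.250  0.405
8 driver42 R_phen ~ R_dN testes_mass_log10   0.0519 0.0198 0.007
9 driver42 R_phen ~ R_dN body_mass_log10    -0.0435 0.0266 0.054
```

Reading it: the branch-variation LRT (D = 297.1 on 62 df) confirms
branch-to-branch molecular rate variation, the gate for the association
models. The rate model finds a decisively positive R_dN coefficient
(`p_x = 0`, row 6) while the level model finds none (`p_x = 0.285`,
row 2): protein-coding change tracks *how fast* testes mass evolved, not
*where it ended up* — the signature of a bidirectional rapid driver,
which is exactly the archetype that was planted.

`glance(res)` returns the one-row summary (D, df, p, classification);
`tidy(res)` the coefficient table of both PGLS models with `p_x` per
term; `autoplot(res)` the two association scatterplots;
`plot_rate_tree(tree, rates)` draws the rate-scaled phylogeny.
`loo_robustness(res)` reruns both regressions leaving out one species at
a time.

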