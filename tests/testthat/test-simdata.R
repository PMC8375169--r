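test_that("pure-birth trees are ultrametric with the right shape", {
  expect_error(simulate_tree(2, 1, 1), "at least 3")
  tr3 <- simulate_tree(3, 1, seed = 1)
  expect_equal(tr3$Nnode, 2)  # root plus one internal node
  for (n in c(5, 17, 40)) {
    tr <- simulate_tree(n, depth = 123, seed = n)
    d <- node_depths_for_test(tr)
    expect_lt(max(abs(d - 123)), 1e-10)
    expect_equal(nrow(tr$edge), 2 * n - 2)
  }
})

test_that("generators are deterministic under the seed", {
  sc <- simulation_scenario(n_taxa = 12, ncodons = 30)
  tr <- simulate_tree(12, sc$depth, seed = 4)
  s1 <- simulate_varrates_traits(tr, sc, seed = 9)
  s2 <- simulate_varrates_traits(tr, sc, seed = 9)
  expect_identical(s1$traits, s2$traits)
  a1 <- simulate_codon_alignment(tr, sc, seed = 9)
  a2 <- simulate_codon_alignment(tr, sc, seed = 9)
  expect_identical(a1$alignment$states, a2$alignment$states)
  a3 <- simulate_codon_alignment(tr, sc, seed = 10)
  expect_false(identical(a1$alignment$states, a3$alignment$states))
})

test_that("trait residual contrasts match the Brownian variance", {
  # homogeneous rates: phylogenetically independent contrasts of the
  # residual have variance sigma2_b (per unit branch length)
  sc <- simulation_scenario(n_taxa = 64, r_scalar = 1)
  ratios <- vapply(1:12, function(s) {
    tr <- simulate_tree(64, sc$depth, seed = 300 + s)
    sim <- simulate_varrates_traits(tr, sc, seed = 300 + s)
    grp <- match(sim$traits$clade, sc$clades$label)
    resid <- sim$traits$testes_mass_log10 -
      (sc$clades$intercept[grp] + sc$clades$slope[grp] *
         sim$traits$body_mass_log10)
    pic <- ape::pic(setNames(resid, sim$traits$species), tr)
    var(pic) / sc$sigma2_b
  }, 0)
  expect_gt(mean(ratios), 0.75)
  expect_lt(mean(ratios), 1.3)

  # normality of contrasts under homogeneous rates
  tr <- simulate_tree(128, sc$depth, seed = 77)
  sc128 <- simulation_scenario(n_taxa = 128, r_scalar = 1)
  sim <- simulate_varrates_traits(tr, sc128, seed = 77)
  grp <- match(sim$traits$clade, sc128$clades$label)
  resid <- sim$traits$testes_mass_log10 -
    (sc128$clades$intercept[grp] + sc128$clades$slope[grp] *
       sim$traits$body_mass_log10)
  pic <- ape::pic(setNames(resid, sim$traits$species), tr)
  expect_gt(stats::shapiro.test(pic)$p.value, 0.01)
})

test_that("fast branches inflate the planted residual variance", {
  sc <- simulation_scenario(n_taxa = 48, fast_set = "clade")
  ratios <- vapply(1:10, function(s) {
    tr <- simulate_tree(48, sc$depth, seed = 400 + s)
    sim <- simulate_varrates_traits(tr, sc, seed = 400 + s)
    inc <- sim$residual_increments
    t <- tr$edge.length
    fast <- sim$fast_edges
    mean(inc[fast]^2 / t[fast]) / mean(inc[!fast]^2 / t[!fast])
  }, 0)
  # planted x16; averaged over replicates the realized ratio is near it
  expect_gt(mean(ratios), 8)
})

test_that("codon evolution respects zero branches and stationarity", {
  sc <- simulation_scenario(n_taxa = 4, ncodons = 150, branch_rate_sd = 0)
  # both children on zero-length branches equal their parent exactly
  tr0 <- read_newick("((A:0,B:0):30,(C:40,D:40):40);")
  st0 <- simulate_codon_alignment(tr0, sc, seed = 5)$alignment$states
  expect_identical(st0["A", ], st0["B", ])
  # a far shorter path separates A from B than C from D
  tr <- read_newick("((A:0,B:20):30,(C:80,D:80):40);")
  sim <- simulate_codon_alignment(tr, sc, seed = 5)
  st <- sim$alignment$states
  dAB <- mean(st["A", ] != st["B", ])
  dCD <- mean(st["C", ] != st["D", ])
  expect_lt(dAB, dCD)

  # long-branch stationarity: tip composition approaches pi
  sc2 <- simulation_scenario(n_taxa = 3, ncodons = 1000, branch_rate_sd = 0)
  tr2 <- read_newick("(A:1,B:1,C:100000);")
  sim2 <- simulate_codon_alignment(tr2, sc2, seed = 6)
  params <- mg94_params(rho = sc2$rho, pi = sc2$pinuc)
  obs <- tabulate(sim2$alignment$states["C", ], nbins = 61)
  expected <- params$pi * 1000
  keep <- expected > 5
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.001)
})

test_that("substitution counts scale with the planted branch rates", {
  # two-taxon trees: one branch at baseline, one with dN x8; the fraction
  # of differing codons that are non-synonymous rises accordingly
  p <- toy_params(1)
  gct <- ratelink:::genetic_code_tables()
  count_kinds <- function(dN) {
    tr <- read_newick("(A:1,B:1);")
    aln <- toy_codon_aln(tr, p, dS = c(0.05, 0.05), dN = c(dN, dN),
                         nsites = 1500, seed = 31)
    st <- aln$states
    diffidx <- which(st[1, ] != st[2, ])
    aa <- gct$aa
    sum(aa[st[1, diffidx]] != aa[st[2, diffidx]]) / length(diffidx)
  }
  frac_lo <- count_kinds(0.02)
  frac_hi <- count_kinds(0.16)
  expect_gt(frac_hi, frac_lo + 0.2)
})

test_that("the benchmark bundle is complete and byte-reproducible", {
  sc <- simulation_scenario(n_taxa = 12, ncodons = 30)
  d1 <- file.path(tempdir(), "bench_a")
  d2 <- file.path(tempdir(), "bench_b")
  b1 <- generate_benchmark(d1, seed = 5, scenario = sc)
  b2 <- generate_benchmark(d2, seed = 5, scenario = sc)
  expect_equal(nrow(b1$manifest), 9)  # 6 genes + tree + traits + truth
  expect_setequal(c("tree.nwk", "traits.tsv", "truth.json"),
                  setdiff(b1$manifest$file,
                          grep("^gene_", b1$manifest$file, value = TRUE)))
  for (f in b1$manifest$file) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
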