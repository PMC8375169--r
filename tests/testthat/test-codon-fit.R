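# Fitting tests use small alignments; the heavier calibration and recovery
# studies live in the acceptance suite.

fit_fixture <- function(ntax = 8, ncod = 80, seed = 2, omega = 0.4) {
  sc <- simulation_scenario(n_taxa = ntax, ncodons = ncod,
                            branch_rate_sd = 0, omega = omega)
  tr <- simulate_tree(ntax, 150, seed = seed)
  utr <- ape::unroot(tr)
  sim <- simulate_codon_alignment(utr, sc, seed = seed)
  list(aln = sim$alignment, tree = utr, sim = sim)
}

test_that("global and local fits nest and produce sane estimates", {
  fx <- fit_fixture()
  cfg <- codon_fit_config(max_sweeps = 5, tol = 1e-3)
  fg <- fit_global(fx$aln, fx$tree, cfg, seed = 1)
  fl <- fit_local(fx$aln, fx$tree, cfg, seed = 1, init = fg)

  expect_gte(fl$loglik, fg$loglik - 1e-4)           # nesting
  expect_true(all(fl$branches$dS >= 0))
  expect_true(all(fl$branches$dN >= 0))
  expect_gt(fg$omega, 0.1)
  expect_lt(fg$omega, 1)
  E <- nrow(fx$tree$edge)
  expect_equal(fg$npar, 5 + 1 + E)
  expect_equal(fl$npar, 5 + 2 * E)

  lrt <- lrt_global_vs_local(fg, fl)
  expect_equal(lrt$df, E - 1)
  expect_gte(lrt$D, 0)
  expect_error(lrt_global_vs_local(fl, fg), "global and local")
})

test_that("the fitted likelihood is at least the truth's likelihood", {
  fx <- fit_fixture(ntax = 6, ncod = 60, seed = 7)
  cfg <- codon_fit_config(max_sweeps = 5, tol = 1e-3)
  fg <- fit_global(fx$aln, fx$tree, cfg, seed = 1)
  params_true <- mg94_params(rho = simulation_scenario()$rho,
                             pi = simulation_scenario()$pinuc)
  ll_truth <- pruning_loglik(fx$aln, fx$tree, params_true,
                             list(dS = fx$sim$truth$dS_true,
                                  dN = fx$sim$truth$dN_true))
  expect_gte(fg$loglik, ll_truth)
})

test_that("fits are deterministic and stable across restarts", {
  fx <- fit_fixture(ntax = 5, ncod = 50, seed = 3)
  cfg <- codon_fit_config(max_sweeps = 4, tol = 1e-3)
  f1 <- fit_global(fx$aln, fx$tree, cfg, seed = 5)
  f2 <- fit_global(fx$aln, fx$tree, cfg, seed = 5)
  expect_identical(f1$loglik, f2$loglik)

  # restarts land on the same optimum
  f3 <- fit_global(fx$aln, fx$tree,
                   codon_fit_config(max_sweeps = 6, tol = 1e-4,
                                    restarts = 3), seed = 11)
  expect_lt(abs(f3$loglik - f1$loglik), 0.5)
})

test_that("a strongly accelerated branch ranks at the top of dN estimates", {
  sc <- simulation_scenario(n_taxa = 10, ncodons = 200, branch_rate_sd = 0)
  tr <- ape::unroot(simulate_tree(10, 150, seed = 9))
  E <- nrow(tr$edge)
  dS <- sc$alpha * tr$edge.length
  dN <- sc$omega * dS
  # choose a long branch and push its non-synonymous rate x10
  b <- which.max(tr$edge.length)
  dN[b] <- dN[b] * 10
  params <- mg94_params(rho = sc$rho, pi = sc$pinuc)
  aln <- toy_codon_aln(tr, params, dS, dN, nsites = sc$ncodons, seed = 12)
  cfg <- codon_fit_config(max_sweeps = 5, tol = 1e-3)
  fl <- fit_local(aln, tr, cfg, seed = 1)
  expect_lte(rank(-fl$branches$dN)[b], ceiling(E / 10) + 1)  # top decile
})

test_that("identical fits give D = 0 and p = 1", {
  fx <- fit_fixture(ntax = 5, ncod = 40, seed = 4)
  cfg <- codon_fit_config(max_sweeps = 3, tol = 1e-2)
  fg <- fit_global(fx$aln, fx$tree, cfg, seed = 1)
  fake_local <- fg
  fake_local$model <- "local"
  fake_local$npar <- 5 + 2 * nrow(fx$tree$edge)
  lrt <- lrt_global_vs_local(fg, fake_local)
  expect_equal(lrt$D, 0)
  expect_equal(lrt$p, 1)
})

test_that("tree/alignment species mismatches are reported", {
  fx <- fit_fixture(ntax = 5, ncod = 30, seed = 6)
  bad <- fx$tree
  bad$tip.label[1] <- "not_in_alignment"
  expect_error(fit_global(fx$aln, bad), "absent")
})
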