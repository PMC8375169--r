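# Classification-map tests use stub posteriors; the pipeline tests run a
# miniature benchmark end to end.

stub_result <- function(est_i, px_i, est_ii, px_ii) {
  mk <- function(est, px) {
    structure(list(summary = tibble::tibble(term = c("(Intercept)", "R_dN"),
                                            estimate = c(0, est),
                                            sd = c(1, 1),
                                            p_x = c(0, px))),
              class = "pgls_posterior")
  }
  structure(list(gene = "stub", skipped = FALSE,
                 model_i = mk(est_i, px_i), model_ii = mk(est_ii, px_ii)),
            class = "gene_association")
}

test_that("the classification map is total and matches the taxonomy", {
  grid <- list(
    # (phen est, phen p, rate est, rate p) -> label
    list(1, 0.5, 1, 0.01, "bidirectional_rapid_driver"),
    list(1, 0.01, 1, 0.01, "directional_rapid_driver"),
    list(1, 0.5, -1, 0.01, "moderator"),
    list(-1, 0.01, -1, 0.01, "directional_moderator"),
    list(1, 0.01, 1, 0.5, "directional_nonrapid_driver"),
    list(-1, 0.01, -1, 0.5, "directional_nonrapid_driver"),
    list(1, 0.5, 1, 0.5, "no_association"),
    list(-1, 0.3, -1, 0.2, "no_association")
  )
  for (g in grid) {
    res <- stub_result(g[[1]], g[[2]], g[[3]], g[[4]])
    expect_equal(classify_gene(res), g[[5]])
  }
  # deterministic: same inputs, same label
  expect_identical(classify_gene(stub_result(1, 0.2, 1, 0.01)),
                   classify_gene(stub_result(1, 0.2, 1, 0.01)))
  # alpha is honoured
  expect_equal(classify_gene(stub_result(1, 0.07, 1, 0.07), alpha = 0.1),
               "directional_rapid_driver")
})

mini_pipeline <- function(seed = 11, archetype = "null") {
  sc <- simulation_scenario(n_taxa = 16, ncodons = 60)
  dir <- file.path(tempdir(), paste0("mini", seed))
  bench <- generate_benchmark(dir, seed = seed, scenario = sc)
  des <- regression_design(bench$traits, bench$ingroup_tree)
  vf <- suppressWarnings(
    varrates_mcmc(des, bench$ingroup_tree,
                  varrates_config(iterations = 4000, samples = 200,
                                  min_ess = 0), seed = seed))
  mrt <- median_rate_tree(vf)
  cfg <- association_config(
    min_taxa = 10,
    lrt_alpha = 0.5,  # tiny alignments: exercise the full path
    codon_config = codon_fit_config(max_sweeps = 3, tol = 1e-2),
    pgls_config = pgls_config(iterations = 3000, samples = 200))
  res <- run_gene_association(
    file.path(dir, paste0("gene_", archetype, ".fasta")),
    bench$traits, bench$tree, mrt$tree, outgroup = sc$outgroup,
    gene = archetype, config = cfg, seed = seed)
  list(res = res, bench = bench, cfg = cfg, dir = dir)
}

test_that("the pipeline produces a complete, reproducible result object", {
  p1 <- mini_pipeline(21)
  res <- p1$res
  expect_false(res$skipped)
  expect_s3_class(res$model_i, "pgls_posterior")
  expect_s3_class(res$model_ii, "pgls_posterior")
  expect_true(res$classification %in%
                c("bidirectional_rapid_driver", "directional_rapid_driver",
                  "moderator", "directional_moderator",
                  "directional_nonrapid_driver", "no_association"))
  expect_equal(res$n_taxa, nrow(res$data))
  expect_true(all(c("R_dN", "R_dS", "R_phen") %in% names(res$data)))

  g <- glance(res)
  expect_equal(g$classification, res$classification)
  t1 <- tidy(res)
  expect_true(all(c("gene", "model", "term", "p_x") %in% names(t1)))

  # byte-identical rerun under the same seed
  p2 <- mini_pipeline(21)
  expect_identical(jsonlite::toJSON(tidy(p1$res), digits = NA),
                   jsonlite::toJSON(tidy(p2$res), digits = NA))
  unlink(p1$dir, recursive = TRUE)
})

test_that("insufficient species overlap yields a structured skip", {
  p <- mini_pipeline(22)
  traits_few <- p$bench$traits[1:4, ]
  res <- run_gene_association(
    file.path(p$dir, "gene_null.fasta"),
    traits_few, p$bench$tree, median_rate_tree_stub(p$bench$ingroup_tree),
    outgroup = "Outgroup", gene = "few", config = p$cfg, seed = 1)
  expect_true(res$skipped)
  expect_match(res$reason, "overlapping species")
  expect_error(classify_gene(res), "skipped")
  unlink(p$dir, recursive = TRUE)
})

test_that("leave-one-out produces one rerun per species and stable labels", {
  p <- mini_pipeline(23)
  res <- p$res
  loo <- loo_robustness(res, p$cfg, seed = 2)
  expect_equal(nrow(loo), res$n_taxa)
  expect_true(all(loo$ok))
  expect_true(all(!is.na(loo$classification)))
  unlink(p$dir, recursive = TRUE)
})
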