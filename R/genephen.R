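# Per-gene association pipeline: codon fits and the branch-variation gate,
# root-to-tip sums of molecular and phenotypic rates, the two PGLS models,
# the driver/moderator classification, and leave-one-species-out reruns.

#' Association-pipeline configuration
#'
#' @param min_taxa Minimum species overlap between tree, traits and
#'   alignment.
#' @param lrt_alpha Gate: genes are analysed only when the likelihood-ratio
#'   test for branch-to-branch molecular rate variation is significant at
#'   this level.
#' @param px_alpha Significance level on p_x for classification.
#' @param log_floor Floor applied inside log10 of root-to-tip sums.
#' @param codon_config See [codon_fit_config()].
#' @param pgls_config See [pgls_config()].
#' @param genus_fallback Allow genus matching when intersecting species.
#' @return List of settings.
#' @export
association_config <- function(min_taxa = 10, lrt_alpha = 0.001,
                               px_alpha = 0.05, log_floor = 1e-8,
                               codon_config = codon_fit_config(),
                               pgls_config = ratelink::pgls_config(),
                               genus_fallback = TRUE) {
  list(min_taxa = min_taxa, lrt_alpha = lrt_alpha, px_alpha = px_alpha,
       log_floor = log_floor, codon_config = codon_config,
       pgls_config = pgls_config, genus_fallback = genus_fallback)
}

.log10_floor <- function(x, floor) log10(pmax(x, floor))

#' Run the per-gene genotype-phenotype association analysis
#'
#' Fits the global and local MG94xREV models on the gene's alignment
#' (unrooted, outgroup included), gates on the likelihood-ratio test for
#' branch-to-branch rate variation, roots the branch-wise dN and dS trees on
#' the outgroup (then removes it), sums branches root-to-tip to obtain R_dN
#' and R_dS, takes R_phen from the phenotypic rate-scaled tree, and runs the
#' two PGLS models on the time tree: (i) testes ~ R_dN + R_dS + body, and
#' (ii) R_phen ~ R_dN + R_dS + testes + body. All root-to-tip sums and
#' masses enter the regressions on the log10 scale.
#'
#' @param alignment Gene alignment (anything [codon_alignment()] accepts);
#'   must contain the outgroup.
#' @param traits Trait tibble (see [read_trait_table()]).
#' @param time_tree Rooted time tree (Myr) containing the analysed species
#'   (the outgroup is only needed in the alignment-facing tree).
#' @param rt_tree Phenotypic rate-scaled tree from [median_rate_tree()].
#' @param outgroup Outgroup tip label in the alignment.
#' @param gene Gene name carried into the result.
#' @param config See [association_config()].
#' @param seed Integer seed (codon-fit restarts and both PGLS chains).
#' @return Object of class `gene_association`: `gene`, `n_taxa`, `lrt`,
#'   `model_i`, `model_ii` (`pgls_posterior`s), `data` (merged per-species
#'   tibble), `classification`, `skipped` (+ `reason` when skipped).
#' @export
run_gene_association <- function(alignment, traits, time_tree, rt_tree,
                                 outgroup, gene = "gene",
                                 config = association_config(), seed = 1) {
  aln <- codon_alignment(alignment)
  traits <- validate_trait_table(traits)
  if (!outgroup %in% aln$species)
    stop("outgroup '", outgroup, "' absent from the alignment", call. = FALSE)

  # species overlap: tree tips with trait data and sequence data
  mp <- match_and_prune(time_tree, traits$species,
                        genus_fallback = config$genus_fallback)
  shared <- intersect(mp$tree$tip.label, aln$species)
  if (length(shared) < config$min_taxa) {
    return(structure(list(gene = gene, skipped = TRUE,
                          reason = paste0("only ", length(shared),
                                          " overlapping species (< ",
                                          config$min_taxa, ")"),
                          n_taxa = length(shared)),
                     class = "gene_association"))
  }
  time_pruned <- ape::keep.tip(mp$tree, shared)

  # codon fits on the unrooted tree including the outgroup
  fit_species <- c(shared, outgroup)
  fit_tree <- ape::keep.tip(rt_tree, intersect(rt_tree$tip.label, shared))
  gene_tree <- NULL
  # the alignment-facing tree: time tree restricted to species with
  # sequences, plus the outgroup grafted if the time tree lacks it
  if (outgroup %in% time_tree$tip.label) {
    gene_tree <- ape::keep.tip(time_tree, fit_species)
  } else {
    gene_tree <- add_outgroup(ape::keep.tip(time_tree, shared), outgroup)
  }
  unrooted <- ape::unroot(gene_tree)
  fg <- fit_global(aln, unrooted, config$codon_config, seed)
  fl <- fit_local(aln, unrooted, config$codon_config, seed, init = fg)
  lrt <- lrt_global_vs_local(fg, fl)
  if (lrt$p >= config$lrt_alpha) {
    return(structure(list(gene = gene, skipped = TRUE,
                          reason = paste0("no significant branch-to-branch ",
                                          "rate variation (LRT p = ",
                                          signif(lrt$p, 3), ")"),
                          lrt = lrt, n_taxa = length(shared),
                          global_fit = fg, local_fit = fl),
                     class = "gene_association"))
  }

  # dN / dS trees: root on the outgroup, drop it, sum root-to-tip
  sum_rates <- function(rate_tree, kind) {
    rooted <- ape::root(rate_tree, outgroup = outgroup, resolve.root = TRUE)
    rooted <- ape::drop.tip(rooted, outgroup)
    root_to_tip_sum(rooted, kind = kind) |>
      dplyr::rename(!!kind := "total") |>
      dplyr::select(dplyr::all_of(c("species", kind)))
  }
  rdn <- sum_rates(fl$dn_tree, "R_dN")
  rds <- sum_rates(fl$ds_tree, "R_dS")
  rphen <- root_to_tip_sum(fit_tree, kind = "R_phen") |>
    dplyr::rename(R_phen = "total") |>
    dplyr::select("species", "R_phen")

  dat <- traits |>
    dplyr::inner_join(rdn, by = "species") |>
    dplyr::inner_join(rds, by = "species") |>
    dplyr::inner_join(rphen, by = "species") |>
    dplyr::mutate(
      R_dN = .log10_floor(.data$R_dN, config$log_floor),
      R_dS = .log10_floor(.data$R_dS, config$log_floor),
      R_phen = .log10_floor(.data$R_phen, config$log_floor)
    )

  spec_i <- pgls_spec(dat, "testes_mass_log10",
                      c("R_dN", "R_dS", "body_mass_log10"), time_pruned)
  spec_ii <- pgls_spec(dat, "R_phen",
                       c("R_dN", "R_dS", "testes_mass_log10",
                         "body_mass_log10"), time_pruned)
  m_i <- pgls_mcmc(spec_i, config$pgls_config, seed)
  m_ii <- pgls_mcmc(spec_ii, config$pgls_config, seed + 1L)

  res <- structure(list(gene = gene, skipped = FALSE,
                        n_taxa = nrow(dat), lrt = lrt,
                        model_i = m_i, model_ii = m_ii, data = dat,
                        global_fit = fg, local_fit = fl,
                        config = config, seed = seed),
                   class = "gene_association")
  res$classification <- classify_gene(res, config$px_alpha)
  res
}

#' @export
print.gene_association <- function(x, ...) {
  cat("<gene_association> ", x$gene, "\n", sep = "")
  if (isTRUE(x$skipped)) {
    cat("  skipped: ", x$reason, "\n", sep = "")
    return(invisible(x))
  }
  cat("  N_taxa = ", x$n_taxa, "; LRT D = ", round(x$lrt$D, 2), " (df ",
      x$lrt$df, ", p = ", signif(x$lrt$p, 3), ")\n", sep = "")
  cat("  classification: ", x$classification, "\n", sep = "")
  invisible(x)
}

.coef_sig_sign <- function(posterior, term, alpha) {
  s <- posterior$summary
  row <- s[s$term == term, ]
  if (!nrow(row)) stop("term '", term, "' not in posterior", call. = FALSE)
  list(sig = row$p_x < alpha, positive = row$estimate > 0)
}

#' Classify a gene as driver, moderator or unassociated
#'
#' Maps the joint pattern of the phenotype-level association (model i: the
#' R_dN coefficient on testes mass) and the rate-level association (model
#' ii: the R_dN coefficient on R_phen) onto the six-category taxonomy:
#' positive rate association without a phenotype association marks a gene
#' driving rapid change in both directions; with one, a directional rapid
#' driver; negative rate associations mark moderators (directional when the
#' phenotype association is also present); a phenotype-only association
#' marks a directional but non-rapid driver.
#'
#' @param result A `gene_association`.
#' @param alpha Significance level on p_x.
#' @return One of `"bidirectional_rapid_driver"`,
#'   `"directional_rapid_driver"`, `"moderator"`, `"directional_moderator"`,
#'   `"directional_nonrapid_driver"`, `"no_association"`.
#' @export
classify_gene <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "gene_association"))
  if (isTRUE(result$skipped))
    stop("gene was skipped (", result$reason, "); nothing to classify",
         call. = FALSE)
  phen <- .coef_sig_sign(result$model_i, "R_dN", alpha)
  rate <- .coef_sig_sign(result$model_ii, "R_dN", alpha)
  if (rate$sig && rate$positive) {
    if (phen$sig) "directional_rapid_driver" else "bidirectional_rapid_driver"
  } else if (rate$sig && !rate$positive) {
    if (phen$sig) "directional_moderator" else "moderator"
  } else {
    if (phen$sig) "directional_nonrapid_driver" else "no_association"
  }
}

#' Leave-one-species-out robustness of the association models
#'
#' Reruns both PGLS models once per species, excluding that species while
#' holding the molecular and phenotypic rate estimates fixed (paths are
#' re-pruned, rates are not re-estimated). Reports the sign and significance
#' of the R_dN coefficient in each rerun.
#'
#' @param result A completed `gene_association`.
#' @param config See [association_config()] (chain settings reused).
#' @param seed Integer seed.
#' @return Tibble with one row per excluded species: `species_excluded`,
#'   `ok`, model-i and model-ii R_dN estimates, p_x values, and the rerun
#'   classification.
#' @export
loo_robustness <- function(result, config = association_config(), seed = 1) {
  stopifnot(inherits(result, "gene_association"))
  if (isTRUE(result$skipped)) stop("gene was skipped; nothing to rerun",
                                   call. = FALSE)
  dat <- result$data
  tree <- result$model_i$spec$tree
  rows <- purrr::map(seq_len(nrow(dat)), function(i) {
    sp <- dat$species[i]
    out <- tryCatch({
      d2 <- dat[-i, ]
      t2 <- ape::drop.tip(tree, sp)
      s_i <- pgls_spec(d2, "testes_mass_log10",
                       c("R_dN", "R_dS", "body_mass_log10"), t2)
      s_ii <- pgls_spec(d2, "R_phen",
                        c("R_dN", "R_dS", "testes_mass_log10",
                          "body_mass_log10"), t2)
      m_i <- pgls_mcmc(s_i, config$pgls_config, seed)
      m_ii <- pgls_mcmc(s_ii, config$pgls_config, seed + 1L)
      stub <- structure(list(skipped = FALSE, model_i = m_i, model_ii = m_ii),
                        class = "gene_association")
      ri <- m_i$summary[m_i$summary$term == "R_dN", ]
      rii <- m_ii$summary[m_ii$summary$term == "R_dN", ]
      tibble::tibble(species_excluded = sp, ok = TRUE,
                     est_i = ri$estimate, p_x_i = ri$p_x,
                     est_ii = rii$estimate, p_x_ii = rii$p_x,
                     classification = classify_gene(stub, config$px_alpha))
    }, error = function(e) {
      tibble::tibble(species_excluded = sp, ok = FALSE,
                     est_i = NA_real_, p_x_i = NA_real_,
                     est_ii = NA_real_, p_x_ii = NA_real_,
                     classification = NA_character_)
    })
    out
  })
  dplyr::bind_rows(rows)
}
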