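# broom-style tidiers for the package's fitted objects.

#' Turn a fitted object into a tidy tibble
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary of a fitted object
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a PGLS posterior
#'
#' @param x A `pgls_posterior`.
#' @param ... Unused.
#' @return Tibble with one row per term: `term`, `estimate`, `sd`, `p_x`.
#' @export
tidy.pgls_posterior <- function(x, ...) x$summary

#' @export
#' @rdname tidy.pgls_posterior
glance.pgls_posterior <- function(x, ...) {
  tibble::tibble(n = length(x$spec$y),
                 lambda = mean(x$trace$lambda),
                 sigma2 = mean(x$trace$sigma2),
                 mean_loglik = mean(x$trace$loglik),
                 samples = nrow(x$trace),
                 lambda_acceptance = x$lambda_acceptance)
}

#' Tidy a variable-rates fit
#'
#' One row per branch with the posterior median and mean rate scalar and the
#' posterior probability that the branch is in the scaled set.
#'
#' @param x A `varrates_fit`.
#' @param ... Unused.
#' @return Tibble: `branch`, `median_r`, `mean_r`, `prob_scaled`.
#' @export
tidy.varrates_fit <- function(x, ...) {
  tibble::tibble(branch = colnames(x$r_samples),
                 median_r = apply(x$r_samples, 2, median),
                 mean_r = colMeans(x$r_samples),
                 prob_scaled = colMeans(x$r_samples != 1))
}

#' @export
#' @rdname tidy.varrates_fit
glance.varrates_fit <- function(x, ...) {
  tibble::tibble(samples = nrow(x$trace),
                 mean_k = mean(x$trace$k),
                 mean_sigma2 = mean(x$trace$sigma2),
                 ess_sigma2 = x$ess_sigma2,
                 birth_acceptance = unname(x$acceptance["birth"]),
                 death_acceptance = unname(x$acceptance["death"]))
}

#' Tidy a codon fit
#'
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @return The per-branch tibble (`branch`, `dS`, `dN`, and `omega_b`).
#' @export
tidy.codon_fit <- function(x, ...) {
  dplyr::mutate(x$branches,
                omega_b = ifelse(.data$dS > 0, .data$dN / .data$dS, NA_real_))
}

#' @export
#' @rdname tidy.codon_fit
glance.codon_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik, npar = x$npar,
                 omega = if (is.null(x$omega)) NA_real_ else x$omega,
                 branches = nrow(x$branches))
}

#' Tidy a gene-association result
#'
#' One row per model and term with coefficient summaries, plus the
#' gene-level metadata.
#'
#' @param x A `gene_association`.
#' @param ... Unused.
#' @return Tibble: `gene`, `model`, `term`, `estimate`, `sd`, `p_x`.
#' @export
tidy.gene_association <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    return(tibble::tibble(gene = x$gene, model = NA_character_,
                          term = NA_character_, estimate = NA_real_,
                          sd = NA_real_, p_x = NA_real_))
  }
  dplyr::bind_rows(
    dplyr::mutate(x$model_i$summary, model = "testes ~ R_dN", .before = 1),
    dplyr::mutate(x$model_ii$summary, model = "R_phen ~ R_dN", .before = 1)
  ) |>
    dplyr::mutate(gene = x$gene, .before = 1)
}

#' @export
#' @rdname tidy.gene_association
glance.gene_association <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    return(tibble::tibble(gene = x$gene, skipped = TRUE,
                          n_taxa = x$n_taxa, D = NA_real_, df = NA_integer_,
                          p = NA_real_, classification = NA_character_))
  }
  tibble::tibble(gene = x$gene, skipped = FALSE, n_taxa = x$n_taxa,
                 D = x$lrt$D, df = as.integer(x$lrt$df), p = x$lrt$p,
                 classification = x$classification)
}
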