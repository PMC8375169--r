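# Bayesian variable-rates phylogenetic regression: a GLS regression whose
# phylogenetically structured residual evolves by Brownian motion with an
# overall background rate sigma2_b and branch-specific rate scalars r,
# estimated by reversible-jump MCMC over the set of scaled branches.

#' Build a clade-wise allometric regression design bound to a tree
#'
#' Response is log10 testes mass; the predictor matrix holds a separate
#' intercept and log10 body-mass slope for every clade. Rows are ordered as
#' the tree's tip labels, the order in which phylogenetic covariance matrices
#' from this tree are laid out.
#'
#' @param traits Trait tibble (see [read_trait_table()]).
#' @param tree A rooted `phylo`; its tip set must be covered by `traits`.
#' @return Object of class `regression_design`: list with `y`, `X`,
#'   `species`, `tree`.
#' @export
regression_design <- function(traits, tree) {
  traits <- validate_trait_table(traits)
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, traits$species)
  if (length(miss)) stop("traits missing for tree tip(s): ",
                         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  tr <- traits[match(tree$tip.label, traits$species), ]
  y <- tr$testes_mass_log10
  if (length(unique(tr$clade)) > 1L) {
    cl <- factor(tr$clade)
    X <- stats::model.matrix(~ 0 + cl + cl:body_mass_log10,
                             data = data.frame(cl = cl,
                                               body_mass_log10 = tr$body_mass_log10))
    colnames(X) <- sub("^cl", "", colnames(X))
  } else {
    X <- cbind(intercept = 1, body = tr$body_mass_log10)
  }
  if (qr(X)$rank < ncol(X))
    stop("design is rank-deficient (a clade with a single body-mass value?)",
         call. = FALSE)
  structure(list(y = y, X = X, species = tr$species, tree = tree),
            class = "regression_design")
}

# Cholesky, falling back to a relative diagonal jitter (1e-10 x mean
# diagonal) only when the plain factorization fails, so well-conditioned
# matrices keep exact likelihoods; errors with conditioning info if still
# singular
.chol_jitter <- function(V) {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(out)) return(out)
  jit <- 1e-10 * mean(diag(V))
  out <- tryCatch(chol(V + diag(jit, nrow(V))), error = function(e) NULL)
  if (is.null(out)) {
    stop("phylogenetic covariance is singular even after jitter ",
         "(reciprocal condition estimate ", format(rcond(V), digits = 3), ")",
         call. = FALSE)
  }
  out
}

# core GLS machinery shared by the variable-rates model and PGLS
.gls_core <- function(y, X, cholV) {
  n <- length(y)
  logdetV <- 2 * sum(log(diag(cholV)))
  Ly <- backsolve(cholV, y, transpose = TRUE)
  LX <- backsolve(cholV, X, transpose = TRUE)
  XtVX <- crossprod(LX)
  XtVy <- crossprod(LX, Ly)
  list(logdetV = logdetV, Ly = Ly, LX = LX, XtVX = XtVX, XtVy = XtVy, n = n)
}

.gls_loglik_core <- function(core, beta, sigma2) {
  resid2 <- sum((core$Ly - core$LX %*% beta)^2)
  -0.5 * (core$n * log(2 * pi * sigma2) + core$logdetV + resid2 / sigma2)
}

# log marginal likelihood of V with beta and sigma2 integrated out
# (flat beta, scale-invariant 1/sigma2), up to an additive constant:
# -1/2 log|V| - 1/2 log|X'V^-1 X| - (n-p)/2 log RSS_gls
.gls_collapsed_core <- function(core) {
  R <- chol(core$XtVX)
  bhat <- backsolve(R, backsolve(R, core$XtVy, transpose = TRUE))
  rss <- sum(core$Ly^2) - sum(core$XtVy * bhat)
  rss <- max(rss, 1e-300)
  -0.5 * core$logdetV - sum(log(diag(R))) -
    0.5 * (core$n - length(bhat)) * log(rss)
}

#' GLS log-likelihood of the variable-rates regression
#'
#' Multivariate-normal log density of the regression residuals with
#' covariance `sigma2 * V`, where `V` is the phylogenetic covariance of the
#' (rate-scaled) tree.
#'
#' @param design A [regression_design()].
#' @param V Phylogenetic covariance matrix in the design's species order.
#' @param beta Regression coefficient vector.
#' @param sigma2 Background Brownian rate (> 0).
#' @return Log-likelihood (scalar).
#' @export
gls_loglik <- function(design, V, beta, sigma2) {
  stopifnot(inherits(design, "regression_design"), sigma2 > 0,
            length(beta) == ncol(design$X))
  core <- .gls_core(design$y, design$X, .chol_jitter(V))
  .gls_loglik_core(core, beta, sigma2)
}

#' Variable-rates chain settings
#'
#' @param iterations Total MCMC iterations.
#' @param burnin Fraction discarded as burn-in.
#' @param samples Number of retained (thinned) samples.
#' @param rj_per_iter Scalar-set moves (birth/death/perturb) attempted per
#'   iteration.
#' @param prior_lnr_sd Prior standard deviation of log rate scalars.
#' @param birth_sd Standard deviation of the log-scalar birth proposal
#'   (wider than the prior so large scalars are reachable; corrected in the
#'   acceptance ratio).
#' @param move_sd Random-walk step for log rate-scalar perturbations.
#' @param sigma2_box Log-uniform prior support for the background rate.
#' @param beta_box Half-width of the uniform box prior on each coefficient
#'   (used by marginal-likelihood runs; the box is wide enough to act as a
#'   flat prior for estimation).
#' @param min_ess Effective-sample-size threshold below which a convergence
#'   warning is emitted.
#' @return List of settings.
#' @export
varrates_config <- function(iterations = 1e5, burnin = 0.2, samples = 1000,
                            rj_per_iter = 3, prior_lnr_sd = 1.5,
                            birth_sd = 2.2, move_sd = 0.6,
                            sigma2_box = c(1e-8, 1e4),
                            beta_box = 100, min_ess = 100) {
  list(iterations = iterations, burnin = burnin, samples = samples,
       rj_per_iter = rj_per_iter, prior_lnr_sd = prior_lnr_sd,
       birth_sd = birth_sd, move_sd = move_sd,
       sigma2_box = sigma2_box, beta_box = beta_box,
       min_ess = min_ess)
}

# crude autocorrelation-based effective sample size
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  max(1, n / (1 + 2 * sum(ac)))
}

#' Variable-rates reversible-jump MCMC
#'
#' Samples the joint posterior of the regression coefficients, the
#' background Brownian rate `sigma2_b`, and the set of branch-specific rate
#' scalars `r` (branches outside the set have r = 1). Coefficients and
#' `sigma2_b` are drawn from their exact full conditionals; the scalar set
#' moves by birth/death/perturb reversible-jump proposals with the log-normal
#' scalar prior as the birth proposal.
#'
#' @param design A [regression_design()].
#' @param tree Rooted `phylo` with branch lengths in time units (usually the
#'   design's tree).
#' @param config See [varrates_config()].
#' @param seed Integer seed; identical seeds give identical traces.
#' @return Object of class `varrates_fit`: `trace` tibble (iteration, k,
#'   sigma2, loglik, coefficients), `r_samples` matrix (samples x branches),
#'   `branch_ids`, `tree`, `acceptance`, `config`.
#' @export
varrates_mcmc <- function(design, tree = design$tree,
                          config = varrates_config(), seed = 1) {
  stopifnot(inherits(design, "regression_design"))
  if (!identical(design$species, tree$tip.label))
    stop("tree tips do not match the design's species order", call. = FALSE)
  set.seed(seed)
  y <- design$y
  X <- design$X
  p <- ncol(X)
  n <- length(y)
  M <- branch_tip_matrix(tree)  # E x n
  tlen <- tree$edge.length
  E <- nrow(M)
  ids <- branch_ids(tree)

  lnr <- rep(0, E)            # log rate scalars; 0 = unassigned (r = 1)
  assigned <- logical(E)
  Mnum <- M * 1                # numeric copy for outer-product updates
  build_v <- function(lnr) crossprod(M * sqrt(tlen * exp(lnr)))
  V <- build_v(lnr)
  core <- .gls_core(y, X, .chol_jitter(V))
  accepted_since_rebuild <- 0
  # rank-1 covariance update when one branch's weight changes
  v_after <- function(b, lnr_new) {
    V + (tlen[b] * (exp(lnr_new) - exp(lnr[b]))) * tcrossprod(Mnum[b, ])
  }
  beta <- as.numeric(solve(core$XtVX, core$XtVy))
  sigma2 <- max(config$sigma2_box[1],
                min(config$sigma2_box[2],
                    sum((core$Ly - core$LX %*% beta)^2) / n))
  cl <- .gls_collapsed_core(core)

  iters <- config$iterations
  keep_at <- unique(round(seq(iters * config$burnin + 1, iters,
                              length.out = config$samples)))
  nk <- length(keep_at)
  tracem <- matrix(NA_real_, nk, 4 + p)
  rsamp <- matrix(NA_real_, nk, E)
  acc <- c(birth = 0, death = 0, move = 0)
  prop <- c(birth = 0, death = 0, move = 0)
  srow <- 0
  psd <- config$prior_lnr_sd

  for (it in seq_len(iters)) {
    # --- reversible-jump / scalar updates (collapsed over beta, sigma2)
    try_scalar <- function(kind, b, z, extra_logprior = 0) {
      V2 <- v_after(b, z)
      core2 <- .gls_core(y, X, .chol_jitter(V2))
      cl2 <- .gls_collapsed_core(core2)
      prop[kind] <<- prop[kind] + 1
      if (log(runif(1)) < cl2 - cl + extra_logprior) {
        lnr[b] <<- z
        assigned[b] <<- z != 0
        V <<- V2
        core <<- core2
        cl <<- cl2
        acc[kind] <<- acc[kind] + 1
        accepted_since_rebuild <<- accepted_since_rebuild + 1
        if (accepted_since_rebuild >= 500) {  # refresh against drift
          V <<- build_v(lnr)
          core <<- .gls_core(y, X, .chol_jitter(V))
          cl <<- .gls_collapsed_core(core)
          accepted_since_rebuild <<- 0
        }
      }
    }
    for (mv in seq_len(config$rj_per_iter)) {
      u <- runif(1)
      k <- sum(assigned)
      if (u < 1 / 3) {          # birth (wide proposal, prior-corrected)
        if (k < E) {
          z <- rnorm(1, 0, config$birth_sd)
          try_scalar("birth", sample(which(!assigned), 1L), z,
                     stats::dnorm(z, 0, psd, log = TRUE) -
                       stats::dnorm(z, 0, config$birth_sd, log = TRUE))
        } else prop["birth"] <- prop["birth"] + 1
      } else if (u < 2 / 3) {   # death
        if (k > 0) {
          b <- if (k == 1) which(assigned) else sample(which(assigned), 1L)
          try_scalar("death", b, 0,
                     stats::dnorm(lnr[b], 0, config$birth_sd, log = TRUE) -
                       stats::dnorm(lnr[b], 0, psd, log = TRUE))
        } else prop["death"] <- prop["death"] + 1
      } else {                  # perturb one scalar
        if (k > 0) {
          b <- if (k == 1) which(assigned) else sample(which(assigned), 1L)
          z <- lnr[b] + rnorm(1, 0, config$move_sd)
          try_scalar("move", b, z,
                     stats::dnorm(z, 0, psd, log = TRUE) -
                       stats::dnorm(lnr[b], 0, psd, log = TRUE))
        } else prop["move"] <- prop["move"] + 1
      }
    }
    # --- exact conditionals for beta and sigma2
    XtVXi <- chol2inv(chol(core$XtVX))
    bhat <- XtVXi %*% core$XtVy
    bprop <- as.numeric(bhat + t(chol(sigma2 * XtVXi)) %*% rnorm(p))
    if (all(abs(bprop) <= config$beta_box)) beta <- bprop
    rss <- sum((core$Ly - core$LX %*% beta)^2)
    s2 <- 1 / rgamma(1, shape = n / 2, rate = rss / 2)
    if (s2 >= config$sigma2_box[1] && s2 <= config$sigma2_box[2]) sigma2 <- s2
    ll <- .gls_loglik_core(core, beta, sigma2)

    if (srow < nk && it == keep_at[srow + 1]) {
      srow <- srow + 1
      tracem[srow, ] <- c(it, sum(assigned), sigma2, ll, beta)
      rsamp[srow, ] <- exp(lnr)
    }
  }
  trace <- tibble::as_tibble(as.data.frame(tracem))
  names(trace) <- c("iteration", "k", "sigma2", "loglik", colnames(X))
  ess <- .ess(trace$sigma2)
  if (ess < config$min_ess)
    warning("low effective sample size for sigma2 (", round(ess, 1),
            "); consider a longer chain", call. = FALSE)
  colnames(rsamp) <- ids
  structure(list(trace = trace, r_samples = rsamp, branch_ids = ids,
                 tree = tree, acceptance = acc / pmax(prop, 1),
                 ess_sigma2 = ess, config = config, seed = seed),
            class = "varrates_fit")
}

#' @export
print.varrates_fit <- function(x, ...) {
  cat("<varrates_fit> ", nrow(x$trace), " samples over ", ncol(x$r_samples),
      " branches\n", sep = "")
  cat("  posterior mean k = ", round(mean(x$trace$k), 2),
      ", sigma2_b = ", signif(mean(x$trace$sigma2), 4), "\n", sep = "")
  invisible(x)
}

#' Posterior-median rate scalars and the rate-scaled tree
#'
#' Branches never scaled in a sample count as r = 1 in that sample; the
#' scaled tree has branch lengths t x median(r) ("rt").
#'
#' @param fit A `varrates_fit`.
#' @param tree Tree to scale (defaults to the fit's tree).
#' @return List with `rates` (a [branch_values()] tibble, kind `"r"`) and
#'   `tree` (the rt-scaled `phylo`).
#' @export
median_rate_tree <- function(fit, tree = fit$tree) {
  stopifnot(inherits(fit, "varrates_fit"))
  if (!nrow(fit$r_samples)) stop("empty posterior trace", call. = FALSE)
  med <- apply(fit$r_samples, 2, median)
  bv <- branch_values(tree, setNames(med, colnames(fit$r_samples)), kind = "r")
  list(rates = bv, tree = scale_branches(tree, bv))
}
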