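# Maximum-likelihood fitting of the MG94xREV codon model, global
# (shared dN/dS across branches) and local (free per-branch dN and dS).
# Optimization is coordinate ascent: Nelder-Mead over the shared GTR
# exchangeabilities, Brent / Nelder-Mead per edge against per-edge
# likelihood contexts, iterated to a log-likelihood tolerance. The global
# model's branch matrices share a single generator up to scale, so one
# spectral decomposition serves all branches and all candidate lengths.

#' Codon-fit configuration
#'
#' @param max_sweeps Maximum coordinate-ascent sweeps.
#' @param tol Convergence tolerance on the log-likelihood between sweeps.
#' @param restarts Number of jittered restarts (the best fit is kept).
#' @param rho_maxit Nelder-Mead iterations for the exchangeability block.
#' @param rho_sweeps Sweeps during which the exchangeabilities are
#'   re-optimized (they stabilize early; later sweeps refine branch rates).
#' @param edge_maxit Iterations for each per-edge optimization.
#' @param optimize_rho_local Re-optimize the exchangeabilities inside the
#'   local fit (default reuses the global fit's estimates as the starting and
#'   fixed values; the local model still contains them, this is a
#'   fitting-order choice).
#' @param log_rate_bounds Bounds for log branch rates.
#' @return A list of settings.
#' @export
codon_fit_config <- function(max_sweeps = 8, tol = 1e-4, restarts = 1,
                             rho_maxit = 150, rho_sweeps = 2, edge_maxit = 40,
                             optimize_rho_local = FALSE,
                             log_rate_bounds = c(-14, 3)) {
  list(max_sweeps = max_sweeps, tol = tol, restarts = restarts,
       rho_maxit = rho_maxit, rho_sweeps = rho_sweeps,
       edge_maxit = edge_maxit, optimize_rho_local = optimize_rho_local,
       log_rate_bounds = log_rate_bounds)
}

.rho_expand <- function(free) {
  r <- exp(free)
  c(r[1], 1, r[2], r[3], r[4], r[5])  # AG fixed to 1
}

# crude counting initializer for the GTR exchangeabilities: tally the
# nucleotide-pair types of single-nucleotide codon differences between a few
# sequence pairs, normalized to the AG count
.rho_count_init <- function(aln) {
  gct <- genetic_code_tables()
  st <- aln$states
  ns <- nrow(st)
  pairs <- cbind(seq_len(min(ns - 1, 8)), min(ns, 2):min(ns, 9))
  counts <- rep(1, 6)  # add-one smoothing
  pairmap <- matrix(0L, 61, 61)
  pairmap[gct$changes[, 1:2] + 1L] <- gct$changes[, 3] + 1L
  for (k in seq_len(nrow(pairs))) {
    a <- st[pairs[k, 1], ]
    b <- st[pairs[k, 2], ]
    ok <- !is.na(a) & !is.na(b) & a != b
    pm <- pairmap[cbind(a[ok], b[ok])]
    pm <- pm[pm > 0]
    counts <- counts + tabulate(pm, 6)
  }
  counts / counts[2]
}

# full log-likelihood from a shared spectral form and per-edge scales
.global_ll <- function(prep, pi, eig, t_post) {
  Pc <- pmats_from_eig_cpp(eig$A, eig$Bi, eig$lambda, t_post)
  prune_loglik_cpp(prep$patterns, prep$weights, prep$edges0, Pc,
                   pi, prep$nnode, prep$root0)
}

# Exact incremental coordinate-ascent sweep over edges. Edges are visited
# in preorder; "up" partials carry the already-updated transition matrices
# of ancestral edges, cached per-edge contributions carry the not-yet-
# visited ones, so each edge is optimized against the current value of every
# other edge at the cost of a single postorder pass per sweep.
# `optimize_edge(tree_edge, S, D, logscale)` must return the edge's new
# transition matrix. Returns the updated P cube (postorder slices).
.edge_sweep <- function(prep, pi, Pc, optimize_edge) {
  E <- nrow(prep$edges0)
  npat <- ncol(prep$patterns)
  dp <- down_pass_cpp(prep$patterns, prep$edges0, Pc, prep$nnode)
  parents <- prep$edges0[, 1] + 1L
  children <- prep$edges0[, 2] + 1L
  kid_edges <- split(seq_len(E), parents)  # postorder edge idx by parent node
  up <- vector("list", prep$nnode)
  upsc <- vector("list", prep$nnode)
  root <- prep$root0 + 1L
  up[[root]] <- matrix(pi, npat, 61, byrow = TRUE)
  upsc[[root]] <- numeric(npat)
  for (e in rev(seq_len(E))) {  # reverse postorder = preorder
    u <- parents[e]
    v <- children[e]
    S <- up[[u]]
    Ssc <- upsc[[u]]
    for (f in setdiff(kid_edges[[as.character(u)]], e)) {
      S <- S * dp$contrib[, , f]
      Ssc <- Ssc + dp$cscale[, f]
    }
    D <- dp$down[, , v, drop = TRUE]
    if (is.null(dim(D))) D <- matrix(D, npat, 61)
    lsc <- Ssc + dp$dscale[, v]
    P <- optimize_edge(prep$edge_order[e], S, D, lsc)
    Pc[, , e] <- P
    dp$contrib[, , e] <- D %*% t(P)
    up[[v]] <- S %*% P
    upsc[[v]] <- Ssc
    mx <- apply(up[[v]], 1, max)
    small <- mx > 0 & mx < 1e-200
    if (any(small)) {
      up[[v]][small, ] <- up[[v]][small, , drop = FALSE] / mx[small]
      upsc[[v]][small] <- upsc[[v]][small] + log(mx[small])
    }
  }
  Pc
}

.local_ll <- function(prep, gct, rho, pinuc, pi, s_post, n_post) {
  Pc <- mg94_pmats_cpp(gct$changes, rho, pinuc, pi, s_post, n_post)
  prune_loglik_cpp(prep$patterns, prep$weights, prep$edges0, Pc,
                   pi, prep$nnode, prep$root0)
}

#' Fit the global MG94xREV model
#'
#' One shared non-synonymous/synonymous rate ratio omega across the tree;
#' per-branch time-scales absorb the synonymous rate (alpha = 1), so
#' `dS_b = t_b` and `dN_b = omega * t_b`.
#'
#' @param aln A [codon_alignment()] (or anything it accepts).
#' @param tree A `phylo`, typically unrooted, tips in the alignment.
#' @param config See [codon_fit_config()].
#' @param seed Integer seed controlling restart jitter.
#' @return An object of class `codon_fit` with elements `loglik`, `omega`,
#'   `rho`, `pi`, `branches` (tibble: branch, dS, dN), `npar`, `model`,
#'   `dn_tree`, `ds_tree`, `convergence`.
#' @export
fit_global <- function(aln, tree, config = codon_fit_config(), seed = 1) {
  aln <- codon_alignment(aln)
  if (length(tree$tip.label) < 3) stop("need >= 3 taxa", call. = FALSE)
  prep <- codon_prep(aln, tree)
  gct <- genetic_code_tables()
  pi <- codon_frequencies_f3x4(aln)
  pinuc <- attr(pi, "pinuc")
  pi <- as.numeric(pi)
  E <- nrow(tree$edge)
  lb <- config$log_rate_bounds
  set.seed(seed)
  rho0 <- log(.rho_count_init(aln)[-2])
  best <- NULL
  for (rs in seq_len(config$restarts)) {
    jit <- if (rs == 1) 0 else 0.5
    logt <- rep(log(0.1), E) + rnorm(E, 0, jit)
    logw <- log(0.5) + rnorm(1, 0, jit)
    rho_free <- rho0 + rnorm(5, 0, jit / 2)
    ll_old <- -Inf
    ll <- NA_real_
    sweeps <- 0
    for (sw in seq_len(config$max_sweeps)) {
      sweeps <- sw
      # branch scales first: a cold start wastes exchangeability effort
      eig <- mg94_eig_cpp(gct$changes, .rho_expand(rho_free), pinuc, pi,
                          1, exp(logw))
      Pc <- pmats_from_eig_cpp(eig$A, eig$Bi, eig$lambda,
                               exp(logt)[prep$edge_order])
      Pc <- .edge_sweep(prep, pi, Pc, function(e, S, D, lsc) {
        oe <- optimise(function(lt) {
          -edge_loglik_eig_cpp(S, D, lsc, prep$weights,
                               eig$A, eig$Bi, eig$lambda, exp(lt))
        }, interval = c(lb[1], lb[2]), tol = 1e-6)
        logt[e] <<- oe$minimum
        pmats_from_eig_cpp(eig$A, eig$Bi, eig$lambda, exp(logt[e]))[, , 1]
      })
      # shared exchangeabilities + omega, warm-started
      t_post <- exp(logt)[prep$edge_order]
      maxit <- if (sw == 1) config$rho_maxit else ceiling(config$rho_maxit / 3)
      opt <- optim(c(rho_free, logw), function(par) {
        eg <- mg94_eig_cpp(gct$changes, .rho_expand(par[1:5]), pinuc, pi,
                           1, exp(par[6]))
        -.global_ll(prep, pi, eg, t_post)
      }, method = "Nelder-Mead",
      control = list(maxit = maxit, reltol = 1e-8))
      rho_free <- opt$par[1:5]
      logw <- opt$par[6]
      ll <- -opt$value
      if (ll - ll_old < config$tol) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik) {
      best <- list(loglik = ll, rho = .rho_expand(rho_free), logw = logw,
                   logt = logt, sweeps = sweeps)
    }
  }
  omega <- exp(best$logw)
  dS <- exp(best$logt)
  dN <- omega * dS
  .codon_fit_result(tree, "global", best$loglik, best$rho, pi, pinuc,
                    dS, dN, omega = omega,
                    npar = 5L + 1L + E,
                    convergence = list(sweeps = best$sweeps,
                                       restarts = config$restarts))
}

#' Fit the local MG94xREV model
#'
#' Free per-branch synonymous and non-synonymous rates (2 parameters per
#' branch) with shared exchangeabilities and F3x4 frequencies. Branch lengths
#' are absorbed directly into `(dS_b, dN_b)`, so the estimates are
#' time-independent instantaneous amounts of synonymous / non-synonymous
#' change per branch.
#'
#' @inheritParams fit_global
#' @param init Optional `codon_fit` (usually the global fit) whose
#'   exchangeabilities and branch rates seed the optimization; this also
#'   guarantees the nesting `lnL_local >= lnL_global` up to tolerance. When
#'   `NULL` a global fit is run first.
#' @return A `codon_fit` as in [fit_global()] (no `omega`; `npar = 5 + 2E`).
#' @export
fit_local <- function(aln, tree, config = codon_fit_config(), seed = 1,
                      init = NULL) {
  aln <- codon_alignment(aln)
  if (length(tree$tip.label) < 3) stop("need >= 3 taxa", call. = FALSE)
  prep <- codon_prep(aln, tree)
  gct <- genetic_code_tables()
  pi <- codon_frequencies_f3x4(aln)
  pinuc <- attr(pi, "pinuc")
  pi <- as.numeric(pi)
  E <- nrow(tree$edge)
  lb <- config$log_rate_bounds
  set.seed(seed + 1L)
  if (is.null(init)) init <- fit_global(aln, tree, config, seed)
  rho <- init$rho
  rho_free <- log(rho[-2])
  clamp <- function(x) pmax(lb[1], pmin(lb[2], x))
  logs <- clamp(log(pmax(init$branches$dS, 1e-6)))
  logn <- clamp(log(pmax(init$branches$dN, 1e-6)))
  ll_old <- .local_ll(prep, gct, rho, pinuc, pi,
                      exp(logs)[prep$edge_order], exp(logn)[prep$edge_order])
  ll <- ll_old
  sweeps <- 0
  for (sw in seq_len(config$max_sweeps)) {
    sweeps <- sw
    if (config$optimize_rho_local && sw <= config$rho_sweeps) {
      opt <- optim(rho_free, function(fr) {
        -.local_ll(prep, gct, .rho_expand(fr), pinuc, pi,
                   exp(logs)[prep$edge_order], exp(logn)[prep$edge_order])
      }, method = "Nelder-Mead",
      control = list(maxit = config$rho_maxit, reltol = 1e-8))
      rho_free <- opt$par
      rho <- .rho_expand(rho_free)
    }
    Pc <- mg94_pmats_cpp(gct$changes, rho, pinuc, pi,
                         exp(logs)[prep$edge_order],
                         exp(logn)[prep$edge_order])
    Pc <- .edge_sweep(prep, pi, Pc, function(e, S, D, lsc) {
      oe <- optim(c(logs[e], logn[e]), function(par) {
        P <- mg94_pmat_cpp(gct$changes, rho, pinuc, pi,
                           exp(par[1]), exp(par[2]))
        -edge_loglik_cpp(S, D, lsc, prep$weights, P)
      }, method = "Nelder-Mead",
      control = list(maxit = config$edge_maxit, reltol = 1e-8))
      logs[e] <<- clamp(oe$par[1])
      logn[e] <<- clamp(oe$par[2])
      mg94_pmat_cpp(gct$changes, rho, pinuc, pi, exp(logs[e]), exp(logn[e]))
    })
    ll <- .local_ll(prep, gct, rho, pinuc, pi,
                    exp(logs)[prep$edge_order], exp(logn)[prep$edge_order])
    if (ll - ll_old < config$tol) break
    ll_old <- ll
  }
  .codon_fit_result(tree, "local", ll, rho, pi, pinuc,
                    exp(logs), exp(logn), omega = NULL,
                    npar = 5L + 2L * E,
                    convergence = list(sweeps = sweeps,
                                       init_loglik = init$loglik))
}

.codon_fit_result <- function(tree, model, loglik, rho, pi, pinuc, dS, dN,
                              omega, npar, convergence) {
  dn_tree <- tree
  dn_tree$edge.length <- dN
  ds_tree <- tree
  ds_tree$edge.length <- dS
  branches <- tibble::tibble(branch = branch_ids(tree), dS = dS, dN = dN)
  structure(list(model = model, loglik = loglik, rho = rho, pi = pi,
                 pinuc = pinuc, omega = omega, branches = branches,
                 npar = npar, dn_tree = dn_tree, ds_tree = ds_tree,
                 tree = tree, convergence = convergence),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("<codon_fit> ", x$model, " MG94xREV model\n", sep = "")
  cat("  lnL = ", format(x$loglik, digits = 10), ", ", x$npar,
      " parameters, ", nrow(x$branches), " branches\n", sep = "")
  if (!is.null(x$omega)) cat("  omega = ", round(x$omega, 4), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test of branch-to-branch rate variation
#'
#' Compares the local (per-branch dN and dS) fit against the nested global
#' (shared) fit: `D = 2 (lnL_local - lnL_global)`, clipped at 0, referred to
#' a chi-squared distribution with df equal to the parameter-count
#' difference.
#'
#' @param global,local `codon_fit` objects from [fit_global()] and
#'   [fit_local()] on the same data.
#' @return Tibble with columns `D`, `df`, `p`.
#' @export
lrt_global_vs_local <- function(global, local) {
  stopifnot(inherits(global, "codon_fit"), inherits(local, "codon_fit"))
  if (global$model != "global" || local$model != "local")
    stop("arguments must be the global and local fits, in that order",
         call. = FALSE)
  df <- local$npar - global$npar
  if (df <= 0) stop("models are not nested: non-positive df", call. = FALSE)
  D <- max(0, 2 * (local$loglik - global$loglik))
  tibble::tibble(D = D, df = df, p = pchisq(D, df, lower.tail = FALSE))
}
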