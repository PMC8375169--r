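# Bayesian phylogenetic generalized least squares with Pagel's lambda.
# Coefficients and the residual variance are drawn from exact conditionals;
# lambda moves by a reflected random walk on [0, 1]. Significance is
# summarized by p_x, the minority-side fraction of a coefficient's
# posterior.

#' Specify a PGLS model
#'
#' @param data Data frame with one row per species, containing the response
#'   and covariates; a `species` column is required.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate column names (an
#'   intercept is always included).
#' @param tree Rooted `phylo` in time units covering all species in `data`.
#' @return Object of class `pgls_spec`: list with `y`, `X`, `V`, `species`,
#'   `response`, `covariates`.
#' @export
pgls_spec <- function(data, response, covariates, tree) {
  stopifnot(is.data.frame(data), "species" %in% names(data))
  miss <- setdiff(c(response, covariates), names(data))
  if (length(miss)) stop("data missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  data <- data[complete.cases(data[, c("species", response, covariates)]), ]
  keep <- intersect(tree$tip.label, data$species)
  if (length(keep) < 3) stop("fewer than 3 species shared by data and tree",
                             call. = FALSE)
  tree <- ape::keep.tip(tree, keep)
  data <- data[match(tree$tip.label, data$species), ]
  y <- as.numeric(data[[response]])
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, covariates, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  V <- phylo_covariance(tree)
  structure(list(y = y, X = X, V = V, species = data$species,
                 response = response, covariates = covariates, tree = tree),
            class = "pgls_spec")
}

.lambda_v <- function(V, lambda) {
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# One-time spectral reduction of the lambda family:
# V(lambda) = D^{1/2} (lambda W + (1-lambda) I) D^{1/2} with
# W = D^{-1/2} V D^{-1/2} = U Lam U', so every lambda evaluation reduces to
# diagonal weights s_i = lambda (Lam_i - 1) + 1 on rotated data.
.pgls_reduce <- function(y, X, V) {
  d <- diag(V)
  Dn <- 1 / sqrt(d)
  W <- V * tcrossprod(Dn)
  eg <- eigen(W, symmetric = TRUE)
  rot <- t(eg$vectors)
  list(yt = as.numeric(rot %*% (Dn * y)),
       Xt = rot %*% (Dn * X),
       lam = eg$values, logdetD = sum(log(d)), n = length(y), p = ncol(X))
}

# GLS pieces at a given lambda from the reduced form
.pgls_at <- function(red, lambda) {
  s <- lambda * (red$lam - 1) + 1
  s <- pmax(s, 1e-12)
  w <- 1 / s
  Xw <- red$Xt * w
  list(logdetV = red$logdetD + sum(log(s)),
       XtVX = crossprod(red$Xt, Xw),
       XtVy = crossprod(Xw, red$yt),
       w = w)
}

.pgls_rss <- function(red, at, beta) {
  r <- red$yt - as.numeric(red$Xt %*% beta)
  sum(r * r * at$w)
}

.pgls_ll <- function(red, at, beta, sigma2) {
  -0.5 * (red$n * log(2 * pi * sigma2) + at$logdetV +
            .pgls_rss(red, at, beta) / sigma2)
}

#' PGLS log-likelihood
#'
#' Multivariate-normal log density of the residuals with covariance
#' `sigma2 * V(lambda)`, where `V(lambda)` multiplies the off-diagonal
#' entries of the phylogenetic covariance by Pagel's lambda.
#'
#' @param spec A [pgls_spec()].
#' @param beta Coefficient vector (intercept first).
#' @param sigma2 Residual variance scale (> 0).
#' @param lambda Phylogenetic signal, in `[0, 1]`.
#' @return Log-likelihood (scalar).
#' @export
pgls_loglik <- function(spec, beta, sigma2, lambda) {
  stopifnot(inherits(spec, "pgls_spec"), sigma2 > 0)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  core <- .gls_core(spec$y, spec$X, .chol_jitter(.lambda_v(spec$V, lambda)))
  .gls_loglik_core(core, beta, sigma2)
}

#' PGLS chain settings
#'
#' @param iterations Total MCMC iterations.
#' @param burnin Fraction discarded.
#' @param samples Retained samples.
#' @param lambda_sd Random-walk step for lambda.
#' @param sigma2_box,beta_box Proper-prior supports (as in
#'   [varrates_config()]).
#' @return List of settings.
#' @export
pgls_config <- function(iterations = 2e4, burnin = 0.25, samples = 1000,
                        lambda_sd = 0.12, sigma2_box = c(1e-10, 1e6),
                        beta_box = 1e3) {
  list(iterations = iterations, burnin = burnin, samples = samples,
       lambda_sd = lambda_sd, sigma2_box = sigma2_box, beta_box = beta_box)
}

#' Bayesian PGLS by Metropolis-within-Gibbs
#'
#' Priors: coefficients uniform on a wide box, `sigma2` log-uniform,
#' `lambda` uniform on `[0, 1]`. Coefficients and `sigma2` are drawn from
#' exact conditionals, `lambda` by a reflected random walk accepted by
#' Metropolis.
#'
#' @param spec A [pgls_spec()] (or a data frame, in which case `response`,
#'   `covariates` and `tree` must be supplied and are passed to
#'   [pgls_spec()]).
#' @param config See [pgls_config()].
#' @param seed Integer seed; identical seeds give identical posteriors.
#' @param response,covariates,tree Used only when `spec` is a data frame.
#' @return Object of class `pgls_posterior`: `trace` tibble, `summary`
#'   tibble (term, estimate, sd, p_x), `lambda_acceptance`, `spec`.
#' @export
pgls_mcmc <- function(spec, config = pgls_config(), seed = 1,
                      response = NULL, covariates = NULL, tree = NULL) {
  if (is.data.frame(spec) && !inherits(spec, "pgls_spec"))
    spec <- pgls_spec(spec, response, covariates, tree)
  stopifnot(inherits(spec, "pgls_spec"))
  set.seed(seed)
  y <- spec$y
  X <- spec$X
  p <- ncol(X)
  n <- length(y)
  red <- .pgls_reduce(y, X, spec$V)

  lambda <- 0.5
  at <- .pgls_at(red, lambda)
  beta <- as.numeric(solve(at$XtVX, at$XtVy))
  sigma2 <- max(config$sigma2_box[1], .pgls_rss(red, at, beta) / n)
  ll <- .pgls_ll(red, at, beta, sigma2)

  iters <- config$iterations
  keep_at <- unique(round(seq(iters * config$burnin + 1, iters,
                              length.out = config$samples)))
  nk <- length(keep_at)
  tracem <- matrix(NA_real_, nk, 4 + p)
  srow <- 0
  acc <- 0

  for (it in seq_len(iters)) {
    # lambda: reflected random walk
    lam2 <- lambda + rnorm(1, 0, config$lambda_sd)
    lam2 <- abs(lam2)
    lam2 <- if (lam2 > 1) 2 - lam2 else lam2
    lam2 <- min(max(lam2, 0), 1)
    at2 <- .pgls_at(red, lam2)
    ll2 <- .pgls_ll(red, at2, beta, sigma2)
    if (log(runif(1)) < ll2 - ll) {
      lambda <- lam2
      at <- at2
      ll <- ll2
      acc <- acc + 1
    }
    # beta, sigma2 conditionals
    XtVXi <- chol2inv(chol(at$XtVX))
    bhat <- XtVXi %*% at$XtVy
    bprop <- as.numeric(bhat + t(chol(sigma2 * XtVXi)) %*% rnorm(p))
    if (all(abs(bprop) <= config$beta_box)) beta <- bprop
    rss <- .pgls_rss(red, at, beta)
    s2 <- 1 / rgamma(1, shape = n / 2, rate = rss / 2)
    if (s2 >= config$sigma2_box[1] && s2 <= config$sigma2_box[2]) sigma2 <- s2
    ll <- .pgls_ll(red, at, beta, sigma2)

    if (srow < nk && it == keep_at[srow + 1]) {
      srow <- srow + 1
      tracem[srow, ] <- c(it, sigma2, lambda, ll, beta)
    }
  }
  trace <- tibble::as_tibble(as.data.frame(tracem))
  names(trace) <- c("iteration", "sigma2", "lambda", "loglik", colnames(X))
  summ <- tibble::tibble(
    term = colnames(X),
    estimate = vapply(colnames(X), function(cn) mean(trace[[cn]]), 0),
    sd = vapply(colnames(X), function(cn) sd(trace[[cn]]), 0),
    p_x = vapply(colnames(X), function(cn) p_x_summary(trace[[cn]]), 0)
  )
  structure(list(trace = trace, summary = summ,
                 lambda_acceptance = acc / iters, spec = spec,
                 config = config, seed = seed),
            class = "pgls_posterior")
}

#' @export
print.pgls_posterior <- function(x, ...) {
  cat("<pgls_posterior> ", x$spec$response, " ~ ",
      paste(x$spec$covariates, collapse = " + "), "  (n = ",
      length(x$spec$y), ")\n", sep = "")
  print(x$summary)
  cat("posterior mean lambda = ", round(mean(x$trace$lambda), 3), "\n",
      sep = "")
  invisible(x)
}

#' Posterior crossing proportion p_x
#'
#' The fraction of a coefficient's posterior samples on the minority side of
#' zero; samples exactly at zero count as crossing (conservative). Values
#' below 0.05 are conventionally read as significant.
#'
#' @param x Numeric vector of posterior samples.
#' @return A value in `[0, 0.5]`.
#' @export
p_x_summary <- function(x) {
  if (!length(x)) stop("empty posterior trace", call. = FALSE)
  npos <- sum(x > 0)
  nneg <- sum(x < 0)
  nz <- length(x) - npos - nneg
  min(0.5, (min(npos, nneg) + nz) / length(x))
}
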