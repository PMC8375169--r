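# Stepping-stone estimation of log marginal likelihoods. The temperature
# ladder places the power-posterior exponents at quantiles of a
# Beta(alpha, beta) distribution (default alpha = 0.40, beta = 1), which
# concentrates stones near the prior where the integrand changes fastest.

#' Generic stepping-stone log marginal likelihood
#'
#' Runs a power-posterior ladder: at each stone the supplied `update`
#' function must advance an MCMC state targeting prior x likelihood^power,
#' and `loglik` must return the (untempered) log-likelihood of a state. The
#' stone contributions are accumulated with log-sum-exp.
#'
#' @param init Initial state (any R object; `power = 0` updates should
#'   sample from the prior).
#' @param update `function(state, power)` returning the next state.
#' @param loglik `function(state)` returning the log-likelihood.
#' @param stones Number of stones (>= 2).
#' @param iters Iterations per stone.
#' @param shape Beta-distribution shape `c(alpha, beta)` for the ladder.
#' @param burnin Fraction of each stone's iterations discarded.
#' @param seed Integer seed.
#' @return Object of class `logml_estimate`: list with `logml`, `stones`,
#'   `iters`, `shape`, `per_stone` tibble (power, next_power, contribution,
#'   mean_loglik).
#' @export
stepping_stone <- function(init, update, loglik, stones = 100, iters = 1000,
                           shape = c(0.4, 1), burnin = 0.1, seed = 1) {
  stopifnot(stones >= 2, iters >= 10)
  set.seed(seed)
  powers <- stats::qbeta(seq(0, 1, length.out = stones + 1),
                         shape[1], shape[2])
  state <- init
  drop <- ceiling(iters * burnin)
  contrib <- numeric(stones)
  meanll <- numeric(stones)
  for (j in seq_len(stones)) {
    bj <- powers[j]
    lls <- numeric(iters)
    for (i in seq_len(iters)) {
      state <- update(state, bj)
      lls[i] <- loglik(state)
    }
    lls <- lls[(drop + 1):iters]
    d <- powers[j + 1] - bj
    mx <- max(d * lls)
    contrib[j] <- mx + log(mean(exp(d * lls - mx)))
    meanll[j] <- mean(lls)
    if (!is.finite(contrib[j]))
      stop("non-finite contribution at stone ", j, " (power ",
           signif(bj, 4), ")", call. = FALSE)
  }
  structure(list(logml = sum(contrib), stones = stones, iters = iters,
                 shape = shape,
                 per_stone = tibble::tibble(power = powers[-length(powers)],
                                            next_power = powers[-1],
                                            contribution = contrib,
                                            mean_loglik = meanll)),
            class = "logml_estimate")
}

#' @export
print.logml_estimate <- function(x, ...) {
  cat("<logml_estimate> log marginal likelihood = ",
      format(x$logml, digits = 8), " (", x$stones, " stones x ", x$iters,
      " iterations)\n", sep = "")
  invisible(x)
}

#' Stepping-stone marginal likelihood of the variable-rates or single-rate model
#'
#' Estimates the log marginal likelihood of the regression under either the
#' variable-rates model (branch scalars active, reversible jump) or the
#' nested single-background-rate model. The two estimates combine into a
#' Bayes factor via [bayes_factor()]. Priors are proper: coefficients
#' uniform on a wide box, `sigma2_b` log-uniform on a box, scalar count
#' uniform, log scalars normal.
#'
#' @param design A [regression_design()].
#' @param tree Rooted `phylo` (defaults to the design's tree).
#' @param model `"variable"` or `"single"`.
#' @param stones,iters Ladder dimensions.
#' @param shape Beta shape for the temperature ladder.
#' @param seed Integer seed.
#' @param config See [varrates_config()] (priors and proposal scales).
#' @return A `logml_estimate` (with the model recorded in `$model`).
#' @export
stepping_stone_logml <- function(design, tree = design$tree,
                                 model = c("variable", "single"),
                                 stones = 100, iters = 1000,
                                 shape = c(0.4, 1), seed = 1,
                                 config = varrates_config()) {
  model <- match.arg(model)
  stopifnot(inherits(design, "regression_design"))
  y <- design$y
  X <- design$X
  p <- ncol(X)
  n <- length(y)
  M <- branch_tip_matrix(tree)
  tlen <- tree$edge.length
  E <- nrow(M)
  psd <- config$prior_lnr_sd
  s2box <- config$sigma2_box
  bbox <- config$beta_box

  build_core <- function(lnr) {
    w <- tlen * exp(lnr)
    V <- crossprod(M * sqrt(w))
    .gls_core(y, X, .chol_jitter(V))
  }

  init <- list(lnr = rep(0, E), assigned = logical(E),
               beta = rep(0, p), sigma2 = 1)
  init$core <- build_core(init$lnr)
  init$ll <- .gls_loglik_core(init$core, init$beta, init$sigma2)

  update <- function(state, power) {
    # scalar set (variable model only)
    if (model == "variable") {
      u <- runif(1)
      k <- sum(state$assigned)
      if (u < 1 / 3 && k < E) {           # birth from the prior
        b <- sample(which(!state$assigned), 1L)
        lnr2 <- state$lnr
        lnr2[b] <- rnorm(1, 0, psd)
        core2 <- build_core(lnr2)
        ll2 <- .gls_loglik_core(core2, state$beta, state$sigma2)
        if (log(runif(1)) < power * (ll2 - state$ll)) {
          state$assigned[b] <- TRUE
          state$lnr <- lnr2
          state$core <- core2
          state$ll <- ll2
        }
      } else if (u < 2 / 3 && k > 0) {    # death
        b <- if (k == 1) which(state$assigned) else sample(which(state$assigned), 1L)
        lnr2 <- state$lnr
        lnr2[b] <- 0
        core2 <- build_core(lnr2)
        ll2 <- .gls_loglik_core(core2, state$beta, state$sigma2)
        if (log(runif(1)) < power * (ll2 - state$ll)) {
          state$assigned[b] <- FALSE
          state$lnr <- lnr2
          state$core <- core2
          state$ll <- ll2
        }
      } else if (u >= 2 / 3 && k > 0) {   # perturb
        b <- if (k == 1) which(state$assigned) else sample(which(state$assigned), 1L)
        z <- state$lnr[b] + rnorm(1, 0, config$move_sd)
        lnr2 <- state$lnr
        lnr2[b] <- z
        core2 <- build_core(lnr2)
        ll2 <- .gls_loglik_core(core2, state$beta, state$sigma2)
        lpr <- stats::dnorm(z, 0, psd, log = TRUE) -
          stats::dnorm(state$lnr[b], 0, psd, log = TRUE)
        if (log(runif(1)) < power * (ll2 - state$ll) + lpr) {
          state$lnr <- lnr2
          state$core <- core2
          state$ll <- ll2
        }
      }
    }
    core <- state$core
    # beta: tempered conditional is normal with precision scaled by power;
    # at power 0 draw from the uniform box prior
    if (power > 1e-12) {
      XtVXi <- chol2inv(chol(core$XtVX))
      bhat <- XtVXi %*% core$XtVy
      bprop <- as.numeric(bhat + t(chol(state$sigma2 * XtVXi / power)) %*% rnorm(p))
      if (all(abs(bprop) <= bbox)) state$beta <- bprop
      rss <- sum((core$Ly - core$LX %*% state$beta)^2)
      s2 <- 1 / rgamma(1, shape = n * power / 2, rate = power * rss / 2)
      if (is.finite(s2) && s2 >= s2box[1] && s2 <= s2box[2]) state$sigma2 <- s2
    } else {
      state$beta <- runif(p, -bbox, bbox)
      state$sigma2 <- exp(runif(1, log(s2box[1]), log(s2box[2])))
    }
    state$ll <- .gls_loglik_core(core, state$beta, state$sigma2)
    state
  }

  out <- stepping_stone(init, update, function(s) s$ll, stones = stones,
                        iters = iters, shape = shape, seed = seed)
  out$model <- model
  out
}

#' Bayes factor from two marginal-likelihood estimates
#'
#' `BF = 2 (log m1 - log m0)`: positive values favour the first model
#' (conventionally the variable-rates model). The verbal category follows
#' Raftery's scale for 2 log Bayes factors.
#'
#' @param m1,m0 `logml_estimate` objects (or bare log marginal likelihoods).
#' @return Numeric BF with attribute `category`.
#' @export
bayes_factor <- function(m1, m0) {
  l1 <- if (inherits(m1, "logml_estimate")) m1$logml else as.numeric(m1)
  l0 <- if (inherits(m0, "logml_estimate")) m0$logml else as.numeric(m0)
  if (!is.finite(l1) || !is.finite(l0))
    stop("non-finite log marginal likelihood", call. = FALSE)
  bf <- 2 * (l1 - l0)
  cat_tbl <- c("no support", "weak", "positive", "strong", "very strong")
  category <- if (bf < 0) "favours the single-rate model" else
    cat_tbl[findInterval(bf, c(0, 2, 6, 10)) + 1][1]
  structure(bf, category = category)
}
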