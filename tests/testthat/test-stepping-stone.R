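test_that("stepping stone is exact for a point-mass (zero-variance) model", {
  # single state with constant likelihood L: log ml must equal log L exactly
  const <- -3.7
  est <- stepping_stone(init = list(), update = function(s, p) s,
                        loglik = function(s) const,
                        stones = 10, iters = 50, seed = 1)
  expect_equal(est$logml, const, tolerance = 1e-12)
})

test_that("stepping stone recovers the conjugate-normal evidence", {
  # y_i ~ N(mu, 1), mu ~ N(0, 1): evidence is N(y; 0, I + 11') with closed
  # form
  set.seed(7)
  n <- 5
  y <- rnorm(n, 0.8, 1)
  Sigma <- diag(n) + matrix(1, n, n)
  exact <- dmvnorm_log(y, rep(0, n), Sigma)
  loglik <- function(mu) sum(stats::dnorm(y, mu, 1, log = TRUE))
  update <- function(mu, power) {
    # exact tempered conditional: prior N(0,1), likelihood^power
    prec <- 1 + power * n
    mean_p <- power * sum(y) / prec
    rnorm(1, mean_p, sqrt(1 / prec))
  }
  ests <- vapply(1:3, function(s)
    stepping_stone(0, update, loglik, stones = 30, iters = 400,
                   seed = s)$logml, 0)
  se <- sd(ests)
  expect_lt(abs(mean(ests) - exact), max(3 * se, 0.05))

  # two stones only, still within tolerance of the exact evidence
  est2 <- stepping_stone(0, update, loglik, stones = 2, iters = 4000,
                         seed = 9)
  expect_lt(abs(est2$logml - exact), 0.25)
})

test_that("more iterations do not move the estimate beyond Monte Carlo error", {
  set.seed(12)
  n <- 6
  y <- rnorm(n, 0, 1)
  loglik <- function(mu) sum(stats::dnorm(y, mu, 1, log = TRUE))
  update <- function(mu, power) {
    prec <- 1 + power * n
    rnorm(1, power * sum(y) / prec, sqrt(1 / prec))
  }
  e1 <- vapply(1:4, function(s) stepping_stone(0, update, loglik, 20, 200,
                                               seed = s)$logml, 0)
  e2 <- vapply(1:4, function(s) stepping_stone(0, update, loglik, 20, 400,
                                               seed = 10 + s)$logml, 0)
  se <- sqrt(var(e1) / 4 + var(e2) / 4)
  expect_lt(abs(mean(e1) - mean(e2)), 4 * se + 0.02)
})

test_that("temperature ladder follows Beta(0.4, 1) quantiles", {
  est <- stepping_stone(list(), function(s, p) s, function(s) -1,
                        stones = 5, iters = 20, seed = 1)
  expect_equal(est$per_stone$power,
               qbeta(seq(0, 0.8, 0.2), 0.4, 1), tolerance = 1e-12)
  expect_equal(max(est$per_stone$next_power), 1)
})

test_that("bayes_factor arithmetic, category and antisymmetry", {
  expect_equal(as.numeric(bayes_factor(-100, -100)), 0)
  bf <- bayes_factor(-100, -110)
  expect_equal(as.numeric(bf), 20)
  expect_equal(attr(bf, "category"), "very strong")
  expect_equal(as.numeric(bayes_factor(-110, -100)), -20)
  expect_equal(as.numeric(bayes_factor(-3, -5)) ,
               -as.numeric(bayes_factor(-5, -3)))
  expect_error(bayes_factor(NaN, -1), "non-finite")
})

test_that("variable-rates marginal likelihood runs and favours truth", {
  # heterogeneous data: the variable-rates model should not be strongly
  # disfavoured; the estimate must be finite and reproducible
  sc <- simulation_scenario(n_taxa = 16, fast_set = "clade")
  tr <- simulate_tree(16, sc$depth, seed = 21)
  sim <- simulate_varrates_traits(tr, sc, seed = 21)
  des <- regression_design(sim$traits, tr)
  m1 <- stepping_stone_logml(des, tr, "variable", stones = 10, iters = 200,
                             seed = 3)
  m0 <- stepping_stone_logml(des, tr, "single", stones = 10, iters = 200,
                             seed = 4)
  expect_true(is.finite(m1$logml) && is.finite(m0$logml))
  m1b <- stepping_stone_logml(des, tr, "variable", stones = 10, iters = 200,
                              seed = 3)
  expect_equal(m1$logml, m1b$logml, tolerance = 1e-12)
})
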