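test_that("Yule and birth-death likelihoods nest at zero extinction", {
  set.seed(31)
  for (k in 1:20) {
    phy <- simulate_chronogram(yule_params(runif(1, 0.3, 2)), 8, 5)
    bt <- branching_times(phy)
    lam <- runif(1, 0.1, 3)
    for (cond in c("ntaxa", "survival")) {
      expect_equal(yule_loglik(bt, lam, cond), bd_loglik(bt, lam, 0, cond),
                   tolerance = 1e-10)
    }
  }
  # profile over eps = 0 equals the Yule supremum
  bt <- branching_times(simulate_chronogram(yule_params(1), 10, 5, seed = 32))
  lam_hat <- yule_mle(bt)$lambda_hat
  expect_equal(max(vapply(seq(0.1, 3, 0.001),
                          function(l) bd_loglik(bt, l, 0), numeric(1))),
               yule_loglik(bt, lam_hat), tolerance = 1e-5)
})

test_that("the likelihood depends only on the sorted branching times", {
  bt <- branching_times(simulate_chronogram(bd_params(0.7, 0.4), 9, 5,
                                            seed = 33))
  shuffled <- sample(bt)
  expect_identical(bd_loglik(bt, 0.6, 0.3), bd_loglik(shuffled, 0.6, 0.3))
})

test_that("Yule loglik vanishes as the rate goes to zero", {
  bt <- branching_times(simulate_chronogram(yule_params(1), 6, 5, seed = 34))
  # with the tip count informative, observing 6 tips at a vanishing rate is
  # impossible; with the tip count fixed the limit is the uniform density
  expect_lt(yule_loglik(bt, 1e-9, "survival"), -50)
  expect_lt(yule_loglik(bt, 1e-12, "survival"),
            yule_loglik(bt, 1e-9, "survival"))
  expect_equal(yule_loglik(bt, 1e-9, "ntaxa"), -4 * log(5), tolerance = 1e-6)
  expect_error(yule_loglik(bt, 0), "positive")
  expect_error(bd_loglik(bt, 0.5, 1), "eps")
})

test_that("the branching-time density matches the forward-simulation oracle", {
  # empirical CDF of post-root times from forward rejection vs the
  # numerically integrated exponential of the single-time log-likelihood
  model <- bd_params(expected_net_diversification(5, 2, 1), 0.5)
  set.seed(35)
  oracle <- unlist(replicate(1500, forward_bd_rejection(model, 5, 1)[-1],
                             simplify = FALSE))
  g <- function(x) exp(vapply(x, function(xi)
    bd_loglik(c(1, xi), model$r, model$epsilon, "ntaxa"), numeric(1)))
  grid <- seq(0.05, 0.95, by = 0.05)
  Fnum <- vapply(grid, function(q) stats::integrate(g, 0, q)$value,
                 numeric(1))
  ks_band <- 1.63 / sqrt(length(oracle))  # ~ alpha = 0.01 one-sample band
  expect_lt(max(abs(stats::ecdf(oracle)(grid) - Fnum)), ks_band)
  expect_equal(stats::integrate(g, 0, 1)$value, 1, tolerance = 1e-6)
})

test_that("Yule MLE agrees with a grid-refinement oracle", {
  bt <- c(5, 1)   # hand-built 3-tip tree
  for (cond in c("ntaxa", "survival")) {
    fit <- yule_mle(bt, cond)
    oracle <- grid_maximize(function(l) yule_loglik(bt, l, cond), 0.01, 5)
    expect_equal(fit$lambda_hat, oracle, tolerance = 1e-6)
  }
  bt2 <- branching_times(simulate_chronogram(yule_params(0.9), 12, 5,
                                             seed = 36))
  fit2 <- yule_mle(bt2)
  oracle2 <- grid_maximize(function(l) yule_loglik(bt2, l), 0.01, 5)
  expect_equal(fit2$lambda_hat, oracle2, tolerance = 1e-6)
})

test_that("birth-death MLE agrees with a 2-D grid-refinement oracle", {
  set.seed(37)
  for (k in 1:3) {
    bt <- branching_times(simulate_chronogram(bd_params(0.7, 0.5), 20, 5))
    fit <- bd_mle(bt)
    oracle <- grid_maximize_2d(function(r, e) bd_loglik(bt, r, e),
                               r_range = c(1e-6, 4), eps_range = c(0, 0.999))
    if (!fit$boundary) {
      expect_equal(fit$r_hat, unname(oracle["r"]), tolerance = 1e-4)
    }
    # on the eps -> 1 ridge only the likelihood value is identified
    expect_gte(bd_loglik(bt, fit$r_hat, fit$eps_hat),
               bd_loglik(bt, oracle["r"], oracle["eps"]) - 1e-6)
    expect_lt(abs(fit$loglik -
                  bd_loglik(bt, oracle["r"], oracle["eps"])), 0.01)
    # ML beats the generating parameters on the same tree
    expect_gte(fit$loglik, bd_loglik(bt, 0.7, 0.5))
  }
})

test_that("time rescaling scales rate estimates and leaves eps alone", {
  bt <- branching_times(simulate_chronogram(bd_params(0.6, 0.4), 15, 5,
                                            seed = 38))
  f1 <- yule_mle(bt); f2 <- yule_mle(2 * bt)
  expect_equal(f1$lambda_hat, 2 * f2$lambda_hat, tolerance = 1e-6)
  b1 <- bd_mle(bt); b2 <- bd_mle(2 * bt)
  expect_equal(b1$r_hat, 2 * b2$r_hat, tolerance = 1e-3)
  expect_equal(b1$eps_hat, b2$eps_hat, tolerance = 1e-2)
})

test_that("Yule rate is biased downward on birth-death trees, less so as n grows", {
  # under the tip-count-informative conditioning (the convention whose
  # lambda-on-birth-death fits mirror the reported "close to r" behaviour)
  set.seed(39)
  mean_lam <- vapply(c(25, 75), function(n) {
    r <- expected_net_diversification(n, 2, 5)
    mean(replicate(200, yule_mle(branching_times(
      simulate_chronogram(bd_params(r, 0.5), n, 5)),
      "survival")$lambda_hat)) /
      (2 * r)   # true lambda = 2 r at eps = 0.5
  }, numeric(1))
  expect_true(all(mean_lam < 1))
  expect_gt(mean_lam[2], mean_lam[1])
})

test_that("estimates carry tidy() and glance() methods", {
  bt <- branching_times(simulate_chronogram(bd_params(0.6, 0.4), 15, 5,
                                            seed = 40))
  fit <- bd_mle(bt)
  td <- tidy(fit)
  expect_setequal(td$term, c("r", "eps", "lambda"))
  expect_equal(td$estimate[td$term == "lambda"],
               fit$r_hat / (1 - fit$eps_hat))
  gl <- glance(fit)
  expect_equal(gl$n, 15L)
  expect_true(gl$converged)
})
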