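test_that("gamma matches the closed form and is scale invariant", {
  expect_equal(gamma_statistic(tree3()), -0.34641, tolerance = 1e-4)
  ## hand evaluation: g2 = g3 = 1, T = 5, numerator -0.5
  expect_equal(gamma_statistic(tree3()), -0.5 / (5 * sqrt(1 / 12)))
  tr <- sim_tree(simulation_spec(lambda0 = 1, mu = 0, ntip = 40), seed = 2)
  bt <- branching_times(tr)
  expect_equal(gamma_statistic(bt), gamma_statistic(bt * 10), tolerance = 1e-12)
  expect_error(gamma_statistic(c(2)), "at least 3")
})

test_that("the gamma test is one-sided with the add-one correction", {
  tr <- tree3()
  g <- gamma_test(tr, n_null = 200, seed = 1)
  expect_gt(g$p_value, 0)
  expect_lte(g$p_value, 1)
  ## a strongly positive gamma lands in the wrong tail
  bt_late <- c(10, 0.01 * (9:1))
  g2 <- gamma_test(bt_late, n_null = 200, seed = 1)
  expect_gt(g2$p_value, 0.9)
  expect_warning(gamma_test(tr, n_null = 50, seed = 1), "100")
})

test_that("constant-rate likelihood reduces to the Yule form at mu = 0", {
  bt <- branching_times(sim_tree(simulation_spec(0.5, ntip = 30), seed = 4))
  n <- length(bt) + 1
  la <- 0.37
  L <- sum(bt[-1]) + 2 * bt[1]      # total branch length
  expect_equal(crbd_loglik(bt, la, 0), (n - 2) * log(la) - la * L,
               tolerance = 1e-10)
  ## ML lambda for the Yule case matches an independent grid search
  f <- function(l) crbd_loglik(bt, l, 0)
  grid <- seq(0.01, 2, by = 1e-4)
  la_grid <- grid[which.max(vapply(grid, f, 0))]
  fit <- fit_diversification(bt, diversification_model("none", dd = FALSE, mu = 0))
  expect_equal(fit$estimates$la1, la_grid, tolerance = 1e-3)
  expect_equal(fit$estimates$la1, (n - 2) / L, tolerance = 1e-4)
  expect_error(crbd_loglik(bt, 0.1, 0.2), "lambda > mu")
})

test_that("diversity-dependent likelihood has the correct limits", {
  bt <- branching_times(sim_tree(simulation_spec(0.5, ntip = 25), seed = 6))
  expect_lt(abs(dd_loglik(bt, 0.4, 0, 1e9) - crbd_loglik(bt, 0.4, 0)), 1e-4)
  ## ODE path agrees with the closed constant-rate form when mu > 0
  bt8 <- branching_times(sim_tree(simulation_spec(0.4, mu = 0.15, ntip = 8),
                                  seed = 42))
  expect_equal(suppressWarnings(dd_loglik(bt8, 0.4, 0.15, 1e9, method = "ode")),
               crbd_loglik(bt8, 0.4, 0.15), tolerance = 1e-5)
})

test_that("the master equation matches the expm brute-force oracle", {
  skip_if_not_installed("Matrix")
  for (s in c(42, 7)) {
    tr <- sim_tree(simulation_spec(0.4, mu = 0.1, ntip = 7), seed = s)
    bt <- branching_times(tr)
    for (K in c(12, 30)) {
      got <- suppressWarnings(
        dd_loglik(bt, 0.45, 0.12, K, method = "ode", condition = FALSE))
      want <- dd_expm_oracle(bt, 0.45, 0.12, K, H = 60)
      expect_equal(got, want, tolerance = 1e-6)
    }
  }
})

test_that("nested specs never lose likelihood and weights behave", {
  tr <- sim_tree(simulation_spec(lambda0 = 0.12, mu = 0, K = 100, ntip = 60,
                                 crown_age = 40, shift_age = 14,
                                 lambda2 = 0.3), seed = 31)
  f0 <- fit_diversification(tr, diversification_model("none", dd = TRUE, mu = 0))
  f1 <- fit_diversification(tr, diversification_model("lambda", mu = 0))
  expect_gte(f1$logLik, f0$logLik - 1e-6)
  tab <- compare_models(list(none = f0, shift = f1))
  expect_equal(sum(tab$AICw), 1)
  ## weight invariance to a constant AIC offset
  w1 <- akaike_weights(c(100, 102, 107))
  w2 <- akaike_weights(c(0, 2, 7))
  expect_equal(w1, w2)
  expect_equal(akaike_weights(c(5, 5)), c(0.5, 0.5))
  expect_equal(akaike_weights(1), 1)
  ## spec collapse: no shift, no DD is the constant-rate fit
  fc <- fit_diversification(tr, diversification_model("none", dd = FALSE, mu = 0))
  bt <- branching_times(tr)
  expect_equal(fc$logLik, crbd_loglik(bt, fc$estimates$la1, 0), tolerance = 1e-8)
})
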