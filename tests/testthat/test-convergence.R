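test_that("hansen likelihood collapses to single-optimum OU", {
  tr <- sim_tree(simulation_spec(0.4, ntip = 20), seed = 8)
  pa0 <- regime_painting(tr, integer(0))
  X <- sim_regime_traits(tr, pa0, rbind(R0 = c(0, 0)), alpha = 0.5,
                         Sigma = diag(0.2, 2), seed = 5)
  th <- matrix(c(1, 1), 1, 2, dimnames = list("R0", NULL))
  ll1 <- hansen_loglik(tr, X, pa0, alpha = c(.5, .5), sigma2 = c(.2, .2),
                       theta = th)
  V <- model_covariance(tr, trait_model("OU"),
                        list(Sigma1 = diag(.2, 2), alpha1 = .5))$V
  U <- chol(V)
  r <- backsolve(U, as.vector(X) - 1, transpose = TRUE)
  ll2 <- -0.5 * (2 * nrow(X) * log(2 * pi) + 2 * sum(log(diag(U))) + sum(r^2))
  expect_equal(ll1, ll2, tolerance = 1e-6)
  expect_error(hansen_loglik(tr, X, pa0, c(-1, 1), c(.2, .2), th), "alpha")
})

test_that("hansen weights are a partition of unity and decay correctly", {
  tr <- sim_tree(simulation_spec(0.4, ntip = 15), seed = 2)
  e <- which(tr$edge[, 2] > length(tr$tip.label))[2]
  pa <- regime_painting(tr, e)
  for (a in c(0.05, 0.5, 3)) {
    W <- karstrad:::hansen_weights(tr, pa, a, c("R0", "R1"))
    expect_equal(unname(rowSums(W)), rep(1, nrow(W)), tolerance = 1e-10)
  }
  ## strong attraction: tip expectation is its own regime's optimum
  W <- karstrad:::hansen_weights(tr, pa, 50, c("R0", "R1"))
  own <- karstrad:::clade_tips(tr, tr$edge[e, 2])
  expect_true(all(W[own, "R1"] > 0.999))
  expect_true(all(W[-own, "R0"] > 0.999))
})

test_that("painting covers every branch and shifts paint whole subtrees", {
  tr <- sim_tree(simulation_spec(0.4, ntip = 15), seed = 2)
  e <- which(tr$edge[, 2] > length(tr$tip.label))[2]
  pa <- regime_painting(tr, e)
  expect_length(pa$regime, nrow(tr$edge))
  sub <- karstrad:::clade_tips(tr, tr$edge[e, 2])
  expect_true(all(pa$regime[tr$edge[, 2] %in% sub] == "R1"))
  expect_equal(pa$regime[e], "R1")
  expect_equal(pa$root_regime, "R0")
})

test_that("forward search improves AICc monotonically and backward never worsens it", {
  tr <- sim_tree(simulation_spec(0.4, ntip = 48), seed = 11)
  n <- length(tr$tip.label)
  intern <- which(tr$edge[, 2] > n)
  sizes <- vapply(tr$edge[intern, 2],
                  function(v) length(karstrad:::clade_tips(tr, v)), 0L)
  e1 <- intern[which(sizes >= 8 & sizes <= 14)[1]]
  pa <- regime_painting(tr, e1, "P")
  X <- sim_regime_traits(tr, pa, rbind(R0 = c(0, 0), P = c(4, 4)),
                         alpha = 1.2, Sigma = diag(0.5, 2), seed = 12)
  fw <- surface_forward(tr, X, max_shifts = 4)
  expect_true(all(diff(fw$aicc) < 0))
  bk <- surface_backward(fw)
  expect_lte(bk$aicc, fw$final$AICc + 1e-9)
  expect_equal(bk$n_convergent + bk$n_unique, bk$n_regimes)
  ## the planted clade is found (its edges share one non-root regime)
  reg <- bk$painting$regime[tr$edge[, 2] %in% karstrad:::clade_tips(tr, tr$edge[e1, 2])]
  expect_gt(max(table(reg)) / length(reg), 0.7)
})

test_that("noise fits stay finite under the shift cap", {
  tr <- sim_tree(simulation_spec(0.4, ntip = 20), seed = 31)
  set.seed(32)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(tr$tip.label, NULL))
  fw <- surface_forward(tr, X, max_shifts = 3)
  expect_lte(length(fw$shifts), 3)
  expect_true(is.finite(fw$final$AICc))
})
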