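test_that("model covariance has the analytic 2-tip form and exact limits", {
  tr <- read_timetree("(A:1,B:1);")
  X <- matrix(c(0, 2), 2, 1, dimnames = list(c("A", "B"), "t"))
  mc <- model_covariance(tr, trait_model("BM"), list(Sigma1 = matrix(1)))
  expect_equal(unname(mc$V), diag(2))
  expect_equal(karstrad:::trait_model_loglik(mc$V, X)$ll,
               2 * (-0.5 * log(2 * pi) - 0.5), tolerance = 1e-6)
  expect_equal(karstrad:::trait_model_loglik(mc$V, X)$ll, -2.8379,
               tolerance = 1e-4)
})

test_that("shift models are continuous in their parameters", {
  tr <- sim_tree(simulation_spec(0.5, ntip = 24), seed = 3)
  S1 <- matrix(c(1, 0.3, 0.3, 0.6), 2)
  s <- tree_height(tr) / 3
  for (mode in c("BM", "EB", "OU")) {
    pars <- list(Sigma1 = S1, r1 = -0.1, alpha1 = 0.4,
                 r2 = -0.1, alpha2 = 0.4)
    V1 <- model_covariance(tr, trait_model(mode), pars)$V
    V2 <- model_covariance(tr, trait_model(mode, mode, shift_age = s), pars)$V
    expect_lt(max(abs(V1 - V2)), 1e-8)
  }
  ## EB with r = 0 equals BM
  Vb <- model_covariance(tr, trait_model("BM"), list(Sigma1 = S1))$V
  Ve <- model_covariance(tr, trait_model("EB"), list(Sigma1 = S1, r1 = 0))$V
  expect_equal(Vb, Ve)
})

test_that("covariance builder matches a simulation estimate on 4 tips", {
  tr <- tree4()
  spec <- trait_model("BM", "EB", shift_age = 1, independent_drift = TRUE)
  pars <- list(Sigma1 = matrix(0.8), Sigma2 = matrix(2), r2 = -0.5)
  V <- model_covariance(tr, spec, pars)$V
  sims <- vapply(1:20000, function(s) {
    m <- trait_sim_spec(matrix(0.8), "BM", shift_age = 1,
                        shift = trait_sim_spec(matrix(2), "EB", r = -0.5))
    sim_traits(tr, m, seed = s)$tips[, 1]
  }, numeric(4))
  Vemp <- cov(t(sims))
  expect_lt(max(abs(V - Vemp)), 0.08)
})

test_that("fitting respects nesting and flags parameter counts", {
  tr <- sim_tree(simulation_spec(0.12, ntip = 40), seed = 8)
  X <- sim_traits(tr, trait_sim_spec(diag(c(0.05, 0.04))), seed = 9)$tips
  fBM <- fit_trait_model(tr, X, trait_model("BM"))
  fEB <- fit_trait_model(tr, X, trait_model("EB"))
  fSh <- fit_trait_model(tr, X, trait_model("BM", "EB",
                                            shift_age = tree_height(tr) / 3,
                                            independent_drift = TRUE))
  expect_equal(fBM$k, 5)    # Sigma (3) + mean (2)
  expect_equal(fEB$k, 6)
  expect_equal(fSh$k, 9)    # two Sigmas + r + mean
  expect_gte(fEB$logLik, fBM$logLik - 1e-4)
  expect_gte(fSh$logLik, fBM$logLik - 1e-4)
  tab <- compare_trait_models(list(fBM, fEB, fSh))
  expect_equal(sum(tab$AICw), 1)
})

test_that("the model set enumerates the full shift family", {
  specs <- trait_model_set(15.5)
  expect_length(specs, 15)
  expect_true("Brownian motion to early burst with independent drift" %in%
                names(specs))
  expect_length(unique(names(specs)), 15)
})

test_that("adding a hopeless model leaves Akaike weights unchanged", {
  w1 <- akaike_weights(c(0, 2.78, 3.02))
  w2 <- akaike_weights(c(0, 2.78, 3.02, 200))
  expect_equal(w1, w2[1:3], tolerance = 1e-10)
  expect_lt(w2[4], 1e-10)
})
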