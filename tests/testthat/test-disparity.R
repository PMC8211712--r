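test_that("disparity equals the brute-force pair enumeration", {
  expect_equal(disparity(matrix(c(0, 2))), 4)
  expect_equal(disparity(matrix(c(0, 1, 2))), 2)
  expect_equal(disparity(matrix(5, 1, 1)), 0)
  expect_error(disparity(matrix(numeric(0), 0, 1)), "empty")
  set.seed(1)
  for (i in 1:5) {
    X <- matrix(rnorm(7 * 3), 7, 3)
    expect_equal(disparity(X), disparity_loops(X), tolerance = 1e-12)
  }
})

test_that("DTT curve matches hand-computed 4-tip constructions", {
  tr <- tree4()
  ## trait = clade indicator: subclades are invariant, all variation
  ## between clades, so the post-root value is 0
  X1 <- matrix(c(0, 0, 10, 10), 4, 1,
               dimnames = list(c("A", "B", "C", "D"), "t"))
  d1 <- dtt_curve(tr, X1)
  expect_equal(d1$disparity[1], 1)          # root: whole clade
  expect_equal(d1$disparity[2], 0)          # just after the root split
  ## within-pair variation swapped across clades: subclade disparity 100,
  ## whole-clade 400/6, mean relative = 1.5 (enumeration oracle)
  X2 <- matrix(c(0, 10, 0, 10), 4, 1,
               dimnames = list(c("A", "B", "C", "D"), "t"))
  d2 <- dtt_curve(tr, X2)
  expect_equal(d2$disparity[2], 100 / (400 / 6))
  expect_equal(d2$disparity[2], 1.5)
  expect_equal(d2$disparity[length(d2$disparity)], 0)  # present: singletons
  expect_error(dtt_curve(tr, X1 * 0), "degenerate")
})

test_that("MDI is the trapezoidal integral of the curve difference", {
  tr <- sim_tree(simulation_spec(0.8, ntip = 20), seed = 3)
  X <- sim_traits(tr, trait_sim_spec(diag(2)), seed = 4)$tips
  obs <- dtt_curve(tr, X)
  nulls <- dtt_null(tr, X, n_sims = 50, seed = 5)
  ## observed identical to the null mean integrates to zero
  fake <- colMeans(nulls)
  m0 <- mdi(fake, nulls, rel_time = obs$rel_time)
  expect_equal(m0$mdi, 0, tolerance = 1e-12)
  ## constant offset integrates to the offset (grid spans 0..1)
  m1 <- mdi(fake + 0.1, nulls, rel_time = obs$rel_time)
  expect_equal(m1$mdi, 0.1, tolerance = 1e-12)
  ## antisymmetry
  m2 <- mdi(fake - 0.07, nulls, rel_time = obs$rel_time)
  expect_equal(m2$mdi, -0.07, tolerance = 1e-12)
  expect_error(mdi(fake[-1], nulls, rel_time = obs$rel_time[-1]), "match")
  expect_error(dtt_null(tr, X, n_sims = 0), "positive")
})

test_that("rank envelope p-interval hits its extreme-rank bounds", {
  set.seed(2)
  nulls <- matrix(rnorm(99 * 12), 99, 12)
  obs <- rep(10, 12)                        # strictly above everywhere
  e <- rank_envelope_test(obs, nulls)
  expect_equal(e$p_interval[1], 1 / 100)
  expect_lte(e$p, 1 / 100 + 1e-12)
  ## pointwise band flags the exceedance
  pw <- pointwise_envelope(obs, nulls)
  expect_true(all(pw$outside))
  pw2 <- pointwise_envelope(colMeans(nulls), nulls)
  expect_true(mean(pw2$outside) < 0.2)
})

test_that("the DTT wrapper returns a coherent test object", {
  tr <- sim_tree(simulation_spec(0.8, ntip = 24), seed = 13)
  X <- sim_traits(tr, trait_sim_spec(diag(3) * 0.5), seed = 14)$tips
  res <- dtt_test(tr, X, n_sims = 120, seed = 15)
  expect_true(is.finite(res$mdi))
  expect_gte(res$p_interval[1], 1 / 121)
  expect_lte(res$p_interval[1], res$p_interval[2])
  expect_true(all(res$observed$disparity >= 0))
})

test_that("missing trait rows are dropped listwise and the tree pruned", {
  tr <- sim_tree(simulation_spec(0.8, ntip = 20), seed = 23)
  X <- sim_traits(tr, trait_sim_spec(diag(2)), seed = 24)$tips
  X[c(2, 5), 1] <- NA
  d <- dtt_curve(tr, X)
  expect_equal(length(d$disparity), 18)     # (n - 1) events + present
  expect_equal(nrow(attr(d, "traits")), 18)
})
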