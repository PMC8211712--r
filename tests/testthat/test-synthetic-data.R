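test_that("pure-birth simulation hits the tip-count target and is seeded", {
  sp <- simulation_spec(lambda0 = 1, mu = 0, ntip = 50)
  tr <- sim_tree(sp, seed = 10)
  expect_equal(length(tr$tip.label), 50)
  expect_s3_class(tr, "timetree")
  tr2 <- sim_tree(sp, seed = 10)
  expect_identical(write_timetree(tr), write_timetree(tr2))
  tr3 <- sim_tree(sp, seed = 11)
  expect_false(identical(write_timetree(tr), write_timetree(tr3)))
})

test_that("diversity dependence holds richness near the carrying capacity", {
  ## long-run standing diversity fluctuates near K
  final_n <- vapply(1:60, function(i) {
    tr <- sim_tree(simulation_spec(lambda0 = 0.5, mu = 0, K = 40,
                                   crown_age = 40), seed = 100 + i)
    length(tr$tip.label)
  }, 0)
  expect_lt(abs(mean(final_n) - 40) / 40, 0.1)
})

test_that("pure-birth gamma is centred at zero", {
  g <- vapply(1:400, function(i)
    gamma_statistic(karstrad:::yule_branching_times(100)), 0)
  expect_lt(abs(mean(g)), 0.1)
  expect_lt(abs(sd(g) - 1), 0.15)
})

test_that("discrete simulation matches the analytic event expectation", {
  Q <- q2(0.5)
  tr <- read_timetree("(A:1,B:1);")
  seeds <- 1:4000
  nev <- vapply(seeds, function(s)
    nrow(map_changes(sim_discrete(tr, Q, seed = s))), 0)
  ## 2 My of branch at total leaving rate 0.5
  expect_equal(mean(nev), 1.0, tolerance = 0.06)
  ## frozen process: essentially no events, tips = root state
  m <- sim_discrete(tr, q2(1e-12), seed = 1)
  expect_equal(nrow(map_changes(m)), 0)
  expect_equal(length(unique(map_tip_states(m))), 1L)
})

test_that("trait simulation has the exact Brownian tip variance", {
  tr <- read_timetree("(A:1,B:1);")
  spec <- trait_sim_spec(matrix(1))
  x <- vapply(1:4000, function(s) sim_traits(tr, spec, seed = s)$tips[1, 1], 0)
  expect_equal(var(x), 1, tolerance = 0.08)
  ## EB with r = 0 is BM in distribution
  y <- vapply(1:800, function(s)
    sim_traits(tr, trait_sim_spec(matrix(1), "EB", r = 0), seed = 9000 + s)$tips[1, 1], 0)
  x2 <- vapply(1:800, function(s) sim_traits(tr, spec, seed = 17000 + s)$tips[1, 1], 0)
  expect_gt(ks.test(y, x2)$p.value, 0.01)
  ## strong OU attraction pins tips at the optimum
  z <- sim_traits(sim_tree(simulation_spec(1, ntip = 30), seed = 2),
                  trait_sim_spec(matrix(1), "OU", alpha = 50,
                                 theta = 3, root = 3), seed = 5)$tips
  expect_lt(max(abs(z - 3)), 0.5)
})

test_that("regime-painted OU pulls clades to their optima", {
  tr <- sim_tree(simulation_spec(lambda0 = 0.5, mu = 0, ntip = 30), seed = 7)
  n <- length(tr$tip.label)
  intern <- which(tr$edge[, 2] > n)
  sizes <- vapply(tr$edge[intern, 2],
                  function(v) length(karstrad:::clade_tips(tr, v)), 0L)
  e1 <- intern[which(sizes >= 8 & sizes <= 15)[1]]
  pa <- regime_painting(tr, e1, "P")
  in_clade <- tr$tip.label[karstrad:::clade_tips(tr, tr$edge[e1, 2])]
  X <- sim_regime_traits(tr, pa, rbind(R0 = 0, P = 6), alpha = 2,
                         Sigma = matrix(0.1), seed = 3)
  expect_lt(max(abs(X[setdiff(rownames(X), in_clade), ])), 3)
  expect_gt(min(X[in_clade, ]), 3)
  expect_error(sim_regime_traits(tr, pa, rbind(R0 = 0), 2, matrix(.1)),
               "optima missing")
})

test_that("the reference dataset has the advertised structure", {
  b <- make_reference_dataset(seed = 1)
  expect_equal(length(b$tree$tip.label), 377)
  expect_equal(tree_height(b$tree), 47, tolerance = 1e-8)
  expect_equal(unname(vapply(b$clades, length, 0L)),
               c(28, 41, 29, 41, 38, 25))
  for (cl in b$clades) expect_true(is_clade(b$tree, cl))
  expect_equal(sum(!is.na(b$habitats)), 331)
  expect_equal(sum(complete.cases(b$traits)), 256)
  expect_equal(nrow(b$coords), 377)
  ## determinism
  b2 <- make_reference_dataset(seed = 1)
  expect_identical(write_timetree(b$tree), write_timetree(b2$tree))
  expect_identical(b$traits, b2$traits)
  expect_identical(b$habitats, b2$habitats)
  ## the built-in shift forces a detectable early burst
  g <- gamma_test(b$tree, n_null = 1000, seed = 7)
  expect_lt(g$gamma, 0)
  expect_lte(g$p_value, 0.01)
})

test_that("the bundle writes and reads back as plain text", {
  b <- make_reference_dataset(seed = 3)
  d <- tempfile()
  write_dataset_bundle(b, d)
  expect_true(all(file.exists(file.path(d, c("tree.nwk", "traits.tsv",
                                             "habitats.tsv", "coords.tsv",
                                             "clades.tsv", "manifest.tsv")))))
  tr <- read_timetree(file.path(d, "tree.nwk"))
  expect_equal(length(tr$tip.label), 377)
  tab <- read_tip_table(file.path(d, "traits.tsv"))
  expect_equal(ncol(tab), 11)
})

test_that("constant-rate fits recover the speciation rate without gross bias", {
  est <- t(vapply(1:60, function(i) {
    tr <- sim_tree(simulation_spec(lambda0 = 0.3, mu = 0.1, crown_age = 17),
                   seed = 5000 + i)
    f <- fit_diversification(tr, diversification_model("none", dd = FALSE),
                             n_starts = 4)
    c(f$estimates$la1, f$estimates$mu1)
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 0.3) / 0.3, 0.2)
  ## the ML extinction rate carries its well-known small-sample upward
  ## bias; assert a sanity window rather than unbiasedness
  expect_gt(mean(est[, 2]), 0)
  expect_lt(mean(est[, 2]), 0.2)
})
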