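test_that("PGLS residuals reduce to OLS on a star tree", {
  star <- ape::stree(8, "star")
  star$tip.label <- LETTERS[1:8]
  star$edge.length <- rep(1, 8)
  star$root.edge <- 0
  star <- suppressWarnings(as_timetree(star))
  set.seed(4)
  x <- setNames(rnorm(8, 10, 2), star$tip.label)
  y <- setNames(2 * x + rnorm(8), star$tip.label)
  res <- pgls_residuals(star, y, x)
  ols <- residuals(lm(y ~ x))
  expect_equal(unname(res[names(ols)]), unname(ols), tolerance = 1e-10)
  ## exact linear relation leaves zero residuals
  y2 <- 2 * x
  expect_equal(max(abs(pgls_residuals(star, y2, x))), 0, tolerance = 1e-10)
  ## intercept absorption
  res3 <- pgls_residuals(star, y + 5, x)
  expect_equal(unname(res3), unname(res), tolerance = 1e-10)
  expect_error(pgls_residuals(star, y, setNames(rep(1, 8), names(x))),
               "singular")
})

test_that("phylogenetic PCA reduces to ordinary PCA on a star tree", {
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, 12)
  star$root.edge <- 0
  star <- suppressWarnings(as_timetree(star))
  set.seed(5)
  X <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(star$tip.label, NULL))
  pp <- phylo_pca(star, X)
  ord <- prcomp(X)
  expect_equal(pp$values, ord$sdev[1:4]^2, tolerance = 1e-8)
  for (k in 1:2) {
    expect_equal(abs(cor(pp$scores[, k], ord$x[, k])), 1, tolerance = 1e-8)
  }
  expect_true(all(diff(pp$values) <= 1e-12))
  ## duplicated trait column collapses into the leading axis
  Xd <- cbind(X[, 1], X[, 1], X[, 2])
  rownames(Xd) <- star$tip.label
  expect_warning(ppd <- phylo_pca(star, Xd), "rank-deficient")
  expect_gt(ppd$values[1] / sum(ppd$values), 0.6)
})

test_that("pPCA scores are centred on the GLS mean", {
  tr <- sim_tree(simulation_spec(0.6, ntip = 25), seed = 6)
  X <- sim_traits(tr, trait_sim_spec(diag(3)), seed = 7)$tips
  pp <- phylo_pca(tr, X)
  C <- ape::vcv(tr)[rownames(pp$scores), rownames(pp$scores)]
  iC1 <- solve(C, rep(1, nrow(C)))
  gmean <- drop(crossprod(pp$scores, iC1)) / sum(iC1)
  expect_equal(unname(gmean), rep(0, ncol(pp$scores)), tolerance = 1e-8)
})

test_that("squared contrasts recover the BM rate (known identity)", {
  tr <- sim_tree(simulation_spec(0.6, ntip = 40), seed = 8)
  x <- sim_traits(tr, trait_sim_spec(matrix(2.5)), seed = 9)$tips[, 1]
  pic <- ape::pic(x, tr)
  C <- ape::vcv(tr)
  ones <- rep(1, nrow(C))
  iC <- solve(C)
  mu <- drop(ones %*% iC %*% x) / drop(ones %*% iC %*% ones)
  s2_gls <- drop(t(x - mu) %*% iC %*% (x - mu)) / (length(x) - 1)
  expect_equal(mean(pic^2), s2_gls, tolerance = 1e-8)
})

test_that("single-contrast value matches the hand computation", {
  tr2 <- read_timetree("(A:1,B:1);")
  x <- c(A = 3, B = 1)
  expect_equal(unname(ape::pic(x[tr2$tip.label], tr2))[1], (3 - 1) / sqrt(2),
               tolerance = 1e-10)
  expect_equal((3 - 1) / sqrt(2), 1.41421, tolerance = 1e-5)
  expect_error(node_height_test(tr2, x), "at least 4")
})

test_that("ward clustering recovers separated blobs and handles k = n", {
  set.seed(10)
  X <- rbind(matrix(rnorm(20 * 3, 0, 0.3), 20, 3),
             matrix(rnorm(15 * 3, 8, 0.3), 15, 3))
  rownames(X) <- paste0("s", 1:35)
  cl <- ward_clusters(X, 2)
  expect_equal(length(unique(cl$labels[1:20])), 1)
  expect_equal(length(unique(cl$labels[21:35])), 1)
  expect_false(cl$labels[1] == cl$labels[35])
  cln <- ward_clusters(X, nrow(X))
  expect_equal(length(unique(cln$labels)), 35)
  expect_error(ward_clusters(X, 36), "exceeds")
})
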