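test_that("spherical coordinate conversion is exact and invertible", {
  expect_equal(unname(to_cartesian(0, 0)), matrix(c(1, 0, 0), 1))
  expect_equal(unname(to_cartesian(90, 0)), matrix(c(0, 1, 0), 1),
               tolerance = 1e-12)
  set.seed(3)
  lon <- runif(1000, -180, 180); lat <- runif(1000, -90, 90)
  back <- from_cartesian(to_cartesian(lon, lat))
  expect_lt(max(abs(back$lon - lon)), 1e-9)
  expect_lt(max(abs(back$lat - lat)), 1e-9)
  expect_error(to_cartesian(200, 0), "longitude")
  expect_error(from_cartesian(matrix(0, 1, 3)), "zero vector")
})

test_that("identical tip positions reconstruct exactly", {
  tr <- sim_tree(simulation_spec(0.5, ntip = 12), seed = 4)
  coords <- data.frame(lon = rep(14.5, 12), lat = rep(46, 12),
                       row.names = tr$tip.label)
  rec <- geo_reconstruct(tr, coords, n_draws = 200, seed = 5)[[1]]
  expect_equal(rec$centroid$lon, 14.5, tolerance = 1e-6)
  expect_equal(rec$centroid$lat, 46, tolerance = 1e-6)
  expect_lt(max(abs(rec$retained$lon - 14.5)), 1e-6)
})

test_that("the root conditional mean equals the GLS phylogenetic mean", {
  tr <- sim_tree(simulation_spec(0.5, ntip = 20), seed = 6)
  b <- make_reference_dataset(seed = 2, ntip = 38)
  coords <- b$coords[b$tree$tip.label, ]
  rec <- geo_reconstruct(b$tree, coords, n_draws = 5000, seed = 7)[[1]]
  xyz <- to_cartesian(coords$lon, coords$lat)
  rownames(xyz) <- rownames(coords)
  C <- ape::vcv(b$tree)
  iC1 <- solve(C, rep(1, nrow(C)))
  gls <- drop(crossprod(xyz[colnames(C), ], iC1)) / sum(iC1)
  gls_ll <- from_cartesian(matrix(gls, 1))
  expect_equal(rec$conditional_mean$lon, gls_ll$lon, tolerance = 1e-6)
  expect_equal(rec$conditional_mean$lat, gls_ll$lat, tolerance = 1e-6)
})

test_that("reconstruction is equivariant under rotation of the inputs", {
  b <- make_reference_dataset(seed = 3, ntip = 38)
  coords <- b$coords[b$tree$tip.label, ]
  rec1 <- geo_reconstruct(b$tree, coords, n_draws = 50, seed = 9)[[1]]
  shift <- 40   # rotation about the polar axis = longitude shift
  coords2 <- coords
  coords2$lon <- ((coords$lon + shift + 180) %% 360) - 180
  rec2 <- geo_reconstruct(b$tree, coords2, n_draws = 50, seed = 9)[[1]]
  d <- ((rec2$conditional_mean$lon - rec1$conditional_mean$lon - shift + 180) %% 360) - 180
  expect_equal(d, 0, tolerance = 1e-6)
  expect_equal(rec2$conditional_mean$lat, rec1$conditional_mean$lat,
               tolerance = 1e-6)
})

test_that("credible regions trim exactly the planted far outliers", {
  set.seed(11)
  base <- to_cartesian(rnorm(95, 10, 0.5), rnorm(95, 45, 0.5))
  out <- to_cartesian(rep(-170, 5), rep(-60, 5))
  cr <- credible_region(rbind(base, out))
  expect_equal(cr$n_retained, 95)
  expect_lt(max(cr$retained$lat), 60)
  expect_true(all(cr$retained$lat > 0))     # outliers gone
  expect_equal(cr$n_retained, ceiling(0.95 * 100))
  expect_error(credible_region(base[1:10, ]), "20 samples")
  expect_error(credible_region(rbind(to_cartesian(0, 0)[rep(1, 10), ],
                                     to_cartesian(180, 0)[rep(1, 10), ])),
               "antipodally")
})

test_that("time-slice targets cover every lineage crossing the slice", {
  b <- make_reference_dataset(seed = 4, ntip = 38)
  age <- tree_height(b$tree) * 0.4
  rec <- geo_reconstruct(b$tree, b$coords, at_age = age, n_draws = 50,
                         seed = 13)
  expect_equal(length(rec), unname(lineages_at_time(b$tree, age)))
  expect_error(geo_reconstruct(b$tree, b$coords, at_age = 100), "older")
})
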