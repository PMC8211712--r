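test_that("Newick parsing yields a validated ultrametric time tree", {
  tr <- tree3()
  expect_s3_class(tr, "timetree")
  expect_equal(tree_height(tr), 2)
  expect_equal(branching_times(tr), c(2, 1))
  expect_error(read_timetree("((A:1,B:2):1,C:2);"), "ultrametric")
  expect_error(read_timetree("((A:1,A:1):1,C:2);"), "duplicate")
})

test_that("writing then reading preserves topology and branch lengths", {
  tr <- sim_tree(simulation_spec(lambda0 = 1, mu = 0, ntip = 100), seed = 3)
  f <- tempfile(fileext = ".nwk")
  write_timetree(tr, f)
  tr2 <- read_timetree(f)
  expect_equal(sort(tr$tip.label), sort(tr2$tip.label))
  expect_equal(branching_times(tr), branching_times(tr2), tolerance = 1e-9)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
})

test_that("lineage counts through time behave at the boundaries", {
  tr <- tree3()
  expect_equal(lineages_at_time(tr, 1.5), 2L)
  expect_equal(lineages_at_time(tr, 0.5), 3L)
  expect_equal(lineages_at_time(tr, 0), 3L)
  expect_equal(lineages_at_time(tr, 2), 2L)   # just below the crown node
  expect_error(lineages_at_time(tr, 2.5), "crown")
  ## edge-length conservation: sum over bins of count x width = total length
  tr2 <- sim_tree(simulation_spec(lambda0 = 0.8, mu = 0.2, ntip = 40), seed = 5)
  breaks <- seq(0, tree_height(tr2), length.out = 200)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  approx_len <- sum(lineages_at_time(tr2, mids) * diff(breaks))
  expect_equal(approx_len, sum(tr2$edge.length), tolerance = 0.02)
})

test_that("clade extraction preserves ages and rejects paraphyly", {
  tr <- tree3()
  sub <- extract_clade(tr, c("A", "B"))
  expect_equal(tree_height(sub), 1)
  expect_error(extract_clade(tr, c("A", "C")), "intruding tips: B")
  ## branching times of a clade are a subset of the parent tree's
  big <- sim_tree(simulation_spec(lambda0 = 0.6, mu = 0, ntip = 60), seed = 9)
  nd <- big$edge[which(big$edge[, 2] > length(big$tip.label))[5], 2]
  tips <- big$tip.label[karstrad:::clade_tips(big, nd)]
  sub2 <- extract_clade(big, tips)
  expect_true(all(vapply(branching_times(sub2), function(b)
    any(abs(branching_times(big) - b) < 1e-9), TRUE)))
})

test_that("branching times agree with an independent depth-first computation", {
  tr <- sim_tree(simulation_spec(lambda0 = 1, mu = 0, ntip = 50), seed = 11)
  bt <- branching_times(tr)
  expect_length(bt, 49)
  expect_equal(max(bt), tree_height(tr))
  expect_equal(sort(bt, decreasing = TRUE),
               sort(unname(ape::branching.times(tr)), decreasing = TRUE),
               tolerance = 1e-9)
})

test_that("polytomies are resolved to zero-length binary splits with a warning", {
  expect_warning(tr <- as_timetree(ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")),
                 "polytomies")
  expect_true(ape::is.binary(tr))
  expect_equal(tree_height(tr), 2)
})

test_that("clade validation enforces monophyly and disjointness", {
  tr <- tree4()
  expect_silent(validate_clades(tr, list(x = c("A", "B"), y = c("C", "D"))))
  expect_error(validate_clades(tr, list(x = c("A", "B"), y = c("B", "C"))),
               "disjoint")
  expect_error(validate_clades(tr, list(x = c("A", "C"))), "monophyletic")
})
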