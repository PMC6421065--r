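test_that("expected_net_diversification inverts the tip-count expectation", {
  expect_equal(round(expected_net_diversification(25, 2, 5), 4), 0.5051)
  expect_equal(round(expected_net_diversification(100, 2, 5), 4), 0.7824)
  expect_equal(expected_net_diversification(2, 2, 5), 0)
  expect_error(expected_net_diversification(25, 2, 0), "positive")
  expect_error(expected_net_diversification(1, 2, 5), "at least")
})

test_that("simulated chronograms satisfy the chronogram invariants", {
  grid <- expand.grid(n = c(2, 5, 25), model = c("yule", "bd"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    model <- if (grid$model[i] == "yule") yule_params(0.9)
             else bd_params(0.9, 0.5)
    phy <- simulate_chronogram(model, n, 5, seed = 100 + i)
    expect_silent(validate_chronogram(phy))
    expect_equal(length(phy$tip.label), n)
    expect_equal(phy$Nnode, n - 1L)
    bt <- branching_times(phy)
    expect_equal(length(bt), n - 1L)
    expect_equal(bt[1], 5)                      # crown age exact
    expect_true(all(diff(bt) <= 0))             # sorted decreasing
    expect_true(all(bt > 0 & bt <= 5))
    # parent strictly older than child along every edge
    depth <- ape::node.depth.edgelength(phy)
    age <- max(depth[seq_len(n)]) - depth
    expect_true(all(age[phy$edge[, 1]] > age[phy$edge[, 2]] - 1e-12))
  }
})

test_that("a two-tip tree is a cherry with root at the crown age", {
  phy <- simulate_chronogram(yule_params(2), 2, 5, seed = 1)
  expect_equal(sort(phy$edge.length), c(5, 5))
  expect_equal(branching_times(phy), 5)
})

test_that("identical seeds give bit-identical Newick output", {
  a <- ape::write.tree(simulate_chronogram(bd_params(0.5, 0.3), 12, 5,
                                           seed = 42))
  b <- ape::write.tree(simulate_chronogram(bd_params(0.5, 0.3), 12, 5,
                                           seed = 42))
  expect_identical(a, b)
  c <- ape::write.tree(simulate_chronogram(bd_params(0.5, 0.3), 12, 5,
                                           seed = 43))
  expect_false(identical(a, c))
})

test_that("conditioned sampling matches the forward-rejection oracle", {
  # pooled post-root branching times, two-sample KS at alpha = 0.01
  cases <- list(list(n = 5, t = 1), list(n = 8, t = 2))
  for (cs in cases) {
    r <- expected_net_diversification(cs$n, 2, cs$t)
    for (model in list(yule_params(r), bd_params(r, 0.5))) {
      set.seed(7 + cs$n)
      mine <- unlist(replicate(2000, {
        bt <- branching_times(simulate_chronogram(model, cs$n, cs$t))
        bt[-1]
      }, simplify = FALSE))
      oracle <- unlist(replicate(2000,
        forward_bd_rejection(model, cs$n, cs$t)[-1], simplify = FALSE))
      ks <- suppressWarnings(stats::ks.test(mine, oracle))
      expect_gt(ks$p.value, 0.01)
    }
  }
})

test_that("birth-death with zero extinction reduces to Yule", {
  set.seed(3)
  a <- unlist(replicate(2000, branching_times(
    simulate_chronogram(bd_params(0.9, 0), 6, 2))[-1], simplify = FALSE))
  b <- unlist(replicate(2000, branching_times(
    simulate_chronogram(yule_params(0.9), 6, 2))[-1], simplify = FALSE))
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("larger net diversification pushes branching times tipward", {
  set.seed(5)
  mean_age <- vapply(c(0.3, 0.7, 1.2, 2), function(r) {
    mean(unlist(replicate(5000, branching_times(
      simulate_chronogram(yule_params(r), 8, 5))[-1], simplify = FALSE)))
  }, numeric(1))
  expect_true(all(diff(mean_age) < 0))
})

test_that("lineage counts from branching times agree with tree traversal", {
  phy <- simulate_chronogram(bd_params(0.7, 0.4), 20, 5, seed = 9)
  bt <- branching_times(phy)
  for (a in seq(0.01, 4.99, length.out = 25)) {
    expect_equal(sum(bt > a) + 1L, lineages_at_age(phy, a))
  }
})

test_that("Newick IO round-trips bit-exactly", {
  trees <- c(simulate_chronogram(yule_params(1), 10, 5, seed = 1),
             simulate_chronogram(bd_params(0.5, 0.5), 7, 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_chronograms(trees, path)
  txt1 <- readLines(path)
  back <- read_chronograms(path)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  write_chronograms(back, path2)
  expect_identical(txt1, readLines(path2))
  expect_length(back, 2L)
})

test_that("invalid inputs are rejected", {
  expect_error(simulate_chronogram(yule_params(1), 1, 5), ">= 2")
  expect_error(simulate_chronogram(yule_params(1), 5, -1), "positive")
  expect_error(yule_params(0), "positive")
  expect_error(bd_params(0.5, 1), "epsilon")
  bad <- simulate_chronogram(yule_params(1), 6, 5, seed = 1)
  bad$edge.length[1] <- bad$edge.length[1] + 0.5
  expect_error(branching_times(bad), "ultrametric")
})
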