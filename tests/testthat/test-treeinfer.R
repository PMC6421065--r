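gtr <- gtr_params()

sim_dataset <- function(n, L, rate = 0.02, model = bd_params(0.7, 0.3),
                        clock_rates = NULL, seed = 1) {
  set.seed(seed)
  phy <- simulate_chronogram(model, n, 5)
  rates <- clock_rates %||% rep(rate, nrow(phy$edge))
  list(phy = phy, rates = rates,
       aln = simulate_alignment(apply_rates(phy, rates), gtr, L))
}
`%||%` <- divclock:::`%||%`

test_that("the pruning likelihood matches an independent implementation", {
  d <- sim_dataset(7, 300, seed = 51)
  ll <- tree_loglik(ape::unroot(apply_rates(d$phy, d$rates)), d$aln, gtr,
                    gamma_categories = 1)
  fit <- phangorn::pml(ape::unroot(apply_rates(d$phy, d$rates)),
                       phangorn::phyDat(d$aln, type = "DNA"),
                       bf = gtr$pi, Q = gtr$exch / gtr$exch[6], k = 1)
  expect_equal(ll, fit$logLik, tolerance = 1e-8)
})

test_that("analytic branch-length gradients match finite differences", {
  d <- sim_dataset(6, 200, seed = 52)
  pd <- divclock:::pruning_data(d$aln, gtr, 4)
  tr <- ape::reorder.phylo(ape::unroot(apply_rates(d$phy, d$rates)),
                           "postorder")
  b <- tr$edge.length
  res <- divclock:::pruning_loglik(tr, pd, blen = b, grad = TRUE)
  for (i in seq_along(b)) {
    h <- 1e-5
    up <- b; up[i] <- up[i] + h
    dn <- b; dn[i] <- max(dn[i] - h, 0)
    num <- (divclock:::pruning_loglik(tr, pd, blen = up)$loglik -
            divclock:::pruning_loglik(tr, pd, blen = dn)$loglik) / (up[i] - dn[i])
    expect_equal(res$gradient[i], num, tolerance = 1e-3)
  }
})

test_that("two-taxon ML branch lengths match a 1-D likelihood oracle", {
  cherry <- ape::read.tree(text = "(a:0.1,b:0.1);")
  set.seed(53)
  aln <- simulate_alignment(cherry, gtr, 4000)
  fit <- ml_branch_lengths(aln, cherry, gtr)
  # direct 1-D maximization of the pairwise likelihood over the path length
  pd <- divclock:::pruning_data(aln, gtr, 4)
  tr <- ape::reorder.phylo(cherry, "postorder")
  path_ll <- function(t) divclock:::pruning_loglik(tr, pd,
                                                   blen = c(t / 2, t / 2))$loglik
  oracle <- grid_maximize(path_ll, 0.01, 1)
  expect_equal(sum(fit$tree$edge.length), oracle, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("identical sequences yield zero branch lengths and sibling tips", {
  base <- sim_dataset(5, 400, seed = 54)
  aln <- base$aln
  aln["t2", ] <- aln["t1", ]          # duplicate one taxon's sequence
  topo <- suppressWarnings(estimate_topology(aln, gtr))
  pair <- ape::getMRCA(topo, c("t1", "t2"))
  kids <- topo$edge[topo$edge[, 1] == pair, 2]
  expect_true(all(match(c("t1", "t2"), topo$tip.label) %in% kids))
  fit <- ml_branch_lengths(aln, topo, gtr)
  e12 <- fit$tree$edge[, 2] %in% match(c("t1", "t2"), fit$tree$tip.label)
  expect_lt(max(fit$tree$edge.length[e12]), 1e-6)
})

test_that("the true split of a 4-taxon tree is recovered from long alignments", {
  quartet <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.12,(c:0.05,d:0.05):0.12);")
  set.seed(55)
  hits <- replicate(40, {
    aln <- simulate_alignment(ape::unroot(quartet), gtr, 5000)
    topo <- estimate_topology(aln, gtr)
    ab <- ape::getMRCA(topo, c("a", "b"))
    cd <- ape::getMRCA(topo, c("c", "d"))
    n <- length(topo$tip.label)
    (ab > n && length(divclock:::tips_below(topo, ab)) == 2) ||
      (cd > n && length(divclock:::tips_below(topo, cd)) == 2)
  })
  expect_gte(mean(hits), 0.97)
})

test_that("topology_source = 'true' passes the generating topology through", {
  d <- sim_dataset(6, 100, seed = 56)
  cfg <- inference_config(topology_source = "true", true_topology = d$phy)
  expect_identical(estimate_topology(d$aln, gtr, cfg), d$phy)
  expect_error(inference_config(topology_source = "true"), "true_topology")
})

test_that("clock rooting minimizes root-to-tip variance", {
  d <- sim_dataset(8, 2000, rate = 0.02, seed = 57)
  fit <- ml_branch_lengths(d$aln, ape::unroot(apply_rates(d$phy, d$rates)),
                           gtr)
  rooted <- clock_root(fit$tree)
  expect_true(ape::is.rooted(rooted))
  depth <- ape::node.depth.edgelength(rooted)[1:8]
  # rooting anywhere else does not reduce the tip-depth variance
  expect_lt(var(depth), var(ape::node.depth.edgelength(
    phytools::midpoint.root(fit$tree))[1:8]) + 1e-8)
})

test_that("constrained dating never beats the unconstrained optimum", {
  d <- sim_dataset(7, 600, seed = 58)
  topo <- clock_root(ml_branch_lengths(d$aln, ape::unroot(d$phy), gtr)$tree)
  pm <- ml_branch_lengths(d$aln, topo, gtr)
  ds <- date_strict(d$aln, topo, gtr, phylogram_ml = pm)
  dr <- date_relaxed(d$aln, topo, gtr, phylogram_ml = pm)
  expect_lte(ds$loglik, pm$loglik + 1e-6)
  expect_lte(dr$loglik, pm$loglik + 1e-6)
  expect_lte(ds$loglik, dr$loglik + 1e-6)  # strict is nested in relaxed
  expect_silent(validate_chronogram(ds$chronogram))
  expect_silent(validate_chronogram(dr$chronogram))
  gl <- glance(dr)
  expect_equal(gl$clock, "relaxed")
})

test_that("heavy smoothing collapses relaxed dating onto the strict clock", {
  d <- sim_dataset(7, 600, seed = 59)
  topo <- clock_root(ml_branch_lengths(d$aln, ape::unroot(d$phy), gtr)$tree)
  pm <- ml_branch_lengths(d$aln, topo, gtr)
  ds <- date_strict(d$aln, topo, gtr, phylogram_ml = pm)
  cv <- vapply(c(1, 100, 1e4), function(sm) {
    dr <- date_relaxed(d$aln, topo, gtr, smoothing = sm, phylogram_ml = pm)
    rate_cv(dr$rates)
  }, numeric(1))
  expect_true(all(diff(cv) < 0))            # rate spread shrinks monotonely
  dr_inf <- date_relaxed(d$aln, topo, gtr, smoothing = 1e4,
                         phylogram_ml = pm)
  a_rel <- sort(branching_times(rescale_to_root(dr_inf$chronogram, 1)))
  a_str <- sort(branching_times(rescale_to_root(ds$chronogram, 1)))
  expect_lt(max(abs(a_rel - a_str)), 1e-3)
})

test_that("strict-clock dating recovers relative node ages", {
  set.seed(60)
  cors <- replicate(6, {
    d <- sim_dataset(10, 1500, rate = 0.02, seed = sample.int(1e6, 1))
    dated <- infer_dated_tree(d$aln, gtr,
                              inference_config(clock_mode = "strict"),
                              crown_age = 5)
    cor(sort(branching_times(dated$chronogram)),
        sort(branching_times(d$phy)))
  })
  expect_gte(median(cors), 0.95)
})

test_that("rescaling to the root age is exact and idempotent", {
  phy <- simulate_chronogram(yule_params(1), 9, 5, seed = 61)
  half <- rescale_to_root(phy, 2.5)
  expect_equal(branching_times(half), branching_times(phy) / 2)
  expect_equal(rescale_to_root(half, 5)$edge.length, phy$edge.length)
  expect_equal(rescale_to_root(rescale_to_root(phy, 7), 5)$edge.length,
               rescale_to_root(phy, 5)$edge.length)
  expect_equal(rescale_to_root(phy, 5)$edge.length, phy$edge.length)
  expect_error(rescale_to_root(phy, 0), "positive")
})
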