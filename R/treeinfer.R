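`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inference configuration for tree re-estimation
#'
#' Bundles the knobs of the dating surrogate. `prior_mode` records the
#' tree-prior condition label (yule vs bd) of the original Bayesian design;
#' it does not enter the point estimate (no branching-process prior appears
#' in the penalized objective), which operationalizes the finding that the
#' tree prior has little effect — see the methods vignette.
#'
#' @param topology_source `"estimate"` (neighbor joining on pairwise ML
#'   distances) or `"true"` (use `true_topology`).
#' @param clock_mode `"strict"` or `"relaxed"`.
#' @param prior_mode `"yule"` or `"bd"`; a condition label only.
#' @param gamma_categories Number of discrete-gamma rate categories used in
#'   inference likelihoods (default 4, median per category).
#' @param smoothing Penalty weight for relaxed dating, `>= 0` (default 1).
#' @param true_topology Optional `phylo` supplying the generating topology
#'   when `topology_source = "true"`.
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(topology_source = c("estimate", "true"),
                             clock_mode = c("strict", "relaxed"),
                             prior_mode = c("yule", "bd"),
                             gamma_categories = 4L, smoothing = 1,
                             true_topology = NULL) {
  topology_source <- match.arg(topology_source)
  clock_mode <- match.arg(clock_mode)
  prior_mode <- match.arg(prior_mode)
  stopifnot(gamma_categories >= 1, smoothing >= 0)
  if (topology_source == "true" && is.null(true_topology))
    stop("`true_topology` must be supplied when topology_source = \"true\"")
  structure(list(topology_source = topology_source, clock_mode = clock_mode,
                 prior_mode = prior_mode,
                 gamma_categories = as.integer(gamma_categories),
                 smoothing = smoothing, true_topology = true_topology),
            class = "inference_config")
}

# Discrete-gamma category rates (median per category, normalized to mean 1).
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(list(rates = 1, weights = 1))
  r <- qgamma((2 * seq_len(k) - 1) / (2 * k), shape = alpha, rate = alpha)
  list(rates = r / mean(r), weights = rep(1 / k, k))
}

# Site-pattern compression plus model quantities consumed by the C++ kernel.
pruning_data <- function(aln, params, gamma_categories = 4L) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  codes <- matrix(match(aln, NUC) - 1L, nrow(aln), ncol(aln))
  if (anyNA(codes)) stop("alignment contains characters other than A/C/G/T")
  key <- do.call(paste, c(as.data.frame(t(codes)), sep = "."))
  first <- which(!duplicated(key))
  idx <- match(key, key[first])
  eig <- gtr_eigen(params)
  gam <- discrete_gamma_rates(params$alpha, gamma_categories)
  list(taxa = rownames(aln),
       tipstates = codes[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = length(first))),
       eig = eig, rates = gam$rates, rweights = gam$weights,
       n_sites = ncol(aln))
}

# Log-likelihood (and optionally branch-length gradient) of a tree whose
# edges are in postorder. `blen` overrides the tree's edge lengths.
pruning_loglik <- function(phy, pd, blen = NULL, grad = FALSE) {
  tip_idx <- match(phy$tip.label, pd$taxa)
  if (anyNA(tip_idx)) stop("tree tips do not match alignment taxa")
  res <- pruning_loglik_cpp(phy$edge, blen %||% phy$edge.length,
                            length(phy$tip.label),
                            pd$tipstates[tip_idx, , drop = FALSE],
                            pd$weights, pd$eig$pi, pd$eig$C1, pd$eig$C2,
                            pd$eig$values, pd$rates, pd$rweights, grad)
  res
}

#' GTR+Gamma log-likelihood of a tree
#'
#' Felsenstein pruning log-likelihood of an alignment on a tree with given
#' branch lengths (substitutions/site), under fixed GTR+discrete-Gamma
#' parameters.
#'
#' @param phy `phylo` with branch lengths in expected substitutions/site.
#' @param aln Character alignment matrix with taxa as row names.
#' @param params A [gtr_params()] object.
#' @param gamma_categories Discrete-gamma category count.
#' @return The log-likelihood (a scalar).
#' @export
tree_loglik <- function(phy, aln, params, gamma_categories = 4L) {
  pd <- pruning_data(aln, params, gamma_categories)
  phy <- ape::reorder.phylo(phy, "postorder")
  pruning_loglik(phy, pd)$loglik
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Optimizes all branch lengths of a (rooted or unrooted) topology to
#' maximize the GTR+discrete-Gamma pruning likelihood, using quasi-Newton
#' updates on log branch lengths with analytic gradients, iterated to a
#' relative log-likelihood change below 1e-6.
#'
#' @param aln Character alignment matrix.
#' @param topology `phylo` over the alignment's taxa (edge lengths, if
#'   present, are used as starting values).
#' @param params A [gtr_params()] object.
#' @param gamma_categories Discrete-gamma category count.
#' @param max_iter Iteration cap; non-convergence is flagged, and the best
#'   solution found is returned.
#' @return A list with `tree` (the topology with ML branch lengths, edges in
#'   postorder), `loglik`, and `converged`.
#' @export
ml_branch_lengths <- function(aln, topology, params, gamma_categories = 4L,
                              max_iter = 500L) {
  pd <- pruning_data(aln, params, gamma_categories)
  phy <- ape::reorder.phylo(topology, "postorder")
  E <- nrow(phy$edge)
  b0 <- phy$edge.length %||% rep(0.05, E)
  b0 <- pmin(pmax(b0, 1e-6), 5)
  # the optimizer asks for fn and gr at the same point: evaluate once
  cache <- new.env(parent = emptyenv())
  eval_pt <- function(lb) {
    if (!identical(lb, cache$par)) {
      r <- pruning_loglik(phy, pd, blen = exp(lb), grad = TRUE)
      cache$par <- lb
      cache$value <- -r$loglik
      cache$grad <- -r$gradient * exp(lb)
    }
  }
  fn <- function(lb) { eval_pt(lb); cache$value }
  gr <- function(lb) { eval_pt(lb); cache$grad }
  opt <- optim(log(b0), fn, gr, method = "L-BFGS-B",
               lower = log(1e-9), upper = log(10),
               control = list(maxit = max_iter, factr = 1e8))
  phy$edge.length <- exp(opt$par)
  list(tree = phy, loglik = -opt$value, converged = opt$convergence == 0L)
}

# Pairwise ML distance under GTR+discrete-Gamma from 16 site-pattern counts.
pairwise_ml_distance <- function(counts16, eig, rates, rweights, cap = 10) {
  lpi <- log(eig$pi)
  negll <- function(t) {
    P <- 0
    for (k in seq_along(rates))
      P <- P + rweights[k] * gtr_prob_matrix(eig, t * rates[k])
    -sum(counts16 * (lpi + log(pmax(P, 1e-300))))
  }
  opt <- optimize(negll, c(1e-9, cap), tol = 1e-8)
  d <- opt$minimum
  if (d > cap - 1e-4 || negll(cap) < opt$objective) {
    warning("saturated pair: ML distance capped at ", cap)
    d <- cap
  }
  d
}

#' Estimate a topology from an alignment
#'
#' Neighbor joining on pairwise maximum-likelihood distances computed under
#' the fixed GTR+discrete-Gamma model. Saturated pairs (undefined ML
#' distance) are capped at 10 substitutions/site with a warning. With
#' `topology_source = "true"` in the config, the generating topology is
#' returned unchanged.
#'
#' @inheritParams ml_branch_lengths
#' @param config An [inference_config()].
#' @return An unrooted `phylo` topology (or `config$true_topology`).
#' @export
estimate_topology <- function(aln, params, config = inference_config()) {
  if (config$topology_source == "true") return(config$true_topology)
  n <- nrow(aln)
  if (n < 3L) stop("need at least 3 taxa to estimate a topology")
  codes <- matrix(match(aln, NUC) - 1L, n, ncol(aln))
  eig <- gtr_eigen(params)
  gam <- discrete_gamma_rates(params$alpha, config$gamma_categories)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      counts <- tabulate(codes[i, ] * 4L + codes[j, ] + 1L, nbins = 16L)
      D[i, j] <- D[j, i] <- pairwise_ml_distance(matrix(counts, 4, 4,
                                                        byrow = TRUE),
                                                 eig, gam$rates, gam$weights)
    }
  }
  ape::nj(D)
}

#' Root a phylogram on its molecular clock
#'
#' Places the root at the point (edge and position along it) minimizing the
#' variance of root-to-tip path lengths — the least-squares strict-clock
#' rooting criterion. Ties are broken by the lexicographically smallest tip
#' bipartition.
#'
#' @param phy An unrooted (or arbitrarily rooted) `phylo` with branch
#'   lengths in substitutions/site.
#' @return A rooted `phylo`.
#' @export
clock_root <- function(phy) {
  n <- length(phy$tip.label)
  if (n < 3L) stop("need at least 3 tips to root")
  Dn <- ape::dist.nodes(phy)
  first_tip <- sort(phy$tip.label)[1L]
  best <- NULL
  for (e in seq_len(nrow(phy$edge))) {
    u <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]; len <- phy$edge.length[e]
    below <- tips_below(phy, v)
    if (length(below) == 0L || length(below) == n) next
    s <- ifelse(seq_len(n) %in% below, 1, -1)
    a <- ifelse(s == 1, Dn[seq_len(n), v], Dn[seq_len(n), u] + len)
    # tip distance = a + s * p for root position p in [0, len] from v
    vs <- var(s)
    p <- if (vs > 0) -stats::cov(a, s) / vs else 0
    p <- min(max(p, 0), len)
    obj <- var(a + s * p)
    side <- sort(phy$tip.label[below])
    key <- if (first_tip %in% side)
      paste(sort(setdiff(phy$tip.label, side)), collapse = ",")
    else paste(side, collapse = ",")
    if (is.null(best) || obj < best$obj - 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 && key < best$key)) {
      best <- list(obj = obj, edge = e, v = v, p = p, len = len, key = key)
    }
  }
  # phytools measures `position` from the ancestral end of the edge
  rooted <- phytools::reroot(phy, best$v, position = best$len - best$p)
  ape::reorder.phylo(rooted, "postorder")
}

tips_below <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(node)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, tips_below, phy = phy))
}

# --- clock-constrained dating -----------------------------------------------

# Internal scaffolding shared by date_strict()/date_relaxed(): a rooted
# postorder tree, preorder-indexed age parameters (age_v = s_v * age_parent,
# root age fixed at 1), and the chain rule taking branch-length gradients to
# age/rate gradients.
dating_scaffold <- function(topology) {
  phy <- ape::reorder.phylo(topology, "postorder")
  if (!ape::is.rooted(phy))
    stop("dating requires a rooted topology; see clock_root()")
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  root <- setdiff(phy$edge[, 1L], phy$edge[, 2L])
  parent <- integer(nn); parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  internal <- setdiff((n + 1L):nn, root)      # nodes carrying an age parameter
  # preorder over edges: reverse postorder
  preorder_nodes <- rev(phy$edge[, 2L])
  list(phy = phy, n = n, nn = nn, root = root, parent = parent,
       internal = internal, preorder_nodes = preorder_nodes,
       edge_above = setNames(seq_len(nrow(phy$edge)), phy$edge[, 2L]))
}

ages_from_s <- function(sc, s) {
  age <- numeric(sc$nn)
  age[sc$root] <- 1
  sv <- numeric(sc$nn)
  sv[sc$internal] <- s
  for (v in sc$preorder_nodes) {
    if (v <= sc$n) next
    age[v] <- sv[v] * age[sc$parent[v]]
  }
  age
}

# gradient of the data part w.r.t. the age logits z (age_v = plogis(z_v) *
# age_parent): a single postorder accumulation of subtree sums
age_logit_gradient <- function(sc, age, s, gr_edge) {
  # gr_edge: d loglik / d b_e  *  rate_e, indexed by edge
  child_sum <- numeric(sc$nn)
  for (e in seq_len(nrow(sc$phy$edge)))
    child_sum[sc$phy$edge[e, 1L]] <- child_sum[sc$phy$edge[e, 1L]] + gr_edge[e]
  phi <- numeric(sc$nn)
  for (v in sc$internal)
    phi[v] <- age[v] * (child_sum[v] - gr_edge[sc$edge_above[as.character(v)]])
  Tacc <- phi
  for (e in seq_len(nrow(sc$phy$edge))) {   # postorder: children before parents
    v <- sc$phy$edge[e, 2L]
    if (v > sc$n && v != sc$root)
      Tacc[sc$phy$edge[e, 1L]] <- Tacc[sc$phy$edge[e, 1L]] + Tacc[v]
  }
  (1 - s) * Tacc[sc$internal]
}

#' Date a tree under a strict molecular clock
#'
#' Jointly estimates relative node ages and a single global substitution
#' rate maximizing the GTR+discrete-Gamma pruning likelihood under the
#' constraint `branch length = rate x duration`. The root age is fixed at 1
#' (relative ages; the absolute scale is arbitrary until
#' [rescale_to_root()]).
#'
#' @param aln Character alignment matrix.
#' @param topology A rooted `phylo` topology (see [clock_root()]); edge
#'   lengths, if present, seed the initial ages.
#' @param params A [gtr_params()] object.
#' @param gamma_categories Discrete-gamma category count.
#' @param phylogram_ml Optional precomputed result of [ml_branch_lengths()]
#'   on the same topology (computed if missing; reported in the estimate).
#' @param max_iter Optimizer iteration cap.
#' @param factr Convergence tolerance passed to the quasi-Newton optimizer
#'   (relative objective change `factr * .Machine$double.eps`; smaller is
#'   tighter).
#' @return An object of class `dated_tree`: `chronogram` (ultrametric,
#'   root age 1), `phylogram_ml`, `loglik` (sequence log-likelihood at the
#'   optimum), `rate` (or per-branch `rates` for relaxed dating),
#'   `objective`, and `converged`.
#' @export
date_strict <- function(aln, topology, params, gamma_categories = 4L,
                        phylogram_ml = NULL, max_iter = 500L, factr = 1e7) {
  date_clock(aln, topology, params, gamma_categories, phylogram_ml,
             max_iter, relaxed = FALSE, smoothing = 0, factr = factr)
}

#' Date a tree under a relaxed (penalized-likelihood) clock
#'
#' Maximizes `loglik - smoothing * sum((log rate_i - mean log rate)^2)` over
#' node ages and per-branch rates: the penalized-likelihood analogue of the
#' UCLN relaxed clock, with the lognormal penalty shrinking branch rates
#' toward a shared value as `smoothing` grows (recovering [date_strict()] in
#' the limit).
#'
#' @inheritParams date_strict
#' @param smoothing Non-negative penalty weight (default 1).
#' @return An object of class `dated_tree`; see [date_strict()].
#' @export
date_relaxed <- function(aln, topology, params, smoothing = 1,
                         gamma_categories = 4L, phylogram_ml = NULL,
                         max_iter = 1000L, factr = 1e7) {
  date_clock(aln, topology, params, gamma_categories, phylogram_ml,
             max_iter, relaxed = TRUE, smoothing = smoothing, factr = factr)
}

date_clock <- function(aln, topology, params, gamma_categories, phylogram_ml,
                       max_iter, relaxed, smoothing, factr = 1e7) {
  if (is.null(phylogram_ml))
    phylogram_ml <- ml_branch_lengths(aln, topology, params, gamma_categories)
  sc <- dating_scaffold(topology)
  phy <- sc$phy
  pd <- pruning_data(aln, params, gamma_categories)
  E <- nrow(phy$edge)

  # initial ages from mean node-to-tip path lengths on the ML phylogram
  ml_tree <- ape::reorder.phylo(phylogram_ml$tree, "postorder")
  perm <- match(paste(phy$edge[, 1L], phy$edge[, 2L]),
                paste(ml_tree$edge[, 1L], ml_tree$edge[, 2L]))
  bl_ml <- if (anyNA(perm)) rep(0.02, E) else ml_tree$edge.length[perm]
  h <- numeric(sc$nn); cnt <- numeric(sc$nn)
  for (e in seq_len(E)) {  # postorder: mean tipward path length per node
    v <- phy$edge[e, 2L]; u <- phy$edge[e, 1L]
    hv <- if (v <= sc$n) 0 else h[v] / cnt[v]
    nv <- if (v <= sc$n) 1 else cnt[v]
    h[u] <- h[u] + (hv + bl_ml[e]) * nv
    cnt[u] <- cnt[u] + nv
  }
  age0 <- numeric(sc$nn)
  age0[sc$root] <- max(h[sc$root] / cnt[sc$root], 1e-8)
  for (v in sc$preorder_nodes)
    if (v > sc$n) age0[v] <- if (cnt[v] > 0) h[v] / cnt[v] else 0
  s0 <- pmin(pmax(age0[sc$internal] / age0[sc$parent[sc$internal]],
                  0.02), 0.98)
  durations <- function(age) age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  rate0 <- max(sum(bl_ml) / max(sum(durations(ages_from_s(sc, s0))), 1e-8),
               1e-8)

  if (!relaxed) {
    par0 <- c(qlogis(s0), log(rate0))
    ni <- length(sc$internal)
    cache <- new.env(parent = emptyenv())
    eval_pt <- function(par) {
      if (identical(par, cache$par)) return(invisible())
      s <- plogis(par[seq_len(ni)])
      rate <- exp(par[ni + 1L])
      age <- ages_from_s(sc, s)
      dur <- durations(age)
      res <- pruning_loglik(phy, pd, blen = pmax(rate * dur, 0), grad = TRUE)
      g <- res$gradient
      cache$par <- par
      cache$value <- -res$loglik
      cache$grad <- -c(age_logit_gradient(sc, age, s, g * rate),
                       sum(g * rate * dur))
    }
    fn <- function(par) { eval_pt(par); cache$value }
    gr <- function(par) { eval_pt(par); cache$grad }
    opt <- optim(par0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter, factr = factr))
    s <- plogis(opt$par[seq_len(ni)])
    rate <- exp(opt$par[ni + 1L])
    age <- ages_from_s(sc, s)
    chron <- phy; chron$edge.length <- durations(age)
    ll <- -opt$value
    out <- list(chronogram = chron, phylogram_ml = phylogram_ml,
                loglik = ll, rate = rate, objective = ll,
                smoothing = NULL, converged = opt$convergence == 0L)
  } else {
    # start branch rates at the ML phylogram's implied per-branch rates so
    # genuine rate heterogeneity is in the optimizer's basin from the start
    dur0 <- durations(ages_from_s(sc, s0))
    lr0 <- log(pmin(pmax(bl_ml / pmax(dur0, 1e-6), rate0 / 50), rate0 * 50))
    par0 <- c(qlogis(s0), lr0)
    ni <- length(sc$internal)
    cache <- new.env(parent = emptyenv())
    eval_pt <- function(par) {
      if (identical(par, cache$par)) return(invisible())
      s <- plogis(par[seq_len(ni)])
      lr <- par[-seq_len(ni)]
      rates <- exp(lr)
      age <- ages_from_s(sc, s)
      dur <- durations(age)
      res <- pruning_loglik(phy, pd, blen = pmax(rates * dur, 0), grad = TRUE)
      g <- res$gradient
      cache$par <- par
      cache$value <- -res$loglik + smoothing * sum((lr - mean(lr))^2)
      cache$grad <- c(-age_logit_gradient(sc, age, s, g * rates),
                      -g * rates * dur + 2 * smoothing * (lr - mean(lr)))
    }
    fn <- function(par) { eval_pt(par); cache$value }
    gr <- function(par) { eval_pt(par); cache$grad }
    opt <- optim(par0, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = max_iter, factr = factr))
    s <- plogis(opt$par[seq_len(ni)])
    lr <- opt$par[-seq_len(ni)]
    age <- ages_from_s(sc, s)
    dur <- durations(age)
    chron <- phy; chron$edge.length <- dur
    ll <- pruning_loglik(phy, pd, blen = pmax(exp(lr) * dur, 0))$loglik
    out <- list(chronogram = chron, phylogram_ml = phylogram_ml,
                loglik = ll, rates = exp(lr), objective = -opt$value,
                smoothing = smoothing, converged = opt$convergence == 0L)
  }
  class(out) <- "dated_tree"
  out
}

#' @export
print.dated_tree <- function(x, ...) {
  kind <- if (is.null(x$rates)) "strict-clock" else "relaxed-clock"
  cat(sprintf("%s dated tree: %d tips, loglik = %.3f, converged = %s\n",
              kind, length(x$chronogram$tip.label), x$loglik, x$converged))
  invisible(x)
}

#' @export
glance.dated_tree <- function(x, ...) {
  tibble::tibble(clock = if (is.null(x$rates)) "strict" else "relaxed",
                 loglik = x$loglik,
                 loglik_unconstrained = x$phylogram_ml$loglik,
                 rate_mean = if (is.null(x$rates)) x$rate else mean(x$rates),
                 rate_cv = if (is.null(x$rates)) 0 else rate_cv(x$rates),
                 smoothing = x$smoothing %||% NA_real_,
                 converged = x$converged)
}

#' Rescale a chronogram to a known root age
#'
#' Multiplies every node age (equivalently every branch length) by
#' `root_age / current root age`, removing the arbitrary absolute time scale
#' of a clock-dated tree. This mirrors the rescale-to-true-root-height step
#' that isolates relative branching patterns from absolute-rate and
#' tree-age error.
#'
#' @param phy A chronogram.
#' @param root_age Target root age, `> 0`.
#' @return The rescaled chronogram, root age exactly `root_age`.
#' @export
rescale_to_root <- function(phy, root_age) {
  stopifnot(inherits(phy, "phylo"))
  if (!is.numeric(root_age) || length(root_age) != 1L || root_age <= 0)
    stop("`root_age` must be a positive scalar")
  depths <- ape::node.depth.edgelength(phy)
  cur <- max(depths[seq_along(phy$tip.label)])
  if (cur <= 0) stop("tree has zero height")
  phy$edge.length <- phy$edge.length * (root_age / cur)
  phy
}

#' Run the full tree re-estimation pipeline on one alignment
#'
#' Topology (NJ on ML distances, or the true topology), maximum-likelihood
#' branch lengths, clock rooting, strict or relaxed dating, and rescaling to
#' the true crown age — the point-estimate surrogate for a full Bayesian
#' dating analysis.
#'
#' @inheritParams estimate_topology
#' @param crown_age True crown age used for rescaling.
#' @return A `dated_tree` whose `chronogram` has root age `crown_age`.
#' @export
infer_dated_tree <- function(aln, params, config = inference_config(),
                             crown_age = 5) {
  infer_dated_trees(aln, params, config, crown_age,
                    clock_modes = config$clock_mode)[[config$clock_mode]]
}

#' @rdname infer_dated_tree
#' @param clock_modes Clock modes to fit; the topology, rooting and
#'   unconstrained ML branch lengths are shared across them.
#' @export
infer_dated_trees <- function(aln, params, config = inference_config(),
                              crown_age = 5,
                              clock_modes = c("strict", "relaxed")) {
  topo <- estimate_topology(aln, params, config)
  fit_ml <- ml_branch_lengths(aln, topo, params, config$gamma_categories)
  rooted <- clock_root(fit_ml$tree)
  fit_ml_rooted <- ml_branch_lengths(aln, rooted, params,
                                     config$gamma_categories)
  out <- list()
  for (cm in clock_modes) {
    dated <- if (cm == "strict") {
      date_strict(aln, rooted, params, config$gamma_categories,
                  phylogram_ml = fit_ml_rooted)
    } else {
      date_relaxed(aln, rooted, params, smoothing = config$smoothing,
                   gamma_categories = config$gamma_categories,
                   phylogram_ml = fit_ml_rooted)
    }
    dated$chronogram <- rescale_to_root(dated$chronogram, crown_age)
    out[[cm]] <- dated
  }
  out
}
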