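#' Net diversification rate implied by an expected tip count
#'
#' Inverts the deterministic expectation `E[N_t] = N0 * exp(r t)` of a
#' birth-death process to obtain the net diversification rate `r` that makes
#' `n_t` tips the expected outcome after time `t` starting from `n0`
#' lineages. This is how generating rates are fixed throughout the package:
#' e.g. 25 tips from a 2-lineage crown over 5 time units gives r = 0.5051.
#'
#' @param n_t Expected number of tips at time `t` (`n_t >= n0`).
#' @param n0 Initial number of lineages (default 2, a crown).
#' @param t Elapsed time (tree height), `> 0`.
#' @return Net diversification rate r = log(n_t / n0) / t (per time unit).
#' @export
#' @examples
#' expected_net_diversification(25, 2, 5)   # 0.5051
#' expected_net_diversification(100, 2, 5)  # 0.7824
expected_net_diversification <- function(n_t, n0 = 2, t) {
  stopifnot(is.numeric(n_t), is.numeric(n0), is.numeric(t))
  if (any(t <= 0)) stop("tree height `t` must be positive")
  if (any(n0 < 1)) stop("`n0` must be at least 1")
  if (any(n_t < n0)) stop("`n_t` must be at least `n0`")
  log(n_t / n0) / t
}

#' Branching-model parameter sets
#'
#' `yule_params()` describes a pure-birth (Yule) process with per-lineage
#' speciation rate `lambda`. `bd_params()` describes a constant-rate
#' birth-death process in its net-diversification parameterization:
#' r = lambda - mu and relative extinction `epsilon = mu / lambda`, from
#' which `lambda = r / (1 - epsilon)` and `mu = epsilon * lambda`.
#'
#' @param lambda Speciation rate, per lineage per time unit, `> 0`.
#' @return An object of class `yule_params` or `bd_params` (both inherit
#'   `branching_model`) with elements `lambda`, `mu`, `r`, `epsilon`.
#' @export
#' @examples
#' yule_params(0.7824)
#' bd_params(r = 0.5051, epsilon = 0.5)
yule_params <- function(lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  if (lambda <= 0) stop("`lambda` must be positive")
  structure(list(lambda = lambda, mu = 0, r = lambda, epsilon = 0),
            class = c("yule_params", "branching_model"))
}

#' @rdname yule_params
#' @param r Net diversification rate `lambda - mu`, per time unit, `> 0`.
#' @param epsilon Relative extinction rate `mu / lambda`, in `[0, 1)`.
#' @export
bd_params <- function(r, epsilon) {
  stopifnot(is.numeric(r), length(r) == 1L,
            is.numeric(epsilon), length(epsilon) == 1L)
  if (r <= 0) stop("`r` must be positive")
  if (epsilon < 0 || epsilon >= 1) stop("`epsilon` must be in [0, 1)")
  lambda <- r / (1 - epsilon)
  structure(list(lambda = lambda, mu = epsilon * lambda, r = r,
                 epsilon = epsilon),
            class = c("bd_params", "branching_model"))
}

#' @export
print.branching_model <- function(x, ...) {
  kind <- if (inherits(x, "yule_params")) "Yule (pure birth)" else "birth-death"
  cat(sprintf("%s model: lambda = %.6g, mu = %.6g (r = %.6g, epsilon = %.4g)\n",
              kind, x$lambda, x$mu, x$r, x$epsilon))
  invisible(x)
}

# CDF of a single speciation time on [0, t] for the reconstructed
# constant-rate BD process conditioned on the crown age:
#   F(s) = (1 - exp(-r s)) / (lambda - mu exp(-r s)),  normalized by F(t).
# Its inverse is available in closed form, which is what the simulator uses.
bd_time_cdf_raw <- function(s, lambda, mu) {
  r <- lambda - mu
  (1 - exp(-r * s)) / (lambda - mu * exp(-r * s))
}

bd_time_quantile <- function(u, lambda, mu, t) {
  r <- lambda - mu
  q <- u * bd_time_cdf_raw(t, lambda, mu)
  x <- (1 - q * lambda) / (1 - q * mu)
  -log(x) / r
}

#' Simulate an ultrametric chronogram conditioned on tip count and crown age
#'
#' Draws a reconstructed tree from a constant-rate Yule or birth-death
#' process conditioned on its crown (root) age, on both crown lineages
#' surviving to the present, and on leaving exactly `n` extant tips. Under
#' this conditioning the `n - 2` post-root speciation times are independent
#' and identically distributed with a known density, so they are sampled
#' directly by inverse-CDF and attached to a uniformly sampled ranked
#' topology; no forward simulation or rejection is involved, and extinct
#' lineages are never materialized.
#'
#' @param model A [yule_params()] or [bd_params()] object.
#' @param n Number of extant tips, `>= 2`.
#' @param crown_age Age of the root, time units, `> 0`.
#' @param seed Optional integer seed; identical inputs give bit-identical
#'   trees. `NULL` continues the current RNG stream.
#' @return A rooted, binary, ultrametric `phylo` with branch lengths in time
#'   units, root age exactly `crown_age`, and tips labelled `t1...tn` in
#'   cladewise traversal order.
#' @export
#' @examples
#' phy <- simulate_chronogram(bd_params(0.5051, 0.5), n = 25, crown_age = 5,
#'                            seed = 1)
#' max(branching_times(phy))  # 5
simulate_chronogram <- function(model, n, crown_age, seed = NULL) {
  stopifnot(inherits(model, "branching_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("`n` must be an integer >= 2")
  if (!is.numeric(crown_age) || length(crown_age) != 1L || crown_age <= 0)
    stop("`crown_age` must be positive")
  seed_rng(seed)
  n <- as.integer(n)

  ages <- crown_age
  if (n > 2L) {
    u <- runif(n - 2L)
    ages <- c(crown_age,
              sort(bd_time_quantile(u, model$lambda, model$mu, crown_age),
                   decreasing = TRUE))
  }
  phy <- assemble_ranked_tree(ages, crown_age)
  phy
}

# Attach i.i.d. speciation ages (sorted descending, ages[1] = crown age) to a
# uniformly sampled ranked topology: walk forward in time and split a
# uniformly chosen extant lineage at each event.
assemble_ranked_tree <- function(ages, crown_age) {
  n <- length(ages) + 1L
  n_nodes <- 2L * n - 1L
  # internal node k (in age order, k = 1 is the root) gets id n + k
  parent <- integer(n_nodes)      # parent id of every node except the root
  # active lineages are represented by the id of the internal node they
  # descend from; tips are assigned ids at the end
  active <- c(n + 1L, n + 1L)
  if (n > 2L) {
    for (k in 2:(n - 1L)) {
      j <- if (length(active) == 1L) 1L else sample.int(length(active), 1L)
      node <- n + k
      parent[node] <- active[j]
      active <- c(active[-j], node, node)
    }
  }
  # remaining active lineages become the tips, ids 1..n
  parent[seq_len(n)] <- active
  node_age <- c(rep(0, n), ages)

  child <- c(seq_len(n), if (n > 2L) (n + 2L):(2L * n - 1L) else integer())
  edge <- cbind(parent[child], child)
  edge_len <- node_age[edge[, 1L]] - node_age[edge[, 2L]]
  phy <- structure(list(edge = edge,
                        edge.length = edge_len,
                        tip.label = rep("", n),
                        Nnode = n - 1L),
                   class = "phylo")
  attr(phy, "order") <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  tip_order <- phy$edge[phy$edge[, 2L] <= n, 2L]
  phy$tip.label[tip_order] <- paste0("t", seq_len(n))
  phy
}

#' Validate a chronogram
#'
#' Checks that a tree is a rooted, binary, ultrametric chronogram: all
#' root-to-tip path lengths equal within a relative tolerance of 1e-9, every
#' parent node is strictly older than its children, and there are exactly
#' `n - 1` internal nodes for `n` tips.
#'
#' @param phy A `phylo` object.
#' @return `phy`, invisibly; otherwise an error.
#' @export
validate_chronogram <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a `phylo` object")
  n <- length(phy$tip.label)
  if (phy$Nnode != n - 1L)
    stop("chronogram must be binary: expected ", n - 1L, " internal nodes")
  if (is.null(phy$edge.length)) stop("chronogram has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  depths <- ape::node.depth.edgelength(phy)
  tip_depths <- depths[seq_len(n)]
  h <- max(tip_depths)
  if (h <= 0) stop("chronogram has zero height")
  if (max(abs(tip_depths - h)) > 1e-9 * h)
    stop("tree is not ultrametric (relative tolerance 1e-9)")
  invisible(phy)
}

#' Branching times of a chronogram
#'
#' Internal-node ages (time before present) sorted in decreasing order; the
#' first element is the crown age. These are the sufficient statistics for
#' constant-rate diversification likelihoods.
#'
#' @param phy A valid chronogram (see [validate_chronogram()]).
#' @return Numeric vector of `n - 1` node ages, sorted decreasing.
#' @export
#' @examples
#' bt <- branching_times(simulate_chronogram(yule_params(1), 10, 5, seed = 1))
branching_times <- function(phy) {
  validate_chronogram(phy)
  bt <- sort(unname(ape::branching.times(phy)), decreasing = TRUE)
  bt
}

#' Read and write chronograms as Newick
#'
#' One tree per line, branch lengths in time units, 12 significant digits;
#' files written by `write_chronograms()` round-trip bit-exactly through
#' `read_chronograms()` followed by `write_chronograms()`.
#'
#' @param phy A `phylo` or `multiPhylo` object.
#' @param path File path.
#' @return `read_chronograms()` returns a `multiPhylo`;
#'   `write_chronograms()` returns `path` invisibly.
#' @export
write_chronograms <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' @rdname write_chronograms
#' @export
read_chronograms <- function(path) {
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  trees
}
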