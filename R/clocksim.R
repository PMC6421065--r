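#' Molecular-clock models for branch-rate simulation
#'
#' `strict_clock()` draws a single substitution rate for the whole tree from
#' a lognormal distribution with real-scale mean `rate_mean` and log-scale
#' standard deviation `rate_sdlog` (so `meanlog = log(rate_mean) -
#' rate_sdlog^2 / 2`). `ucln_clock()` is the uncorrelated lognormal (UCLN)
#' relaxed clock: per tree, a real-scale mean `m ~ U(mean_low, mean_high)`
#' and a log-scale standard deviation `sigma ~ U(sigma_low, sigma_high)` are
#' drawn once, then every branch receives an independent lognormal rate with
#' real-scale mean `m` and log-scale sd `sigma`. `ucln_preset()` returns the
#' three named heterogeneity levels used throughout the study conditions:
#' sigma bounds `U(0.17, 0.18)` (low), `U(0.25, 1)` (medium), and
#' `U(0.25, 1.75)` (high), all with mean bounds `U(0.0050, 0.015)`.
#'
#' Rates are in expected substitutions per site per time unit.
#'
#' @param rate_mean Real-scale mean of the strict-clock rate draw, `> 0`.
#' @param rate_sdlog Log-scale sd of the strict-clock rate draw, `>= 0`
#'   (0 makes the rate exactly `rate_mean`).
#' @return A clock-model object (class `strict_clock` or `ucln_clock`, both
#'   inheriting `clock_model`).
#' @export
#' @examples
#' strict_clock()
#' ucln_preset("high")
strict_clock <- function(rate_mean = 0.01, rate_sdlog = 0.5) {
  stopifnot(is.numeric(rate_mean), rate_mean > 0,
            is.numeric(rate_sdlog), rate_sdlog >= 0)
  structure(list(rate_mean = rate_mean, rate_sdlog = rate_sdlog),
            class = c("strict_clock", "clock_model"))
}

#' @rdname strict_clock
#' @param mean_low,mean_high Bounds of the uniform draw for the lognormal's
#'   real-scale mean, `0 < mean_low <= mean_high`.
#' @param sigma_low,sigma_high Bounds of the uniform draw for the log-scale
#'   sd, `0 <= sigma_low <= sigma_high`.
#' @export
ucln_clock <- function(mean_low = 0.0050, mean_high = 0.015,
                       sigma_low, sigma_high) {
  stopifnot(mean_low > 0, mean_low <= mean_high,
            sigma_low >= 0, sigma_low <= sigma_high)
  structure(list(mean_low = mean_low, mean_high = mean_high,
                 sigma_low = sigma_low, sigma_high = sigma_high),
            class = c("ucln_clock", "clock_model"))
}

#' @rdname strict_clock
#' @param level One of `"low"`, `"medium"`, `"high"`: the among-lineage rate
#'   heterogeneity level.
#' @export
ucln_preset <- function(level = c("low", "medium", "high")) {
  level <- match.arg(level)
  bounds <- switch(level,
                   low = c(0.17, 0.18),
                   medium = c(0.25, 1),
                   high = c(0.25, 1.75))
  clock <- ucln_clock(sigma_low = bounds[1], sigma_high = bounds[2])
  clock$level <- level
  clock
}

#' @export
print.clock_model <- function(x, ...) {
  if (inherits(x, "strict_clock")) {
    cat(sprintf("strict clock: rate ~ lognormal(mean = %.4g, sdlog = %.3g)\n",
                x$rate_mean, x$rate_sdlog))
  } else {
    cat(sprintf(
      "UCLN relaxed clock%s: mean ~ U(%.4g, %.4g), sigma ~ U(%.3g, %.3g)\n",
      if (is.null(x$level)) "" else paste0(" (", x$level, ")"),
      x$mean_low, x$mean_high, x$sigma_low, x$sigma_high))
  }
  invisible(x)
}

# lognormal with real-scale mean m and log-scale sd sigma
rlnorm_meanreal <- function(k, m, sigma) {
  rlnorm(k, meanlog = log(m) - sigma^2 / 2, sdlog = sigma)
}

#' Draw per-branch substitution rates under a clock model
#'
#' Strict clock: a single lognormal rate draw shared by all branches. UCLN:
#' one independent lognormal rate per branch (continuous draws; see the
#' methods vignette for why the reference implementation's discretization is
#' not emulated).
#'
#' @param phy A chronogram (`phylo`).
#' @param clock A [strict_clock()] or [ucln_clock()] object.
#' @param seed Optional integer seed.
#' @return Numeric vector of positive rates, one per row of `phy$edge`, with
#'   attributes `m` and `sigma` recording the tree-level lognormal
#'   parameters actually used.
#' @export
#' @examples
#' phy <- simulate_chronogram(yule_params(0.7824), 10, 5, seed = 1)
#' rates <- draw_branch_rates(phy, ucln_preset("low"), seed = 2)
#' rate_cv(rates)
draw_branch_rates <- function(phy, clock, seed = NULL) {
  stopifnot(inherits(phy, "phylo"), inherits(clock, "clock_model"))
  seed_rng(seed)
  n_edge <- nrow(phy$edge)
  if (inherits(clock, "strict_clock")) {
    rate <- if (clock$rate_sdlog == 0) clock$rate_mean else
      rlnorm_meanreal(1L, clock$rate_mean, clock$rate_sdlog)
    rates <- rep(rate, n_edge)
    m <- clock$rate_mean
    sigma <- clock$rate_sdlog
  } else {
    m <- runif(1L, clock$mean_low, clock$mean_high)
    sigma <- runif(1L, clock$sigma_low, clock$sigma_high)
    rates <- rlnorm_meanreal(n_edge, m, sigma)
  }
  attr(rates, "m") <- m
  attr(rates, "sigma") <- sigma
  rates
}

#' Convert a chronogram to a phylogram with per-branch rates
#'
#' Multiplies each branch duration (time units) by its substitution rate to
#' give branch lengths in expected substitutions per site.
#'
#' @param phy A chronogram.
#' @param rates Numeric vector of positive rates, one per row of `phy$edge`
#'   (as returned by [draw_branch_rates()]).
#' @return A `phylo` with substitution-scaled branch lengths.
#' @export
apply_rates <- function(phy, rates) {
  stopifnot(inherits(phy, "phylo"))
  if (length(rates) != nrow(phy$edge))
    stop("need exactly one rate per branch (", nrow(phy$edge), ")")
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("branch rates must be positive and finite")
  phy$edge.length <- phy$edge.length * as.numeric(rates)
  phy
}

#' Coefficient of variation of branch rates
#'
#' Sample standard deviation (n - 1 denominator) divided by sample mean; 0
#' under a strict clock. For lognormal rates with log-scale sd `sigma` the
#' population value is `sqrt(exp(sigma^2) - 1)`.
#'
#' @param rates Numeric vector of at least two branch rates.
#' @return Dimensionless CV.
#' @export
rate_cv <- function(rates) {
  rates <- as.numeric(rates)
  if (length(rates) < 2L) stop("need at least 2 branch rates")
  sd(rates) / mean(rates)
}

#' Tabulate per-branch rates
#'
#' @param phy The tree the rates belong to.
#' @param rates Per-branch rates as returned by [draw_branch_rates()].
#' @return A tibble with one row per branch: `parent`, `child`, `duration`
#'   (time units) and `rate` (substitutions/site/time unit), suitable for
#'   CSV export.
#' @export
branch_rate_table <- function(phy, rates) {
  stopifnot(inherits(phy, "phylo"), length(rates) == nrow(phy$edge))
  tibble::tibble(parent = phy$edge[, 1L], child = phy$edge[, 2L],
                 duration = phy$edge.length, rate = as.numeric(rates))
}
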