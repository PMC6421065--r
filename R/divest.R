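# Constant-rate diversification likelihoods on branching times.
#
# Under a constant-rate birth-death process conditioned on the crown age t
# and the survival of both crown lineages, the reconstructed tree's
# post-root speciation times are i.i.d. with density
#   g(s) = f(s) / F(t),  f(s) = r^2 exp(-r s) / (lambda - mu exp(-r s))^2,
#   F(s) = (1 - exp(-r s)) / (lambda - mu exp(-r s)),
# and the number of tips is the sum of two independent geometric variables
# with success probability 1 - u, u = lambda F(t). The "survival"
# conditioning multiplies the two parts; the "ntaxa" conditioning (tip count
# treated as fixed by design) keeps only the branching-time part.

check_bt <- function(bt, min_n = 3L) {
  bt <- sort(as.numeric(bt), decreasing = TRUE)
  if (any(!is.finite(bt)) || any(bt <= 0))
    stop("branching times must be positive and finite")
  n <- length(bt) + 1L
  if (n < min_n) stop("need at least ", min_n - 1L, " branching times")
  bt
}

bd_core_loglik <- function(bt, lambda, mu, conditioning) {
  t <- bt[1L]
  x <- bt[-1L]
  n <- length(bt) + 1L
  r <- lambda - mu
  Ft <- (1 - exp(-r * t)) / (lambda - mu * exp(-r * t))
  ll_times <- if (n > 2L) {
    sum(2 * log(r) - r * x - 2 * log(lambda - mu * exp(-r * x))) -
      (n - 2L) * log(Ft)
  } else 0
  if (conditioning == "ntaxa") return(ll_times)
  u <- lambda * Ft
  # log(1 - u) = log r - r t - log(lambda - mu e^{-rt}), stable for large r t
  log(n - 1L) + 2 * (log(r) - r * t - log(lambda - mu * exp(-r * t))) +
    (n - 2L) * log(u) + ll_times
}

#' Yule (pure-birth) log-likelihood of branching times
#'
#' Log-likelihood of the post-root speciation times of a chronogram under a
#' pure-birth process with rate `lambda`, conditioned on the crown age. The
#' default `"ntaxa"` conditioning treats the tip count as fixed by design
#' (matching trees simulated conditioned on tip count and crown age) and
#' uses the truncated-exponential density of the times; `"survival"`
#' conditions only on both crown lineages surviving, making the tip count
#' informative through its geometric distribution.
#'
#' @param bt Branching times (internal-node ages); sorted internally, first
#'   element is the crown age. At least 2 entries (3 tips).
#' @param lambda Speciation rate, `> 0`.
#' @param conditioning `"ntaxa"` (default) or `"survival"`; see Details.
#' @return Log-likelihood value.
#' @export
yule_loglik <- function(bt, lambda, conditioning = c("ntaxa", "survival")) {
  conditioning <- match.arg(conditioning)
  bt <- check_bt(bt)
  if (!is.numeric(lambda) || lambda <= 0) stop("`lambda` must be positive")
  t <- bt[1L]
  x <- bt[-1L]
  n <- length(bt) + 1L
  # truncated-exponential density of the times; geometric tip-count term
  ll_times <- sum(log(lambda) - lambda * x) -
    (n - 2L) * log1p(-exp(-lambda * t))
  if (conditioning == "ntaxa") return(ll_times)
  u <- -expm1(-lambda * t)
  # log(1 - u) = -lambda t exactly; avoids overflow to -Inf for large lambda
  log(n - 1L) - 2 * lambda * t + (n - 2L) * log(u) + ll_times
}

#' Birth-death log-likelihood of branching times
#'
#' Nee-style reconstructed-process log-likelihood of a chronogram's
#' branching times under a constant-rate birth-death process with net
#' diversification `r` and relative extinction `eps`, conditioned on the
#' crown age, with the tip count either fixed by design (`"ntaxa"`, the
#' default) or random given survival of both crown lineages (`"survival"`).
#'
#' @inheritParams yule_loglik
#' @param r Net diversification rate `lambda - mu`, `> 0`.
#' @param eps Relative extinction `mu / lambda`, in `[0, 1)`.
#' @return Log-likelihood value; reduces to [yule_loglik()] at `eps = 0`.
#' @export
bd_loglik <- function(bt, r, eps, conditioning = c("ntaxa", "survival")) {
  conditioning <- match.arg(conditioning)
  bt <- check_bt(bt)
  if (!is.numeric(r) || r <= 0) stop("`r` must be positive")
  if (!is.numeric(eps) || eps < 0 || eps >= 1)
    stop("`eps` must be in [0, 1)")
  lambda <- r / (1 - eps)
  bd_core_loglik(bt, lambda, eps * lambda, conditioning)
}

new_div_estimate <- function(model, lambda_hat, r_hat, eps_hat, loglik,
                             converged, boundary, n, conditioning) {
  structure(list(model = model, lambda_hat = lambda_hat, r_hat = r_hat,
                 eps_hat = eps_hat, loglik = loglik, converged = converged,
                 boundary = boundary, n = n, conditioning = conditioning),
            class = "div_estimate")
}

#' Maximum-likelihood Yule speciation rate
#'
#' One-dimensional maximization of [yule_loglik()] over `lambda`.
#'
#' @inheritParams yule_loglik
#' @param interval Search interval for `lambda`.
#' @return A `div_estimate` with `lambda_hat` (`r_hat` equals `lambda_hat`
#'   under a pure-birth model), `loglik` and `converged`.
#' @export
#' @examples
#' phy <- simulate_chronogram(yule_params(0.7824), 50, 5, seed = 1)
#' yule_mle(branching_times(phy))
yule_mle <- function(bt, conditioning = c("ntaxa", "survival"),
                     interval = c(1e-8, 50)) {
  conditioning <- match.arg(conditioning)
  bt <- check_bt(bt)
  opt <- optimize(function(l) -yule_loglik(bt, l, conditioning),
                  interval, tol = 1e-10)
  lam <- opt$minimum
  converged <- lam > interval[1] * 1.01 && lam < interval[2] * 0.99
  new_div_estimate("yule", lambda_hat = lam, r_hat = lam, eps_hat = 0,
                   loglik = -opt$objective, converged = converged,
                   boundary = !converged, n = length(bt) + 1L, conditioning)
}

#' Maximum-likelihood birth-death diversification parameters
#'
#' Bounded two-dimensional maximization of [bd_loglik()] over
#' `(r, eps)` with `r` in `(1e-6, 10]` and `eps` in `[0, 0.999]`, using a
#' Nelder-Mead simplex on transformed coordinates from five coarse-grid
#' starts. An optimum on the `eps` boundary is flagged (`boundary = TRUE`)
#' but still counts as converged.
#'
#' @inheritParams yule_loglik
#' @return A `div_estimate` with `r_hat`, `eps_hat`, derived
#'   `lambda_hat = r_hat / (1 - eps_hat)`, `loglik`, `converged`,
#'   `boundary`.
#' @export
#' @examples
#' phy <- simulate_chronogram(bd_params(0.5051, 0.5), 25, 5, seed = 1)
#' bd_mle(branching_times(phy))
bd_mle <- function(bt, conditioning = c("ntaxa", "survival")) {
  conditioning <- match.arg(conditioning)
  bt <- check_bt(bt)
  n <- length(bt) + 1L
  if (n < 4L) warning("fewer than 4 tips: birth-death MLE is ill-determined")
  t <- bt[1L]
  r_guess <- max(log(n / 2) / t, 1e-3)
  eps_floor <- 1e-9
  to_eps <- function(z) 0.999 * plogis(z)
  negll <- function(par) {
    r <- exp(par[1L])
    if (r < 1e-6 || r > 10) return(1e10)
    -bd_loglik(bt, r, max(to_eps(par[2L]), eps_floor), conditioning)
  }
  starts <- rbind(c(log(r_guess), qlogis(0.05 / 0.999)),
                  c(log(r_guess), qlogis(0.5 / 0.999)),
                  c(log(r_guess), qlogis(0.9 / 0.999)),
                  c(log(r_guess / 2), qlogis(0.5 / 0.999)),
                  c(log(2 * r_guess), qlogis(0.5 / 0.999)))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    opt <- optim(starts[k, ], negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  r_hat <- exp(best$par[1L])
  eps_hat <- max(to_eps(best$par[2L]), eps_floor)
  boundary <- eps_hat < 1e-4 || eps_hat > 0.99 ||
    r_hat < 2e-6 || r_hat > 9.99
  if (eps_hat < 1e-4) eps_hat <- 0
  new_div_estimate("bd", lambda_hat = r_hat / (1 - eps_hat), r_hat = r_hat,
                   eps_hat = eps_hat, loglik = -best$value,
                   converged = best$convergence == 0L, boundary = boundary,
                   n = n, conditioning = conditioning)
}

#' @export
print.div_estimate <- function(x, ...) {
  cat(sprintf("%s ML estimate (n = %d, conditioning = %s)\n",
              toupper(x$model), x$n, x$conditioning))
  if (x$model == "yule") {
    cat(sprintf("  lambda_hat = %.5f, loglik = %.4f\n", x$lambda_hat,
                x$loglik))
  } else {
    cat(sprintf("  r_hat = %.5f, eps_hat = %.4f, lambda_hat = %.5f, loglik = %.4f%s\n",
                x$r_hat, x$eps_hat, x$lambda_hat, x$loglik,
                if (x$boundary) " [boundary]" else ""))
  }
  if (!x$converged) cat("  warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
tidy.div_estimate <- function(x, ...) {
  if (x$model == "yule") {
    tibble::tibble(term = "lambda", estimate = x$lambda_hat)
  } else {
    tibble::tibble(term = c("r", "eps", "lambda"),
                   estimate = c(x$r_hat, x$eps_hat, x$lambda_hat))
  }
}

#' @export
glance.div_estimate <- function(x, ...) {
  tibble::tibble(model = x$model, lambda_hat = x$lambda_hat,
                 r_hat = x$r_hat, eps_hat = x$eps_hat, loglik = x$loglik,
                 converged = x$converged, boundary = x$boundary,
                 n = x$n, conditioning = x$conditioning)
}
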