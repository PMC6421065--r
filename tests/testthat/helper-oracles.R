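# Independent oracles used across the suite. These deliberately avoid the
# package's sampling shortcuts: trees are simulated forward in time with
# explicit extinction and rejection, and optima are found by grid refinement.

# Forward Gillespie simulation of a constant-rate birth-death process from 2
# crown lineages, rejected unless both crown lineages leave survivors and
# exactly `n` tips are extant at `crown_age`. Returns the reconstructed
# branching times (ages, sorted decreasing, including the crown age).
forward_bd_rejection <- function(model, n, crown_age, max_tries = 1e6) {
  lambda <- model$lambda
  mu <- model$mu
  for (try in seq_len(max_tries)) {
    # lineage table: birth time, death time (NA = extant), parent lineage
    birth <- c(0, 0); death <- c(NA_real_, NA_real_); parent <- c(0L, 0L)
    alive <- c(1L, 2L)
    t <- 0
    repeat {
      k <- length(alive)
      if (k == 0L) break
      t <- t + rexp(1, k * (lambda + mu))
      if (t >= crown_age) break
      i <- alive[sample.int(k, 1L)]
      if (runif(1) < lambda / (lambda + mu)) {
        birth <- c(birth, t); death <- c(death, NA_real_)
        parent <- c(parent, i)
        alive <- c(alive, length(birth))
      } else {
        death[i] <- t
        alive <- setdiff(alive, i)
      }
      if (length(alive) > 50L * n) break  # runaway well beyond target; reject
    }
    if (length(alive) != n) next
    # reconstructed split times via survivor propagation
    rec_bt <- function(lin, from) {
      kids <- which(parent == lin & birth > from)
      kids <- kids[order(birth[kids])]
      if (length(kids) == 0L)
        return(list(surv = is.na(death[lin]), bt = numeric()))
      ch <- kids[1L]
      tau <- birth[ch]
      left <- rec_bt(lin, tau)
      right <- rec_bt(ch, tau)
      if (left$surv && right$surv)
        list(surv = TRUE, bt = c(crown_age - tau, left$bt, right$bt))
      else if (left$surv) left
      else if (right$surv) right
      else list(surv = FALSE, bt = numeric())
    }
    s1 <- rec_bt(1L, 0); s2 <- rec_bt(2L, 0)
    if (!(s1$surv && s2$surv)) next
    return(sort(c(crown_age, s1$bt, s2$bt), decreasing = TRUE))
  }
  stop("forward-rejection oracle exhausted max_tries")
}

# 1-D grid-refinement maximizer
grid_maximize <- function(f, lower, upper, rounds = 4L, points = 400L) {
  for (r in seq_len(rounds)) {
    g <- seq(lower, upper, length.out = points)
    v <- vapply(g, f, numeric(1))
    i <- which.max(v)
    lower <- g[max(i - 1L, 1L)]
    upper <- g[min(i + 1L, points)]
  }
  (lower + upper) / 2
}

# 2-D grid-refinement maximizer over (r, eps); the window kept after each
# round spans +/-3 grid cells so diagonal likelihood ridges are not lost
grid_maximize_2d <- function(f, r_range = c(0.02, 4), eps_range = c(0, 0.95),
                             rounds = 8L, points = 60L) {
  for (k in seq_len(rounds)) {
    rg <- seq(r_range[1], r_range[2], length.out = points)
    eg <- seq(eps_range[1], eps_range[2], length.out = points)
    v <- outer(rg, eg, Vectorize(f))
    i <- which(v == max(v), arr.ind = TRUE)[1, ]
    r_range <- c(rg[max(i[1] - 3L, 1L)], rg[min(i[1] + 3L, points)])
    eps_range <- c(eg[max(i[2] - 3L, 1L)], eg[min(i[2] + 3L, points)])
  }
  c(r = mean(r_range), eps = mean(eps_range))
}

# lineage count at age `a` by direct edge traversal (spans the age slice)
lineages_at_age <- function(phy, a) {
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth[seq_len(n)])
  age <- h - depth
  sum(age[phy$edge[, 1L]] > a & age[phy$edge[, 2L]] <= a)
}
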