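NUC <- c("A", "C", "G", "T")

#' GTR+Gamma substitution-model parameters
#'
#' General time-reversible model with gamma-distributed among-site rate
#' variation. Defaults are the nuclear rRNA estimates used as the study's
#' generating model: stationary frequencies `pi = (0.1978, 0.2874, 0.3403,
#' 0.1835)` (A, C, G, T), exchangeabilities `(AC, AG, AT, CG, CT, GT) =
#' (1.6493, 2.9172, 0.3969, 0.9164, 8.4170, 1)` and gamma shape
#' `alpha = 2.3592`.
#'
#' @param pi Stationary base frequencies (A, C, G, T), positive. Values
#'   within 1% of summing to 1 are renormalized exactly (the published rRNA
#'   frequencies sum to 1.009 as printed); larger deviations are an error.
#' @param exch Six positive exchangeabilities in the order AC, AG, AT, CG,
#'   CT, GT (GT conventionally 1).
#' @param alpha Gamma shape for among-site rate variation, `> 0`.
#' @return An object of class `gtr_params`.
#' @export
#' @examples
#' gtr_params()
gtr_params <- function(pi = c(0.1978, 0.2874, 0.3403, 0.1835),
                       exch = c(1.6493, 2.9172, 0.3969, 0.9164, 8.4170, 1),
                       alpha = 2.3592) {
  stopifnot(length(pi) == 4L, length(exch) == 6L, length(alpha) == 1L)
  if (any(pi <= 0)) stop("all stationary frequencies must be positive")
  if (abs(sum(pi) - 1) > 0.01)
    stop("`pi` must sum to 1 (at most 1% slack before renormalization)")
  pi <- pi / sum(pi)
  if (any(exch <= 0)) stop("all exchangeabilities must be positive")
  if (alpha <= 0) stop("`alpha` must be positive")
  structure(list(pi = setNames(as.numeric(pi), NUC),
                 exch = setNames(as.numeric(exch),
                                 c("AC", "AG", "AT", "CG", "CT", "GT")),
                 alpha = as.numeric(alpha)),
            class = "gtr_params")
}

#' @export
print.gtr_params <- function(x, ...) {
  cat("GTR+Gamma model\n")
  cat("  pi:   ", paste(sprintf("%s=%.4f", NUC, x$pi), collapse = " "), "\n")
  cat("  exch: ", paste(sprintf("%s=%.4f", names(x$exch), x$exch),
                        collapse = " "), "\n")
  cat("  alpha:", sprintf("%.4f", x$alpha), "\n")
  invisible(x)
}

#' Normalized GTR instantaneous rate matrix
#'
#' Builds the 4x4 rate matrix `Q` with `q_ij = exch_ij * pi_j` off the
#' diagonal, diagonal entries making rows sum to zero, scaled so the
#' expected substitution rate at stationarity `-sum(pi_i q_ii)` is 1: branch
#' lengths are then in expected substitutions per site.
#'
#' @param params A [gtr_params()] object.
#' @return A 4x4 matrix with dimnames A, C, G, T.
#' @export
build_rate_matrix <- function(params) {
  stopifnot(inherits(params, "gtr_params"))
  ex <- params$exch
  pi <- params$pi
  R <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  R["A", "C"] <- ex["AC"]; R["A", "G"] <- ex["AG"]; R["A", "T"] <- ex["AT"]
  R["C", "G"] <- ex["CG"]; R["C", "T"] <- ex["CT"]; R["G", "T"] <- ex["GT"]
  R <- R + t(R)
  Q <- R * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

# Eigendecomposition of the reversible Q via its symmetrized form
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)); P(t) = C1 %*% diag(exp(vals t)) %*% C2.
gtr_eigen <- function(params) {
  Q <- build_rate_matrix(params)
  pi <- params$pi
  sp <- sqrt(pi)
  B <- (Q * rep(sp, times = 4)) * rep(1 / sp, each = 4)  # diag(sp) Q diag(1/sp)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       C1 = e$vectors / sp,              # diag(1/sp) %*% V
       C2 = t(e$vectors) * rep(sp, each = 4),  # t(V) %*% diag(sp)
       pi = pi, Q = Q)
}

# Transition-probability matrix P(t) = exp(Q t)
gtr_prob_matrix <- function(eig, t) {
  P <- eig$C1 %*% (exp(eig$values * t) * eig$C2)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Gamma-distributed site-rate multipliers
#'
#' Independent continuous draws from `Gamma(shape = alpha, rate = alpha)`,
#' i.e. mean 1 and variance `1/alpha`.
#'
#' @param alpha Gamma shape, `> 0`.
#' @param L Number of sites, `>= 1`.
#' @param seed Optional integer seed.
#' @return Numeric vector of `L` positive rate multipliers.
#' @export
draw_site_rates <- function(alpha, L, seed = NULL) {
  stopifnot(is.numeric(alpha), alpha > 0, is.numeric(L), L >= 1)
  seed_rng(seed)
  rgamma(as.integer(L), shape = alpha, rate = alpha)
}

#' Simulate a nucleotide alignment along a phylogram
#'
#' Root states are drawn from the stationary frequencies, then evolved down
#' each branch with transition matrices `exp(Q * b * rho_s)`, where `b` is
#' the branch length in substitutions/site and `rho_s` a per-site continuous
#' gamma rate multiplier (shape `params$alpha`). Sites are independent; no
#' gaps or ambiguity codes are produced.
#'
#' @param phy A phylogram (`phylo`, branch lengths in substitutions/site).
#' @param params A [gtr_params()] object.
#' @param L Alignment length in base pairs.
#' @param seed Optional integer seed.
#' @param site_rates Optional vector of `L` site-rate multipliers overriding
#'   the gamma draw (used mainly for oracle tests).
#' @return Character matrix (`n x L`, values A/C/G/T) with tip labels as row
#'   names.
#' @export
#' @examples
#' phy <- simulate_chronogram(yule_params(1), 5, 5, seed = 1)
#' aln <- simulate_alignment(apply_rates(phy, rep(0.01, nrow(phy$edge))),
#'                           gtr_params(), L = 100, seed = 2)
#' dim(aln)
simulate_alignment <- function(phy, params, L, seed = NULL, site_rates = NULL) {
  stopifnot(inherits(phy, "phylo"), inherits(params, "gtr_params"),
            is.numeric(L), L >= 1)
  if (is.null(phy$edge.length) || any(phy$edge.length < 0))
    stop("phylogram must have non-negative branch lengths")
  seed_rng(seed)
  L <- as.integer(L)
  if (is.null(site_rates)) {
    site_rates <- rgamma(L, shape = params$alpha, rate = params$alpha)
  } else {
    stopifnot(length(site_rates) == L, all(site_rates >= 0))
  }
  eig <- gtr_eigen(params)
  n <- length(phy$tip.label)
  n_nodes <- n + phy$Nnode
  phy <- ape::reorder.phylo(phy, "cladewise")
  root <- n + 1L

  states <- matrix(0L, n_nodes, L)
  states[root, ] <- sample.int(4L, L, replace = TRUE, prob = eig$pi)
  # eigen-basis evolution, vectorized over sites: the state at the child is
  # categorical with probabilities (E * C1[parent_state, ]) %*% C2 per site
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]
    chd <- phy$edge[e, 2L]
    b <- phy$edge.length[e]
    if (b == 0) {
      states[chd, ] <- states[par, ]
      next
    }
    E <- exp(outer(site_rates * b, eig$values))          # L x 4
    probs <- (E * eig$C1[states[par, ], , drop = FALSE]) %*% eig$C2  # L x 4
    probs[probs < 0] <- 0
    cum <- probs %*% upper.tri(diag(4), diag = TRUE)
    u <- runif(L) * cum[, 4L]
    states[chd, ] <- 1L + (u > cum[, 1L]) + (u > cum[, 2L]) + (u > cum[, 3L])
  }
  aln <- matrix(NUC[states[seq_len(n), , drop = FALSE]], n, L)
  rownames(aln) <- phy$tip.label
  aln
}

#' Alignment file IO (FASTA and NEXUS)
#'
#' Thin wrappers around ape's readers and writers, fixed to the package's
#' alignment representation (character matrix over A/C/G/T with taxa as row
#' names). NEXUS files use a non-interleaved DATA block.
#'
#' @param aln Character matrix alignment.
#' @param path File path.
#' @return Readers return a character matrix; writers return `path`
#'   invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  ape::write.FASTA(ape::as.DNAbin(aln), path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  dna <- as.character(ape::read.FASTA(path))
  aln <- toupper(do.call(rbind, dna))
  aln
}

#' @rdname write_alignment_fasta
#' @export
write_alignment_nexus <- function(aln, path) {
  ape::write.nexus.data(ape::as.DNAbin(aln), path, interleaved = FALSE)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_nexus <- function(path) {
  dna <- ape::read.nexus.data(path)
  aln <- toupper(do.call(rbind, lapply(dna, as.character)))
  aln
}
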