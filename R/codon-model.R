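#' Equilibrium codon frequencies from an alignment
#'
#' @param caln A cleaned `codon_alignment` (missing entries are ignored for
#'   counting, so a partially cleaned alignment is also accepted).
#' @param freq_model `"F3x4"` (products of position-specific nucleotide
#'   frequencies, stops zeroed and renormalized over the 61 sense codons),
#'   `"F61"` (observed codon proportions with a pseudo-count of 1), or
#'   `"uniform"` (1/61 each).
#' @param code A [genetic_code()].
#' @return Numeric vector of length 61, named by sense codon, summing to 1.
#' @export
estimate_codon_frequencies <- function(caln,
                                       freq_model = c("F3x4", "F61",
                                                      "uniform"),
                                       code = genetic_code()) {
  freq_model <- match.arg(freq_model)
  sense <- code$sense_codons
  nsense <- length(sense)
  if (freq_model == "uniform")
    return(stats::setNames(rep(1 / nsense, nsense), sense))
  counts <- tabulate(caln$states[!is.na(caln$states)], nbins = nsense)
  if (sum(counts) == 0L) stop("empty alignment: no observed codons")
  if (freq_model == "F61") {
    p <- (counts + 1) / sum(counts + 1)
    return(stats::setNames(p, sense))
  }
  # F3x4: per-codon-position nucleotide frequencies
  bases <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(sense, ""))
  posfreq <- matrix(0, 3, 4, dimnames = list(NULL, bases))
  for (pos in 1:3)
    for (b in bases)
      posfreq[pos, b] <- sum(counts[cmat[, pos] == b])
  posfreq <- posfreq / rowSums(posfreq)
  p <- posfreq[1, cmat[, 1]] * posfreq[2, cmat[, 2]] * posfreq[3, cmat[, 3]]
  # stops carry zero mass by construction (they are absent from `sense`);
  # renormalize the sense-codon mass they would have absorbed
  p <- p / sum(p)
  stats::setNames(p, sense)
}

#' Goldman-Yang codon rate matrix
#'
#' Instantaneous rate generator over the 61 sense codons: codons differing at
#' more than one nucleotide position have rate 0; a single-nucleotide change
#' from i to j has rate `pi_j`, multiplied by `kappa` if the change is a
#' transition and by `omega` if it is nonsynonymous. The diagonal is set so
#' rows sum to zero; the matrix satisfies detailed balance with `pi`.
#'
#' @param pi Equilibrium frequencies over the 61 sense codons.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (> 0).
#' @param code A [genetic_code()].
#' @return The 61 x 61 generator, with attribute `rate` holding the expected
#'   substitution rate per codon \eqn{-\sum_i \pi_i Q_{ii}} (the flux used to
#'   normalize branch lengths to substitutions per codon).
#' @export
build_rate_matrix <- function(pi, kappa, omega, code = genetic_code()) {
  stopifnot(length(pi) == length(code$sense_codons), all(pi >= 0),
            kappa > 0, omega > 0)
  type <- codon_step_types(code)
  fac <- c(0, 1, kappa, omega, kappa * omega)[type + 1L]
  dim(fac) <- dim(type)
  Q <- fac * rep(pi, each = nrow(type))  # multiply columns by pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- dimnames(type)
  attr(Q, "rate") <- -sum(pi * diag(Q))
  Q
}

# Eigendecomposition of the (reversible) codon generator via symmetrization:
# with D = diag(pi), A = D^{1/2} Q D^{-1/2} is symmetric, A = U L U', and
# P(t) = D^{-1/2} U exp(Lt) U' D^{1/2}. Returns the two transform matrices so
# a transition matrix costs one 61x61 matrix product.
codon_eigen <- function(pi, kappa, omega, code = genetic_code()) {
  if (any(pi <= 0))
    stop("eigendecomposition requires strictly positive codon frequencies")
  Q <- build_rate_matrix(pi, kappa, omega, code)
  sq <- sqrt(pi)
  A <- Q * (sq / rep(sq, each = length(pi)))  # A_ij = sqrt(pi_i/pi_j) q_ij? no:
  # Q * sq[i]/sq[j]: rows scaled by sq, columns divided by sq
  A <- (A + t(A)) / 2  # symmetrize against rounding
  es <- eigen(A, symmetric = TRUE)
  list(values = es$values,
       V1 = es$vectors / sq,            # D^{-1/2} U
       V2 = t(es$vectors * sq),         # U' D^{1/2}
       rate = attr(Q, "rate"),
       pi = pi, kappa = kappa, omega = omega)
}

#' Codon transition probability matrix
#'
#' Matrix exponential `expm(Q t / scale)` computed from the cached
#' eigendecomposition of the reversible generator. `scale` converts branch
#' lengths to expected substitutions per codon: for a site-class mixture it is
#' the mixture-averaged expected rate, for a branch model the branch's own
#' expected rate.
#'
#' @param eig Eigensystem from the internal decomposition of
#'   [build_rate_matrix()] (as stored in fitted models), or a generator
#'   matrix `Q` from [build_rate_matrix()] together with `pi` implied by it.
#' @param t Branch length (>= 0).
#' @param scale Positive rate normalizer.
#' @return Row-stochastic 61 x 61 matrix.
#' @export
transition_matrix <- function(eig, t, scale = 1) {
  stopifnot(t >= 0, scale > 0)
  if (is.matrix(eig))
    stop("pass the eigensystem list produced by the model machinery; ",
         "build one with phydnds:::codon_eigen()")
  P <- eig$V1 %*% (exp(eig$values * (t / scale)) * eig$V2)
  if (!all(is.finite(P)))
    stop("non-finite transition probabilities at t = ", t)
  P[P < 0] <- 0
  P
}

#' Decompose a branch length into dN and dS
#'
#' Splits a branch length `t` (expected substitutions per codon) into
#' nonsynonymous and synonymous distances: `dN = t * rhoN / fN` and
#' `dS = t * rhoS / fS`, where `rhoN`/`rhoS` are the proportions of the
#' substitution flux through nonsynonymous/synonymous single-nucleotide
#' changes under the branch's fitted matrix, and `fN`/`fS` are the
#' nonsynonymous/synonymous site (mutational-opportunity) proportions of the
#' same matrix evaluated at omega = 1. The identity `dN/dS = omega` holds
#' exactly.
#'
#' @param pi,kappa,omega Parameters of the branch's rate matrix.
#' @param t Branch length in expected substitutions per codon (>= 0).
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(dN =, dS =)`.
#' @export
branch_dn_ds <- function(pi, kappa, omega, t, code = genetic_code()) {
  stopifnot(t >= 0)
  flux <- codon_flux(pi, kappa, omega, code)
  f <- codon_flux(pi, kappa, 1, code)
  fN <- f$N / (f$N + f$S)
  fS <- f$S / (f$N + f$S)
  tot <- flux$N + flux$S
  c(dN = t * (flux$N / tot) / fN, dS = t * (flux$S / tot) / fS)
}

# pi-weighted flux through nonsynonymous and synonymous single-nucleotide
# changes of the generator (unnormalized)
codon_flux <- function(pi, kappa, omega, code = genetic_code()) {
  type <- codon_step_types(code)
  fac <- c(0, 1, kappa, omega, kappa * omega)[type + 1L]
  dim(fac) <- dim(type)
  Q <- fac * rep(pi, each = nrow(type))
  w <- pi * Q  # pi_i q_ij elementwise by row
  list(N = sum(w[type == 3L | type == 4L]),
       S = sum(w[type == 1L | type == 2L]))
}
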