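# Shared fixtures and independent oracles.

# small rescaled pure-birth tree
sim_tree <- function(n, seed, depth = 0.5) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n))
  d <- mean(diag(ape::vcv.phylo(tr)))
  tr$edge.length <- tr$edge.length * depth / d
  tr
}

# Brute-force likelihood of one codon column: sum over all interior-node
# state assignments of pi(root) times the product of transition
# probabilities. Transition matrices via the Pade matrix exponential in
# Matrix::expm, independent of the package's eigendecomposition route.
brute_force_loglik <- function(tree, states, pi, kappa, omega,
                               scale = NULL) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  Q <- build_rate_matrix(pi, kappa, omega)
  if (is.null(scale)) scale <- attr(Q, "rate")
  Pe <- lapply(tree$edge.length, function(t)
    as.matrix(Matrix::expm(Matrix::Matrix(Q * (t / scale)))))
  interior <- (ntip + 1L):(ntip + tree$Nnode)
  grid <- do.call(expand.grid, rep(list(seq_len(61L)), length(interior)))
  state_of <- function(node, col) {
    if (node <= ntip) rep.int(states[tree$tip.label[node], col], nrow(grid))
    else grid[[match(node, interior)]]
  }
  total <- 0
  for (col in seq_len(ncol(states))) {
    lik <- pi[state_of(ntip + 1L, col)]
    for (e in seq_len(nrow(tree$edge))) {
      sp <- state_of(tree$edge[e, 1L], col)
      sc <- state_of(tree$edge[e, 2L], col)
      lik <- lik * Pe[[e]][cbind(sp, sc)]
    }
    total <- total + log(sum(lik))
  }
  total
}

# independent Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(rev(cummin(rev(n * p[o] / seq_len(n)))), 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# alignment with given nucleotide strings
nuc_aln <- function(taxa, seqs) {
  structure(list(taxa = taxa, seqs = seqs), class = "nuc_alignment")
}

# the printed full-species absolute-brain-size nominal p-values (model 1)
# for the 14 regressable genes, used as FDR-arithmetic inputs
TABLE2_MODEL1_P <- c(
  AKT1 = 0.942, BRWD3 = 0.211, CCND2 = 0.960, EXT2 = 0.753, GPC3 = 0.061,
  HEPACAM = 0.714, KIF7 = 0.304, MTOR = 0.861, OFD1 = 0.643, PIK3CA = 0.989,
  RIN2 = 0.642, SPRED1 = 0.603, STRADA = 0.077, TBC1D7 = 0.094)
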