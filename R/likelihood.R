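# Likelihood engine: Felsenstein pruning over the 61 sense codons with
# site-pattern compression, per-node rescaling against underflow, and cached
# directional (upward/downward) partials so that the likelihood as a function
# of a single branch length costs one small matrix product.

# Build the pruning engine for one cleaned alignment on a rooted tree.
# The tree is pruned to the alignment's taxa; tips must all have data.
codon_engine <- function(caln, tree) {
  if (anyNA(caln$states))
    stop("alignment contains missing codons; run apply_cleandata() first")
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  missing_tips <- setdiff(caln$taxa, tree$tip.label)
  if (length(missing_tips))
    stop("taxa absent from the tree: ", paste(missing_tips, collapse = ", "))
  if (length(caln$taxa) < 2L) stop("need at least 2 taxa")
  if (length(setdiff(tree$tip.label, caln$taxa)))
    tree <- ape::keep.tip(tree, caln$taxa)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  # site-pattern compression
  key <- apply(caln$states, 2L, paste, collapse = ".")
  upat <- !duplicated(key)
  weights <- as.vector(table(factor(key, levels = key[upat])))
  tipstate <- caln$states[tree$tip.label, upat, drop = FALSE]
  list(tree = tree, edge = tree$edge, nedge = nrow(tree$edge), ntip = ntip,
       nnode = tree$Nnode, root = ntip + 1L,
       tipstate = tipstate, weights = weights, npat = sum(upat),
       n_codons = caln$n_codons, taxa = tree$tip.label, gene = caln$gene)
}

# Per-class transition matrices for every edge. `eig` one eigensystem,
# `tvec` edge lengths in engine edge order.
edge_pmats <- function(eig, tvec, scale) {
  lapply(tvec, function(t) {
    P <- eig$V1 %*% (exp(eig$values * (t / scale)) * eig$V2)
    P[P < 0] <- 0
    P
  })
}

# Downward pass for one class: returns per-internal-node partials (61 x npat),
# per-edge messages M_e = P_e L_child, per-pattern log-rescalers per node,
# and the per-pattern site log-likelihood.
prune_down <- function(eng, Plist, pi) {
  nn <- eng$ntip + eng$nnode
  partial <- vector("list", nn)
  scaler <- vector("list", nn)   # cumulative per-pattern log scalers
  msg <- vector("list", eng$nedge)
  zero <- numeric(eng$npat)
  for (e in seq_len(eng$nedge)) {
    par <- eng$edge[e, 1L]; ch <- eng$edge[e, 2L]
    if (ch <= eng$ntip) {
      M <- Plist[[e]][, eng$tipstate[ch, ], drop = FALSE]
      s <- zero
    } else {
      M <- Plist[[e]] %*% partial[[ch]]
      s <- scaler[[ch]]
    }
    msg[[e]] <- M
    if (is.null(partial[[par]])) {
      partial[[par]] <- M
      scaler[[par]] <- s
    } else {
      partial[[par]] <- partial[[par]] * M
      scaler[[par]] <- scaler[[par]] + s
    }
    if (min(partial[[par]]) < 1e-130) {
      cm <- col_max(partial[[par]])
      cm[cm == 0] <- 1
      partial[[par]] <- partial[[par]] / rep(cm, each = 61L)
      scaler[[par]] <- scaler[[par]] + log(cm)
    }
  }
  root_lik <- colSums(pi * partial[[eng$root]])
  list(partial = partial, scaler = scaler, msg = msg,
       site_loglik = log(root_lik) + scaler[[eng$root]])
}

col_max <- function(m) {
  i <- max.col(t(m), ties.method = "first")
  m[cbind(i, seq_len(ncol(m)))]
}

# Upward pass: for every edge e = (p, c), U_e = (partial likelihood of all
# data outside the subtree of c, as a function of the state at p, root prior
# included) and its per-pattern log-rescaler. Needs the downward pass.
prune_up <- function(eng, Plist, pi, down) {
  U <- vector("list", eng$nedge)
  us <- vector("list", eng$nedge)
  # children edges per internal node
  kids <- split(seq_len(eng$nedge), eng$edge[, 1L])
  parent_edge <- integer(eng$ntip + eng$nnode)
  parent_edge[eng$edge[, 2L]] <- seq_len(eng$nedge)
  ones <- matrix(1, 61L, eng$npat)
  zero <- numeric(eng$npat)
  # preorder: reverse postorder guarantees a node's parent edge is processed
  # before its children edges
  for (e in rev(seq_len(eng$nedge))) {
    p <- eng$edge[e, 1L]
    sibs <- setdiff(kids[[as.character(p)]], e)
    if (p == eng$root) {
      A <- pi * ones
      sa <- zero
    } else {
      g <- parent_edge[p]
      A <- crossprod(Plist[[g]], U[[g]])
      sa <- us[[g]]
    }
    for (f in sibs) {
      A <- A * down$msg[[f]]
      ch <- eng$edge[f, 2L]
      if (ch > eng$ntip) sa <- sa + down$scaler[[ch]]
    }
    if (min(A) < 1e-130) {
      cm <- col_max(A)
      cm[cm == 0] <- 1
      A <- A / rep(cm, each = 61L)
      sa <- sa + log(cm)
    }
    U[[e]] <- A
    us[[e]] <- sa
  }
  list(U = U, scaler = us)
}

# Site log-likelihoods along one edge for one class, as a function of the
# edge's transition matrix: log( U_e . (P L_child) ) + frozen rescalers.
edge_site_loglik <- function(eng, e, P, down, up) {
  ch <- eng$edge[e, 2L]
  if (ch <= eng$ntip) {
    PL <- P[, eng$tipstate[ch, ], drop = FALSE]
    s <- up$scaler[[e]]
  } else {
    PL <- P %*% down$partial[[ch]]
    s <- up$scaler[[e]] + down$scaler[[ch]]
  }
  log(colSums(up$U[[e]] * PL)) + s
}

# Mix per-class site log-likelihoods (npat x K matrix) with proportions.
mix_site_loglik <- function(site_mat, props) {
  if (length(props) == 1L) return(drop(site_mat))
  m <- do.call(pmax, as.data.frame(site_mat))
  m + log(as.vector(exp(site_mat - m) %*% props))
}

# Total log-likelihood for a site-class mixture model.
# eigs: list of K eigensystems; scale: common rate normalizer.
mixture_loglik_engine <- function(eng, eigs, props, tvec, scale,
                                  details = FALSE) {
  K <- length(eigs)
  site <- matrix(0, eng$npat, K)
  downs <- if (details) vector("list", K)
  for (k in seq_len(K)) {
    Plist <- edge_pmats(eigs[[k]], tvec, scale)
    d <- prune_down(eng, Plist, eigs[[k]]$pi)
    site[, k] <- d$site_loglik
    if (details) downs[[k]] <- d
  }
  sl <- mix_site_loglik(site, props)
  ll <- sum(eng$weights * sl)
  if (details) list(loglik = ll, site_loglik = sl, downs = downs) else ll
}

# Total log-likelihood for a branch model: one eigensystem per edge
# (eigs indexed by edge), each branch normalized by its own expected rate.
branch_loglik_engine <- function(eng, eigs_by_edge, tvec) {
  Plist <- vector("list", eng$nedge)
  for (e in seq_len(eng$nedge)) {
    eig <- eigs_by_edge[[e]]
    P <- eig$V1 %*% (exp(eig$values * (tvec[e] / eig$rate)) * eig$V2)
    P[P < 0] <- 0
    Plist[[e]] <- P
  }
  d <- prune_down(eng, Plist, eigs_by_edge[[1L]]$pi)
  sum(eng$weights * d$site_loglik)
}

#' Total log-likelihood of a codon alignment under a site-class mixture
#'
#' Evaluates \eqn{\ell = \sum_{columns} \log \sum_k p_k L_k(column)} by
#' Felsenstein pruning in log space, where class k evolves under the rate
#' matrix with dN/dS `omegas[k]`. Branch lengths are interpreted as expected
#' substitutions per codon under the mixture-averaged rate.
#'
#' @param caln Cleaned `codon_alignment`.
#' @param tree Rooted `phylo` tree with branch lengths; tips must match the
#'   alignment taxa.
#' @param omegas Per-class dN/dS values.
#' @param props Per-class proportions (summing to 1).
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies; default estimated by F3x4.
#' @param code A [genetic_code()].
#' @return The total natural-log likelihood (numeric scalar).
#' @export
mixture_log_likelihood <- function(caln, tree, omegas, props = rep(1, length(omegas)) / length(omegas),
                                   kappa = 2, pi = NULL,
                                   code = genetic_code()) {
  stopifnot(length(omegas) == length(props),
            abs(sum(props) - 1) < 1e-8, all(props >= 0))
  if (is.null(pi)) pi <- estimate_codon_frequencies(caln, "F3x4", code)
  eng <- codon_engine(caln, tree)
  tvec <- eng$tree$edge.length
  if (is.null(tvec)) stop("tree has no branch lengths")
  eigs <- lapply(omegas, function(w) codon_eigen(pi, kappa, w, code))
  scale <- sum(props * vapply(eigs, `[[`, 0, "rate"))
  mixture_loglik_engine(eng, eigs, props, tvec, scale)
}
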