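# Seeded simulators: codon alignments under site-class mixtures or
# per-branch dN/dS variation, and phylogenetically correlated traits.

#' Simulate a codon alignment along a tree
#'
#' Root codons are drawn from the equilibrium frequencies, each site is
#' assigned a dN/dS class by the mixture proportions, and states evolve along
#' every branch by exact sampling from the branch's transition matrix (only
#' endpoint states matter for likelihood work, so no event-level simulation
#' is needed). Branch lengths are read as expected substitutions per codon
#' under the mixture-averaged rate; with `branch_omegas` set, each branch
#' uses its own dN/dS (and its own rate normalization).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param n_codons Number of codon sites.
#' @param omegas,props Site-class dN/dS values and proportions.
#' @param branch_omegas Optional per-branch dN/dS, one per edge of
#'   `reorder(tree, "postorder")` (overrides the site mixture).
#' @param kappa Transition/transversion ratio.
#' @param pi Codon frequencies (default uniform over the 61 sense codons).
#' @param seed Integer seed; identical seeds give identical alignments.
#' @param gene Gene label.
#' @param code A [genetic_code()].
#' @return A `codon_alignment` with attribute `site_class` (true class per
#'   site) and `truth` (the generating parameters).
#' @export
simulate_alignment <- function(tree, n_codons, omegas = 0.3, props = 1,
                               branch_omegas = NULL, kappa = 2, pi = NULL,
                               seed = 1L, gene = "simgene",
                               code = genetic_code()) {
  stopifnot(length(omegas) == length(props), abs(sum(props) - 1) < 1e-8)
  nsense <- length(code$sense_codons)
  if (is.null(pi)) pi <- rep(1 / nsense, nsense)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nedge <- nrow(tree$edge)
  if (!is.null(branch_omegas) && length(branch_omegas) != nedge)
    stop("branch_omegas must have one value per edge (", nedge, ")")
  with_local_seed(seed, {
    site_class <- sample.int(length(props), n_codons, replace = TRUE,
                             prob = props)
    states <- matrix(NA_integer_, ntip + tree$Nnode, n_codons)
    states[root, ] <- sample.int(nsense, n_codons, replace = TRUE, prob = pi)
    if (is.null(branch_omegas)) {
      eigs <- lapply(omegas, function(w) codon_eigen(pi, kappa, w, code))
      scale <- sum(props * vapply(eigs, `[[`, 0, "rate"))
    }
    for (e in rev(seq_len(nedge))) {  # preorder
      par <- tree$edge[e, 1L]
      ch <- tree$edge[e, 2L]
      t <- tree$edge.length[e]
      if (is.null(branch_omegas)) {
        Ps <- lapply(eigs, function(eg) transition_matrix(eg, t, scale))
        cls <- site_class
      } else {
        eg <- codon_eigen(pi, kappa, branch_omegas[e], code)
        Ps <- list(transition_matrix(eg, t, eg$rate))
        cls <- rep(1L, n_codons)
      }
      out <- integer(n_codons)
      for (k in unique(cls)) {
        P <- Ps[[k]]
        sel <- which(cls == k)
        par_states <- states[par, sel]
        for (s in unique(par_states)) {
          here <- sel[par_states == s]
          out[here] <- sample.int(nsense, length(here), replace = TRUE,
                                  prob = P[s, ])
        }
      }
      states[ch, ] <- out
    }
    tips <- states[seq_len(ntip), , drop = FALSE]
    rownames(tips) <- tree$tip.label
    aln <- new_codon_alignment(gene, tips)
    attr(aln, "site_class") <- site_class
    attr(aln, "truth") <- list(omegas = omegas, props = props,
                               branch_omegas = branch_omegas, kappa = kappa,
                               seed = seed)
    aln
  })
}

#' Simulate phylogenetically correlated brain and body traits
#'
#' Generates `log_brain = beta0 + beta1 * log(ratio) + eps` with
#' `eps ~ N(0, sigma2 * V_lambda)` (Brownian-motion covariance of the tree,
#' lambda-scaled), and `log_body` from its own intercept and phylogenetic
#' noise, optionally correlated with the brain residuals.
#'
#' @param tree Rooted `phylo` covering the species.
#' @param rate_table Data frame with `species` and positive `ratio`
#'   (root-to-tip dN/dS) used as the selection predictor.
#' @param beta0,beta1 Intercept and slope on `log(ratio)`.
#' @param lambda_true Pagel's lambda of the residual covariance.
#' @param sigma2 Residual variance of `log_brain`.
#' @param body_beta0,body_sigma2 Body-size intercept and variance.
#' @param body_cor Correlation between brain and body residuals.
#' @param seed Integer seed.
#' @return A trait table: `species`, `brain_size`, `body_size`, `log_brain`,
#'   `log_body`.
#' @export
simulate_traits <- function(tree, rate_table, beta0 = 4, beta1 = 0,
                            lambda_true = 1, sigma2 = 0.25,
                            body_beta0 = 8, body_sigma2 = 0.5,
                            body_cor = 0.5, seed = 1L) {
  rt <- as.data.frame(rate_table)
  if (any(is.na(rt$ratio) | rt$ratio <= 0))
    stop("rate_table ratios must be positive for trait simulation")
  sp <- rt$species
  V <- phylo_covariance(tree, sp)
  Vl <- lambda_transform(V, lambda_true)
  with_local_seed(seed, {
    n <- length(sp)
    if (sigma2 > 0 || body_sigma2 > 0) {
      L <- t(chol(Vl))
      z1 <- as.vector(L %*% stats::rnorm(n))
      z2raw <- as.vector(L %*% stats::rnorm(n))
      z2 <- body_cor * z1 + sqrt(max(0, 1 - body_cor^2)) * z2raw
    } else z1 <- z2 <- numeric(n)
    log_brain <- beta0 + beta1 * log(rt$ratio) + sqrt(sigma2) * z1
    log_body <- body_beta0 + sqrt(body_sigma2) * z2
    data.frame(species = sp, brain_size = exp(log_brain),
               body_size = exp(log_body), log_brain = log_brain,
               log_body = log_body, stringsAsFactors = FALSE)
  })
}

#' Build a miniature end-to-end study fixture
#'
#' A 12-taxon pure-birth tree (rescaled to a mean root-to-tip length of 0.5
#' substitutions per codon — divergent enough for identifiable dN/dS without
#' saturation) carrying three genes with known ground truth: `geneA` neutral+
#' purifying (M1a), `geneB` with a positive-selection class (2% of sites at
#' dN/dS = 6), and `geneC` with per-branch dN/dS variation coupled to a
#' simulated brain-size trait through a known slope on log root-to-tip
#' dN/dS.
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, writes PHYLIP alignments, the
#'   Newick tree, the trait CSV and a JSON manifest of the generating
#'   parameters.
#' @param n_taxa,n_codons Fixture size.
#' @param trait_slope Generating slope of log brain size on log root-to-tip
#'   dN/dS for `geneC`.
#' @return List with `tree`, `alignments` (list of `codon_alignment`),
#'   `traits`, `truth`, and (if `dir` is given) `files`.
#' @export
make_study_fixture <- function(seed = 1L, dir = NULL, n_taxa = 12L,
                               n_codons = 400L, trait_slope = 2) {
  with_local_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tree$tip.label <- paste0("sp", seq_len(n_taxa))
    depth <- mean(diag(ape::vcv.phylo(tree)))
    tree$edge.length <- tree$edge.length * (0.5 / depth)
    tree <- stats::reorder(tree, "postorder")
    kappa <- 2.5
    # per-branch dN/dS for the trait-coupled gene
    bomega <- exp(stats::rnorm(nrow(tree$edge), log(0.25), 0.6))
    truth <- list(
      seed = seed, n_taxa = n_taxa, n_codons = n_codons, kappa = kappa,
      geneA = list(model = "M1a", omegas = c(0.1, 1), props = c(0.8, 0.2)),
      geneB = list(model = "M2a", omegas = c(0.1, 1, 6),
                   props = c(0.78, 0.2, 0.02)),
      geneC = list(model = "free", branch_omegas = bomega),
      trait = list(beta0 = 4, beta1 = trait_slope, lambda = 1,
                   sigma2 = 0.04))
    alnA <- simulate_alignment(tree, n_codons, truth$geneA$omegas,
                               truth$geneA$props, kappa = kappa,
                               seed = seed + 101L, gene = "geneA")
    alnB <- simulate_alignment(tree, n_codons, truth$geneB$omegas,
                               truth$geneB$props, kappa = kappa,
                               seed = seed + 202L, gene = "geneB")
    alnC <- simulate_alignment(tree, n_codons, branch_omegas = bomega,
                               kappa = kappa, seed = seed + 303L,
                               gene = "geneC")
    # true root-to-tip rates of geneC from the generating branch parameters
    pi <- rep(1 / 61, 61)
    dnds <- t(vapply(seq_len(nrow(tree$edge)), function(e)
      branch_dn_ds(pi, kappa, bomega[e], tree$edge.length[e]),
      c(dN = 0, dS = 0)))
    ntip <- length(tree$tip.label)
    bt <- data.frame(child = tree$edge[, 2L], dN = dnds[, 1], dS = dnds[, 2])
    pseudo <- list(tree = tree, branch_table = bt, gene = "geneC")
    rows <- t(vapply(tree$tip.label, function(s) root_to_tip(pseudo, s),
                     c(sum_dN = 0, sum_dS = 0, ratio = 0, n_branches = 0)))
    rt_true <- data.frame(species = tree$tip.label, ratio = rows[, "ratio"],
                          stringsAsFactors = FALSE)
    traits <- simulate_traits(tree, rt_true, beta0 = truth$trait$beta0,
                              beta1 = truth$trait$beta1,
                              lambda_true = truth$trait$lambda,
                              sigma2 = truth$trait$sigma2,
                              seed = seed + 404L)
    out <- list(tree = tree, alignments = list(geneA = alnA, geneB = alnB,
                                               geneC = alnC),
                traits = traits, truth = truth,
                true_rate_table = rt_true)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- list(tree = file.path(dir, "tree.nwk"),
                    traits = file.path(dir, "traits.csv"),
                    manifest = file.path(dir, "manifest.json"))
      ape::write.tree(tree, files$tree)
      utils::write.csv(traits[, c("species", "brain_size", "body_size")],
                       files$traits, row.names = FALSE, quote = FALSE)
      for (g in names(out$alignments)) {
        f <- file.path(dir, paste0(g, ".phy"))
        write_alignment(decode_codons(out$alignments[[g]]), f)
        files[[g]] <- f
      }
      jsonlite::write_json(truth, files$manifest, auto_unbox = TRUE,
                           digits = NA)
      out$files <- files
    }
    out
  })
}
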