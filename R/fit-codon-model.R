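# Maximum-likelihood fitting of codon models.
#
# Strategy: a short coordinate warmup (per-edge Newton updates on cached
# directional partials, with damped/over-relaxed acceptance) moves the fit
# into the basin of attraction, then a joint bounded quasi-Newton over all
# parameters finishes the optimization. The joint step uses analytic
# gradients for every branch length — along one edge the site likelihood is
# S(t) = sum_i g_i exp(lambda_i t), so dS/dt is one extra matrix-vector
# product — and class-structured finite differences for the global
# parameters (a proportion parameter only re-mixes cached per-class site
# likelihoods; a class dN/dS only re-prunes its own class).
#
# Branch lengths are kept internally in raw generator time, so each class's
# rate matrix depends only on its own dN/dS; they are converted to expected
# substitutions per codon (site models: mixture-averaged rate; free-ratio:
# each branch's own rate) on output.

SITE_MODELS <- c("M0", "M1a", "M2a")

#' Fit a codon substitution model by maximum likelihood
#'
#' @param caln A cleaned `codon_alignment` (no missing codons; see
#'   [apply_cleandata()]).
#' @param tree Rooted `phylo` tree containing all alignment taxa. Its branch
#'   lengths seed the optimizer; branch lengths are re-estimated under the
#'   codon model (the topology is fixed).
#' @param model `"M0"` (one dN/dS class), `"M1a"` (purifying + neutral),
#'   `"M2a"` (purifying + neutral + positive, class dN/dS >= 1), or `"free"`
#'   (one dN/dS per branch, constant across sites). Richer models are warm
#'   started from the next simpler one, which also enforces likelihood
#'   nesting up to optimizer tolerance.
#' @param freq_model Codon frequency model passed to
#'   [estimate_codon_frequencies()]; default `"F3x4"`.
#' @param n_restarts Number of seeded random restarts of the global
#'   parameters (branch lengths stay warm); the best likelihood is kept.
#' @param max_rounds Cap on optimization passes.
#' @param tol Convergence tolerance on the change in log-likelihood between
#'   passes.
#' @param seed Integer seed controlling the restart draws; the fit is
#'   deterministic given the seed.
#' @param code A [genetic_code()].
#' @return An object of class `codon_fit` with components `gene`, `model`,
#'   `logLik`, `kappa`, `omegas`, `props` (site models), `branch_omegas`
#'   (free-ratio), `pi`, `tree` (estimated branch lengths, substitutions per
#'   codon), `branch_table` (per branch `t`, `omega`, `dN`, `dS`),
#'   `converged`, `n_function_evals` and the restart record.
#' @seealso [fit_site_model()], [fit_free_ratio()], [likelihood_ratio_test()]
#' @export
fit_codon_model <- function(caln, tree, model = c("M0", "M1a", "M2a", "free"),
                            freq_model = "F3x4", n_restarts = 3,
                            max_rounds = 30, tol = 1e-8, seed = 1L,
                            start = NULL, code = genetic_code()) {
  model <- match.arg(model)
  eng <- codon_engine(caln, tree)
  pi <- estimate_codon_frequencies(caln, freq_model, code)
  tv0 <- eng$tree$edge.length
  if (is.null(tv0)) tv0 <- rep(0.1, eng$nedge)
  tv0 <- pmin(pmax(tv0, 1e-4), 20)
  # the input tree's lengths (substitutions per codon) converted to raw
  # generator time at the starting parameter values
  tv0 <- tv0 / attr(build_rate_matrix(pi, 2, 0.3, code), "rate")
  with_local_seed(seed, {
    if (model == "free") {
      m0 <- site_fit_driver(eng, pi, "M0", tv0, NULL, n_restarts = 0,
                            max_rounds = max_rounds, tol = 1e-6, code = code)
      fit <- free_fit_driver(eng, pi, m0, n_restarts, max_rounds, tol, code)
    } else if (!is.null(start)) {
      fit <- site_fit_driver(eng, pi, model, tv0,
                             pack_from_start(model, start),
                             n_restarts = n_restarts,
                             max_rounds = max_rounds, tol = tol, code = code,
                             props_start = start$props)
    } else {
      fit <- NULL
      warm_t <- tv0
      warm_g <- NULL
      warm_p <- NULL
      for (m in SITE_MODELS[seq_len(match(model, SITE_MODELS))]) {
        last <- m == model
        fit <- site_fit_driver(eng, pi, m, warm_t, warm_g,
                               n_restarts = if (last) n_restarts else 0,
                               max_rounds = max_rounds,
                               tol = if (last) tol else 1e-6, code = code,
                               n_evals_carry = if (is.null(fit)) 0L else
                                 fit$n_function_evals,
                               props_start = promote_props(m, warm_p))
        warm_t <- fit$tvec_raw
        warm_g <- fit$g
        warm_p <- fit$params$props
      }
    }
    finish_codon_fit(fit, eng, pi, freq_model, model, seed, code)
  })
}

#' @rdname fit_codon_model
#' @param models Which site models to fit (in nesting order). The chain is
#'   shared: each model warm starts from the previous one, so fitting all
#'   three costs little more than fitting M2a alone.
#' @export
fit_site_models <- function(caln, tree, models = c("M0", "M1a", "M2a"),
                            freq_model = "F3x4", n_restarts = 3,
                            max_rounds = 30, tol = 1e-8, seed = 1L,
                            code = genetic_code()) {
  models <- match.arg(models, several.ok = TRUE)
  eng <- codon_engine(caln, tree)
  pi <- estimate_codon_frequencies(caln, freq_model, code)
  tv0 <- eng$tree$edge.length
  if (is.null(tv0)) tv0 <- rep(0.1, eng$nedge)
  tv0 <- pmin(pmax(tv0, 1e-4), 20)
  tv0 <- tv0 / attr(build_rate_matrix(pi, 2, 0.3, code), "rate")
  upto <- max(match(models, SITE_MODELS))
  with_local_seed(seed, {
    out <- list()
    fit <- NULL
    warm_t <- tv0
    warm_g <- NULL
    warm_p <- NULL
    for (m in SITE_MODELS[seq_len(upto)]) {
      fit <- site_fit_driver(eng, pi, m, warm_t, warm_g,
                             n_restarts = if (m == "M2a") n_restarts else 0,
                             max_rounds = max_rounds, tol = tol, code = code,
                             props_start = promote_props(m, warm_p))
      warm_t <- fit$tvec_raw
      warm_g <- fit$g
      warm_p <- fit$params$props
      if (m %in% models)
        out[[m]] <- finish_codon_fit(fit, eng, pi, freq_model, m, seed, code)
    }
    out
  })
}

# map a user-supplied start (kappa, omegas, props) onto the packed scale
pack_from_start <- function(model, start) {
  g <- pack_init(model)
  if (!is.null(start$kappa)) g[[1]] <- log(start$kappa)
  om <- start$omegas
  if (!is.null(om)) {
    if (model == "M0") g[[2]] <- log(om[[1]])
    else g[[2]] <- stats::qlogis(min(max(om[[1]], 1e-6), 1 - 1e-6))
    if (model == "M2a" && length(om) >= 3L)
      g[[3]] <- log(max(om[[3]] - 1, 1e-8))
  }
  g
}

#' @rdname fit_codon_model
#' @param model_id Site model identifier (`"M0"`, `"M1a"` or `"M2a"`).
#' @param ... Passed on to [fit_codon_model()].
#' @export
fit_site_model <- function(caln, tree, model_id = c("M1a", "M2a", "M0"), ...) {
  fit_codon_model(caln, tree, model = match.arg(model_id), ...)
}

#' @rdname fit_codon_model
#' @export
fit_free_ratio <- function(caln, tree, ...) {
  fit_codon_model(caln, tree, model = "free", ...)
}

with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# ---- parameter packing -----------------------------------------------------

# Class proportions are not free optimizer coordinates: for a fixed site
# matrix the mixture proportions have a concave profile likelihood that an
# inner EM solves in microseconds, so the quasi-Newton only sees (kappa,
# class dN/dS values, branch lengths). This removes the flattest ridge of
# the M2a surface (the positive-selection class trading proportion against
# dN/dS).
pack_init <- function(model) {
  switch(model,
    M0  = c(lk = log(2), lw = log(0.3)),
    M1a = c(lk = log(2), qw0 = stats::qlogis(0.15)),
    M2a = c(lk = log(2), qw0 = stats::qlogis(0.15), lw2 = log(0.5)))
}

props_init <- function(model) {
  switch(model,
    M0 = 1,
    M1a = c(0.8, 0.2),
    M2a = c(0.78, 0.2, 0.02))
}

pack_bounds <- function(model) {
  B <- 13.8  # plogis(13.8) ~ 1 - 1e-6
  switch(model,
    M0  = list(lower = c(log(0.01), log(1e-6)),
               upper = c(log(100), log(999))),
    M1a = list(lower = c(log(0.01), -B), upper = c(log(100), B)),
    M2a = list(lower = c(log(0.01), -B, log(1e-8)),
               upper = c(log(100), B, log(998))))
}

unpack_params <- function(model, g) {
  kappa <- exp(g[[1]])
  switch(model,
    M0  = list(kappa = kappa, omegas = exp(g[[2]])),
    M1a = list(kappa = kappa, omegas = c(stats::plogis(g[[2]]), 1)),
    M2a = list(kappa = kappa,
               omegas = c(stats::plogis(g[[2]]), 1, 1 + exp(g[[3]]))))
}

# EM for the mixture proportions at a fixed per-class site log-likelihood
# matrix; concave, so convergence is clean
em_props <- function(site, w, p, iters = 300L, tol = 1e-10) {
  if (ncol(site) == 1L) return(list(props = 1, ll = sum(w * site[, 1L])))
  m <- do.call(pmax, as.data.frame(site))
  E <- exp(site - m)
  W <- sum(w)
  ll_old <- -Inf
  for (i in seq_len(iters)) {
    A <- E * rep(p, each = nrow(E))
    Z <- rowSums(A)
    ll <- sum(w * (m + log(Z)))
    if (ll - ll_old < tol && i > 1L) break
    ll_old <- ll
    p <- colSums(w * (A / Z)) / W
  }
  A <- E * rep(p, each = nrow(E))
  list(props = p, ll = sum(w * (m + log(rowSums(A)))))
}

LT_BOUNDS <- log(c(1e-10, 1e4))  # raw-time branch-length box

# ---- site-model driver -----------------------------------------------------

site_fit_driver <- function(eng, pi, model, tvec, g_init, n_restarts,
                            max_rounds, tol, code, n_evals_carry = 0L,
                            props_start = NULL) {
  g <- if (is.null(g_init)) pack_init(model) else promote_params(model, g_init)
  bounds <- pack_bounds(model)
  n_core <- length(g)
  nb <- eng$nedge
  st <- new.env(parent = emptyenv())
  st$n_evals <- n_evals_carry
  st$theta <- NULL
  st$props <- if (is.null(props_start)) props_init(model) else props_start
  w <- eng$weights

  ll_of <- function(site, props) sum(w * mix_site_loglik(site, props))

  state_at <- function(g, tvec) {
    st$n_evals <- st$n_evals + 1L
    p <- unpack_params(model, g)
    eigs <- lapply(p$omegas, function(x) codon_eigen(pi, p$kappa, x, code))
    K <- length(eigs)
    Pl <- vector("list", K)
    down <- vector("list", K)
    site <- matrix(0, eng$npat, K)
    for (k in seq_len(K)) {
      Pl[[k]] <- edge_pmats(eigs[[k]], tvec, 1)
      down[[k]] <- prune_down(eng, Pl[[k]], pi)
      site[, k] <- down[[k]]$site_loglik
    }
    em <- em_props(site, w, pmax(st$props, 1e-8) / sum(pmax(st$props, 1e-8)))
    st$props <- em$props
    list(p = p, props = em$props, eigs = eigs, Pl = Pl, down = down,
         site = site, ll = em$ll)
  }
  get_state <- function(theta) {
    if (is.null(st$theta) || !identical(st$theta, theta))  {
      st$state <- state_at(theta[seq_len(n_core)],
                           exp(theta[n_core + seq_len(nb)]))
      st$theta <- theta
    }
    st$state
  }
  neg_full <- function(theta) -get_state(theta)$ll
  neg_grad <- function(theta) {
    s <- get_state(theta)
    K <- length(s$eigs)
    tvec <- exp(theta[n_core + seq_len(nb)])
    props <- s$props
    # per-pattern class weights for the mixture gradient
    if (K > 1L) {
      m <- do.call(pmax, as.data.frame(s$site))
      A <- exp(s$site - m) * rep(props, each = eng$npat)
      wt <- A / rowSums(A)
      wt[, props == 0] <- 0
    } else wt <- matrix(1, eng$npat, 1L)
    gt <- numeric(nb)
    for (k in seq_len(K)) {
      up <- prune_up(eng, s$Pl[[k]], pi, s$down[[k]])
      for (e in seq_len(nb)) {
        ch <- eng$edge[e, 2L]
        U2 <- crossprod(s$eigs[[k]]$V1, up$U[[e]])
        W <- if (ch <= eng$ntip)
          s$eigs[[k]]$V2[, eng$tipstate[ch, ], drop = FALSE]
        else s$eigs[[k]]$V2 %*% s$down[[k]]$partial[[ch]]
        G <- U2 * W
        v <- s$eigs[[k]]$values
        Et <- exp(v * tvec[e])
        S0 <- as.vector(crossprod(G, Et))
        R1 <- as.vector(crossprod(G, v * Et)) / S0
        gt[e] <- gt[e] + sum(w * wt[, k] * R1)
      }
    }
    gt <- gt * tvec  # d/d log t
    h <- 1e-4
    # profiled objective: proportions held at their inner-EM optimum
    # (envelope theorem), so only the affected classes are re-pruned
    ll_shift <- function(gj) {
      pj <- unpack_params(model, gj)
      site_j <- s$site
      ks <- which(vapply(seq_along(pj$omegas), function(k)
        pj$omegas[k] != s$p$omegas[k] || pj$kappa != s$p$kappa, TRUE))
      ks <- ks[props[ks] > 0]
      for (k in ks) {
        eig <- codon_eigen(pi, pj$kappa, pj$omegas[k], code)
        site_j[, k] <- prune_down(eng, edge_pmats(eig, tvec, 1),
                                  pi)$site_loglik
      }
      if (length(ks)) st$n_evals <- st$n_evals + 1L
      ll_of(site_j, props)
    }
    gg <- numeric(n_core)
    for (j in seq_len(n_core)) {
      gp <- gm <- theta[seq_len(n_core)]
      gp[j] <- gp[j] + h
      gm[j] <- gm[j] - h
      gg[j] <- (ll_shift(gp) - ll_shift(gm)) / (2 * h)
    }
    -c(gg, gt)
  }

  warmup <- function(g, tvec, rounds = 3L) {
    ll <- NULL
    for (r in seq_len(rounds)) {
      s <- state_at(g, tvec)
      if (is.null(ll)) ll <- s$ll
      tv_new <- sweep_site_edges(eng, s$eigs, s$props, tvec, pi)
      ls <- damped_step(tvec, tv_new,
                        function(tv) state_at(g, tv)$ll, ll)
      tvec <- ls$x
      ll <- ls$ll
    }
    list(g = g, tvec = tvec, ll = ll)
  }

  joint <- function(g, tvec, passes = 4L, iter_max = 100L) {
    theta <- c(g, log(pmin(pmax(tvec, exp(LT_BOUNDS[1])), exp(LT_BOUNDS[2]))))
    lower <- c(bounds$lower, rep(LT_BOUNDS[1], nb))
    upper <- c(bounds$upper, rep(LT_BOUNDS[2], nb))
    ll <- -neg_full(theta)
    converged <- FALSE
    used <- 0L
    for (pass in seq_len(passes)) {
      used <- pass
      op <- stats::nlminb(theta, neg_full, gradient = neg_grad,
                          lower = lower, upper = upper,
                          control = list(iter.max = iter_max,
                                         eval.max = 2L * iter_max))
      improved <- -op$objective - ll
      if (-op$objective >= ll) {
        theta <- op$par
        ll <- -op$objective
      }
      if (abs(improved) < tol) {
        converged <- TRUE
        break
      }
    }
    ll <- -neg_full(theta)  # refresh the cached state (and props) at theta
    list(g = theta[seq_len(n_core)], tvec = exp(theta[n_core + seq_len(nb)]),
         ll = ll, converged = converged, passes = used)
  }

  wu <- warmup(g, tvec)
  best <- joint(wu$g, wu$tvec, passes = max_rounds %/% 8L + 2L)
  best$props <- st$props
  restart_lls <- numeric(0)
  if (n_restarts > 0) {
    K <- length(props_init(model))
    for (r in seq_len(n_restarts)) {
      gr <- perturb_params(model, best$g, bounds)
      pr <- stats::rgamma(K, 1)
      st$props <- pr / sum(pr)
      st$theta <- NULL  # invalidate the state cache
      cand <- joint(gr, best$tvec, passes = 1L, iter_max = 30L)
      cand$props <- st$props
      restart_lls <- c(restart_lls, cand$ll)
      if (cand$ll > best$ll + 1e-9) {
        cand$converged <- cand$converged || best$converged
        best <- cand
      }
    }
  }
  p <- unpack_params(model, best$g)
  p$props <- best$props
  list(model = model, g = best$g, tvec_raw = best$tvec, ll = best$ll,
       params = p, converged = best$converged, rounds = best$passes,
       n_function_evals = st$n_evals, restart_lls = restart_lls)
}

# Damped line search along a coordinate-sweep proposal (log scale). The
# per-edge updates are individually optimal with the others frozen, so the
# full step can overshoot when branches are strongly coupled; geometric
# interpolation toward the proposal restores ascent, and over-relaxation
# exploits the frequent undershoot of the joint direction.
damped_step <- function(x_old, x_new, f, ll_old) {
  lx_old <- log(x_old)
  lx_new <- log(x_new)
  step_at <- function(alpha) exp((1 - alpha) * lx_old + alpha * lx_new)
  ll1 <- f(x_new)
  if (ll1 >= ll_old - 1e-12) {
    for (alpha in c(2.4, 1.6)) {
      x2 <- step_at(alpha)
      ll2 <- f(x2)
      if (ll2 > ll1) return(list(x = x2, ll = ll2))
    }
    return(list(x = x_new, ll = ll1))
  }
  for (alpha in c(0.5, 0.25, 0.1)) {
    x <- step_at(alpha)
    ll <- f(x)
    if (ll >= ll_old - 1e-12) return(list(x = x, ll = ll))
  }
  list(x = x_old, ll = ll_old)
}

# carry a simpler model's estimates into a richer model's start
promote_params <- function(model, g_prev) {
  init <- pack_init(model)
  n_prev <- length(g_prev)
  if (n_prev >= length(init)) return(g_prev[seq_along(init)])
  init[[1]] <- g_prev[[1]]  # kappa always first
  if (model == "M1a" && n_prev == 2L) {
    # from M0: purifying class near the single-ratio estimate
    w0 <- min(exp(g_prev[[2]]), 0.95)
    init[[2]] <- stats::qlogis(max(w0, 1e-4))
  }
  if (model == "M2a" && n_prev == 2L) {
    # from M1a: same purifying class, omega2 starts at 1.5
    init[[2]] <- g_prev[[2]]
    init[[3]] <- log(0.5)
  }
  init
}

# promote a simpler model's class proportions (new classes start small)
promote_props <- function(model, props_prev) {
  K <- length(props_init(model))
  if (is.null(props_prev) || length(props_prev) >= K)
    return(props_init(model))
  p <- c(props_prev * (1 - 0.02), rep(0.02, K - length(props_prev)))
  p / sum(p)
}

perturb_params <- function(model, g, bounds) {
  gr <- g + stats::rnorm(length(g), 0, 0.75)
  if (model == "M2a") gr[[3]] <- stats::runif(1, -2, 2.5)
  pmin(pmax(gr, bounds$lower), bounds$upper)
}

# ---- per-edge Newton updates (warmup sweeps) -------------------------------

sweep_site_edges <- function(eng, eigs, props, tvec, pi) {
  K <- length(eigs)
  downs <- vector("list", K)
  ups <- vector("list", K)
  for (k in seq_len(K)) {
    Pl <- edge_pmats(eigs[[k]], tvec, 1)
    downs[[k]] <- prune_down(eng, Pl, pi)
    ups[[k]] <- prune_up(eng, Pl, pi, downs[[k]])
  }
  for (e in seq_len(eng$nedge)) {
    ch <- eng$edge[e, 2L]
    G <- vector("list", K)
    s <- vector("list", K)
    vals <- vector("list", K)
    for (k in seq_len(K)) {
      U2 <- crossprod(eigs[[k]]$V1, ups[[k]]$U[[e]])
      if (ch <= eng$ntip) {
        W <- eigs[[k]]$V2[, eng$tipstate[ch, ], drop = FALSE]
        s[[k]] <- ups[[k]]$scaler[[e]]
      } else {
        W <- eigs[[k]]$V2 %*% downs[[k]]$partial[[ch]]
        s[[k]] <- ups[[k]]$scaler[[e]] + downs[[k]]$scaler[[ch]]
      }
      G[[k]] <- U2 * W
      vals[[k]] <- eigs[[k]]$values
    }
    tvec[e] <- newton_edge_t(tvec[e], G, vals, s, props, eng$weights)
  }
  tvec
}

# Safeguarded Newton on the edge log-likelihood
# l(t) = sum_pat w * log( sum_k p_k exp(s_k) S_k(t) ),  S_k(t) = G_k' exp(v_k t)
newton_edge_t <- function(t0, G, vals, s, props, w,
                          lo = 1e-10, hi = 1e4, iter = 8L) {
  K <- length(G)
  npat <- length(w)
  evalf <- function(t) {
    lk <- matrix(0, npat, K)
    R1 <- matrix(0, npat, K)
    R2 <- matrix(0, npat, K)
    for (k in seq_len(K)) {
      Et <- exp(vals[[k]] * t)
      S0 <- as.vector(crossprod(G[[k]], Et))
      if (any(S0 <= 0)) return(NULL)
      lk[, k] <- log(S0) + s[[k]]
      R1[, k] <- as.vector(crossprod(G[[k]], vals[[k]] * Et)) / S0
      R2[, k] <- as.vector(crossprod(G[[k]], vals[[k]]^2 * Et)) / S0
    }
    m <- do.call(pmax, as.data.frame(lk))
    A <- exp(lk - m) * rep(props, each = npat)
    Z <- rowSums(A)
    wt <- A / Z
    r1 <- rowSums(wt * R1)
    list(ll = sum(w * (m + log(Z))), g = sum(w * r1),
         h = sum(w * (rowSums(wt * R2) - r1^2)))
  }
  t <- max(min(t0, hi), lo)
  f <- evalf(t)
  if (is.null(f)) return(t0)
  for (i in seq_len(iter)) {
    step <- if (is.finite(f$h) && f$h < -1e-14) -f$g / f$h
            else sign(f$g) * 0.5 * t
    if (abs(step) < 1e-10 * (1 + t) || abs(f$g) < 1e-12) break
    tn <- max(min(t + step, hi), lo)
    fn <- evalf(tn)
    tries <- 0L
    while ((is.null(fn) || fn$ll < f$ll - 1e-12) && tries < 6L) {
      tn <- (t + tn) / 2
      fn <- evalf(tn)
      tries <- tries + 1L
    }
    if (is.null(fn) || fn$ll < f$ll - 1e-12) break
    if (abs(tn - t) < 1e-12 * (1 + t)) { t <- tn; f <- fn; break }
    t <- tn
    f <- fn
  }
  t
}

# ---- free-ratio driver -----------------------------------------------------

free_fit_driver <- function(eng, pi, m0, n_restarts, max_rounds, tol, code) {
  st <- new.env(parent = emptyenv())
  st$n_evals <- m0$n_function_evals
  st$theta <- NULL
  nb <- eng$nedge
  w <- eng$weights
  lw_b <- log(c(1e-6, 999))
  # theta = (log kappa, log omega per edge, log t per edge)
  i_w <- 1L + seq_len(nb)
  i_t <- 1L + nb + seq_len(nb)

  state_at <- function(kappa, wvec, tvec) {
    st$n_evals <- st$n_evals + 1L
    eigs <- lapply(wvec, function(x) codon_eigen(pi, kappa, x, code))
    Pl <- lapply(seq_len(nb), function(e) {
      P <- eigs[[e]]$V1 %*% (exp(eigs[[e]]$values * tvec[e]) * eigs[[e]]$V2)
      P[P < 0] <- 0
      P
    })
    down <- prune_down(eng, Pl, pi)
    list(eigs = eigs, Pl = Pl, down = down,
         ll = sum(w * down$site_loglik))
  }
  get_state <- function(theta) {
    if (is.null(st$theta) || !identical(st$theta, theta)) {
      st$state <- state_at(exp(theta[1L]), exp(theta[i_w]), exp(theta[i_t]))
      st$theta <- theta
    }
    st$state
  }
  neg_full <- function(theta) -get_state(theta)$ll
  neg_grad <- function(theta) {
    s <- get_state(theta)
    kappa <- exp(theta[1L])
    wvec <- exp(theta[i_w])
    tvec <- exp(theta[i_t])
    up <- prune_up(eng, s$Pl, pi, s$down)
    gt <- numeric(nb)
    gw <- numeric(nb)
    h <- 1e-4
    for (e in seq_len(nb)) {
      ch <- eng$edge[e, 2L]
      eig <- s$eigs[[e]]
      U2 <- crossprod(eig$V1, up$U[[e]])
      Lc <- if (ch <= eng$ntip) NULL else s$down$partial[[ch]]
      W <- if (is.null(Lc)) eig$V2[, eng$tipstate[ch, ], drop = FALSE]
           else eig$V2 %*% Lc
      G <- U2 * W
      v <- eig$values
      Et <- exp(v * tvec[e])
      S0 <- as.vector(crossprod(G, Et))
      gt[e] <- sum(w * as.vector(crossprod(G, v * Et)) / S0) * tvec[e]
      # edge-local exact recomputation for the dN/dS derivative (central)
      edge_ll <- function(lw) {
        eg <- codon_eigen(pi, kappa, exp(lw), code)
        U2e <- crossprod(eg$V1, up$U[[e]])
        We <- if (is.null(Lc)) eg$V2[, eng$tipstate[ch, ], drop = FALSE]
              else eg$V2 %*% Lc
        sum(w * log(as.vector(crossprod(U2e * We, exp(eg$values * tvec[e])))))
      }
      lw <- log(wvec[e])
      gw[e] <- (edge_ll(lw + h) - edge_ll(lw - h)) / (2 * h)
    }
    gk <- (state_at(exp(theta[1L] + h), wvec, tvec)$ll -
           state_at(exp(theta[1L] - h), wvec, tvec)$ll) / (2 * h)
    -c(gk, gw, gt)
  }

  sweep_free <- function(kappa, wvec, tvec) {
    s <- state_at(kappa, wvec, tvec)
    up <- prune_up(eng, s$Pl, pi, s$down)
    for (e in seq_len(nb)) {
      ch <- eng$edge[e, 2L]
      tip <- ch <= eng$ntip
      s_e <- if (tip) up$scaler[[e]] else
        up$scaler[[e]] + s$down$scaler[[ch]]
      eval_w <- function(lw) {
        eig <- codon_eigen(pi, kappa, exp(lw), code)
        U2 <- crossprod(eig$V1, up$U[[e]])
        W <- if (tip) eig$V2[, eng$tipstate[ch, ], drop = FALSE]
             else eig$V2 %*% s$down$partial[[ch]]
        G <- list(U2 * W)
        tn <- newton_edge_t(tvec[e], G, list(eig$values), list(s_e), 1, w)
        S0 <- as.vector(crossprod(G[[1]], exp(eig$values * tn)))
        if (any(S0 <= 0)) return(list(ll = -Inf, t = tn))
        list(ll = sum(w * (log(S0) + s_e)), t = tn)
      }
      lw <- log(wvec[e])
      win <- c(max(lw - 1.5, lw_b[1]), min(lw + 1.5, lw_b[2]))
      for (grow in 1:5) {
        op <- stats::optimize(function(x) -eval_w(x)$ll, win, tol = 1e-3)
        at_lo <- op$minimum - win[1] < 0.05 && win[1] > lw_b[1] + 1e-9
        at_hi <- win[2] - op$minimum < 0.05 && win[2] < lw_b[2] - 1e-9
        if (!at_lo && !at_hi) break
        if (at_lo) win[1] <- max(win[1] - 3, lw_b[1])
        if (at_hi) win[2] <- min(win[2] + 3, lw_b[2])
      }
      res <- eval_w(op$minimum)
      wvec[e] <- exp(op$minimum)
      tvec[e] <- res$t
    }
    list(wvec = wvec, tvec = tvec)
  }

  kappa <- m0$params$kappa
  wvec <- rep(m0$params$omegas[1], nb)
  tvec <- m0$tvec_raw
  ll <- state_at(kappa, wvec, tvec)$ll
  for (r in 1:2) {
    sw <- sweep_free(kappa, wvec, tvec)
    ls <- damped_step(c(wvec, tvec), c(sw$wvec, sw$tvec),
                      function(x) state_at(kappa, x[seq_len(nb)],
                                           x[nb + seq_len(nb)])$ll, ll)
    wvec <- ls$x[seq_len(nb)]
    tvec <- ls$x[nb + seq_len(nb)]
    ll <- ls$ll
  }
  lower <- c(log(0.01), rep(lw_b[1], nb), rep(LT_BOUNDS[1], nb))
  upper <- c(log(100), rep(lw_b[2], nb), rep(LT_BOUNDS[2], nb))
  theta <- pmin(pmax(c(log(kappa), log(wvec), log(tvec)), lower), upper)
  converged <- FALSE
  passes <- 0L
  for (pass in seq_len(max_rounds %/% 8L + 2L)) {
    passes <- pass
    op <- stats::nlminb(theta, neg_full, gradient = neg_grad,
                        lower = lower, upper = upper,
                        control = list(iter.max = 400L, eval.max = 800L))
    improved <- -op$objective - ll
    if (-op$objective >= ll) {
      theta <- op$par
      ll <- -op$objective
    }
    if (abs(improved) < max(tol, 1e-8)) {
      converged <- TRUE
      break
    }
  }
  wvec <- exp(theta[i_w])
  tvec <- exp(theta[i_t])
  at_bound <- wvec <= exp(lw_b[1]) * 1.01 | wvec >= exp(lw_b[2]) * 0.99
  list(model = "free", kappa = exp(theta[1L]), wvec = wvec, tvec_raw = tvec,
       ll = ll,
       params = list(kappa = exp(theta[1L]), omegas = wvec, props = NULL),
       converged = converged, rounds = passes, at_bound = at_bound,
       n_function_evals = st$n_evals, restart_lls = numeric(0))
  }

# ---- assembling the fitted object ------------------------------------------

finish_codon_fit <- function(fit, eng, pi, freq_model, model, seed, code) {
  tree <- eng$tree
  edge <- eng$edge
  child_lab <- ifelse(edge[, 2L] <= eng$ntip, tree$tip.label[edge[, 2L]],
                      paste0("node", edge[, 2L]))
  if (model == "free") {
    mus <- vapply(fit$wvec, function(x)
      attr(build_rate_matrix(pi, fit$kappa, x, code), "rate"), 0)
    t_out <- fit$tvec_raw * mus
    dnds <- t(vapply(seq_along(t_out), function(e)
      branch_dn_ds(pi, fit$kappa, fit$wvec[e], t_out[e], code),
      c(dN = 0, dS = 0)))
    bt <- data.frame(edge = seq_len(eng$nedge), parent = edge[, 1L],
                     child = edge[, 2L], label = child_lab, t = t_out,
                     omega = fit$wvec, dN = dnds[, 1], dS = dnds[, 2])
    np <- eng$nedge * 2L + 1L
    omegas <- NULL
    props <- NULL
  } else {
    p <- fit$params
    omegas <- p$omegas
    props <- p$props
    rates <- vapply(omegas, function(x)
      attr(build_rate_matrix(pi, p$kappa, x, code), "rate"), 0)
    scale <- sum(props * rates)
    t_out <- fit$tvec_raw * scale
    # mixture-averaged flux decomposition into dN and dS
    fl <- lapply(omegas, function(x) codon_flux(pi, p$kappa, x, code))
    Nbar <- sum(props * vapply(fl, `[[`, 0, "N"))
    Sbar <- sum(props * vapply(fl, `[[`, 0, "S"))
    f1 <- codon_flux(pi, p$kappa, 1, code)
    fN <- f1$N / (f1$N + f1$S)
    fS <- f1$S / (f1$N + f1$S)
    bt <- data.frame(edge = seq_len(eng$nedge), parent = edge[, 1L],
                     child = edge[, 2L], label = child_lab, t = t_out,
                     omega = NA_real_,
                     dN = t_out * (Nbar / (Nbar + Sbar)) / fN,
                     dS = t_out * (Sbar / (Nbar + Sbar)) / fS)
    # free parameters: branch lengths + globals + (K - 1) class proportions
    np <- eng$nedge + length(pack_init(model)) + length(props) - 1L
  }
  tree$edge.length <- unname(t_out)
  ll <- structure(fit$ll, df = np, nobs = eng$n_codons, class = "logLik")
  structure(list(gene = eng$gene, model = model, logLik = ll,
                 kappa = fit$params$kappa, omegas = omegas, props = props,
                 branch_omegas = if (model == "free") fit$wvec,
                 pi = pi, freq_model = freq_model, tree = tree,
                 branch_table = bt, converged = fit$converged,
                 rounds = fit$rounds,
                 omega_at_bound = fit$at_bound,
                 n_function_evals = fit$n_function_evals,
                 restart_lls = fit$restart_lls, seed = seed,
                 n_taxa = eng$ntip, n_codons = eng$n_codons,
                 n_patterns = eng$npat),
            class = "codon_fit")
}

# ---- methods ---------------------------------------------------------------

#' @export
print.codon_fit <- function(x, digits = 4, ...) {
  cat("Codon model fit [", x$gene, "], model ", x$model, "\n", sep = "")
  cat("  taxa: ", x$n_taxa, ", codons: ", x$n_codons,
      " (", x$n_patterns, " patterns)\n", sep = "")
  cat("  log-likelihood: ", formatC(as.numeric(x$logLik), digits = 3,
                                    format = "f"),
      if (!x$converged) "  [not converged]", "\n", sep = "")
  cat("  kappa: ", round(x$kappa, digits), "\n", sep = "")
  if (x$model == "free") {
    rng <- range(x$branch_omegas)
    cat("  per-branch dN/dS in [", round(rng[1], digits), ", ",
        round(rng[2], digits), "]\n", sep = "")
  } else {
    tab <- rbind(proportion = round(x$props, digits),
                 omega = round(x$omegas, digits))
    colnames(tab) <- paste0("class", seq_along(x$omegas))
    print(tab)
  }
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) object$logLik

#' @export
coef.codon_fit <- function(object, ...) {
  if (object$model == "free")
    c(kappa = object$kappa,
      stats::setNames(object$branch_omegas,
                      paste0("omega.", object$branch_table$label)))
  else
    c(kappa = object$kappa,
      stats::setNames(object$omegas,
                      paste0("omega", seq_along(object$omegas))),
      stats::setNames(object$props, paste0("p", seq_along(object$props))))
}

#' @export
summary.codon_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.codon_fit")
}

#' @export
print.summary.codon_fit <- function(x, ...) {
  print(x$fit)
  cat("  convergence passes: ", x$fit$rounds, ", function evaluations: ",
      x$fit$n_function_evals, "\n", sep = "")
  bt <- x$fit$branch_table
  cat("  branch table (", nrow(bt), " branches): total dN = ",
      round(sum(bt$dN), 4), ", total dS = ", round(sum(bt$dS), 4), "\n",
      sep = "")
  invisible(x)
}

#' Simulate alignments from a fitted codon model
#'
#' Parametric-bootstrap simulator: draws codon alignments on the fitted tree
#' under the fitted parameters (site-class mixture for site models, per-branch
#' dN/dS for the free-ratio model).
#'
#' @param object A `codon_fit`.
#' @param nsim Number of alignments.
#' @param seed Integer seed (required for reproducibility; default 1).
#' @param n_codons Number of codon columns; defaults to the fitted
#'   alignment's length.
#' @param ... Unused.
#' @return A list of `codon_alignment` objects of length `nsim`.
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = 1L,
                               n_codons = object$n_codons, ...) {
  lapply(seq_len(nsim), function(i) {
    if (object$model == "free")
      simulate_alignment(object$tree, n_codons = n_codons,
                         omegas = 1, props = 1,
                         branch_omegas = object$branch_omegas,
                         kappa = object$kappa, pi = object$pi,
                         seed = seed + i - 1L,
                         gene = paste0(object$gene, "_sim", i))
    else
      simulate_alignment(object$tree, n_codons = n_codons,
                         omegas = object$omegas, props = object$props,
                         kappa = object$kappa, pi = object$pi,
                         seed = seed + i - 1L,
                         gene = paste0(object$gene, "_sim", i))
  })
}
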