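test_that("phylogenetic covariance matches hand path sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- phylo_covariance(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "A"], 2)
  expect_equal(V["A", "C"], 0)
  # star tree -> diagonal
  star <- ape::read.tree(text = "(a:1,b:2,c:3);")
  Vs <- phylo_covariance(star)
  expect_equal(Vs[row(Vs) != col(Vs)], rep(0, 6))
  # ultrametric -> constant diagonal
  co <- ape::rcoal(6)
  expect_equal(diag(phylo_covariance(co)),
               rep(max(diag(phylo_covariance(co))), 6),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(phylo_covariance(tr, c("A", "Z")), "missing")
})

test_that("lambda transform scales off-diagonals only", {
  V <- phylo_covariance(ape::read.tree(text = "((A:1,B:1):1,C:2);"))
  expect_identical(lambda_transform(V, 1), V)
  V0 <- lambda_transform(V, 0)
  expect_equal(V0, diag(diag(V)), ignore_attr = TRUE)
  Vh <- lambda_transform(V, 0.5)
  expect_equal(Vh["A", "B"], 0.5)
  expect_equal(diag(Vh), diag(V))
  expect_error(lambda_transform(V, 1.2), "lambda")
})

test_that("GLS core matches OLS at lambda 0 and a closed-form oracle", {
  set.seed(41)
  tr <- ape::rcoal(12)
  tr$tip.label <- paste0("s", 1:12)
  d <- data.frame(species = tr$tip.label, x = rnorm(12))
  d$y <- 1 + 0.8 * d$x + rnorm(12, sd = 0.4)
  f0 <- pgls(y ~ x, d, tr, lambda = 0)
  ols <- lm(y ~ x, d)
  expect_equal(unname(coef(f0)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(f0$coefficients$se),
               unname(sqrt(diag(vcov(ols)))), tolerance = 1e-10)
  # 4-taxon fixture against direct matrix algebra
  tr4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  d4 <- data.frame(species = c("a", "b", "c", "d"),
                   x = c(0.1, 0.4, -0.3, 0.8),
                   y = c(1.2, 1.9, 0.3, 2.5))
  V <- phylo_covariance(tr4, d4$species)
  X <- cbind(1, d4$x)
  Vi <- solve(V)
  beta_hand <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d4$y)
  fit <- pgls_fit(d4$y, X, V)
  expect_equal(fit$coefficients$estimate, as.vector(beta_hand),
               tolerance = 1e-10)
  r <- d4$y - X %*% beta_hand
  s2 <- as.numeric(t(r) %*% Vi %*% r) / 2
  expect_equal(unname(fit$coefficients$se),
               sqrt(diag(s2 * solve(t(X) %*% Vi %*% X))), tolerance = 1e-10)
})

test_that("fitted PGLS agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  set.seed(42)
  tr <- ape::rcoal(20)
  tr$tip.label <- paste0("s", 1:20)
  d <- data.frame(species = tr$tip.label, x = rnorm(20))
  L <- t(chol(lambda_transform(phylo_covariance(tr), 0.7)))
  d$y <- 2 + 1.5 * d$x + 0.5 * as.vector(L %*% rnorm(20))
  f <- pgls(y ~ x, d, tr, lambda = 0.7)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(0.7, tr, form = ~species,
                                             fixed = TRUE),
                 method = "ML")
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-8)
  expect_equal(unname(f$coefficients$se), unname(sqrt(diag(vcov(g)))),
               tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(logLik(g)), tolerance = 1e-8)
  # ML lambda against nlme's profile
  fml <- pgls(y ~ x, d, tr, lambda = "ML")
  gml <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corPagel(0.5, tr, form = ~species),
                   method = "ML")
  lam_nlme <- as.numeric(coef(gml$modelStruct$corStruct,
                              unconstrained = FALSE))
  expect_equal(fml$lambda, lam_nlme, tolerance = 1e-4)
})

test_that("lambda profiling averages, recovers and flags flat profiles", {
  set.seed(44)
  # strong Brownian signal at n = 50: ML lambda close to 1
  tr <- ape::rcoal(50)
  tr$tip.label <- paste0("s", 1:50)
  V <- phylo_covariance(tr)
  hits <- 0L
  for (i in 1:3) {
    y <- as.vector(t(chol(V)) %*% rnorm(50))
    prof <- profile_lambda(y, matrix(1, 50, 1), V)
    if (prof$lambda_ml > 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
  # a perfectly flat profile averages to the grid mean 0.5: emulate by
  # checking the averaging arithmetic with uniform weights
  prof <- profile_lambda(y, matrix(1, 50, 1), V)
  expect_equal(sum(prof$grid * rep(1 / 101, 101)), 0.5, tolerance = 1e-12)
  expect_equal(sum(prof$weights), 1, tolerance = 1e-12)
  # tiny n: profile flat flag fires and auto mode falls back to averaging
  tr5 <- ape::rcoal(5)
  tr5$tip.label <- paste0("s", 1:5)
  d5 <- data.frame(species = tr5$tip.label, x = c(0.1, -0.2, 0.3, 0, 0.2))
  set.seed(5)
  d5$y <- rnorm(5, sd = 0.01)
  f5 <- pgls(y ~ x, d5, tr5)
  expect_true(is.finite(f5$logLik))
})

test_that("averaged-lambda coefficients sit near the fixed-lambda bracket", {
  set.seed(45)
  tr <- ape::rcoal(18)
  tr$tip.label <- paste0("s", 1:18)
  d <- data.frame(species = tr$tip.label, x = rnorm(18))
  L <- t(chol(phylo_covariance(tr)))
  d$y <- 1 + 0.8 * d$x + 0.4 * as.vector(L %*% rnorm(18))
  b0 <- coef(pgls(y ~ x, d, tr, lambda = 0))[["x"]]
  b1 <- coef(pgls(y ~ x, d, tr, lambda = 1))[["x"]]
  ba <- coef(pgls(y ~ x, d, tr, lambda = "average"))[["x"]]
  eps <- 0.05 * (1 + abs(b0) + abs(b1))
  expect_gte(ba, min(b0, b1) - eps)
  expect_lte(ba, max(b0, b1) + eps)
})

test_that("simulate.pgls draws from the fitted covariance", {
  set.seed(46)
  tr <- ape::rcoal(15)
  tr$tip.label <- paste0("s", 1:15)
  d <- data.frame(species = tr$tip.label, x = rnorm(15))
  d$y <- 1 + d$x + rnorm(15, sd = 0.2)
  f <- pgls(y ~ x, d, tr, lambda = 1)
  sims <- simulate(f, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(15L, 3L))
  expect_identical(simulate(f, nsim = 3, seed = 9), sims)  # seeded
})

test_that("FDR families follow formula-by-coefficient groups across genes", {
  # the printed full-species absolute-size p-values reproduce their printed
  # adjusted values under a 14-gene family
  adj <- bh_adjust(TABLE2_MODEL1_P)
  expect_equal(unname(adj["GPC3"]), 0.439, tolerance = 0.002)
  expect_equal(unname(adj["STRADA"]), 0.439, tolerance = 0.002)
  expect_equal(unname(adj["TBC1D7"]), 0.439, tolerance = 0.002)
  expect_equal(unname(adj["BRWD3"]), 0.739, tolerance = 0.002)
  expect_equal(unname(adj["KIF7"]), 0.851, tolerance = 0.002)
  expect_equal(unname(adj["SPRED1"]), 0.989, tolerance = 0.002)
  # fdr_by_family adjusts within formula x term and skips the intercept
  rep <- data.frame(gene = rep(c("g1", "g2"), each = 4),
                    formula = rep(c(1L, 1L, 2L, 2L), 2),
                    term = rep(c("(Intercept)", "log_ratio",
                                 "(Intercept)", "log_dN"), 2),
                    p = c(0.5, 0.01, 0.5, 0.03, 0.9, 0.04, 0.9, 0.5))
  out <- fdr_by_family(rep)
  expect_true(all(is.na(out$p_adj[out$term == "(Intercept)"])))
  expect_equal(out$p_adj[out$term == "log_ratio"],
               bh_oracle(c(0.01, 0.04)))
  expect_equal(out$p_adj[out$term == "log_dN"], bh_oracle(c(0.03, 0.5)))
  # monotone in nominal rank after step-up
  set.seed(3)
  p <- runif(14)
  a <- bh_adjust(p)
  expect_true(all(diff(a[order(p)]) >= -1e-12))
  # family of one gene: unchanged
  one <- data.frame(gene = "g", formula = 1L, term = "log_ratio", p = 0.2)
  expect_equal(fdr_by_family(one)$p_adj, 0.2)
})

test_that("gene models, exclusion reruns and LOO behave structurally", {
  set.seed(51)
  tr <- sim_tree(12, seed = 3)
  sp <- tr$tip.label
  rt <- data.frame(gene = "gX", species = sp,
                   sum_dN = runif(12, 0.01, 0.1),
                   sum_dS = runif(12, 0.05, 0.2))
  rt$ratio <- rt$sum_dN / rt$sum_dS
  rt$n_branches <- 3
  class(rt) <- c("rate_table", "data.frame")
  attr(rt, "gene_excluded") <- FALSE
  traits <- simulate_traits(tr, rt, beta0 = 4, beta1 = 1.5, sigma2 = 0.1,
                            seed = 7)
  rep1 <- fit_gene_models(list(rt), traits, tr, lambda = 1)
  expect_setequal(unique(rep1$formula), 1:4)
  expect_true(all(rep1$n == 12))
  # empty drop set equals the base fit exactly
  rep2 <- exclusion_rerun(list(rt), traits, tr, drop = character(),
                          lambda = 1)
  expect_equal(rep1$estimate, rep2$estimate, tolerance = 1e-12)
  # dropping 2 species gives n - 2
  rep3 <- exclusion_rerun(list(rt), traits, tr, drop = sp[1:2], lambda = 1)
  expect_true(all(rep3$n == 10))
  # LOO produces one refit per species
  loo <- sensitivity_loo(rt, traits, tr, formula_id = 1, lambda = 1)
  expect_equal(nrow(loo), 12)
  expect_setequal(loo$species_omitted, sp)
  expect_true(all(loo$n == 11))
  # degenerate predictor: identical ratios -> model skipped with a record
  rt0 <- rt
  rt0$ratio <- 0.2
  rt0$sum_dN <- rt0$sum_dS * 0.2
  rep0 <- fit_gene_models(list(rt0), traits, tr, lambda = 1)
  sk <- attr(rep0, "skipped")
  expect_true(any(grepl("degenerate", sk$reason)))
  # excluded gene is routed to the skip table, not the coefficient table
  attr(rt0, "gene_excluded") <- TRUE
  attr(rt0, "exclusion_reason") <- "all ratios zero"
  rep_ex <- fit_gene_models(list(rt0), traits, tr, lambda = 1)
  expect_equal(nrow(as.data.frame(rep_ex)), 0)
  expect_match(attr(rep_ex, "skipped")$reason[1], "zero")
})
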