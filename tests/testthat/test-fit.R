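# Model fitting: these tests run real optimizations and take tens of
# seconds in total; sizes are kept small (8-10 taxa, 100-300 codons).

test_that("site-model likelihoods nest and parameters are recovered", {
  tr <- sim_tree(8, seed = 71)
  aln <- simulate_alignment(tr, 200, omegas = c(0.1, 1), props = c(0.8, 0.2),
                            kappa = 2.5, seed = 19)
  fits <- fit_site_models(aln, tr, n_restarts = 1, tol = 1e-6)
  ll <- vapply(fits, function(f) as.numeric(logLik(f)), 0)
  expect_lte(ll[["M0"]], ll[["M1a"]] + 0.01)
  expect_lte(ll[["M1a"]], ll[["M2a"]] + 0.01)
  expect_true(all(vapply(fits, `[[`, TRUE, "converged")))
  # M1a recovers a small purifying omega and a neutral class
  expect_lt(fits$M1a$omegas[1], 0.45)
  expect_identical(fits$M1a$omegas[2], 1)
  expect_equal(sum(fits$M1a$props), 1, tolerance = 1e-9)
  # kappa in a sane range around the generating value
  expect_gt(fits$M1a$kappa, 1.2)
  expect_lt(fits$M1a$kappa, 5)
  # degrees of freedom differ by 2 between M1a and M2a
  expect_equal(attr(logLik(fits$M2a), "df") - attr(logLik(fits$M1a), "df"), 2)
})

test_that("strong positive selection is detected by the M2a-vs-M1a LRT", {
  tr <- sim_tree(10, seed = 72)
  aln <- simulate_alignment(tr, 250, omegas = c(0.1, 1, 8),
                            props = c(0.7, 0.22, 0.08), kappa = 2, seed = 23)
  fits <- fit_site_models(aln, tr, models = c("M1a", "M2a"),
                          n_restarts = 1, tol = 1e-6)
  lrt <- likelihood_ratio_test(as.numeric(logLik(fits$M1a)),
                               as.numeric(logLik(fits$M2a)), df = 2)
  expect_lt(lrt$p, 0.001)
  expect_gt(fits$M2a$omegas[3], 1.5)
  expect_gt(fits$M2a$props[3], 0.01)
})

test_that("a supplied start reaches the same optimum as the warm chain", {
  tr <- sim_tree(8, seed = 73)
  aln <- simulate_alignment(tr, 150, omegas = 0.25, props = 1, kappa = 2,
                            seed = 29)
  f_chain <- fit_codon_model(aln, tr, "M0", n_restarts = 0, tol = 1e-6)
  f_start <- fit_codon_model(aln, tr, "M0", n_restarts = 0, tol = 1e-6,
                             start = list(kappa = 2, omegas = 0.25))
  expect_equal(as.numeric(logLik(f_chain)), as.numeric(logLik(f_start)),
               tolerance = 1e-3)
  expect_equal(f_chain$omegas, f_start$omegas, tolerance = 0.01)
})

test_that("free-ratio model nests above M0 and collapses on two taxa", {
  tr <- sim_tree(6, seed = 74)
  aln <- simulate_alignment(tr, 150, omegas = 0.3, props = 1, kappa = 2,
                            seed = 31)
  f0 <- fit_codon_model(aln, tr, "M0", n_restarts = 0, tol = 1e-6)
  ff <- fit_codon_model(aln, tr, "free", n_restarts = 0, tol = 1e-6)
  expect_gte(as.numeric(logLik(ff)), as.numeric(logLik(f0)) - 0.01)
  expect_true(all(ff$branch_table$dN >= 0))
  expect_true(all(ff$branch_table$dS >= 0))
  # per-branch dN/dS equals the branch omega
  ok <- ff$branch_table$dS > 1e-8
  expect_equal(ff$branch_table$dN[ok] / ff$branch_table$dS[ok],
               unname(ff$branch_omegas[ok]), tolerance = 1e-8)
  # two taxa: a single path, so the free model reduces to M0
  tr2 <- ape::read.tree(text = "(a:0.25,b:0.25);")
  aln2 <- simulate_alignment(tr2, 300, omegas = 0.4, props = 1, kappa = 2,
                             seed = 37)
  f0_2 <- fit_codon_model(aln2, tr2, "M0", n_restarts = 0, tol = 1e-6)
  ff_2 <- fit_codon_model(aln2, tr2, "free", n_restarts = 0, tol = 1e-6)
  expect_equal(as.numeric(logLik(ff_2)), as.numeric(logLik(f0_2)),
               tolerance = 0.02)
})

test_that("an elevated branch omega is recovered by the free-ratio fit", {
  tr <- reorder(sim_tree(8, seed = 75), "postorder")
  bo <- rep(0.2, nrow(tr$edge))
  target <- which(tr$edge[, 2] <= 8)[2]
  bo[target] <- 2
  aln <- simulate_alignment(tr, 300, branch_omegas = bo, kappa = 2, seed = 41)
  ff <- fit_codon_model(aln, tr, "free", n_restarts = 0, tol = 1e-6)
  expect_gt(ff$branch_omegas[target], 1)
  # branches with essentially no synonymous signal have unbounded omega
  # estimates; judge only branches carrying signal
  informative <- ff$branch_table$dS > 0.01
  informative[target] <- FALSE
  expect_true(all(ff$branch_omegas[informative] < 1))
})

test_that("simulate.codon_fit performs a parametric bootstrap round trip", {
  tr <- sim_tree(6, seed = 76)
  aln <- simulate_alignment(tr, 100, omegas = c(0.2, 1), props = c(0.7, 0.3),
                            kappa = 2, seed = 43)
  fit <- fit_codon_model(aln, tr, "M1a", n_restarts = 0, tol = 1e-5)
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_equal(sims[[1]]$n_codons, 100)
  expect_setequal(sims[[1]]$taxa, aln$taxa)
  expect_false(identical(sims[[1]]$states, sims[[2]]$states))
  expect_identical(simulate(fit, nsim = 1, seed = 5)[[1]]$states,
                   sims[[1]]$states)
})
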