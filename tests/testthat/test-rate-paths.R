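# helper: minimal object accepted by root_to_tip / build_rate_table
fake_free_fit <- function(tree, dN, dS, gene = "g") {
  tree <- reorder(tree, "postorder")
  list(tree = tree,
       branch_table = data.frame(child = tree$edge[, 2L], dN = dN, dS = dS),
       gene = gene)
}

test_that("root-to-tip sums follow the quoted path rule", {
  # single branch from the root
  tr <- ape::read.tree(text = "(a:1,b:1);")
  f <- fake_free_fit(tr, dN = c(0.02, 0.05), dS = c(0.10, 0.10))
  r <- root_to_tip(f, "a")
  ia <- which(reorder(tr, "postorder")$edge[, 2] == 1)
  expect_equal(unname(r[c("sum_dN", "sum_dS", "ratio")]),
               if (ia == 1) c(0.02, 0.10, 0.2) else c(0.05, 0.10, 0.5))
  # two-branch path: ratio is the quotient of sums, not the mean of ratios
  tr2 <- reorder(ape::read.tree(text = "((a:1,b:1):1,c:1);"), "postorder")
  dN <- dS <- numeric(4)
  e_a <- which(tr2$edge[, 2] == 1)               # terminal branch to a
  e_in <- which(tr2$edge[, 2] == tr2$edge[e_a, 1])  # branch above (a,b)
  dN[e_a] <- 0.02; dS[e_a] <- 0.15
  dN[e_in] <- 0.01; dS[e_in] <- 0.05
  f2 <- fake_free_fit(tr2, dN, dS)
  r2 <- root_to_tip(f2, "a")
  expect_equal(unname(r2["ratio"]), 0.03 / 0.20)
  expect_equal(unname(r2["n_branches"]), 2)
  # mean of per-branch ratios would be (0.2 + 0.2)/2 = 0.2; quotient differs
  expect_false(isTRUE(all.equal(unname(r2["ratio"]),
                                mean(c(0.02 / 0.15, 0.01 / 0.05)))))
  # all-zero dN on the path gives ratio 0; zero dS gives undefined
  f3 <- fake_free_fit(tr, dN = c(0, 0), dS = c(0.1, 0.1))
  expect_equal(unname(root_to_tip(f3, "a")["ratio"]), 0)
  f4 <- fake_free_fit(tr, dN = c(0.1, 0.1), dS = c(0, 0))
  expect_true(is.na(root_to_tip(f4, "a")["ratio"]))
  expect_error(root_to_tip(f3, "zebra"), "not in tree")
})

test_that("summed ratio lies between the per-branch extremes (mediant)", {
  set.seed(17)
  for (i in 1:10) {
    tr <- ape::rtree(6, rooted = TRUE)
    tr <- reorder(tr, "postorder")
    ne <- nrow(tr$edge)
    dS <- runif(ne, 0.01, 0.3)
    dN <- dS * exp(runif(ne, -2, 1.5))
    f <- fake_free_fit(tr, dN, dS)
    rt <- build_rate_table(f)
    for (sp in tr$tip.label) {
      path <- ape::nodepath(tr, from = 7, to = match(sp, tr$tip.label))
      on_path <- tr$edge[, 2] %in% path[-1]
      br_ratios <- dN[on_path] / dS[on_path]
      ratio <- rt$ratio[rt$species == sp]
      expect_gte(ratio, min(br_ratios) - 1e-12)
      expect_lte(ratio, max(br_ratios) + 1e-12)
    }
    # shared internal branches contribute identical addends: check a cherry
    cherries <- table(tr$edge[tr$edge[, 2] <= 6, 1])
    cherry <- as.integer(names(cherries)[cherries == 2][1])
    if (!is.na(cherry)) {
      tips <- tr$edge[tr$edge[, 1] == cherry & tr$edge[, 2] <= 6, 2]
      t1 <- tr$tip.label[tips[1]]; t2 <- tr$tip.label[tips[2]]
      e1 <- which(tr$edge[, 2] == tips[1]); e2 <- which(tr$edge[, 2] == tips[2])
      expect_equal(rt$sum_dN[rt$species == t1] - dN[e1],
                   rt$sum_dN[rt$species == t2] - dN[e2], tolerance = 1e-12)
      expect_equal(rt$sum_dS[rt$species == t1] - dS[e1],
                   rt$sum_dS[rt$species == t2] - dS[e2], tolerance = 1e-12)
    }
  }
})

test_that("rate tables are invariant to the tree's internal edge order", {
  set.seed(23)
  tr <- ape::rtree(8, rooted = TRUE)
  trp <- reorder(tr, "postorder")
  ne <- nrow(trp$edge)
  dS <- runif(ne, 0.01, 0.2)
  dN <- runif(ne, 0, 0.1)
  f <- fake_free_fit(trp, dN, dS)
  rt1 <- build_rate_table(f)
  # same per-branch values keyed by child on a cladewise-ordered copy
  trc <- reorder(trp, "cladewise")
  key <- match(trc$edge[, 2], trp$edge[, 2])
  f2 <- list(tree = trc,
             branch_table = data.frame(child = trc$edge[, 2],
                                       dN = dN[key], dS = dS[key]),
             gene = "g")
  rt2 <- build_rate_table(f2)
  rt2 <- rt2[match(rt1$species, rt2$species), ]
  expect_equal(rt1$sum_dN, rt2$sum_dN, tolerance = 1e-12)
  expect_equal(rt1$sum_dS, rt2$sum_dS, tolerance = 1e-12)
})

test_that("degenerate genes are flagged when most species carry no signal", {
  tr <- reorder(sim_tree(8, seed = 31), "postorder")
  ne <- nrow(tr$edge)
  # no nonsynonymous change anywhere: all ratios zero -> excluded
  f <- fake_free_fit(tr, dN = rep(0, ne), dS = runif(ne, 0.01, 0.1))
  rt <- build_rate_table(f)
  expect_true(attr(rt, "gene_excluded"))
  expect_match(attr(rt, "exclusion_reason"), "8 of 8")
  # healthy gene
  f2 <- fake_free_fit(tr, dN = runif(ne, 0.01, 0.1), dS = runif(ne, 0.01, 0.1))
  expect_false(attr(build_rate_table(f2), "gene_excluded"))
  # exactly half degenerate is retained under the strict > 50% rule
  dN <- runif(ne, 0.01, 0.1)
  zero_tips <- tr$tip.label[1:4]
  # zero out every terminal branch to 4 of 8 species and their private dN
  for (sp in zero_tips) {
    path <- ape::nodepath(tr, 9, match(sp, tr$tip.label))
    dN[tr$edge[, 2] %in% path[-1]] <- 0
  }
  f3 <- fake_free_fit(tr, dN, dS = runif(ne, 0.01, 0.1))
  rt3 <- build_rate_table(f3)
  frac <- mean(rt3$ratio == 0)
  expect_identical(attr(rt3, "gene_excluded"), frac > 0.5)
})
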