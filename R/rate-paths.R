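# Root-to-tip aggregation of per-branch dN and dS from a free-ratio fit.

#' Root-to-tip dN, dS and their ratio for one species
#'
#' Sums the per-branch dN values and per-branch dS values along the unique
#' path from the tree root to a species' tip (terminal branch included) and
#' returns the ratio of the sums. This is deliberately the quotient of the
#' summed distances, not the mean of per-branch ratios.
#'
#' @param fit A free-ratio `codon_fit` (from
#'   [fit_free_ratio()]), or a list with elements `tree` (rooted `phylo`) and
#'   `branch_table` (data frame with columns `child` and `dN`, `dS` keyed by
#'   child node).
#' @param species Tip label.
#' @return Named numeric vector `c(sum_dN, sum_dS, ratio, n_branches)`;
#'   `ratio` is `NA` when `sum_dS` is 0 (undefined) and 0 when only `sum_dN`
#'   is 0.
#' @export
root_to_tip <- function(fit, species) {
  tree <- fit$tree
  bt <- fit$branch_table
  tipn <- match(species, tree$tip.label)
  if (is.na(tipn)) stop("species not in tree: ", species)
  root <- length(tree$tip.label) + 1L
  path <- ape::nodepath(tree, from = root, to = tipn)
  on_path <- bt$child %in% path[-1L]  # every branch below the root, inclusive
  sdN <- sum(bt$dN[on_path])
  sdS <- sum(bt$dS[on_path])
  c(sum_dN = sdN, sum_dS = sdS,
    ratio = if (sdS > 0) sdN / sdS else NA_real_,
    n_branches = sum(on_path))
}

#' Per-species root-to-tip rate table for one gene
#'
#' Applies [root_to_tip()] to every tip and flags genes in which selection
#' signal is too degenerate to regress on: when more than `zero_fraction` of
#' the species have a root-to-tip ratio of zero or undefined (no synonymous
#' change on the path), the gene is marked excluded, mirroring the treatment
#' of genes for which most species carry no signal.
#'
#' @param fit A free-ratio `codon_fit`.
#' @param zero_fraction Exclusion threshold on the fraction of zero/undefined
#'   ratios (default 0.5; exclusion when strictly greater).
#' @param zero_tol Summed distances below this are treated as exactly zero:
#'   branch dN/dS estimates sit at a small positive bound rather than 0 when
#'   no substitution of that kind is inferred, so a path can accumulate a
#'   numerically-nonzero sum that carries no signal.
#' @return A data frame of class `rate_table` (`gene`, `species`, `sum_dN`,
#'   `sum_dS`, `ratio`, `n_branches`) with attributes `gene_excluded`
#'   (logical) and `exclusion_reason`.
#' @export
build_rate_table <- function(fit, zero_fraction = 0.5, zero_tol = 1e-5) {
  sp <- fit$tree$tip.label
  rows <- t(vapply(sp, function(s) root_to_tip(fit, s),
                   c(sum_dN = 0, sum_dS = 0, ratio = 0, n_branches = 0)))
  sdN <- ifelse(rows[, "sum_dN"] < zero_tol, 0, rows[, "sum_dN"])
  sdS <- ifelse(rows[, "sum_dS"] < zero_tol, 0, rows[, "sum_dS"])
  out <- data.frame(gene = fit$gene, species = sp,
                    sum_dN = sdN, sum_dS = sdS,
                    ratio = ifelse(sdS > 0, sdN / sdS, NA_real_),
                    n_branches = rows[, "n_branches"],
                    row.names = NULL, stringsAsFactors = FALSE)
  degen <- is.na(out$ratio) | out$ratio == 0
  frac <- mean(degen)
  excluded <- frac > zero_fraction
  attr(out, "gene_excluded") <- excluded
  attr(out, "exclusion_reason") <- if (excluded)
    sprintf("%d of %d species have zero or undefined root-to-tip dN/dS",
            sum(degen), length(sp)) else NA_character_
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Write a root-to-tip rate table as TSV
#'
#' @param rt A `rate_table` from [build_rate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rt, path) {
  df <- as.data.frame(rt)
  df$gene_excluded <- attr(rt, "gene_excluded")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
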