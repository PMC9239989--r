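# Gene x formula PGLS regressions of brain size on selection measures.
#
# Four model formulas per gene:
#   1  log(brain) ~ log(dN/dS)                      (absolute brain size)
#   2  log(brain) ~ log(dN) + log(dS)               (absolute, rates split)
#   3  log(brain) ~ log(body) + log(dN/dS)          (relative brain size)
#   4  log(brain) ~ log(body) + log(dN) + log(dS)   (relative, rates split)

gene_model_formulas <- function() {
  list(`1` = log_brain ~ log_ratio,
       `2` = log_brain ~ log_dN + log_dS,
       `3` = log_brain ~ log_body + log_ratio,
       `4` = log_brain ~ log_body + log_dN + log_dS)
}

#' Read a species trait table
#'
#' @param path CSV with columns `species`, `brain_size`, `body_size`
#'   (positive sizes in the units of the source literature).
#' @return Data frame with added natural-log columns `log_brain`, `log_body`.
#' @export
read_trait_table <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "brain_size", "body_size")
  if (!all(need %in% names(tt)))
    stop("trait table must have columns: ", paste(need, collapse = ", "))
  if (any(tt$brain_size <= 0) || any(tt$body_size <= 0))
    stop("brain and body sizes must be positive")
  tt$log_brain <- log(tt$brain_size)
  tt$log_body <- log(tt$body_size)
  tt
}

# assemble per-gene regression data: intersection of species with sequence
# signal, traits and tree tips; zero/undefined ratios are dropped from
# log-scale regressions with a warning
gene_regression_data <- function(rate_table, traits, tree,
                                 drop_species = character()) {
  rt <- as.data.frame(rate_table)
  rt <- rt[!(rt$species %in% drop_species), , drop = FALSE]
  degen <- is.na(rt$ratio) | rt$ratio == 0
  if (any(degen)) {
    warning("gene ", rt$gene[1], ": dropping ", sum(degen),
            " species with zero/undefined root-to-tip dN/dS from ",
            "log-scale regressions")
    rt <- rt[!degen, , drop = FALSE]
  }
  if (is.null(traits$log_brain)) traits$log_brain <- log(traits$brain_size)
  if (is.null(traits$log_body)) traits$log_body <- log(traits$body_size)
  d <- merge(rt, traits, by = "species")
  d <- d[d$species %in% tree$tip.label, , drop = FALSE]
  d$log_ratio <- log(d$ratio)
  d$log_dN <- ifelse(d$sum_dN > 0, log(d$sum_dN), NA_real_)
  d$log_dS <- ifelse(d$sum_dS > 0, log(d$sum_dS), NA_real_)
  d[order(d$species), , drop = FALSE]
}

#' Fit the four brain-size model formulas for each gene
#'
#' For every gene's rate table (skipping genes flagged excluded), fits the
#' four PGLS formulas on the intersection of species with sequence, trait and
#' tree data, then applies Benjamini-Hochberg FDR within each
#' formula-by-coefficient family across genes.
#'
#' @param rate_tables List of `rate_table` objects (one per gene) from
#'   [build_rate_table()].
#' @param traits Trait table (see [read_trait_table()]).
#' @param tree Rooted `phylo` covering the species.
#' @param lambda Lambda mode passed to [pgls()] (`"auto"`, `"ML"`,
#'   `"average"`, or a number).
#' @param drop_species Species excluded before fitting (e.g. phyletic
#'   dwarfs).
#' @return A `regression_report` data frame: one row per gene x formula x
#'   coefficient with `estimate`, `se`, `t`, `p`, `p_adj`, `lambda`,
#'   `lambda_mode`, `n`; attribute `skipped` records gene-formula pairs that
#'   could not be fitted and why.
#' @export
fit_gene_models <- function(rate_tables, traits, tree,
                            lambda = "auto", drop_species = character()) {
  if (inherits(rate_tables, "rate_table")) rate_tables <- list(rate_tables)
  forms <- gene_model_formulas()
  rows <- list()
  skipped <- list()
  for (rt in rate_tables) {
    gene <- rt$gene[1]
    if (isTRUE(attr(rt, "gene_excluded"))) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        gene = gene, formula = NA_integer_,
        reason = attr(rt, "exclusion_reason"))
      next
    }
    d <- gene_regression_data(rt, traits, tree, drop_species)
    for (fi in names(forms)) {
      f <- forms[[fi]]
      vars <- all.vars(f)
      dd <- d[stats::complete.cases(d[, vars, drop = FALSE]), , drop = FALSE]
      npred <- length(vars) - 1L
      if (nrow(dd) < npred + 3L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          gene = gene, formula = as.integer(fi),
          reason = sprintf("only %d usable species", nrow(dd)))
        next
      }
      novar <- vars[-1L][vapply(vars[-1L], function(v)
        stats::var(dd[[v]]) < 1e-12, TRUE)]
      if (length(novar)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          gene = gene, formula = as.integer(fi),
          reason = paste("degenerate predictor:",
                         paste(novar, collapse = ", ")))
        next
      }
      fit <- tryCatch(pgls(f, dd, tree, species = dd$species,
                           lambda = lambda),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          gene = gene, formula = as.integer(fi),
          reason = conditionMessage(fit))
        next
      }
      co <- fit$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, formula = as.integer(fi), n = fit$n,
        lambda = fit$lambda, lambda_mode = fit$lambda_mode,
        term = rownames(co), estimate = co$estimate, se = co$se,
        t = co$t, p = co$p, row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), formula = integer(), n = integer(),
               lambda = numeric(), lambda_mode = character(),
               term = character(), estimate = numeric(), se = numeric(),
               t = numeric(), p = numeric())
  report <- fdr_by_family(report)
  attr(report, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  class(report) <- c("regression_report", "data.frame")
  report
}

#' FDR adjustment within formula-by-coefficient families
#'
#' Applies Benjamini-Hochberg separately within each family defined by the
#' same formula and same coefficient across genes (the intercept is left
#' unadjusted), so that m equals the number of genes fitted for that
#' formula.
#'
#' @param report A `regression_report` (or compatible data frame with
#'   columns `formula`, `term`, `p`).
#' @return The report with a `p_adj` column.
#' @export
fdr_by_family <- function(report) {
  report$p_adj <- rep(NA_real_, nrow(report))
  idx <- which(report$term != "(Intercept)")
  if (length(idx)) {
    fam <- interaction(report$formula[idx], report$term[idx], drop = TRUE)
    report$p_adj[idx] <- stats::ave(report$p[idx], fam,
                                    FUN = function(p) bh_adjust(p))
  }
  report
}

#' Leave-one-out sensitivity analysis for one gene-formula model
#'
#' Refits the model omitting each species in turn (the phylogenetic
#' covariance is re-extracted for every subset) and reports the focal
#' coefficient and whether significance at `alpha` flips relative to the
#' base fit.
#'
#' @param rate_table One gene's `rate_table`.
#' @param traits,tree As in [fit_gene_models()].
#' @param formula_id Which of the four formulas (1-4).
#' @param term Focal coefficient; defaults to the formula's first selection
#'   predictor.
#' @param lambda,drop_species As in [fit_gene_models()].
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame: `species_omitted`, `n`, `estimate`, `p`,
#'   `significant`, `flips` (TRUE when the omission changes significance).
#' @export
sensitivity_loo <- function(rate_table, traits, tree, formula_id = 1,
                            term = NULL, lambda = "auto",
                            drop_species = character(), alpha = 0.05) {
  f <- gene_model_formulas()[[as.character(formula_id)]]
  vars <- all.vars(f)
  if (is.null(term)) term <- setdiff(vars[-1L], "log_body")[1L]
  d <- gene_regression_data(rate_table, traits, tree, drop_species)
  d <- d[stats::complete.cases(d[, vars, drop = FALSE]), , drop = FALSE]
  base <- pgls(f, d, tree, species = d$species, lambda = lambda)
  base_sig <- base$coefficients[term, "p"] < alpha
  out <- lapply(d$species, function(s) {
    dd <- d[d$species != s, , drop = FALSE]
    fit <- pgls(f, dd, tree, species = dd$species, lambda = lambda)
    data.frame(species_omitted = s, n = fit$n,
               estimate = fit$coefficients[term, "estimate"],
               p = fit$coefficients[term, "p"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$significant <- out$p < alpha
  out$flips <- out$significant != base_sig
  attr(out, "base_p") <- base$coefficients[term, "p"]
  attr(out, "term") <- term
  out
}

#' Re-run the gene regressions on a reduced species set
#'
#' Convenience wrapper around [fit_gene_models()] that drops a fixed species
#' set first — by default the two phyletic dwarfs (lineages with secondary
#' evolutionary reductions in brain and body size), whose reversed
#' selection-to-brain-size relationship can mask primate-wide associations.
#'
#' @inheritParams fit_gene_models
#' @param drop Species to exclude.
#' @return A `regression_report` (see [fit_gene_models()]).
#' @export
exclusion_rerun <- function(rate_tables, traits, tree,
                            drop = c("Callithrix_jacchus",
                                     "Microcebus_murinus"),
                            lambda = "auto") {
  fit_gene_models(rate_tables, traits, tree, lambda = lambda,
                  drop_species = drop)
}
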