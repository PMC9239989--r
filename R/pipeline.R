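# Pipeline orchestration: per-gene selection scan (site models + LRT + FDR)
# and brain-size regression scan (free-ratio + root-to-tip + PGLS), driven by
# a YAML config.

#' Read and validate a pipeline run configuration
#'
#' @param path YAML file with fields `alignments` (glob), `tree` (Newick
#'   path), `traits` (CSV path, brain scan only), `out_dir`, and optional
#'   `coverage_threshold` (default 0.70), `alpha` (default 0.05), `lambda`
#'   (default "auto"), `exclude_species` (default the two phyletic dwarfs),
#'   `dwarf_exclusion` (default TRUE), `seed` (default 1), `freq_model`,
#'   `n_restarts`.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- list(coverage_threshold = 0.70, alpha = 0.05,
                   fdr_method = "BH", lambda = "auto",
                   exclude_species = c("Callithrix_jacchus",
                                       "Microcebus_murinus"),
                   dwarf_exclusion = TRUE, seed = 1L, freq_model = "F3x4",
                   n_restarts = 3L, out_dir = "results")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("alignments", "tree"))
    if (is.null(cfg[[nm]])) stop("config is missing required field: ", nm)
  for (nm in c("coverage_threshold", "alpha"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop("config field ", nm, " must lie in (0, 1)")
  if (!file.exists(cfg$tree)) stop("tree file not found: ", cfg$tree)
  cfg$gene_files <- sort(Sys.glob(cfg$alignments))
  if (length(cfg$gene_files) == 0L)
    stop("alignment glob matched no files: ", cfg$alignments)
  structure(cfg, class = "run_config")
}

prepare_gene <- function(path, cfg, code = genetic_code()) {
  gene <- tools::file_path_sans_ext(basename(path))
  raw <- read_alignment(path)
  caln <- encode_codons(raw, code, gene = gene)
  cf <- coverage_filter(caln, cfg$coverage_threshold)
  cleaned <- apply_cleandata(cf$alignment)
  list(gene = gene, alignment = cleaned, exclusions = cf$excluded,
       n_removed_columns = length(attr(cleaned, "removed_columns")))
}

#' Run the positive-selection scan (site models)
#'
#' For every gene alignment: coverage filter, column cleaning, M0/M1a/M2a
#' fits, M2a-vs-M1a likelihood-ratio test (df = 2), then Benjamini-Hochberg
#' FDR across genes. Per-gene failures are isolated and logged; the scan
#' continues.
#'
#' @param cfg A `run_config` (or path to a YAML config).
#' @param tree Optional pre-loaded `phylo`; defaults to reading `cfg$tree`.
#' @return A `selection_scan` list: `table` (per gene: M0/M1a/M2a summaries,
#'   LRT statistic, p, p_adj), `fits` (nested `codon_fit` objects),
#'   `exclusions`, `failures`. Reports are written under `cfg$out_dir` as
#'   TSV and JSON with a provenance header (seed, package version).
#' @export
run_selection_scan <- function(cfg, tree = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(tree)) tree <- ape::read.tree(cfg$tree)
  code <- genetic_code()
  rows <- list()
  fits <- list()
  exclusions <- list()
  failures <- list()
  for (path in cfg$gene_files) {
    res <- tryCatch({
      prep <- prepare_gene(path, cfg, code)
      gene_fits <- lapply(c(M0 = "M0", M1a = "M1a", M2a = "M2a"),
        function(m) fit_codon_model(prep$alignment, tree, model = m,
                                    freq_model = cfg$freq_model,
                                    n_restarts = cfg$n_restarts,
                                    seed = cfg$seed))
      lrt <- likelihood_ratio_test(as.numeric(gene_fits$M1a$logLik),
                                   as.numeric(gene_fits$M2a$logLik),
                                   df = 2, gene = prep$gene)
      m2 <- gene_fits$M2a
      list(row = data.frame(
             gene = prep$gene, n_taxa = gene_fits$M0$n_taxa,
             n_codons = gene_fits$M0$n_codons,
             omega_m0 = gene_fits$M0$omegas,
             lnl_m0 = as.numeric(gene_fits$M0$logLik),
             lnl_m1a = as.numeric(gene_fits$M1a$logLik),
             lnl_m2a = as.numeric(gene_fits$M2a$logLik),
             m2a_prop_pos = m2$props[3], m2a_omega_pos = m2$omegas[3],
             lrt = lrt$statistic, p = lrt$p, stringsAsFactors = FALSE),
           fits = gene_fits, excl = prep$exclusions)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("gene ", basename(path), " failed: ", conditionMessage(res))
      failures[[basename(path)]] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res$row
      fits[[res$row$gene]] <- res$fits
      exclusions[[length(exclusions) + 1L]] <- res$excl
    }
  }
  if (length(rows) == 0L) stop("no gene could be analyzed")
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_adjust(tab$p)
  out <- list(table = tab, fits = fits,
              exclusions = do.call(rbind, exclusions),
              failures = failures, config = cfg)
  class(out) <- "selection_scan"
  write_scan_outputs(out, cfg)
  out
}

write_scan_outputs <- function(scan, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- c(sprintf("# phydnds %s selection scan",
                      as.character(utils::packageVersion("phydnds"))),
              sprintf("# seed: %d", as.integer(cfg$seed)),
              sprintf("# coverage_threshold: %g", cfg$coverage_threshold))
  tsv <- file.path(cfg$out_dir, "selection_scan.tsv")
  writeLines(header, tsv)
  suppressWarnings(utils::write.table(scan$table, tsv, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  if (!is.null(scan$exclusions))
    utils::write.table(scan$exclusions,
                       file.path(cfg$out_dir, "coverage_exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  arch <- lapply(scan$fits, function(gf) lapply(gf, fit_to_list))
  jsonlite::write_json(list(seed = cfg$seed,
                            version = as.character(
                              utils::packageVersion("phydnds")),
                            fits = arch),
                       file.path(cfg$out_dir, "selection_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(scan)
}

fit_to_list <- function(fit) {
  list(gene = fit$gene, model = fit$model,
       log_likelihood = as.numeric(fit$logLik), kappa = fit$kappa,
       omegas = fit$omegas, props = fit$props,
       branch_omegas = fit$branch_omegas,
       converged = fit$converged, n_function_evals = fit$n_function_evals,
       seed = fit$seed,
       branch_table = fit$branch_table[, c("label", "t", "omega", "dN", "dS")])
}

#' Run the brain-size regression scan
#'
#' For every gene: free-ratio branch-model fit, per-species root-to-tip
#' dN/dS table, degenerate-gene exclusion, then the four PGLS formulas on
#' the full species set and (optionally) with the phyletic dwarfs excluded,
#' leave-one-out sensitivity for the absolute-size model, and runs with
#' lambda fixed at 0 and 1 alongside the main lambda mode.
#'
#' @param cfg A `run_config` (or path to YAML). Must name a trait CSV in
#'   `cfg$traits`.
#' @param tree Optional pre-loaded `phylo`.
#' @param fits Optional named list of pre-computed free-ratio `codon_fit`
#'   objects (from a previous scan), keyed by gene.
#' @return A `brain_scan` list: `rate_tables`, `excluded_genes`, `reports`
#'   (main, lambda0, lambda1, and dwarf-excluded variants), `sensitivity`.
#'   TSV reports are written under `cfg$out_dir`.
#' @export
run_brain_scan <- function(cfg, tree = NULL, fits = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(cfg$traits)) stop("config is missing required field: traits")
  if (is.null(tree)) tree <- ape::read.tree(cfg$tree)
  traits <- read_trait_table(cfg$traits)
  code <- genetic_code()
  rate_tables <- list()
  excluded <- list()
  failures <- list()
  for (path in cfg$gene_files) {
    res <- tryCatch({
      prep <- prepare_gene(path, cfg, code)
      fit <- if (!is.null(fits[[prep$gene]])) fits[[prep$gene]]
             else fit_codon_model(prep$alignment, tree, model = "free",
                                  freq_model = cfg$freq_model,
                                  n_restarts = cfg$n_restarts,
                                  seed = cfg$seed)
      build_rate_table(fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("gene ", basename(path), " failed: ", conditionMessage(res))
      failures[[basename(path)]] <- conditionMessage(res)
    } else if (isTRUE(attr(res, "gene_excluded"))) {
      excluded[[res$gene[1]]] <- attr(res, "exclusion_reason")
      rate_tables[[res$gene[1]]] <- res
    } else {
      rate_tables[[res$gene[1]]] <- res
    }
  }
  usable <- rate_tables[!names(rate_tables) %in% names(excluded)]
  if (length(usable) == 0L) stop("no gene with usable root-to-tip signal")
  reports <- list(
    main = fit_gene_models(usable, traits, tree, lambda = cfg$lambda),
    lambda0 = fit_gene_models(usable, traits, tree, lambda = 0),
    lambda1 = fit_gene_models(usable, traits, tree, lambda = 1))
  sens <- NULL
  if (isTRUE(cfg$dwarf_exclusion)) {
    reports$dwarf_excluded <- exclusion_rerun(usable, traits, tree,
                                              drop = cfg$exclude_species,
                                              lambda = cfg$lambda)
    sens <- lapply(usable, function(rt)
      tryCatch(sensitivity_loo(rt, traits, tree, formula_id = 1,
                               lambda = cfg$lambda,
                               drop_species = cfg$exclude_species,
                               alpha = cfg$alpha),
               error = function(e) NULL))
  }
  out <- list(rate_tables = rate_tables, excluded_genes = excluded,
              reports = reports, sensitivity = sens, failures = failures,
              config = cfg)
  class(out) <- "brain_scan"
  write_brain_outputs(out, cfg)
  out
}

write_brain_outputs <- function(scan, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rt_all <- do.call(rbind, lapply(scan$rate_tables, as.data.frame))
  utils::write.table(rt_all, file.path(cfg$out_dir, "root_to_tip.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(scan$reports)) {
    utils::write.table(as.data.frame(scan$reports[[nm]]),
                       file.path(cfg$out_dir,
                                 paste0("brain_regressions_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(scan$excluded_genes))
    writeLines(c("gene\treason",
                 paste(names(scan$excluded_genes),
                       unlist(scan$excluded_genes), sep = "\t")),
               file.path(cfg$out_dir, "excluded_genes.tsv"))
  if (!is.null(scan$sensitivity)) {
    sl <- scan$sensitivity[!vapply(scan$sensitivity, is.null, TRUE)]
    if (length(sl)) {
      sdf <- do.call(rbind, Map(function(g, d) cbind(gene = g, d),
                                names(sl), sl))
      utils::write.table(sdf, file.path(cfg$out_dir, "sensitivity_loo.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(scan)
}

#' @export
print.selection_scan <- function(x, ...) {
  cat("Selection scan:", nrow(x$table), "genes\n")
  sig <- x$table$gene[x$table$p_adj < x$config$alpha]
  cat("  positive selection (p_adj < ", x$config$alpha, "): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' @export
print.brain_scan <- function(x, ...) {
  cat("Brain-size regression scan:", length(x$rate_tables), "genes (",
      length(x$excluded_genes), "excluded as degenerate)\n")
  invisible(x)
}
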