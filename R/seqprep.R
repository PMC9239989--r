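#' Encode a nucleotide alignment as codons
#'
#' Maps every in-frame triplet to its index in the 61 sense codons of the
#' genetic code. Triplets containing gaps or ambiguity characters (`-`, `N`,
#' `?`, or any non-ACGT character) become missing. In-frame stop codons also
#' become missing, with a warning: curated coding alignments should not
#' contain them, and the column-cleaning step removes such columns anyway.
#'
#' @param aln A `nuc_alignment` from [read_alignment()].
#' @param code A [genetic_code()].
#' @param gene Gene label carried through reports.
#' @return A `codon_alignment`: list with `gene`, `taxa`, `states` (taxa x
#'   codon-column integer matrix of 1-based sense-codon indices, `NA` for
#'   missing) and `n_codons`.
#' @examples
#' aln <- list(taxa = c("a", "b"), seqs = c("ATGAAA", "ATGA-A"))
#' encode_codons(aln)$states
#' @export
encode_codons <- function(aln, code = genetic_code(), gene = "gene") {
  len <- nchar(aln$seqs)
  bad <- which(len %% 3L != 0L)
  if (length(bad))
    stop("frame error: sequence length of taxon '", aln$taxa[bad[1]],
         "' (", len[bad[1]], ") is not divisible by 3")
  n_codons <- len[1] %/% 3L
  idx_of <- stats::setNames(seq_along(code$sense_codons), code$sense_codons)
  chars <- strsplit(aln$seqs, "")
  states <- matrix(NA_integer_, length(aln$taxa), n_codons,
                   dimnames = list(aln$taxa, NULL))
  n_stop <- 0L
  for (i in seq_along(aln$taxa)) {
    m <- matrix(toupper(chars[[i]]), nrow = 3L)
    triplets <- paste0(m[1, ], m[2, ], m[3, ])
    s <- unname(idx_of[triplets])
    stopped <- triplets %in% code$stop_codons
    n_stop <- n_stop + sum(stopped)
    states[i, ] <- s
  }
  if (n_stop > 0L)
    warning("masked ", n_stop, " in-frame stop codon(s) as missing in gene ",
            gene)
  new_codon_alignment(gene, states)
}

new_codon_alignment <- function(gene, states) {
  stopifnot(is.matrix(states), nrow(states) >= 1L, ncol(states) >= 1L)
  structure(list(gene = gene, taxa = rownames(states), states = states,
                 n_codons = ncol(states)),
            class = "codon_alignment")
}

#' Decode a codon alignment back to nucleotides
#'
#' Inverse of [encode_codons()] for fully observed states; missing codons
#' decode to `---`.
#'
#' @param caln A `codon_alignment`.
#' @param code A [genetic_code()].
#' @return A `nuc_alignment`.
#' @export
decode_codons <- function(caln, code = genetic_code()) {
  lookup <- c(code$sense_codons, "---")
  s <- caln$states
  s[is.na(s)] <- length(lookup)
  seqs <- apply(s, 1L, function(row) paste(lookup[row], collapse = ""))
  new_nuc_alignment(caln$taxa, unname(seqs))
}

#' Remove codon columns with any missing data
#'
#' The `cleandata` convention: every codon column in which any retained taxon
#' is missing (gap, ambiguity, or masked stop codon) is removed before
#' likelihood analysis. Idempotent; column order is preserved.
#'
#' @param caln A `codon_alignment`.
#' @return The cleaned `codon_alignment`, with attribute `removed_columns`
#'   giving the 1-based indices of dropped codon columns.
#' @export
apply_cleandata <- function(caln) {
  any_missing <- colSums(is.na(caln$states)) > 0L
  if (all(any_missing))
    stop("cleandata removed every codon column of gene ", caln$gene,
         ": alignment is empty")
  out <- new_codon_alignment(caln$gene, caln$states[, !any_missing,
                                                    drop = FALSE])
  attr(out, "removed_columns") <- which(any_missing)
  out
}

#' Drop species with insufficient gene coverage
#'
#' Computes per-species coverage as the fraction of non-missing codons over
#' all codon columns of the alignment (before any column removal) and drops
#' species strictly below the threshold. Intended to run before
#' [apply_cleandata()] so that coverage reflects per-species missingness.
#'
#' @param caln A `codon_alignment`.
#' @param threshold Minimum coverage fraction retained; default 0.70, with
#'   exclusion at strictly less than the threshold.
#' @return A list with `alignment` (the retained `codon_alignment`) and
#'   `excluded` (data frame: `gene`, `species`, `coverage`, `action`, one
#'   row per input species).
#' @export
coverage_filter <- function(caln, threshold = 0.70) {
  cov <- rowMeans(!is.na(caln$states))
  drop <- cov < threshold
  if (all(drop))
    stop("coverage filter excluded every species of gene ", caln$gene)
  log <- data.frame(gene = caln$gene, species = caln$taxa,
                    coverage = unname(cov),
                    action = ifelse(drop, "excluded", "retained"),
                    stringsAsFactors = FALSE)
  list(alignment = new_codon_alignment(caln$gene,
                                       caln$states[!drop, , drop = FALSE]),
       excluded = log)
}

#' @export
print.codon_alignment <- function(x, ...) {
  nmiss <- sum(is.na(x$states))
  cat("Codon alignment [", x$gene, "]: ", length(x$taxa), " taxa x ",
      x$n_codons, " codons", if (nmiss) paste0(" (", nmiss, " missing)"),
      "\n", sep = "")
  invisible(x)
}
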