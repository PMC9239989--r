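#' The standard genetic code
#'
#' Builds the standard (table 1) genetic code used throughout the package to
#' define synonymy. Sense codons are ordered lexicographically over the
#' nucleotide order A < C < G < T with the three stop codons removed, giving
#' the 61-state alphabet of the codon substitution models.
#'
#' @param table_id Identifier of the code. Only the standard code (1) is
#'   supported.
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `sense_codons` (character, length 61), `stop_codons`
#'   (character, length 3) and `aa_of` (named character vector over all 64
#'   codons; stop codons translate to `"*"`).
#' @examples
#' code <- genetic_code()
#' length(code$sense_codons)  # 61
#' code$aa_of[["ATG"]]        # "M"
#' @export
genetic_code <- function(table_id = 1L) {
  if (!identical(as.integer(table_id), 1L))
    stop("only the standard genetic code (table_id = 1) is supported")
  tcag <- c("T", "C", "A", "G")
  codons_tcag <- as.vector(t(outer(
    as.vector(t(outer(tcag, tcag, paste0))), tcag, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  names(aa) <- codons_tcag
  all_codons <- sort(codons_tcag)  # lexicographic, A < C < G < T
  aa <- aa[all_codons]
  stops <- names(aa)[aa == "*"]
  sense <- names(aa)[aa != "*"]
  structure(list(table_id = 1L,
                 sense_codons = sense,
                 stop_codons = stops,
                 aa_of = aa),
            class = "genetic_code")
}

# Single-nucleotide change classification over the sense codons, cached per
# session. Entry (i, j): 0 = not a single-nucleotide change, 1 = synonymous
# transversion, 2 = synonymous transition, 3 = nonsynonymous transversion,
# 4 = nonsynonymous transition. Transitions are A<->G and C<->T.
codon_step_types <- local({
  cache <- NULL
  function(code = genetic_code()) {
    if (!is.null(cache)) return(cache)
    sense <- code$sense_codons
    n <- length(sense)
    mat <- do.call(rbind, strsplit(sense, ""))
    type <- matrix(0L, n, n, dimnames = list(sense, sense))
    is_transition <- function(a, b)
      (a == "A" & b == "G") | (a == "G" & b == "A") |
      (a == "C" & b == "T") | (a == "T" & b == "C")
    for (pos in 1:3) {
      same_other <- TRUE
      for (q in setdiff(1:3, pos))
        same_other <- same_other & outer(mat[, q], mat[, q], "==")
      diff_here <- outer(mat[, pos], mat[, pos], "!=")
      single <- same_other & diff_here
      ti <- outer(mat[, pos], mat[, pos], is_transition)
      syn <- outer(code$aa_of[sense], code$aa_of[sense], "==")
      type[single & syn & !ti] <- 1L
      type[single & syn & ti] <- 2L
      type[single & !syn & !ti] <- 3L
      type[single & !syn & ti] <- 4L
    }
    cache <<- type
    type
  }
})

#' @export
print.genetic_code <- function(x, ...) {
  cat("Standard genetic code:", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stop codons (",
      paste(x$stop_codons, collapse = ", "), ")\n")
  invisible(x)
}
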