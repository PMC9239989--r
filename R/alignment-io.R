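#' Read a nucleotide sequence alignment
#'
#' Reads FASTA or PHYLIP (sequential or interleaved) alignments into a plain
#' taxa-by-sequence representation. PHYLIP reading is relaxed: taxon names of
#' any length are accepted as the first whitespace-delimited token, and
#' sequence lines may contain internal whitespace. Writing (see
#' [write_alignment()]) emits strict 10-character-padded sequential PHYLIP, and
#' a file written by the package reads back identically.
#'
#' @param path Path to the alignment file.
#' @param format One of `"fasta"`, `"phylip"` (auto-detect sequential vs
#'   interleaved), `"phylip-sequential"`, `"phylip-interleaved"`. The default
#'   guesses from the file extension (`.fa`, `.fasta`, `.fna` are FASTA,
#'   everything else PHYLIP).
#' @return A list of class `nuc_alignment` with elements `taxa` (character)
#'   and `seqs` (uppercase character strings, all the same length), in file
#'   order.
#' @seealso [write_alignment()], [encode_codons()]
#' @export
read_alignment <- function(path, format = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("fa", "fasta", "fna", "ffn")) "fasta" else "phylip"
  }
  format <- match.arg(format,
    c("fasta", "phylip", "phylip-sequential", "phylip-interleaved"))
  aln <- switch(format,
    "fasta" = read_fasta_alignment(path),
    "phylip" = {
      seqok <- try(read_phylip_alignment(path, interleaved = FALSE),
                   silent = TRUE)
      if (inherits(seqok, "try-error"))
        read_phylip_alignment(path, interleaved = TRUE) else seqok
    },
    "phylip-sequential" = read_phylip_alignment(path, interleaved = FALSE),
    "phylip-interleaved" = read_phylip_alignment(path, interleaved = TRUE))
  validate_nuc_alignment(aln, path)
}

read_fasta_alignment <- function(path) {
  x <- ape::read.FASTA(path)
  if (length(x) == 0L) stop("FASTA parse error in ", path, ": no sequences")
  seqs <- toupper(vapply(as.character(x), paste, "", collapse = ""))
  new_nuc_alignment(names(x), unname(seqs))
}

read_phylip_alignment <- function(path, interleaved = FALSE) {
  lines <- readLines(path)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L)
    stop("PHYLIP parse error in ", path, ": empty file")
  hline <- nonblank[1]
  header <- strsplit(trimws(lines[hline]), "\\s+")[[1]]
  ntax <- suppressWarnings(as.integer(header[1]))
  nchar_decl <- suppressWarnings(as.integer(header[2]))
  if (length(header) != 2L || is.na(ntax) || is.na(nchar_decl) ||
      ntax < 1L || nchar_decl < 1L)
    stop("PHYLIP parse error in ", path, ", line ", hline,
         ": malformed header '", trimws(lines[hline]), "'")
  body <- nonblank[-1]
  taxa <- character(ntax)
  seqs <- character(ntax)
  if (!interleaved) {
    li <- 1L
    for (k in seq_len(ntax)) {
      if (li > length(body))
        stop("PHYLIP parse error in ", path, ": header declares ", ntax,
             " taxa but the body ends after ", k - 1L)
      tok <- strsplit(trimws(lines[body[li]]), "\\s+")[[1]]
      taxa[k] <- tok[1]
      seqs[k] <- paste(tok[-1], collapse = "")
      li <- li + 1L
      while (nchar(seqs[k]) < nchar_decl && li <= length(body) &&
             nchar(seqs[k]) + nchar(gsub("\\s", "", lines[body[li]])) <=
               nchar_decl) {
        seqs[k] <- paste0(seqs[k], gsub("\\s", "", lines[body[li]]))
        li <- li + 1L
      }
      if (nchar(seqs[k]) != nchar_decl)
        stop("PHYLIP parse error in ", path, ", line ", body[min(li, length(body))],
             ": sequence for taxon '", taxa[k], "' has ", nchar(seqs[k]),
             " characters, header declares ", nchar_decl)
    }
    if (li <= length(body))
      stop("PHYLIP parse error in ", path, ", line ", body[li],
         ": trailing content after the ", ntax, " declared taxa")
  } else {
    if (length(body) < ntax)
      stop("PHYLIP parse error in ", path, ": header declares ", ntax,
           " taxa but the first block has ", length(body), " lines")
    for (k in seq_len(ntax)) {
      tok <- strsplit(trimws(lines[body[k]]), "\\s+")[[1]]
      taxa[k] <- tok[1]
      seqs[k] <- paste(tok[-1], collapse = "")
    }
    rest <- body[-seq_len(ntax)]
    if (length(rest) %% ntax != 0L)
      stop("PHYLIP parse error in ", path, ": interleaved continuation of ",
           length(rest), " lines is not a multiple of ", ntax, " taxa")
    for (b in seq_len(length(rest) / ntax)) {
      for (k in seq_len(ntax)) {
        ln <- rest[(b - 1L) * ntax + k]
        seqs[k] <- paste0(seqs[k], gsub("\\s", "", lines[ln]))
      }
    }
    bad <- which(nchar(seqs) != nchar_decl)
    if (length(bad))
      stop("PHYLIP parse error in ", path, ": sequence for taxon '",
           taxa[bad[1]], "' has ", nchar(seqs[bad[1]]),
           " characters, header declares ", nchar_decl)
  }
  new_nuc_alignment(taxa, toupper(seqs))
}

new_nuc_alignment <- function(taxa, seqs) {
  structure(list(taxa = as.character(taxa), seqs = as.character(seqs)),
            class = "nuc_alignment")
}

validate_nuc_alignment <- function(aln, path = "<memory>") {
  dup <- unique(aln$taxa[duplicated(aln$taxa)])
  if (length(dup))
    stop("alignment parse error in ", path, ": duplicate taxon name(s): ",
         paste(dup, collapse = ", "))
  len <- nchar(aln$seqs)
  if (length(unique(len)) > 1L)
    stop("alignment parse error in ", path, ": ragged sequences (lengths ",
         paste(unique(len), collapse = ", "), ")")
  aln
}

#' Write a nucleotide alignment
#'
#' Writes strict sequential PHYLIP (taxon names padded or truncated to 10
#' characters followed by two spaces) or FASTA. The PHYLIP dialect written
#' here is the package's canonical dialect and round-trips byte-identically
#' through [read_alignment()] followed by `write_alignment()`.
#'
#' @param aln A `nuc_alignment` (or anything with `$taxa` and `$seqs`).
#' @param path Output path.
#' @param format `"phylip"` (strict sequential) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("phylip", "fasta")) {
  format <- match.arg(format)
  if (format == "phylip") {
    names10 <- formatC(substr(aln$taxa, 1, 10), width = -10)
    lines <- c(paste(length(aln$taxa), nchar(aln$seqs[1])),
               paste0(names10, "  ", aln$seqs))
  } else {
    lines <- as.vector(rbind(paste0(">", aln$taxa), aln$seqs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.nuc_alignment <- function(x, ...) {
  cat("Nucleotide alignment:", length(x$taxa), "taxa x",
      nchar(x$seqs[1]), "sites\n")
  invisible(x)
}
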