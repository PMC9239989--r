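test_that("genetic code partitions the 64 triplets", {
  code <- genetic_code()
  expect_length(code$sense_codons, 61)
  expect_length(code$stop_codons, 3)
  expect_setequal(c(code$sense_codons, code$stop_codons),
                  names(code$aa_of))
  expect_setequal(code$stop_codons, c("TAA", "TAG", "TGA"))
  # cross-check the translation table with an independent implementation
  skip_if_not_installed("seqinr")
  aa2 <- vapply(names(code$aa_of), function(cd)
    seqinr::translate(strsplit(cd, "")[[1]]), "")
  expect_identical(unname(code$aa_of), unname(aa2))
})

test_that("alignment writers and readers round-trip", {
  aln <- nuc_aln(c("alpha", "beta", "gamma"),
                 c("ATGAAACCC", "ATGAAACCG", "ATGAATCCC"))
  for (fmt in c("phylip", "fasta")) {
    f <- tempfile(fileext = if (fmt == "fasta") ".fasta" else ".phy")
    write_alignment(aln, f, fmt)
    back <- read_alignment(f)
    expect_identical(back$taxa, aln$taxa)
    expect_identical(back$seqs, aln$seqs)
    # byte-level round trip of the canonical dialect
    f2 <- tempfile()
    write_alignment(back, f2, fmt)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("interleaved PHYLIP and relaxed names are read", {
  f <- tempfile()
  writeLines(c("3 12",
               "long_taxon_name_a  ATGAAA",
               "b ATGAAA",
               "c  ATG AAA",
               "",
               "CCCTTT", "CCCTTA", "CCCTTG"), f)
  aln <- read_alignment(f, "phylip-interleaved")
  expect_identical(aln$taxa, c("long_taxon_name_a", "b", "c"))
  expect_identical(aln$seqs[3], "ATGAAACCCTTG")
})

test_that("malformed PHYLIP input gives named parse errors", {
  f <- tempfile()
  writeLines(c("4 9", "a  ATGAAACCC", "b  ATGAAACCC", "c  ATGAAACCC"), f)
  expect_error(read_alignment(f, "phylip-sequential"), "declares 4 taxa")
  writeLines(c("x 9", "a  ATGAAACCC"), f)
  expect_error(read_alignment(f, "phylip-sequential"), "malformed header")
  writeLines(c("2 9", "a  ATGAAACCC", "a  ATGAAACCC"), f)
  expect_error(read_alignment(f, "phylip-sequential"), "duplicate taxon")
  writeLines(c("2 9", "a  ATGAAACCC", "b  ATGAAAC"), f)
  expect_error(read_alignment(f, "phylip-sequential"), "header declares")
})

test_that("codon encoding maps triplets, gaps and stops correctly", {
  code <- genetic_code()
  idx <- function(x) match(x, code$sense_codons)
  enc <- encode_codons(nuc_aln("a", "ATGAAA"))
  expect_identical(as.vector(enc$states), idx(c("ATG", "AAA")))
  enc <- encode_codons(nuc_aln("a", "ATGA-A"))
  expect_identical(as.vector(enc$states), c(idx("ATG"), NA_integer_))
  # in-frame stop codon masks to missing with a warning
  expect_warning(enc <- encode_codons(nuc_aln("a", "TAAATG")),
                 "stop codon")
  expect_identical(as.vector(enc$states), c(NA_integer_, idx("ATG")))
  expect_error(encode_codons(nuc_aln("a", "ATGAA")), "frame error.*'a'")
  # decode round-trips unambiguous input
  aln <- nuc_aln(c("a", "b"), c("ATGAAACCC", "TTTGGGCAT"))
  expect_identical(decode_codons(encode_codons(aln))$seqs, aln$seqs)
})

test_that("cleandata removes exactly the columns with any missing entry", {
  states <- matrix(1L, 3, 10, dimnames = list(c("a", "b", "c"), NULL))
  states[2, 2] <- NA
  states[3, 7] <- NA
  caln <- phydnds:::new_codon_alignment("g", states)
  cleaned <- apply_cleandata(caln)
  expect_equal(cleaned$n_codons, 8)
  expect_equal(attr(cleaned, "removed_columns"), c(2L, 7L))
  # idempotent
  again <- apply_cleandata(cleaned)
  expect_identical(again$states, cleaned$states)
  # no-missing input unchanged
  full <- phydnds:::new_codon_alignment("g", matrix(2L, 2, 4,
    dimnames = list(c("a", "b"), NULL)))
  expect_identical(apply_cleandata(full)$states, full$states)
  # fully missing taxon removes everything
  states[1, ] <- NA
  expect_error(apply_cleandata(phydnds:::new_codon_alignment("g", states)),
               "empty")
})

test_that("coverage filter excludes strictly below the threshold", {
  states <- matrix(1L, 3, 100, dimnames = list(c("lo", "edge", "hi"), NULL))
  states[1, 1:31] <- NA  # 69% coverage -> excluded
  states[2, 1:30] <- NA  # 70% coverage -> retained (strict less-than)
  caln <- phydnds:::new_codon_alignment("g", states)
  res <- coverage_filter(caln, threshold = 0.70)
  expect_identical(res$alignment$taxa, c("edge", "hi"))
  log <- res$excluded
  expect_equal(log$coverage[log$species == "lo"], 0.69)
  expect_identical(log$action[log$species == "lo"], "excluded")
  expect_identical(log$action[log$species == "edge"], "retained")
  expect_equal(log$coverage[log$species == "hi"], 1.0)
  # all species below threshold is an error
  states[3, 1] <- NA
  expect_error(coverage_filter(phydnds:::new_codon_alignment("g", states),
                               threshold = 1), "every species")
})

test_that("coverage filter then cleandata leaves no missing entries", {
  set.seed(9)
  states <- matrix(sample.int(61, 400, TRUE), 5, 80,
                   dimnames = list(paste0("s", 1:5), NULL))
  states[1, sample.int(80, 40)] <- NA  # 50% coverage species
  states[2, sample.int(80, 8)] <- NA
  caln <- phydnds:::new_codon_alignment("g", states)
  out <- apply_cleandata(coverage_filter(caln, 0.7)$alignment)
  expect_false(anyNA(out$states))
  expect_false("s1" %in% out$taxa)
})
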