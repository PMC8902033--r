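rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# small two-family genome used by several module tests
small_two_family_genome <- function(seed = 11L) {
  set.seed(seed)
  satA <- rand_dna(140)
  satB <- rand_dna(120)
  spec <- genome_spec(
    c(chr1 = 1e5, chr2 = 1e5),
    list(
      repeat_family("satA", "tandem_satellite", monomer = satA,
                    copy_number = 80, divergence = 0.02,
                    chromosomes = "chr1"),
      repeat_family("satB", "tandem_satellite", monomer = satB,
                    copy_number = 70, divergence = 0.02,
                    chromosomes = "chr2")),
    seed = seed)
  g <- build_genome(spec)
  list(genome = g, satA = satA, satB = satB)
}
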