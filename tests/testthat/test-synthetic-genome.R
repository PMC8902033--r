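test_that("a zero-divergence tandem satellite is planted exactly", {
  mono <- rand_dna(140, seed = 1)
  spec <- genome_spec(c(chr1 = 1e5),
                     repeat_family("sat", "tandem_satellite", monomer = mono,
                                   copy_number = 100, divergence = 0),
                     seed = 5)
  g <- build_genome(spec)
  tr <- g$truth
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$end - tr$start == 140))
  # copies are contiguous head-to-tail
  tr <- tr[order(tr$start), ]
  expect_equal(tr$start[-1], tr$end[-nrow(tr)])
  locus <- substring(as.character(g$sequences[["chr1"]]),
                     min(tr$start) + 1, max(tr$end))
  expect_identical(locus, strrep(mono, 100))
})

test_that("dispersed copies are non-overlapping and counted per chromosome", {
  spec <- genome_spec(
    stats::setNames(rep(6e4, 5), paste0("chr", 1:5)),
    repeat_family("el", "dispersed_element", monomer_length = 300,
                  copy_number = 500, divergence = 0.05),
    seed = 9)
  g <- build_genome(spec)
  tr <- g$truth
  expect_equal(nrow(tr), 500)
  expect_equal(sum(table(tr$chrom)), 500)
  for (ch in unique(tr$chrom)) {
    x <- tr[tr$chrom == ch, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1) expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  # both strands get used at these numbers
  expect_true(all(c("+", "-") %in% tr$strand))
})

test_that("telomeric arrays sit exactly at chromosome ends", {
  spec <- genome_spec(c(chrA = 5e4, chrB = 7e4),
                     repeat_family("telo", "telomeric_array",
                                   copy_number = 400),
                     seed = 3)
  g <- build_genome(spec)
  lens <- c(chrA = 5e4, chrB = 7e4)
  by_locus <- split(g$truth, g$truth$locus)
  expect_length(by_locus, 4) # both ends of both chromosomes
  for (loc in by_locus) {
    expect_true(min(loc$start) == 0 || max(loc$end) == lens[[loc$chrom[1]]])
  }
})

test_that("mutate_copy preserves length and hits the binomial divergence", {
  expect_identical(mutate_copy("ACGT", 0), "ACGT")
  set.seed(42)
  template <- strrep("A", 10000)
  mut <- mutate_copy(template, 0.1)
  expect_equal(nchar(mut), 10000)
  d <- sum(strsplit(mut, "")[[1]] != "A")
  sigma <- sqrt(10000 * 0.1 * 0.9)
  expect_lt(abs(d - 1000), 3 * sigma)
  # at the maximum divergence of 0.5, identity stays near 0.5 because every
  # substitution always changes the base
  mut5 <- mutate_copy(template, 0.5)
  ident <- mean(strsplit(mut5, "")[[1]] == "A")
  expect_lt(abs(ident - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("genome build is deterministic and conserves length", {
  spec <- example_genome_spec(seed = 7, layout = "distribution")
  g1 <- build_genome(spec)
  g2 <- build_genome(spec)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$truth, g2$truth)
  # planted length + background = chromosome length on every chromosome
  for (ch in names(spec$chromosome_lengths)) {
    planted <- sum(with(g1$truth[g1$truth$chrom == ch, ], end - start))
    expect_lte(planted, spec$chromosome_lengths[[ch]])
    expect_equal(Biostrings::width(g1$sequences[ch]),
                 unname(spec$chromosome_lengths[ch]), ignore_attr = TRUE)
  }
})

test_that("collapse_assembly applies ceiling arithmetic per locus", {
  mono <- rand_dna(100, seed = 2)
  spec <- genome_spec(
    c(chr1 = 1e5, chr2 = 1e5),
    repeat_family("sat", "tandem_satellite", monomer = mono,
                  copy_number = 1000, divergence = 0,
                  placement = "per_chromosome_locus"),
    seed = 8)
  g <- build_genome(spec)
  expect_equal(nrow(g$truth), 1000) # 500 per locus
  asm <- collapse_assembly(g, c(sat = 4))
  # each locus independently retains ceiling(500/4) = 125 copies
  expect_equal(as.vector(table(asm$truth$locus)), c(125L, 125L))
  lost <- 1000 - 250
  expect_equal(sum(Biostrings::width(g$sequences)) -
                 sum(Biostrings::width(asm$sequences)), lost * 100)
  # assembly truth intervals still carry the planted sequence
  x <- asm$truth[asm$truth$chrom == "chr1", ][1, ]
  expect_identical(substring(as.character(asm$sequences[["chr1"]]),
                             x$start + 1, x$end), mono)
})

test_that("collapse factor 1 is the identity and bad factors error", {
  spec <- example_genome_spec(seed = 2, layout = "distribution")
  g <- build_genome(spec)
  same <- collapse_assembly(g, c(satCEN = 1))
  expect_identical(as.character(same$sequences), as.character(g$sequences))
  expect_identical(same$truth, g$truth)
  expect_error(collapse_assembly(g, c(satCEN = 0.5)), "factor")
  expect_error(collapse_assembly(g, c(gypsyL = 2)), "dispersed")
  expect_error(collapse_assembly(g, c(nosuch = 2)), "unknown")
})

test_that("capacity violations and invalid specs are rejected", {
  expect_error(
    build_genome(genome_spec(c(chr1 = 1000),
                             repeat_family("s", "tandem_satellite",
                                           monomer_length = 140,
                                           copy_number = 50,
                                           divergence = 0),
                             seed = 1)),
    "capacity")
  expect_error(repeat_family("t", "telomeric_array",
                             placement = "single_locus"), "terminal")
  expect_error(repeat_family("d", "dispersed_element",
                             placement = "single_locus"), "scatter")
  expect_error(repeat_family("s", "tandem_satellite", copy_number = 10,
                             divergence = 0.7), "divergence")
})

test_that("FASTA/BED round trip preserves sequences and intervals", {
  spec <- genome_spec(c(chr1 = 2e4),
                     repeat_family("sat", "tandem_satellite",
                                   monomer_length = 50, copy_number = 20,
                                   divergence = 0),
                     seed = 4)
  g <- build_genome(spec)
  fa <- tempfile(fileext = ".fasta"); bed <- tempfile(fileext = ".bed")
  write_genome(g, fa, bed)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(as.character(back), as.character(g$sequences))
  tab <- utils::read.table(bed, sep = "\t")
  expect_equal(nrow(tab), nrow(g$truth))
  expect_equal(tab$V2, g$truth$start)
  expect_true(all(tab$V4 == paste0(g$truth$family, ":",
                                   g$truth$copy_index)))
})
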