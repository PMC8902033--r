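test_that("local_align finds exact substrings on both strands", {
  set.seed(61)
  target <- rand_dna(5000)
  q <- substring(target, 2001, 2300)
  h <- local_align(q, target)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1.0)
  expect_equal(h$q_start, 0); expect_equal(h$q_end, 300)
  expect_equal(h$t_start, 2000); expect_equal(h$t_end, 2300)
  expect_equal(h$strand, "+")
  h2 <- local_align(revcomp_chr(q), target)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$t_start, 2000); expect_equal(h2$t_end, 2300)
})

test_that("heavily diverged queries fall below the 70/70 filters", {
  set.seed(62)
  target <- rand_dna(4000)
  q0 <- substring(target, 1001, 1500)
  q <- mutate_copy(q0, 0.4) # ~60% identity, below any qualifying run
  expect_equal(nrow(local_align(q, target)), 0)
})

test_that("assembly copy number recovers exact planted tandem copies", {
  mono <- rand_dna(140, seed = 63)
  spec <- genome_spec(c(chr1 = 1e5),
                     repeat_family("sat", "tandem_satellite", monomer = mono,
                                   copy_number = 100, divergence = 0),
                     seed = 64)
  g <- build_genome(spec)
  est <- assembly_copy_number(mono, g)
  expect_gte(est$copies, 99)
  expect_lte(est$copies, 101)
  expect_equal(est$copies, est$total_aligned_length / est$contig_length)
  # absent contig and self-alignment limits
  expect_equal(assembly_copy_number(rand_dna(500, seed = 65), g)$copies, 0)
  asm <- as.character(g$sequences[["chr1"]])
  expect_equal(assembly_copy_number(asm, g)$copies, 1.0)
})

test_that("read copy number approaches 1 for reads drawn from the contig", {
  contig <- rand_dna(30000, seed = 66)
  g <- Biostrings::DNAStringSet(c(ctg = contig))
  r <- simulate_reads(g, 1.0, error_rate = 0, seed = 67)
  est <- read_copy_number(contig, r)
  expect_lt(abs(est$copies - 1), 0.05)
  # reads from an unrelated genome give ~0
  g2 <- build_genome(genome_spec(c(chr1 = 5e4), list(), seed = 68))
  r2 <- simulate_reads(g2, 1.0, seed = 69)
  expect_lt(read_copy_number(contig, r2)$copies, 0.01)
  empty <- subsample_reads(r2, 0, seed = 1)
  expect_equal(read_copy_number(contig, empty)$copies, 0)
})

test_that("raising either filter threshold never increases copies", {
  spec <- example_genome_spec(seed = 70, layout = "distribution")
  g <- build_genome(spec)
  contig <- unname(g$consensus["satCEN"])
  grid <- expand.grid(id = c(0.7, 0.8, 0.9), cov = c(0.7, 0.8, 0.9))
  copies <- mapply(function(id, cov)
    assembly_copy_number(contig, g, id, cov)$copies, grid$id, grid$cov)
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$id[j] >= grid$id[i] && grid$cov[j] >= grid$cov[i])
      expect_lte(copies[j], copies[i] + 1e-9)
  }
})

test_that("fold change divides read by assembly copies and flags absence", {
  a <- tibble::tibble(contig_id = "x", method = "assembly", copies = 50)
  r <- tibble::tibble(contig_id = "x", method = "read_1x", copies = 50)
  expect_equal(fold_change(r, a), 1.0)
  expect_equal(fold_change(100, 40), 2.5)
  fc <- fold_change(10, 0)
  expect_true(is.na(fc))
  expect_true(attr(fc, "absent_from_assembly"))
  b <- tibble::tibble(contig_id = "y", method = "assembly", copies = 5)
  expect_error(fold_change(r, b), "same contig")
})

test_that("selection thresholds scale with karyotype", {
  expect_equal(selection_threshold(80), 320)
  expect_equal(selection_threshold(64), 256)
  expect_equal(selection_threshold(10, 2), 20)
})

test_that("outfmt-6 export uses 1-based inclusive BLAST conventions", {
  set.seed(71)
  target <- rand_dna(2000)
  q <- substring(target, 501, 700)
  h <- local_align(q, target)
  path <- tempfile(fileext = ".tsv")
  write_hits_outfmt6(h, "q1", path)
  tab <- utils::read.table(path, sep = "\t")
  expect_equal(ncol(tab), 12)
  expect_equal(tab$V7, 1); expect_equal(tab$V8, 200)
  expect_equal(tab$V9, 501); expect_equal(tab$V10, 700)
  expect_equal(tab$V3, 100)
  # minus-strand hits swap subject coordinates
  h2 <- local_align(revcomp_chr(q), target)
  write_hits_outfmt6(h2, "q2", path)
  tab2 <- utils::read.table(path, sep = "\t")
  expect_gt(tab2$V9, tab2$V10)
})

test_that("merged and unmerged aligned totals differ only for overlaps", {
  # non-overlapping planted copies: identical under both semantics
  mono <- rand_dna(200, seed = 72)
  spec <- genome_spec(c(chr1 = 5e4),
                     repeat_family("s", "tandem_satellite", monomer = mono,
                                   copy_number = 30, divergence = 0),
                     seed = 73)
  g <- build_genome(spec)
  e1 <- assembly_copy_number(mono, g)
  e2 <- assembly_copy_number(mono, g, merge_overlaps = TRUE)
  expect_equal(e1$copies, e2$copies)
  # a query of two monomer units produces overlapping period-shifted hits:
  # the literal sum double-counts, the union does not
  e3 <- assembly_copy_number(strrep(mono, 2), g)
  e4 <- assembly_copy_number(strrep(mono, 2), g, merge_overlaps = TRUE)
  expect_gt(e3$copies, e4$copies)
})
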