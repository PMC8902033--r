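make_hits <- function(chrom, t_start, t_end) {
  tibble::tibble(chrom = chrom, q_start = 0L, q_end = t_end - t_start,
                 t_start = t_start, t_end = t_end,
                 length = t_end - t_start, matches = t_end - t_start,
                 identity = 1, strand = "+")
}

test_that("profiles accumulate aligned bp into the right windows", {
  lens <- c(chr1 = 50000, chr2 = 30000)
  p0 <- profile_hits(make_hits(character(0), integer(0), integer(0)), lens,
                     window_bp = 10000)
  expect_equal(p0$total_aligned_bp, 0)
  expect_equal(nrow(p0$windows), 8)
  p1 <- profile_hits(make_hits("chr1", 0L, 140L), lens, window_bp = 10000)
  expect_equal(p1$windows$aligned_bp[p1$windows$chrom == "chr1" &
                                       p1$windows$window == 0], 140)
  # a hit spanning a window boundary is split proportionally
  p2 <- profile_hits(make_hits("chr1", 9950L, 10100L), lens,
                     window_bp = 10000)
  w <- p2$windows[p2$windows$chrom == "chr1", ]
  expect_equal(w$aligned_bp[w$window == 0], 50)
  expect_equal(w$aligned_bp[w$window == 1], 100)
  expect_error(profile_hits(make_hits("chr1", 49990L, 50140L), lens),
               "beyond")
  expect_error(profile_hits(make_hits("chrX", 0L, 10L), lens), "unknown")
})

test_that("profile totals equal the copy estimator's aligned length", {
  spec <- example_genome_spec(seed = 81, layout = "distribution")
  g <- build_genome(spec)
  est <- assembly_copy_number(unname(g$consensus["satCEN"]), g)
  prof <- profile_hits(attr(est, "hits"),
                       stats::setNames(Biostrings::width(g$sequences),
                                       names(g$sequences)),
                       window_bp = 2000)
  expect_equal(prof$total_aligned_bp, est$total_aligned_length)
})

test_that("the concentration rule separates locus-bound from scattered", {
  lens <- c(chr1 = 1e6)
  # all signal in one window of a 1-Mb genome -> non-dispersed
  conc <- profile_hits(make_hits("chr1", rep(5000L, 10), rep(5100L, 10)),
                       lens, window_bp = 10000)
  conc <- classify_dispersion(conc)
  expect_equal(conc$dispersion_class, "non_dispersed")
  expect_equal(nrow(conc$enriched_windows), 1)
  # signal spread over 30% of the genome -> dispersed
  starts <- as.integer(seq(0, 9.9e5, by = 3.3e4))
  disp <- profile_hits(make_hits("chr1", starts, starts + 100L), lens,
                       window_bp = 10000)
  disp <- classify_dispersion(disp)
  expect_equal(disp$dispersion_class, "dispersed")
  # boundary: exactly half the signal in exactly 1% of the genome counts
  # as non-dispersed (inclusive comparisons)
  half <- profile_hits(make_hits("chr1", c(100L, 500100L), c(5100L, 505100L)),
                       lens, window_bp = 10000)
  half <- classify_dispersion(half, concentration_fraction = 0.5,
                              span_fraction = 0.01)
  expect_equal(half$dispersion_class, "non_dispersed")
  expect_error(classify_dispersion(
    profile_hits(make_hits(character(0), integer(0), integer(0)), lens)),
    "no hits")
})

test_that("terminal enrichment measures signal within distal ends", {
  lens <- c(chr1 = 4e5, chr2 = 4e5)
  telo <- profile_hits(make_hits(c("chr1", "chr2"), c(0L, 399000L),
                                 c(1000L, 400000L)), lens)
  expect_true(terminal_enrichment(telo, terminal_bp = 50000))
  mid <- profile_hits(make_hits("chr1", 200000L, 201000L), lens)
  expect_false(terminal_enrichment(mid, terminal_bp = 50000))
  empty <- profile_hits(make_hits(character(0), integer(0), integer(0)),
                        lens)
  expect_false(terminal_enrichment(empty, terminal_bp = 50000))
  expect_error(terminal_enrichment(mid, terminal_bp = 3e5), "half")
})

test_that("colocalization is the Jaccard index of enriched windows", {
  lens <- c(chr1 = 1e6)
  a <- classify_dispersion(profile_hits(
    make_hits("chr1", rep(5000L, 5), rep(5200L, 5)), lens))
  b <- classify_dispersion(profile_hits(
    make_hits("chr1", rep(5100L, 7), rep(5300L, 7)), lens))
  d <- classify_dispersion(profile_hits(
    make_hits("chr1", rep(800000L, 5), rep(800200L, 5)), lens))
  expect_equal(colocalization(a, a), 1.0)
  expect_equal(colocalization(a, b), 1.0) # same window
  expect_equal(colocalization(a, d), 0.0)
  bad <- classify_dispersion(profile_hits(
    make_hits("chr1", 0L, 100L), lens, window_bp = 5000))
  expect_error(colocalization(a, bad), "grid")
})

test_that("two families planted at the same loci colocalize", {
  set.seed(82)
  m1 <- rand_dna(140); m2 <- rand_dna(140)
  spec <- genome_spec(
    c(chr1 = 4e5),
    list(repeat_family("f1", "tandem_satellite", monomer = m1,
                       copy_number = 30, divergence = 0,
                       locus_start = 100000),
         repeat_family("f2", "tandem_satellite", monomer = m2,
                       copy_number = 30, divergence = 0,
                       locus_start = 104300)),
    seed = 83)
  g <- build_genome(spec)
  lens <- stats::setNames(Biostrings::width(g$sequences), names(g$sequences))
  p1 <- classify_dispersion(profile_hits(
    attr(assembly_copy_number(m1, g), "hits"), lens, window_bp = 10000))
  p2 <- classify_dispersion(profile_hits(
    attr(assembly_copy_number(m2, g), "hits"), lens, window_bp = 10000))
  expect_gte(colocalization(p1, p2), 0.6)
})

test_that("bedGraph export writes one row per window", {
  lens <- c(chr1 = 30000)
  p <- profile_hits(make_hits("chr1", 100L, 240L), lens, window_bp = 10000)
  path <- tempfile(fileext = ".bedgraph")
  export_bedgraph(p, path)
  tab <- utils::read.table(path, sep = "\t")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$V4, c(140, 0, 0))
})
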