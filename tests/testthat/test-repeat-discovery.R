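test_that("read_similarity is 1 for identity and orientation-invariant", {
  x <- rand_dna(150, seed = 21)
  expect_equal(read_similarity(x, x), 1.0)
  expect_equal(read_similarity(x, revcomp_chr(x)), 1.0)
  # two reads from monomers at 20% divergence share few 15-mers; compare
  # against a brute-force k-mer set computation
  set.seed(22)
  y <- mutate_copy(x, 0.2)
  s <- read_similarity(x, y, k = 15)
  kx <- unique(substring(x, 1:136, 15:150))
  ky <- unique(substring(y, 1:136, 15:150))
  expect_equal(s, length(intersect(kx, ky)) / length(kx))
  expect_lt(s, 0.55)
})

test_that("reads from two distinct satellite families form two pure clusters", {
  fx <- small_two_family_genome(seed = 23)
  r <- simulate_reads(fx$genome, 0.6, seed = 24)
  cl <- cluster_reads(r)
  expect_equal(nrow(cl), 2)
  # membership matches read origins (family loci occupy known intervals)
  tr <- fx$genome$truth
  for (i in 1:2) {
    orig <- r$origins[match(cl$members[[i]], r$origins$read_id), ]
    fams <- vapply(seq_len(nrow(orig)), function(j) {
      hit <- tr$family[tr$chrom == orig$chrom[j] &
                         tr$start < orig$start[j] + 150 &
                         tr$end > orig$start[j]]
      if (length(hit) == 0) "bg" else hit[1]
    }, "")
    expect_gt(mean(fams == names(which.max(table(fams)))), 0.95)
  }
})

test_that("unique random reads yield no clusters", {
  set.seed(25)
  reads <- Biostrings::DNAStringSet(
    vapply(1:300, function(i) rand_dna(150), ""))
  cl <- cluster_reads(reads)
  expect_equal(nrow(cl), 0)
  expect_equal(attr(cl, "total_reads"), 300)
})

test_that("cluster memberships are invariant to reverse-complementing input", {
  fx <- small_two_family_genome(seed = 26)
  r <- simulate_reads(fx$genome, 0.4, seed = 27)
  cl1 <- cluster_reads(r)
  flipped <- Biostrings::reverseComplement(r$reads)
  names(flipped) <- names(r$reads)
  cl2 <- cluster_reads(flipped)
  expect_equal(nrow(cl1), nrow(cl2))
  m1 <- lapply(cl1$members, sort)
  m2 <- lapply(cl2$members, sort)
  expect_setequal(vapply(m1, paste, "", collapse = ","),
                  vapply(m2, paste, "", collapse = ","))
})

test_that("cluster proportions estimate the planted genome fraction", {
  # one 140-bp satellite at ~10% of a genome; binomial 3-sigma recovery
  mono <- rand_dna(140, seed = 28)
  spec <- genome_spec(c(chr1 = 2e5),
                     repeat_family("sat", "tandem_satellite", monomer = mono,
                                   copy_number = 143, divergence = 0.05),
                     seed = 29)
  g <- build_genome(spec)
  p <- 143 * 140 / 2e5
  r <- simulate_reads(g, 1.5, seed = 30)
  s <- subsample_reads(r, 1500, seed = 31)
  cl <- cluster_reads(s)
  expect_gte(nrow(cl), 1)
  expect_lt(abs(cl$genome_proportion[1] - p), 3 * sqrt(p * (1 - p) / 1500))
})

test_that("the enrichment filter is strict and order-preserving", {
  cl <- tibble::tibble(cluster_id = c("a", "b", "c"),
                       size = c(200L, 10L, 1L),
                       genome_proportion = c(0.02, 1e-4, 5e-5),
                       members = list("x", "y", "z"))
  class(cl) <- c("read_clusters", class(cl))
  out <- enriched_clusters(cl)
  expect_equal(out$cluster_id, "a") # exactly 1e-4 is excluded
  expect_equal(nrow(enriched_clusters(cl[0, ])), 0)
  expect_equal(enriched_clusters(cl, 1e-5)$cluster_id, c("a", "b", "c"))
})

test_that("a satellite cluster's contig is a rotation of the monomer array", {
  mono <- rand_dna(140, seed = 32)
  spec <- genome_spec(c(chr1 = 1.5e5),
                     repeat_family("sat", "tandem_satellite", monomer = mono,
                                   copy_number = 100, divergence = 0),
                     seed = 33)
  g <- build_genome(spec)
  r <- simulate_reads(g, 1, error_rate = 0, seed = 34)
  cl <- cluster_reads(r)
  rc <- build_representative_contig(cl, r, cl$cluster_id[1])
  expect_gte(nchar(rc$sequence), 150)
  expect_gte(rc$mean_read_depth, 1)
  # aligning the doubled monomer onto the contig covers it end to end
  hits <- local_align(rc$sequence, strrep(mono, 2 + nchar(rc$sequence) %/% 140),
                      0.9, 0, min_hit_len = 50)
  expect_gt(max(hits$length), 0.95 * nchar(rc$sequence))
})

test_that("a dispersed-element cluster reconstructs the element consensus", {
  spec <- example_genome_spec(seed = 35, layout = "recovery")
  g <- build_genome(spec)
  r <- simulate_reads(g, 1, seed = 36)
  s <- subsample_reads(r, 5000, seed = 37)
  cl <- cluster_reads(s)
  rc <- build_representative_contig(cl, s, cl$cluster_id[1]) # largest = element
  cons <- g$consensus[["gypsyL"]]
  hits <- local_align(rc$sequence, cons, 0.8, 0, min_hit_len = 100)
  # the contig matches the planted consensus at >=80% identity over >=80%
  # of its own length (union of hit intervals: an assembly may represent
  # the element as a rotation, covering it in two blocks)
  o <- order(hits$q_start)
  covered <- sum(pmin(cummax(c(0, hits$q_end[o]))[-1], hits$q_end[o]) -
                   pmin(cummax(c(0, hits$q_end[o]))[-1], hits$q_start[o]))
  union_len <- local({
    st <- hits$q_start[o]; en <- hits$q_end[o]
    tot <- 0; cs <- st[1]; ce <- en[1]
    for (i in seq_along(st)[-1]) {
      if (st[i] > ce) { tot <- tot + ce - cs; cs <- st[i]; ce <- en[i] }
      else ce <- max(ce, en[i])
    }
    tot + ce - cs
  })
  expect_gt(union_len / nchar(rc$sequence), 0.8)
  expect_gt(min(hits$identity), 0.8)
})

test_that("a single-read cluster returns the read itself at depth 1", {
  x <- rand_dna(150, seed = 38)
  reads <- Biostrings::DNAStringSet(c(r1 = x))
  cl <- cluster_reads(reads, min_cluster_size = 1)
  rc <- build_representative_contig(cl, reads, cl$cluster_id[1])
  expect_identical(rc$sequence, x)
  expect_equal(rc$mean_read_depth, 1)
})
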