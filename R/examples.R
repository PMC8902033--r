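#' Standard synthetic study conditions
#'
#' Constructs the package's reference synthetic genome specs, used in the
#' documentation, the test suite and the acceptance script.
#'
#' `layout = "recovery"` is a 2-Mb genome (4 x 500 kb chromosomes) built
#' for copy-number parameter recovery: a 140-bp centromeric-style satellite
#' x1000 in a single locus, a 5-kb dispersed LTR-like element x100, an
#' rDNA-like 3-kb tandem unit x50, and telomeric arrays (3200 motif copies
#' over all chromosome ends), all at 5% per-copy divergence except the
#' telomere (0, telomerase-uniform). About 41% of the genome is repetitive,
#' comparable to a repeat-rich plant genome surveyed at low pass.
#'
#' `layout = "distribution"` uses the same family kinds but tandem loci
#' small enough (under 1% of the genome each) that the quantitative
#' dispersed/non-dispersed rule is meaningful: satellite x100, rDNA x5,
#' telomeres, plus a x50 scattered element.
#'
#' @param seed Integer seed for the genome build.
#' @param layout `"recovery"` or `"distribution"`.
#' @return A [genome_spec()]. Family consensus sequences are drawn
#'   deterministically from the seed.
#' @export
example_genome_spec <- function(seed = 1L,
                                layout = c("recovery", "distribution")) {
  layout <- match.arg(layout)
  set.seed(seed * 1009L + 271L)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  sat <- rand(140)
  rdna <- rand(3000)
  chroms <- c(chr1 = 5e5, chr2 = 5e5, chr3 = 5e5, chr4 = 5e5)
  fams <- if (layout == "recovery") list(
    repeat_family("satCEN", "tandem_satellite", monomer = sat,
                  copy_number = 1000, divergence = 0.05,
                  chromosomes = "chr1"),
    repeat_family("rdnaU", "rdna_array", monomer = rdna, copy_number = 50,
                  divergence = 0.05, chromosomes = "chr2"),
    repeat_family("teloA", "telomeric_array", copy_number = 3200),
    repeat_family("gypsyL", "dispersed_element", copy_number = 100,
                  divergence = 0.05)
  ) else list(
    repeat_family("satCEN", "tandem_satellite", monomer = sat,
                  copy_number = 100, divergence = 0.05,
                  chromosomes = "chr1"),
    repeat_family("rdnaU", "rdna_array", monomer = rdna, copy_number = 5,
                  divergence = 0.05, chromosomes = "chr2"),
    repeat_family("teloA", "telomeric_array", copy_number = 1600),
    repeat_family("gypsyL", "dispersed_element", copy_number = 50,
                  divergence = 0.05)
  )
  genome_spec(chroms, fams, seed = seed)
}

#' Query contigs matching [example_genome_spec()] families
#'
#' The planted consensus sequences in query form: the satellite monomer,
#' the rDNA unit, the full dispersed element, and a 20-unit telomere motif
#' array (telomere queries must exceed the seed k-mer length, so the bare
#' 7-bp motif is concatenated).
#'
#' @param genome A `synthetic_genome` built from [example_genome_spec()].
#' @return Named character vector of query sequences.
#' @export
example_query_contigs <- function(genome) {
  c(satCEN = unname(genome$consensus["satCEN"]),
    rdnaU = unname(genome$consensus["rdnaU"]),
    gypsyL = unname(genome$consensus["gypsyL"]),
    teloA = paste(rep("TTTAGGG", 20), collapse = ""))
}

#' Synthetic accession panel for comparative presence/absence typing
#'
#' Builds a panel of five accessions -- an outgroup, the reference the
#' repeat was discovered in, and three ingroup accessions -- as small
#' genomes (200 kb) in which a centromeric-style satellite family is
#' planted (150 copies) or absent according to the requested pattern, with
#' a 1x read set simulated per accession:
#' `"type1"` plants it everywhere; `"type2"` everywhere except the
#' outgroup; `"type3"` in the reference, outgroup and two of three ingroup
#' accessions; `"type4"` only in the reference.
#'
#' @param pattern `"type1"`, `"type2"`, `"type3"` or `"type4"`.
#' @param seed Integer seed.
#' @return List with `samples` (named list of 1x `read_set`s), `contig`
#'   (the satellite monomer query), `reference`, `outgroup`, and
#'   `planted` (named logical).
#' @export
example_comparative_panel <- function(pattern = c("type1", "type2",
                                                  "type3", "type4"),
                                      seed = 1L) {
  pattern <- match.arg(pattern)
  set.seed(seed * 3331L + 17L)
  sat <- paste(sample(c("A", "C", "G", "T"), 140, TRUE), collapse = "")
  samples <- c("outgroup", "reference", "ingroup1", "ingroup2", "ingroup3")
  planted <- switch(pattern,
    type1 = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    type2 = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    type3 = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    type4 = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  names(planted) <- samples
  read_sets <- list()
  for (i in seq_along(samples)) {
    fams <- list()
    if (planted[i])
      fams <- list(repeat_family(
        "satX", "tandem_satellite", monomer = sat, copy_number = 150,
        divergence = 0.05))
    fams <- c(fams, list(repeat_family(
      "filler", "dispersed_element", monomer_length = 1000,
      copy_number = 10, divergence = 0.05)))
    sp <- genome_spec(c(c1 = 1e5, c2 = 1e5), fams,
                      seed = seed * 100L + i)
    read_sets[[samples[i]]] <- simulate_reads(build_genome(sp), 1.0,
                                              seed = seed * 200L + i)
  }
  list(samples = read_sets, contig = c(satX = sat),
       reference = "reference", outgroup = "outgroup", planted = planted)
}
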