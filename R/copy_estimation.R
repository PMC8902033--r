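#' Ungapped seeded local alignment with identity/coverage filters
#'
#' Finds local alignments of `query` against `target` on both strands.
#' Because the simulators in this package mutate by substitution only, the
#' model is ungapped: each hit is the maximum-scoring run (match +1,
#' mismatch -2) on one diagonal, found by exact shared-k-mer seeding.
#' Hits are kept when `identity > min_identity` and aligned query fraction
#' `> min_coverage` (both strict), and sorted by target position. On small
#' instances the hit set equals that of an exhaustive all-diagonals scan;
#' the seeding is an acceleration, not a change of definition.
#'
#' @param query,target DNA strings.
#' @param min_identity Strict identity lower bound (default 0.7).
#' @param min_coverage Strict lower bound on aligned query length / query
#'   length (default 0.7).
#' @param min_hit_len Minimum hit length in bp (default 30), suppressing
#'   chance micro-matches.
#' @param seed_k Seed k-mer length (default 12; internal acceleration
#'   parameter).
#' @return Tibble of hits: `q_start`, `q_end`, `t_start`, `t_end` (0-based
#'   half-open; query coordinates on the original strand), `length`,
#'   `matches`, `identity`, `strand`.
#' @export
local_align <- function(query, target, min_identity = 0.7,
                        min_coverage = 0.7, min_hit_len = 30L,
                        seed_k = 12L) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  tibble::as_tibble(cpp_local_align(query, target, min_identity,
                                    min_coverage, as.integer(min_hit_len),
                                    as.integer(seed_k)))
}

#' Copy number of a contig from a genome assembly
#'
#' Aligns the contig to every assembly sequence and computes
#' `copies = total aligned length / contig length`, where the total aligned
#' length sums the aligned query length of every hit passing the strict
#' identity/coverage filters. By default overlapping hits are *not* merged
#' (each counts in full); `merge_overlaps = TRUE` instead takes the union
#' of target-side intervals, the meaningful semantics for highly periodic
#' contigs whose shifted self-matches would otherwise multiply-count.
#'
#' @param contig Contig sequence (character), optionally named.
#' @param assembly Named [Biostrings::DNAStringSet] (or character vector)
#'   of assembly sequences, or a `synthetic_genome`.
#' @param min_identity,min_coverage Strict hit filters (defaults 0.7/0.7).
#' @param merge_overlaps Use target-interval-union semantics
#'   (default FALSE).
#' @param contig_id Identifier recorded in the estimate.
#' @return A `copy_estimate` tibble row: `contig_id`, `method`,
#'   `total_aligned_length`, `contig_length`, `copies`, `min_identity`,
#'   `min_coverage`, `merged`. The hit table is attached as attribute
#'   `"hits"` (with a `chrom` column).
#' @export
assembly_copy_number <- function(contig, assembly, min_identity = 0.7,
                                 min_coverage = 0.7, merge_overlaps = FALSE,
                                 contig_id = NULL) {
  if (is.null(contig_id))
    contig_id <- if (!is.null(names(contig))) names(contig)[1] else "contig"
  contig <- unname(contig)
  stopifnot(nchar(contig) > 0)
  if (inherits(assembly, "synthetic_genome")) assembly <- assembly$sequences
  if (inherits(assembly, "DNAStringSet")) assembly <- as.character(assembly)
  if (is.null(names(assembly)))
    names(assembly) <- paste0("seq", seq_along(assembly))

  hit_list <- purrr::map(names(assembly), function(ch) {
    h <- local_align(contig, assembly[[ch]], min_identity, min_coverage)
    if (nrow(h) > 0) dplyr::mutate(h, chrom = ch, .before = 1) else NULL
  })
  hits <- dplyr::bind_rows(hit_list)
  total <- if (nrow(hits) == 0) 0L else if (merge_overlaps) {
    sum(vapply(split(hits, hits$chrom), function(h)
      interval_union_length(h$t_start, h$t_end), 0))
  } else sum(hits$length)
  est <- tibble::tibble(
    contig_id = contig_id, method = "assembly",
    total_aligned_length = as.integer(total),
    contig_length = nchar(contig),
    copies = total / nchar(contig),
    min_identity = min_identity, min_coverage = min_coverage,
    merged = merge_overlaps)
  attr(est, "hits") <- hits
  class(est) <- c("copy_estimate", class(est))
  est
}

# total length of the union of 0-based half-open intervals
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > ce) { total <- total + (ce - cs); cs <- start[i]; ce <- end[i] }
    else ce <- max(ce, end[i])
  }
  total + (ce - cs)
}

#' Copy number of a contig from a 1x read sample
#'
#' Maps every read of a 1x-coverage sample to the contig and computes
#' `copies = total aligned length / contig length`. Per hit, identity must
#' exceed `min_identity`; per read, the union of its identity-passing
#' aligned intervals must cover more than `min_coverage` of the read (the
#' read-level coverage rule, so that reads wrapping a tandem monomer
#' boundary -- which split into two diagonal pieces -- are kept). Passing
#' reads contribute the summed length of their hits, or the union length
#' when `merge_overlaps = TRUE` (recommended for contigs whose periodicity
#' is much shorter than the read length).
#'
#' @param contig Contig sequence (character), optionally named.
#' @param reads A `read_set` subsampled to 1x of the genome of interest
#'   (or a DNAStringSet).
#' @param min_identity,min_coverage Strict filters (defaults 0.7/0.7).
#' @param merge_overlaps Per-read union semantics (default FALSE).
#' @param min_hit_len Minimum per-hit length (default 20 bp, just above the
#'   seed k-mer size so every seedable piece of a monomer-wrapping read is
#'   counted).
#' @param contig_id Identifier recorded in the estimate.
#' @return A `copy_estimate` tibble row (`method = "read_1x"`), with the
#'   per-hit table attached as attribute `"hits"`.
#' @export
read_copy_number <- function(contig, reads, min_identity = 0.7,
                             min_coverage = 0.7, merge_overlaps = FALSE,
                             min_hit_len = 20L, contig_id = NULL) {
  if (is.null(contig_id))
    contig_id <- if (!is.null(names(contig))) names(contig)[1] else "contig"
  contig <- unname(contig)
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  empty <- length(seqs) == 0
  hits <- if (empty) NULL else
    tibble::as_tibble(cpp_map_reads(as.character(seqs), contig,
                                    min_identity, as.integer(min_hit_len),
                                    12L))
  total <- 0
  kept <- NULL
  if (!empty && nrow(hits) > 0) {
    rl <- Biostrings::width(seqs)[hits$read]
    m <- nchar(contig)
    # under union semantics each identity-passing hit is extended to its
    # full diagonal span inside the contig: aligned-length columns include
    # the end mismatches that the run scoring trims, exactly as a gapless
    # alignment over the whole overlap would count them; the extension can
    # never reach past the contig, so partially overlapping reads are not
    # inflated
    eqs <- ifelse(hits$strand == "+",
                  hits$q_start - pmin(hits$q_start, hits$t_start),
                  hits$q_start - pmin(hits$q_start, m - hits$t_end))
    eqe <- ifelse(hits$strand == "+",
                  hits$q_end + pmin(rl - hits$q_end, m - hits$t_end),
                  hits$q_end + pmin(rl - hits$q_end, hits$t_start))
    per_read <- hits |>
      dplyr::mutate(read_len = rl, eqs = eqs, eqe = eqe) |>
      dplyr::group_by(.data$read) |>
      dplyr::summarise(
        union_len = interval_union_length(.data$q_start, .data$q_end),
        union_ext = interval_union_length(.data$eqs, .data$eqe),
        sum_len = sum(.data$length),
        read_len = .data$read_len[1], .groups = "drop") |>
      dplyr::filter(.data$union_len / .data$read_len > min_coverage)
    total <- if (merge_overlaps) sum(per_read$union_ext) else
      sum(per_read$sum_len)
    kept <- hits[hits$read %in% per_read$read, , drop = FALSE]
  }
  est <- tibble::tibble(
    contig_id = contig_id, method = "read_1x",
    total_aligned_length = as.integer(total),
    contig_length = nchar(contig),
    copies = total / nchar(contig),
    min_identity = min_identity, min_coverage = min_coverage,
    merged = merge_overlaps)
  attr(est, "hits") <- kept
  class(est) <- c("copy_estimate", class(est))
  est
}

#' Read/assembly copy-number fold change
#'
#' The ratio of read-based to assembly-based copy number for one contig;
#' values above 1 indicate copies under-represented (collapsed) in the
#' assembly. Reports round it to one decimal. When the assembly estimate is
#' zero the contig is flagged absent from the assembly and `NA` is
#' returned.
#'
#' @param read_est,assembly_est `copy_estimate` rows (or bare copy
#'   numbers).
#' @return The fold change (numeric); `NA` with attribute
#'   `absent_from_assembly = TRUE` when assembly copies are 0.
#' @export
fold_change <- function(read_est, assembly_est) {
  rc <- if (inherits(read_est, "data.frame")) read_est$copies else read_est
  ac <- if (inherits(assembly_est, "data.frame")) assembly_est$copies
        else assembly_est
  if (inherits(read_est, "data.frame") &&
      inherits(assembly_est, "data.frame") &&
      !identical(read_est$contig_id, assembly_est$contig_id))
    stop("fold_change requires estimates for the same contig")
  if (ac == 0) {
    out <- NA_real_
    attr(out, "absent_from_assembly") <- TRUE
    return(out)
  }
  rc / ac
}

#' Copy-count selection threshold for a karyotype
#'
#' The minimum total copy number corresponding to an average of
#' `copies_per_chromosome` copies on each chromosome, used to select
#' abundant repeats for distribution analysis (e.g. 320 for 80 chromosomes,
#' 256 for 64).
#'
#' @param n_chromosomes Chromosome count of the accession.
#' @param copies_per_chromosome Average copies per chromosome (default 4).
#' @return The selection threshold (numeric).
#' @export
selection_threshold <- function(n_chromosomes, copies_per_chromosome = 4) {
  stopifnot(n_chromosomes > 0, copies_per_chromosome > 0)
  n_chromosomes * copies_per_chromosome
}

#' Export alignment hits in BLAST outfmt-6 column order
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore. Coordinates are converted to
#' 1-based inclusive as in BLAST tabular output; gapopen is always 0
#' (ungapped model) and evalue/bitscore are placeholders (0, hit length).
#'
#' @param hits Hit tibble from [local_align()] or a `copy_estimate`'s
#'   `"hits"` attribute (needs a `chrom` or `read` column for sseqid/qseqid
#'   as appropriate; otherwise `"target"` is used).
#' @param query_id Query identifier.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_hits_outfmt6 <- function(hits, query_id, path) {
  sseqid <- if ("chrom" %in% names(hits)) hits$chrom else "target"
  out <- data.frame(
    qseqid = query_id, sseqid = sseqid,
    pident = round(hits$identity * 100, 3), length = hits$length,
    mismatch = hits$length - hits$matches, gapopen = 0L,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(hits$strand == "+", hits$t_start + 1L, hits$t_end),
    send = ifelse(hits$strand == "+", hits$t_end, hits$t_start + 1L),
    evalue = 0, bitscore = hits$length)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
tidy.copy_estimate <- function(x, ...) {
  h <- attr(x, "hits")
  if (is.null(h)) tibble::tibble() else tibble::as_tibble(h)
}

#' @export
glance.copy_estimate <- function(x, ...) tibble::as_tibble(unclass(x))
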