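#' Number of reads giving 1x genome coverage
#'
#' @param genome_size Genome size in bp.
#' @param read_length Read length in bp (default 150).
#' @return `round(genome_size / read_length)` as a double (may exceed
#'   integer range for multi-Gb genomes).
#' @examples
#' reads_for_1x(6.7e9, 150) # ~45 million, a typical 1x budget for a 6.7-Gb genome
#' @export
reads_for_1x <- function(genome_size, read_length = 150) {
  stopifnot(genome_size > 0, read_length > 0)
  round(genome_size / read_length)
}

#' Simulate fixed-length shotgun reads
#'
#' Draws `round(coverage * genome_size / read_length)` single-end reads with
#' uniform start positions (chromosomes chosen proportionally to length),
#' uniform strand, and i.i.d. per-base substitution errors. True origins are
#' retained for oracle tests and, unless suppressed, encoded in the read ids
#' as `chrom:start:strand:serial`.
#'
#' @param genome A `synthetic_genome` or named [Biostrings::DNAStringSet].
#' @param coverage Mean per-base depth requested.
#' @param read_length Read length (default 150 bp).
#' @param error_rate Per-base substitution error rate (default 0.001,
#'   matching high-quality filtered short reads).
#' @param seed Integer seed; simulation is deterministic given it.
#' @param encode_origin If `FALSE`, read ids are opaque serials, proving no
#'   downstream stage depends on origin metadata.
#' @return A `read_set`: list with `reads` (named DNAStringSet), `origins`
#'   (tibble: read_id, chrom, start, strand), `read_length`,
#'   `source_genome_size`.
#' @export
simulate_reads <- function(genome, coverage, read_length = 150L,
                           error_rate = 0.001, seed = 1L,
                           encode_origin = TRUE) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$sequences
          else genome
  stopifnot(inherits(seqs, "DNAStringSet"), coverage >= 0,
            error_rate >= 0, error_rate < 1)
  lens <- Biostrings::width(seqs)
  names(lens) <- names(seqs)
  if (any(lens < read_length) && coverage > 0)
    stop("chromosome(s) shorter than read_length: ",
         paste(names(lens)[lens < read_length], collapse = ", "))
  gsize <- sum(lens)
  n <- round(coverage * gsize / read_length)
  if (n == 0) {
    return(structure(list(
      reads = Biostrings::DNAStringSet(),
      origins = tibble::tibble(read_id = character(0), chrom = character(0),
                               start = integer(0), strand = character(0)),
      read_length = as.integer(read_length),
      source_genome_size = gsize), class = "read_set"))
  }
  set.seed(seed)
  chrom_idx <- sample.int(length(lens), n, replace = TRUE, prob = lens)
  starts <- integer(n)
  for (i in seq_along(lens)) {
    sel <- chrom_idx == i
    if (any(sel))
      starts[sel] <- sample.int(lens[i] - read_length + 1L, sum(sel),
                                replace = TRUE) - 1L
  }
  strands <- ifelse(stats::runif(n) < 0.5, "+", "-")

  # extract by chromosome for speed
  out <- character(n)
  for (i in seq_along(lens)) {
    sel <- which(chrom_idx == i)
    if (length(sel) == 0) next
    s <- as.character(seqs[[i]])
    out[sel] <- substring(s, starts[sel] + 1L, starts[sel] + read_length)
  }
  minus <- which(strands == "-")
  if (length(minus) > 0)
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))

  if (error_rate > 0) {
    n_err <- stats::rbinom(n, read_length, error_rate)
    bad <- which(n_err > 0)
    bases <- c("A", "C", "G", "T")
    for (i in bad) {
      chars <- strsplit(out[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(read_length, n_err[i])
      for (p in pos) {
        alt <- bases[bases != chars[p]]
        chars[p] <- alt[sample.int(3L, 1L)]
      }
      out[i] <- paste(chars, collapse = "")
    }
  }

  ids <- if (encode_origin)
    sprintf("%s:%d:%s:%06d", names(lens)[chrom_idx], starts, strands,
            seq_len(n))
  else sprintf("read%06d", seq_len(n))
  reads <- Biostrings::DNAStringSet(out)
  names(reads) <- ids
  structure(list(
    reads = reads,
    origins = tibble::tibble(read_id = ids, chrom = names(lens)[chrom_idx],
                             start = starts, strand = strands),
    read_length = as.integer(read_length),
    source_genome_size = gsize), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set> ", length(x$reads), " reads x ", x$read_length,
      " bp (source genome ", x$source_genome_size, " bp)\n", sep = "")
  invisible(x)
}

#' Subsample a read set without replacement
#'
#' @param reads A `read_set`.
#' @param n Number of reads to keep (`n <= length(reads$reads)`).
#' @param seed Integer seed.
#' @return A `read_set` with `n` uniformly chosen reads.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  stopifnot(inherits(reads, "read_set"))
  total <- length(reads$reads)
  if (n > total)
    stop("cannot subsample ", n, " reads from ", total)
  set.seed(seed)
  keep <- sort(sample.int(total, n))
  out <- reads
  out$reads <- reads$reads[keep]
  out$origins <- reads$origins[keep, , drop = FALSE]
  out
}

#' Write reads as FASTQ (constant Q30 qualities) or FASTA
#'
#' @param reads A `read_set`.
#' @param path Output path.
#' @param format `"fastq"` or `"fasta"`.
#' @return Invisibly, `path`.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "fastq") {
    quals <- Biostrings::BStringSet(
      rep(paste(rep("?", reads$read_length), collapse = ""),
          length(reads$reads)))
    Biostrings::writeXStringSet(reads$reads, path, format = "fastq",
                                qualities = quals)
  } else {
    Biostrings::writeXStringSet(reads$reads, path, width = 60L)
  }
  invisible(path)
}

#' Read a FASTQ/FASTA file into a read_set
#'
#' Origins are reconstructed from ids of the form `chrom:start:strand:serial`
#' when present, otherwise left as `NA`.
#'
#' @param path Input path.
#' @param format `"fastq"` or `"fasta"`.
#' @param source_genome_size Genome size the reads were drawn from (needed
#'   by 1x copy estimators when subsampling).
#' @return A `read_set`.
#' @export
read_reads <- function(path, format = c("fastq", "fasta"),
                       source_genome_size = NA_real_) {
  format <- match.arg(format)
  reads <- Biostrings::readDNAStringSet(path, format = format)
  ids <- names(reads)
  parts <- stringr::str_match(ids, "^(.+):(\\d+):([+-]):\\d+$")
  origins <- tibble::tibble(
    read_id = ids,
    chrom = parts[, 2],
    start = suppressWarnings(as.integer(parts[, 3])),
    strand = parts[, 4])
  structure(list(reads = reads, origins = origins,
                 read_length = max(Biostrings::width(reads)),
                 source_genome_size = source_genome_size),
            class = "read_set")
}
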