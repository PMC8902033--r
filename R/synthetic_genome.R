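#' Specify a planted repeat family
#'
#' Describes one repeat family to plant in a synthetic genome: its kind
#' (tandem satellite, rDNA-like tandem unit, telomeric array, or dispersed
#' LTR-like element), consensus sequence, copy number, per-copy divergence
#' and placement rule. Tandem kinds place copies head-to-tail within each
#' designated locus; dispersed elements are scattered at non-overlapping
#' random positions, on either strand with probability 1/2.
#'
#' @param name Family identifier (unique within a genome spec).
#' @param kind One of `"tandem_satellite"`, `"dispersed_element"`,
#'   `"rdna_array"`, `"telomeric_array"`.
#' @param monomer Consensus monomer/element sequence (character). If `NULL`,
#'   a random sequence of `monomer_length` bases is drawn when the genome is
#'   built. For `telomeric_array` the default is the plant telomere motif
#'   `TTTAGGG`.
#' @param monomer_length Length of the random consensus drawn when `monomer`
#'   is `NULL`. Defaults by kind: satellite 140 bp, rDNA unit 3000 bp,
#'   telomere motif 7 bp, dispersed element 5000 bp (with `ltr_length`
#'   terminal repeats).
#' @param copy_number Total planted copies across all loci (monomer copies
#'   for tandem kinds, element copies for dispersed kinds).
#' @param divergence Expected per-base substitution rate applied
#'   independently to each copy, in \[0, 0.5\]. Defaults to 0.05 except for
#'   telomeric arrays, which default to 0 (telomerase-synthesized units are
#'   essentially identical).
#' @param placement One of `"single_locus"`, `"per_chromosome_locus"`,
#'   `"terminal"`, `"uniform_scatter"`. Telomeric arrays must be terminal;
#'   dispersed elements must use `"uniform_scatter"`.
#' @param chromosomes Chromosome identifiers the family may occupy
#'   (`NULL` = all).
#' @param locus_start Optional explicit 0-based start position(s) for tandem
#'   loci (one per locus), mainly for constructing colocalized families in
#'   tests.
#' @param ltr_length Terminal-repeat length for randomly drawn dispersed
#'   elements (default 300 bp; the element then has identical terminal
#'   repeats flanking a random body).
#' @return A `repeat_family` object (list).
#' @export
repeat_family <- function(name, kind, monomer = NULL, monomer_length = NULL,
                          copy_number = 1, divergence = NULL,
                          placement = NULL, chromosomes = NULL,
                          locus_start = NULL, ltr_length = 300) {
  kinds <- c("tandem_satellite", "dispersed_element", "rdna_array",
             "telomeric_array")
  kind <- match.arg(kind, kinds)
  if (is.null(placement)) {
    placement <- switch(kind,
      tandem_satellite = "single_locus",
      dispersed_element = "uniform_scatter",
      rdna_array = "single_locus",
      telomeric_array = "terminal")
  }
  placement <- match.arg(placement, c("single_locus", "per_chromosome_locus",
                                      "terminal", "uniform_scatter"))
  if (kind == "telomeric_array" && placement != "terminal")
    stop("telomeric_array placement must be 'terminal'")
  if (kind == "dispersed_element" && placement != "uniform_scatter")
    stop("dispersed_element placement must be 'uniform_scatter'")
  if (kind != "dispersed_element" && placement == "uniform_scatter")
    stop("tandem kinds require a locus-based or terminal placement")
  if (is.null(divergence))
    divergence <- if (kind == "telomeric_array") 0 else 0.05
  stopifnot(copy_number >= 1, divergence >= 0, divergence <= 0.5)
  if (is.null(monomer) && kind == "telomeric_array") monomer <- "TTTAGGG"
  if (is.null(monomer) && is.null(monomer_length)) {
    monomer_length <- switch(kind,
      tandem_satellite = 140L,
      rdna_array = 3000L,
      dispersed_element = 5000L)
  }
  structure(list(name = as.character(name), kind = kind, monomer = monomer,
                 monomer_length = monomer_length,
                 copy_number = as.integer(copy_number),
                 divergence = divergence, placement = placement,
                 chromosomes = chromosomes, locus_start = locus_start,
                 ltr_length = as.integer(ltr_length)),
            class = "repeat_family")
}

#' Specify a synthetic genome
#'
#' @param chromosome_lengths Named numeric vector of chromosome lengths (bp).
#' @param families List of [repeat_family()] specs.
#' @param background_gc GC fraction of the i.i.d. random background
#'   (default 0.44, a typical grass-genome value).
#' @param seed Integer seed; the build is fully deterministic given the spec.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(chromosome_lengths, families = list(),
                        background_gc = 0.44, seed = 1L) {
  stopifnot(length(chromosome_lengths) >= 1, all(chromosome_lengths > 0),
            background_gc >= 0, background_gc <= 1)
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  if (anyDuplicated(names(chromosome_lengths)))
    stop("chromosome identifiers must be unique")
  if (inherits(families, "repeat_family")) families <- list(families)
  structure(list(chromosome_lengths = chromosome_lengths,
                 families = families, background_gc = background_gc,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Mutate a sequence by random substitutions
#'
#' Applies i.i.d. per-base substitutions at the given rate; each selected
#' base is replaced by one of the three alternatives uniformly, so the
#' expected Hamming distance equals `divergence * nchar(template)`. Length is
#' preserved exactly (no indels). Uses the current RNG state.
#'
#' @param template DNA string.
#' @param divergence Substitution probability per base, in \[0, 0.5\].
#' @return Mutated DNA string of identical length.
#' @export
mutate_copy <- function(template, divergence) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  n <- nchar(template)
  if (divergence == 0 || n == 0) return(template)
  hit <- which(stats::runif(n) < divergence)
  if (length(hit) == 0) return(template)
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    alt <- bases[bases != chars[i]]
    chars[i] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

# Draw non-overlapping intervals of length `len` by rejection sampling
# against already-occupied intervals on one chromosome.
place_scattered <- function(n, len, chrom_len, occupied, max_tries = 10000L) {
  starts <- integer(0)
  occ <- occupied
  tries <- 0L
  while (length(starts) < n && tries < max_tries) {
    tries <- tries + 1L
    s <- sample.int(chrom_len - len + 1L, 1L) - 1L
    e <- s + len
    if (nrow(occ) == 0 || all(e <= occ$start | s >= occ$end)) {
      starts <- c(starts, s)
      occ <- rbind(occ, data.frame(start = s, end = e))
    }
  }
  if (length(starts) < n)
    stop("could not place ", n, " non-overlapping copies of length ", len,
         " (chromosome too full)")
  list(starts = starts, occupied = occ)
}

#' Build a synthetic genome with planted repeats
#'
#' Generates i.i.d. random background sequence for each chromosome and
#' plants every family of the spec, recording each planted copy in a
#' ground-truth interval table (0-based half-open, BED-compatible). Tandem
#' copies are laid head-to-tail on the forward strand within their loci;
#' dispersed copies land at non-overlapping positions on a random strand.
#' Deterministic for a fixed spec (including its seed).
#'
#' @param spec A [genome_spec()].
#' @return A `synthetic_genome` object: list with `sequences`
#'   (named [Biostrings::DNAStringSet]), `truth` (tibble: chrom, start, end,
#'   family, copy_index, strand, kind, locus), `consensus` (named character
#'   vector of realized family consensus sequences) and `spec`.
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  lens <- as.integer(spec$chromosome_lengths)
  names(lens) <- names(spec$chromosome_lengths)

  # realize consensus sequences first so they are seed-stable
  consensus <- character(0)
  fams <- spec$families
  for (f in fams) {
    if (is.null(f$monomer)) {
      if (f$kind == "dispersed_element") {
        # terminal repeats scale down for short elements so the element
        # length equals monomer_length exactly
        ltr_len <- if (2L * f$ltr_length + 50L <= f$monomer_length)
          f$ltr_length else max(0L, f$monomer_length %/% 5L)
        if (ltr_len < 20L) ltr_len <- 0L
        ltr <- random_dna(ltr_len, 0.5)
        body <- random_dna(f$monomer_length - 2L * ltr_len, 0.5)
        consensus[f$name] <- paste0(ltr, body, ltr)
      } else {
        consensus[f$name] <- random_dna(f$monomer_length, 0.5)
      }
    } else {
      consensus[f$name] <- toupper(f$monomer)
    }
  }

  # plan placements per chromosome
  plan <- list() # rows: chrom, start, len, family, copy_index, strand, locus
  occupied <- stats::setNames(
    lapply(lens, function(x) data.frame(start = integer(0), end = integer(0))),
    names(lens))

  for (f in fams) {
    mono <- consensus[f$name]
    mlen <- nchar(mono)
    chroms <- if (is.null(f$chromosomes)) names(lens) else f$chromosomes
    if (!all(chroms %in% names(lens)))
      stop("family ", f$name, " references unknown chromosomes")
    if (f$kind == "dispersed_element") {
      counts <- tabulate(
        sample(seq_along(chroms), f$copy_number, replace = TRUE,
               prob = lens[chroms]),
        nbins = length(chroms))
      ci <- 0L
      for (ic in seq_along(chroms)) {
        ch <- chroms[ic]
        if (counts[ic] == 0) next
        pl <- place_scattered(counts[ic], mlen, lens[ch], occupied[[ch]])
        occupied[[ch]] <- pl$occupied
        for (s in pl$starts) {
          ci <- ci + 1L
          plan[[length(plan) + 1L]] <- data.frame(
            chrom = ch, start = s, len = mlen, family = f$name,
            copy_index = ci, strand = if (stats::runif(1) < 0.5) "+" else "-",
            locus = paste0(f$name, "_L", ci))
        }
      }
    } else {
      # tandem kinds: decide loci, then copies per locus
      loci <- list() # (chrom, start or NA-for-terminal-end marker)
      if (f$placement == "single_locus") {
        ch <- if (length(chroms) == 1) chroms else
          sample(chroms, 1, prob = lens[chroms])
        loci[[1]] <- list(chrom = ch, start = NA, terminal = NA)
      } else if (f$placement == "per_chromosome_locus") {
        for (ch in chroms) loci[[length(loci) + 1L]] <-
            list(chrom = ch, start = NA, terminal = NA)
      } else { # terminal: one locus at each end of each chromosome
        for (ch in chroms) {
          loci[[length(loci) + 1L]] <- list(chrom = ch, start = NA, terminal = "start")
          loci[[length(loci) + 1L]] <- list(chrom = ch, start = NA, terminal = "end")
        }
      }
      nl <- length(loci)
      per <- rep(f$copy_number %/% nl, nl)
      extra <- f$copy_number %% nl
      if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
      if (!is.null(f$locus_start)) {
        if (length(f$locus_start) != nl)
          stop("locus_start must have one entry per locus for family ", f$name)
      }
      for (il in seq_len(nl)) {
        if (per[il] == 0) next
        lc <- loci[[il]]
        span <- per[il] * mlen
        ch <- lc$chrom
        if (span >= lens[ch])
          stop("planted repeats exceed capacity of chromosome ", ch)
        if (!is.null(f$locus_start)) {
          s <- as.integer(f$locus_start[il])
        } else if (identical(lc$terminal, "start")) {
          s <- 0L
        } else if (identical(lc$terminal, "end")) {
          s <- lens[ch] - span
        } else {
          occ <- occupied[[ch]]
          s <- NULL
          for (try in seq_len(10000L)) {
            cand <- sample.int(lens[ch] - span + 1L, 1L) - 1L
            if (nrow(occ) == 0 ||
                all(cand + span <= occ$start | cand >= occ$end)) {
              s <- cand; break
            }
          }
          if (is.null(s))
            stop("could not place locus of family ", f$name,
                 " on chromosome ", ch)
        }
        if (s < 0 || s + span > lens[ch])
          stop("planted repeats exceed capacity of chromosome ", ch)
        occupied[[ch]] <- rbind(occupied[[ch]],
                                data.frame(start = s, end = s + span))
        base_index <- sum(per[seq_len(il - 1L)])
        for (ic in seq_len(per[il])) {
          plan[[length(plan) + 1L]] <- data.frame(
            chrom = ch, start = s + (ic - 1L) * mlen, len = mlen,
            family = f$name, copy_index = base_index + ic, strand = "+",
            locus = paste0(f$name, "_locus", il))
        }
      }
    }
  }

  truth <- if (length(plan) > 0) do.call(rbind, plan) else
    data.frame(chrom = character(0), start = integer(0), len = integer(0),
               family = character(0), copy_index = integer(0),
               strand = character(0), locus = character(0))

  # check non-overlap across all planted intervals per chromosome
  for (ch in names(lens)) {
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    if (nrow(tr) > 1) {
      tr <- tr[order(tr$start), ]
      if (any(tr$start[-1] < (tr$start + tr$len)[-nrow(tr)]))
        stop("internal error: overlapping planted intervals on ", ch)
    }
  }

  # assemble sequences: background then splice in mutated copies
  seqs <- character(length(lens))
  names(seqs) <- names(lens)
  kind_of <- stats::setNames(vapply(fams, function(f) f$kind, ""),
                             vapply(fams, function(f) f$name, ""))
  div_of <- stats::setNames(vapply(fams, function(f) f$divergence, 0),
                            vapply(fams, function(f) f$name, ""))
  for (ch in names(lens)) {
    bg <- random_dna(lens[ch], spec$background_gc)
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    if (nrow(tr) > 0) {
      tr <- tr[order(tr$start), ]
      pieces <- character(0)
      cursor <- 0L
      for (r in seq_len(nrow(tr))) {
        if (tr$start[r] > cursor)
          pieces <- c(pieces, substring(bg, cursor + 1L, tr$start[r]))
        cp <- mutate_copy(consensus[tr$family[r]], div_of[tr$family[r]])
        if (tr$strand[r] == "-")
          cp <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cp)))
        pieces <- c(pieces, cp)
        cursor <- tr$start[r] + tr$len[r]
      }
      if (cursor < lens[ch])
        pieces <- c(pieces, substring(bg, cursor + 1L, lens[ch]))
      seqs[ch] <- paste(pieces, collapse = "")
    } else {
      seqs[ch] <- bg
    }
    stopifnot(nchar(seqs[ch]) == lens[ch])
  }

  truth_tbl <- tibble::tibble(
    chrom = truth$chrom, start = as.integer(truth$start),
    end = as.integer(truth$start + truth$len), family = truth$family,
    copy_index = as.integer(truth$copy_index), strand = truth$strand,
    kind = unname(kind_of[truth$family]), locus = truth$locus)
  truth_tbl <- dplyr::arrange(truth_tbl, .data$chrom, .data$start)

  structure(list(sequences = Biostrings::DNAStringSet(seqs),
                 truth = truth_tbl, consensus = consensus, spec = spec),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> ", length(x$sequences), " chromosome(s), ",
      sum(Biostrings::width(x$sequences)), " bp; ",
      nrow(x$truth), " planted copies across ",
      length(unique(x$truth$family)), " family(ies)\n", sep = "")
  invisible(x)
}

#' Collapse tandem arrays in a synthetic genome
#'
#' Emulates assembly collapse of tandem repeats: for each named tandem
#' family, every locus retains its first `ceiling(copies / factor)`
#' consecutive copies and the remainder are excised, with flanking sequence
#' rejoined and all ground-truth coordinates remapped. Factor 1 is the
#' identity transform. Factors may only be applied to tandem kinds.
#'
#' @param genome A `synthetic_genome` from [build_genome()].
#' @param collapse_factors Named numeric vector, family name -> factor >= 1.
#' @return A new `synthetic_genome` representing the collapsed assembly.
#' @export
collapse_assembly <- function(genome, collapse_factors) {
  stopifnot(inherits(genome, "synthetic_genome"))
  if (length(collapse_factors) == 0) return(genome)
  if (is.null(names(collapse_factors)) || any(names(collapse_factors) == ""))
    stop("collapse_factors must be a named vector (family -> factor)")
  if (any(collapse_factors < 1))
    stop("collapse factors must be >= 1")
  truth <- genome$truth
  for (fam in names(collapse_factors)) {
    kinds <- unique(truth$kind[truth$family == fam])
    if (length(kinds) == 0)
      stop("unknown family in collapse_factors: ", fam)
    if (kinds == "dispersed_element")
      stop("collapse factors are unsupported for dispersed families (", fam, ")")
  }

  # deletion intervals per chromosome
  del <- truth[0, c("chrom", "start", "end")]
  keep_flag <- rep(TRUE, nrow(truth))
  for (fam in names(collapse_factors)) {
    f <- collapse_factors[[fam]]
    rows <- which(truth$family == fam)
    for (lc in unique(truth$locus[rows])) {
      lr <- rows[truth$locus[rows] == lc]
      lr <- lr[order(truth$start[lr])]
      n <- length(lr)
      keep_n <- as.integer(ceiling(n / f))
      if (keep_n < n) {
        drop_rows <- lr[(keep_n + 1L):n]
        keep_flag[drop_rows] <- FALSE
        del <- rbind(del, data.frame(
          chrom = truth$chrom[drop_rows[1]],
          start = min(truth$start[drop_rows]),
          end = max(truth$end[drop_rows])))
      }
    }
  }
  if (nrow(del) == 0) return(genome)

  seqs <- as.character(genome$sequences)
  new_truth <- truth[keep_flag, , drop = FALSE]
  for (ch in unique(del$chrom)) {
    dch <- del[del$chrom == ch, , drop = FALSE]
    dch <- dch[order(dch$start), , drop = FALSE]
    s <- seqs[[ch]]
    keep_pieces <- character(0)
    cursor <- 0L
    for (r in seq_len(nrow(dch))) {
      if (dch$start[r] > cursor)
        keep_pieces <- c(keep_pieces, substring(s, cursor + 1L, dch$start[r]))
      cursor <- dch$end[r]
    }
    keep_pieces <- c(keep_pieces, substring(s, cursor + 1L, nchar(s)))
    seqs[[ch]] <- paste(keep_pieces, collapse = "")
    # remap coordinates: shift by total deleted bp before each interval
    idx <- which(new_truth$chrom == ch)
    if (length(idx) > 0) {
      shift <- vapply(new_truth$start[idx], function(p)
        sum(pmin(dch$end, p) - pmin(dch$start, p)), 0)
      new_truth$start[idx] <- as.integer(new_truth$start[idx] - shift)
      new_truth$end[idx] <- as.integer(new_truth$end[idx] - shift)
    }
  }
  out <- genome
  out$sequences <- Biostrings::DNAStringSet(seqs)
  out$truth <- new_truth
  out
}

#' Write a synthetic genome as FASTA (and its truth as BED)
#'
#' FASTA is wrapped at 60 columns. The BED file has six columns:
#' chrom, start, end, name (`family:copy_index`), score (0), strand.
#'
#' @param genome A `synthetic_genome`.
#' @param fasta Path for the FASTA output.
#' @param bed Optional path for the ground-truth BED output.
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta, bed = NULL) {
  Biostrings::writeXStringSet(genome$sequences, fasta, width = 60L)
  if (!is.null(bed)) write_truth_bed(genome$truth, bed)
  invisible(c(fasta = fasta, bed = bed))
}

#' @rdname write_genome
#' @param truth Ground-truth tibble as in `synthetic_genome$truth`.
#' @param path Output path.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- data.frame(chrom = truth$chrom, start = truth$start,
                    end = truth$end,
                    name = paste0(truth$family, ":", truth$copy_index),
                    score = 0L, strand = truth$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
tidy.synthetic_genome <- function(x, ...) x$truth

#' @export
glance.synthetic_genome <- function(x, ...) {
  gsize <- sum(Biostrings::width(x$sequences))
  x$truth |>
    dplyr::group_by(.data$family, .data$kind) |>
    dplyr::summarise(copies = dplyr::n(),
                     total_bp = sum(.data$end - .data$start),
                     loci = length(unique(.data$locus)),
                     .groups = "drop") |>
    dplyr::mutate(genome_proportion = .data$total_bp / gsize)
}
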