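#' Detect tandem periodicity in a contig
#'
#' Self-comparison at every offset `p <= length/2`: the monomer length is
#' the smallest offset at which the contig agrees with itself shifted by
#' `p` at `min_identity` or better (an ungapped diagonal self-alignment
#' scan). Substitution-only copies preserve the period exactly.
#'
#' @param contig DNA string.
#' @param min_monomer Smallest offset considered (default 5 bp).
#' @param min_identity Identity required along the shifted overlap
#'   (default 0.8).
#' @return The monomer length, or `NULL` when no offset qualifies.
#' @export
detect_tandem_periodicity <- function(contig, min_monomer = 5L,
                                      min_identity = 0.8) {
  L <- nchar(contig)
  if (L < 2L * min_monomer) return(NULL)
  chars <- strsplit(toupper(contig), "", fixed = TRUE)[[1]]
  for (p in min_monomer:(L %/% 2L)) {
    a <- chars[1:(L - p)]
    b <- chars[(p + 1L):L]
    if (mean(a == b) >= min_identity) return(p)
  }
  NULL
}

#' Detect a terminal-repeat (LTR-like) structure
#'
#' Searches for a repeated sequence shared between the two ends of a
#' contig, as left by long-terminal-repeat retrotransposons. The first and
#' second halves are compared by ungapped local alignment; a qualifying hit
#' must be at least `min_len` long, reach `min_identity`, and sit near the
#' contig start and end (within `end_margin` or 20% of the length,
#' whichever is larger, so that ragged assembly ends are tolerated). Among
#' qualifying hits the score-maximal one (match +1 / mismatch -2) is
#' reported, which recovers the planted terminal-repeat length exactly
#' rather than drifting into flanking chance matches.
#'
#' @param contig DNA string.
#' @param min_len Minimum terminal-repeat length (default 100 bp).
#' @param min_identity Identity threshold (default 0.8).
#' @param end_margin Base tolerance for distance from the contig ends
#'   (default 200 bp).
#' @return The terminal-repeat length, or `NULL`.
#' @export
detect_terminal_repeat <- function(contig, min_len = 100L,
                                   min_identity = 0.8, end_margin = 200L) {
  L <- nchar(contig)
  if (L < 2L * min_len) return(NULL)
  half <- L %/% 2L
  first <- substring(contig, 1L, half)
  second <- substring(contig, half + 1L, L)
  hits <- cpp_local_align(first, second, min_identity, 0, as.integer(min_len), 12L)
  if (nrow(hits) == 0) return(NULL)
  margin <- max(end_margin, ceiling(0.2 * L))
  near_ends <- hits$strand == "+" &
    hits$q_start <= margin &
    (L - (half + hits$t_end)) <= margin
  hits <- hits[near_ends, , drop = FALSE]
  if (nrow(hits) == 0) return(NULL)
  score <- hits$matches - 2L * (hits$length - hits$matches)
  as.integer(hits$length[which.max(score)])
}

#' Match a contig against a reference repeat library
#'
#' Aligns the contig to every library entry (both strands, ungapped local
#' alignment) and reports the entry whose best hit maximizes
#' `coverage * identity` among those passing both thresholds, where
#' coverage is the aligned query length over the contig length.
#'
#' @param contig DNA string.
#' @param library Named character vector or [Biostrings::DNAStringSet] of
#'   library sequences.
#' @param min_identity Identity threshold (default 0.8).
#' @param min_coverage Contig-coverage threshold (default 0.5).
#' @return `NULL`, or a list with `entry_id`, `identity`, `coverage`.
#' @export
match_library <- function(contig, library, min_identity = 0.8,
                          min_coverage = 0.5) {
  if (length(library) == 0) stop("library is empty")
  if (inherits(library, "DNAStringSet")) library <- as.character(library)
  if (is.null(names(library)))
    names(library) <- paste0("entry", seq_along(library))
  L <- nchar(contig)
  best <- NULL
  for (id in names(library)) {
    hits <- cpp_local_align(contig, library[[id]], min_identity, 0, 20L, 12L)
    if (nrow(hits) == 0) next
    cov <- hits$length / L
    score <- cov * hits$identity
    i <- which.max(score)
    if (hits$identity[i] >= min_identity && cov[i] >= min_coverage) {
      if (is.null(best) || score[i] > best$score)
        best <- list(entry_id = id, identity = hits$identity[i],
                     coverage = cov[i], score = score[i])
    }
  }
  if (is.null(best)) return(NULL)
  best$score <- NULL
  best
}

# longest run of consecutive exact telomere-motif units on either strand,
# at any rotation of the motif
telomere_units <- function(contig, motif = "TTTAGGG") {
  count_units <- function(seq) {
    best <- 0L
    for (r in seq_len(nchar(motif))) {
      rot <- paste0(substring(motif, r, nchar(motif)),
                    substring(motif, 1, r - 1L))
      m <- gregexpr(paste0("(", rot, ")+"), seq)[[1]]
      if (m[1] != -1)
        best <- max(best, max(attr(m, "match.length")) %/% nchar(motif))
    }
    best
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  max(count_units(toupper(contig)), count_units(rc))
}

#' Classify a repeat contig
#'
#' Assigns one label per contig with the precedence: telomeric (at least
#' `min_telomere_units` consecutive exact `TTTAGGG` units on either strand)
#' > reference-library match > tandem periodicity (`Simple/Sat`) >
#' terminal-repeat structure (`LTR_like`) > `Unknown`. Periodicity outranks
#' terminal-repeat detection because tandem arrays trivially contain
#' prefix/suffix matches. Library matches whose entry id contains `rdna`
#' (case-insensitive) are labelled `rdna_like`, and `telo` entries
#' `telomeric`; other matches are `library_match`.
#'
#' @param contig DNA string.
#' @param library Optional reference library (see [match_library()]).
#' @param contig_id Identifier recorded in the output row.
#' @param min_identity,min_coverage Library-match thresholds.
#' @param min_telomere_units Minimum consecutive exact telomere units
#'   (default 10).
#' @return A one-row tibble: `contig_id`, `label`, `detail`,
#'   `match_identity`, `match_coverage`.
#' @export
classify_repeat <- function(contig, library = NULL, contig_id = "contig",
                            min_identity = 0.8, min_coverage = 0.5,
                            min_telomere_units = 10L) {
  row <- function(label, detail = NA_character_, id = NA_real_,
                  cov = NA_real_) {
    tibble::tibble(contig_id = contig_id, label = label, detail = detail,
                   match_identity = id, match_coverage = cov)
  }
  units <- telomere_units(contig)
  if (units >= min_telomere_units)
    return(row("telomeric", sprintf("%d consecutive TTTAGGG units", units),
               1.0, min(1, units * 7 / nchar(contig))))
  if (!is.null(library) && length(library) > 0) {
    m <- match_library(contig, library, min_identity, min_coverage)
    if (!is.null(m)) {
      label <- if (grepl("rdna", m$entry_id, ignore.case = TRUE)) "rdna_like"
        else if (grepl("telo", m$entry_id, ignore.case = TRUE)) "telomeric"
        else "library_match"
      return(row(label, m$entry_id, m$identity, m$coverage))
    }
  }
  p <- detect_tandem_periodicity(contig)
  if (!is.null(p))
    return(row("Simple/Sat", sprintf("monomer %d bp", p)))
  tr <- detect_terminal_repeat(contig)
  if (!is.null(tr))
    return(row("LTR_like", sprintf("terminal repeat %d bp", tr)))
  row("Unknown")
}

#' Classify several contigs at once
#'
#' @param contigs Named character vector of contig sequences.
#' @inheritParams classify_repeat
#' @return A tibble with one [classify_repeat()] row per contig.
#' @export
annotate_contigs <- function(contigs, library = NULL, min_identity = 0.8,
                             min_coverage = 0.5) {
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig", seq_along(contigs))
  purrr::map_dfr(names(contigs), function(id)
    classify_repeat(contigs[[id]], library, contig_id = id,
                    min_identity = min_identity,
                    min_coverage = min_coverage))
}

#' Load the small bundled reference library
#'
#' A synthetic fixture library shipped with the package: the plant telomere
#' motif as an array, a 140-bp satellite consensus, and a generic rDNA-unit
#' stand-in. All sequences are randomly generated stand-ins, not database
#' sequences.
#'
#' @return Named character vector of library sequences.
#' @export
bundled_library <- function() {
  path <- system.file("extdata", "repeat_library.fasta",
                      package = "repeatscape")
  lib <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(lib), names(lib))
}
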