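#' Shared-k-mer similarity between two reads
#'
#' Fraction of `a`'s distinct k-mers found in `b` or in the reverse
#' complement of `b`, whichever is larger. In \[0, 1\]; 1 for identical or
#' reverse-complementary sequences. This is the lightweight similarity
#' kernel used for exploratory comparison of read pairs; the clustering
#' graph itself uses an alignment-overlap edge rule (see [cluster_reads()]).
#'
#' @param a,b DNA strings.
#' @param k k-mer size (default 15); must not exceed the read length.
#' @return Shared-k-mer fraction.
#' @export
read_similarity <- function(a, b, k = 15L) {
  stopifnot(k <= nchar(a), k <= nchar(b), k <= 32)
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                         seq_len(nchar(a) - k + 1L) + k - 1L))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1L),
                         seq_len(nchar(b) - k + 1L) + k - 1L))
  brc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  kbrc <- unique(substring(brc, seq_len(nchar(brc) - k + 1L),
                           seq_len(nchar(brc) - k + 1L) + k - 1L))
  max(length(intersect(ka, kb)), length(intersect(ka, kbrc))) / length(ka)
}

#' Cluster reads into repeat families
#'
#' Builds a read-similarity graph and reports its connected components of at
#' least `min_cluster_size` reads as repeat clusters, with each cluster's
#' genome proportion estimated as its share of all sampled reads (singletons
#' and small components stay in the denominator). An edge joins two reads
#' when some ungapped local alignment between them (either orientation)
#' reaches `min_identity` over at least `similarity_threshold` of the
#' shorter read's length -- the classical "similarity over a length
#' fraction" edge criterion of graph-based repeat discovery. Candidate
#' pairs are restricted, losslessly, to pairs sharing at least one exact
#' canonical k-mer. Deterministic and seed-free.
#'
#' @param reads A `read_set` (or DNAStringSet).
#' @param similarity_threshold Minimum aligned fraction of the shorter read
#'   (default 0.55).
#' @param min_identity Minimum identity of the aligned run (default 0.8,
#'   tolerant of ~5% planted divergence on both reads).
#' @param min_cluster_size Smallest component reported as a cluster
#'   (default 10).
#' @param seed_k k-mer size of the candidate-pair index (default 11).
#' @param bucket_cap Ignore k-mers occurring in more than this many reads
#'   when enumerating candidate pairs (default 5000).
#' @return A `read_clusters` tibble: `cluster_id`, `size`,
#'   `genome_proportion`, `members` (list of read ids), ordered by
#'   descending size. Attributes: `total_reads`, `membership` (named
#'   integer, cluster per read; NA = unclustered), `degree` (named integer).
#' @export
cluster_reads <- function(reads, similarity_threshold = 0.55,
                          min_identity = 0.8, min_cluster_size = 10L,
                          seed_k = 11L, bucket_cap = 5000L) {
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  stopifnot(length(seqs) > 0)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  chr <- as.character(seqs)
  edges <- cpp_cluster_edges(chr, as.integer(seed_k), min_identity,
                             similarity_threshold, as.integer(bucket_cap))
  g <- igraph::make_empty_graph(n = length(chr), directed = FALSE)
  if (length(edges$from) > 0)
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  comp <- igraph::components(g)
  degree <- igraph::degree(g)
  names(degree) <- ids

  sizes <- comp$csize
  big <- which(sizes >= min_cluster_size)
  # stable ordering: by size desc, then by smallest member index
  first_member <- vapply(big, function(cc) min(which(comp$membership == cc)), 0)
  big <- big[order(-sizes[big], first_member)]

  membership <- rep(NA_integer_, length(chr))
  rows <- lapply(seq_along(big), function(i) {
    members <- which(comp$membership == big[i])
    membership[members] <<- i
    tibble::tibble(cluster_id = sprintf("CL%d", i),
                   size = length(members),
                   genome_proportion = length(members) / length(chr),
                   members = list(ids[members]))
  })
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(cluster_id = character(0), size = integer(0),
                   genome_proportion = numeric(0), members = list())
  names(membership) <- ids
  attr(out, "total_reads") <- length(chr)
  attr(out, "membership") <- membership
  attr(out, "degree") <- degree
  class(out) <- c("read_clusters", class(out))
  out
}

#' Filter clusters to the enriched fraction of the genome
#'
#' Keeps clusters whose genome proportion strictly exceeds `min_proportion`
#' (default 0.01% of sampled reads), ordered by descending proportion.
#'
#' @param clusters A `read_clusters` tibble.
#' @param min_proportion Strict lower bound on genome proportion
#'   (default 1e-4).
#' @return The filtered `read_clusters` tibble.
#' @export
enriched_clusters <- function(clusters, min_proportion = 1e-4) {
  out <- clusters[clusters$genome_proportion > min_proportion, , drop = FALSE]
  out[order(-out$genome_proportion), , drop = FALSE]
}

#' Build the representative contig of a read cluster
#'
#' Greedy overlap-layout consensus: the seed read is the cluster member with
#' the highest degree in the similarity graph; the contig is extended at
#' both ends by overlapping members (ungapped overlap of at least
#' `min_overlap` bases at `min_identity`), then polished by per-column
#' plurality vote over all members that align to it (ties broken by the
#' alphabetically first base). When leftover members assemble into further
#' contigs, the one with the highest mean read depth is returned (ties:
#' longer contig, then lexicographically smaller id).
#'
#' @param clusters A `read_clusters` tibble.
#' @param reads The `read_set` the clusters were built from.
#' @param cluster_id Cluster to assemble (default: first row).
#' @param min_overlap Minimum extension overlap in bp (default 40).
#' @param min_identity Minimum identity of overlaps (default 0.8).
#' @param max_length Hard cap on contig growth (default 20000 bp).
#' @return A `representative_contig`: list with `contig_id`, `sequence`,
#'   `mean_read_depth`, `source_cluster_id`, `n_reads_used`.
#' @export
build_representative_contig <- function(clusters, reads,
                                        cluster_id = NULL,
                                        min_overlap = 40L,
                                        min_identity = 0.8,
                                        max_length = 20000L) {
  stopifnot(inherits(clusters, "read_clusters"))
  if (is.null(cluster_id)) cluster_id <- clusters$cluster_id[1]
  row <- which(clusters$cluster_id == cluster_id)
  if (length(row) != 1) stop("unknown cluster_id: ", cluster_id)
  member_ids <- clusters$members[[row]]
  seqs <- if (inherits(reads, "read_set")) reads$reads else reads
  member_seq <- as.character(seqs[member_ids])
  degree <- attr(clusters, "degree")[member_ids]
  if (is.null(degree)) degree <- rep(0L, length(member_ids))

  candidates <- list()
  unused <- rep(TRUE, length(member_seq))
  attempt <- 0L
  while (sum(unused) >= 1 && attempt < 5L) {
    attempt <- attempt + 1L
    seed_idx <- which(unused)[which.max(degree[unused])]
    asm <- grow_contig(member_seq, unused, seed_idx, min_overlap,
                       min_identity, max_length)
    unused <- asm$unused
    candidates[[attempt]] <- extend_ends(asm$contig, member_seq,
                                         min_overlap, min_identity)
    if (sum(unused) == 0) break
  }

  # polish every candidate (per-column consensus plus trimming of ends
  # lacking two-read support), drop candidates essentially contained in a
  # longer polished candidate (e.g. a terminal-repeat-only fragment inside
  # the full element), then pick the highest mean read depth
  polished <- lapply(candidates, polish_contig, member_seq = member_seq,
                     min_identity = min_identity)
  if (length(polished) > 1) {
    contained <- vapply(seq_along(polished), function(i) {
      a <- polished[[i]]$sequence
      any(vapply(seq_along(polished), function(j) {
        b <- polished[[j]]$sequence
        if (j == i || nchar(b) <= nchar(a)) return(FALSE)
        h <- cpp_local_align(a, b, 0.8, 0, 30L, 12L)
        if (nrow(h) == 0) return(FALSE)
        interval_union_length(h$q_start, h$q_end) / nchar(a) >= 0.75
      }, NA))
    }, NA)
    if (!all(contained)) polished <- polished[!contained]
  }
  best <- NULL
  for (i in seq_along(polished)) {
    p <- polished[[i]]
    cand <- list(sequence = p$sequence, mean_read_depth = p$depth,
                 id = sprintf("%sContig%d", cluster_id, i),
                 n_reads_used = p$n_reads)
    if (is.null(best) ||
        p$depth > best$mean_read_depth ||
        (p$depth == best$mean_read_depth &&
         nchar(cand$sequence) > nchar(best$sequence)) ||
        (p$depth == best$mean_read_depth &&
         nchar(cand$sequence) == nchar(best$sequence) && cand$id < best$id))
      best <- cand
  }
  structure(list(contig_id = best$id, sequence = best$sequence,
                 mean_read_depth = best$mean_read_depth,
                 source_cluster_id = cluster_id,
                 n_reads_used = best$n_reads_used),
            class = "representative_contig")
}

#' @export
print.representative_contig <- function(x, ...) {
  cat("<representative_contig> ", x$contig_id, ": ", nchar(x$sequence),
      " bp, mean depth ", round(x$mean_read_depth, 2), " (cluster ",
      x$source_cluster_id, ")\n", sep = "")
  invisible(x)
}

# End-completion pass: extend both contig ends using *all* member reads
# (including reads already consumed by the greedy phase, whose best
# placement may lie at another copy of a repeated segment, e.g. the twin
# LTR of a retroelement). Every end-touching hit is an extension candidate;
# the chosen overhang must agree with >60% of the other candidates over
# its adjacent 20 bp, so an end closes at a true sequence fork (the outer
# edge of a terminal repeat, where genomic flanks of different copies
# meet). Growth is capped per end to keep periodic contigs bounded.
extend_ends <- function(contig, member_seq, min_overlap = 40L,
                        min_identity = 0.8, ext_cap = 400L,
                        max_iter = 60L) {
  end_slack <- 10L
  rc_all <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(member_seq)))
  added <- c(left = 0L, right = 0L)
  open <- c(left = TRUE, right = TRUE)
  it <- 0L
  while (any(open) && it < max_iter) {
    it <- it + 1L
    hits <- cpp_map_reads(member_seq, contig, min_identity,
                          as.integer(min_overlap), 11L)
    if (nrow(hits) == 0) break
    L <- nchar(contig)
    rl <- nchar(member_seq[hits$read])
    oqs <- ifelse(hits$strand == "+", hits$q_start, rl - hits$q_end)
    oqe <- oqs + hits$length
    offset <- hits$t_start - oqs
    ext_left <- pmax(0L, -offset)
    ext_right <- pmax(0L, offset + rl - L)
    oriented <- function(i) {
      if (hits$strand[i] == "+") member_seq[hits$read[i]] else
        rc_all[hits$read[i]]
    }
    progressed <- FALSE
    sides <- if (it %% 2L == 1L) c("left", "right") else c("right", "left")
    for (side in sides) {
      if (!open[[side]]) next
      cand <- if (side == "left")
        which(ext_left > 0 & hits$t_start <= end_slack) else
        which(ext_right > 0 & hits$t_end >= L - end_slack)
      if (length(cand) == 0) { open[[side]] <- FALSE; next }
      overhang <- vapply(cand, function(i) {
        r <- oriented(i)
        if (side == "left") {
          o <- substring(r, 1L, ext_left[i])
          paste(rev(strsplit(o, "", fixed = TRUE)[[1]]), collapse = "")
        } else {
          substring(r, nchar(r) - ext_right[i] + 1L, nchar(r))
        }
      }, "")
      gains <- (if (side == "left") ext_left else ext_right)[cand]
      ord <- order(-gains)
      pick <- NA_integer_
      for (ci in ord) {
        if (length(cand) < 3) { pick <- ci; break }
        agree <- vapply(seq_along(cand)[-ci], function(cj)
          prefix_identity(overhang[ci], overhang[cj], 20L) >= 0.8, NA)
        if (mean(agree) > 0.6) { pick <- ci; break }
      }
      if (is.na(pick)) { open[[side]] <- FALSE; next }
      i <- cand[pick]
      r <- oriented(i)
      gain <- min(gains[pick], ext_cap - added[[side]])
      if (gain <= 0) { open[[side]] <- FALSE; next }
      if (side == "left") {
        add <- substring(r, oqs[i] - gain + 1L, oqs[i])
        contig <- paste0(add, substring(contig, hits$t_start[i] + 1L))
      } else {
        add <- substring(r, oqe[i] + 1L, oqe[i] + gain)
        contig <- paste0(substring(contig, 1L, hits$t_end[i]), add)
      }
      added[[side]] <- added[[side]] + gain
      if (added[[side]] >= ext_cap) open[[side]] <- FALSE
      progressed <- TRUE
      break
    }
    if (!progressed) break
  }
  contig
}

# identity between the first `n` characters of two strings
prefix_identity <- function(a, b, n) {
  n <- min(n, nchar(a), nchar(b))
  if (n == 0) return(0)
  mean(strsplit(substr(a, 1, n), "", fixed = TRUE)[[1]] ==
         strsplit(substr(b, 1, n), "", fixed = TRUE)[[1]])
}

# Greedy bidirectional extension from a seed read. Returns the contig and
# the updated unused mask. Reads are consumed once they align fully within
# the contig or contribute an extension. Extension of an end is fork-aware:
# when three or more candidate reads overhang that end, the chosen read's
# overhang must agree (>= 0.8 identity over the adjacent 20 bp) with more
# than half of the other candidates; at a repeat boundary whose flanking
# contexts disagree (e.g. the outer edge of an LTR, where genomic flanks
# from different element copies meet) no candidate has a majority and the
# end is closed, so contigs stop at the element boundary instead of
# assembling a chimera.
grow_contig <- function(member_seq, unused, seed_idx, min_overlap,
                        min_identity, max_length) {
  contig <- member_seq[seed_idx]
  unused[seed_idx] <- FALSE
  rc_all <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(member_seq)))
  left_open <- TRUE
  right_open <- TRUE
  end_slack <- 10L # tolerated divergence-trimmed junk at a contig end
  it <- 0L
  repeat {
    it <- it + 1L
    idx <- which(unused)
    if ((!left_open && !right_open) || length(idx) == 0 ||
        nchar(contig) >= max_length) break
    hits <- cpp_map_reads(member_seq[idx], contig, min_identity,
                          as.integer(min_overlap), 11L)
    if (nrow(hits) == 0) break
    hits <- hits |>
      dplyr::group_by(.data$read) |>
      dplyr::slice_max(.data$length, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    L <- nchar(contig)
    rl <- nchar(member_seq[idx[hits$read]])
    # exact placement of the full oriented read on contig coordinates
    oqs <- ifelse(hits$strand == "+", hits$q_start, rl - hits$q_end)
    oqe <- oqs + hits$length
    offset <- hits$t_start - oqs
    ext_left <- pmax(0L, -offset)
    ext_right <- pmax(0L, offset + rl - L)
    interior <- ext_left == 0 & ext_right == 0
    if (any(interior)) unused[idx[hits$read[interior]]] <- FALSE

    oriented <- function(i) {
      if (hits$strand[i] == "+") member_seq[idx[hits$read[i]]] else
        rc_all[idx[hits$read[i]]]
    }
    extended <- FALSE
    sides <- if (it %% 2L == 1L) c("left", "right") else c("right", "left")
    for (side in sides) {
      open <- if (side == "left") left_open else right_open
      if (!open) next
      cand <- if (side == "left")
        which(ext_left > 0 & hits$t_start <= end_slack) else
        which(ext_right > 0 & hits$t_end >= L - end_slack)
      if (length(cand) == 0) next
      # overhang strings read *outward* from the contig end, so candidate
      # agreement is assessed on the bases adjacent to the contig
      overhang <- vapply(cand, function(i) {
        r <- oriented(i)
        if (side == "left") {
          o <- substring(r, 1L, ext_left[i])
          paste(rev(strsplit(o, "", fixed = TRUE)[[1]]), collapse = "")
        } else {
          substring(r, nchar(r) - ext_right[i] + 1L, nchar(r))
        }
      }, "")
      gains <- (if (side == "left") ext_left else ext_right)[cand]
      ord <- order(-gains)
      pick <- NA_integer_
      for (ci in ord) {
        if (length(cand) < 3) { pick <- ci; break }
        agree <- vapply(seq_along(cand)[-ci], function(cj)
          prefix_identity(overhang[ci], overhang[cj], 20L) >= 0.8, NA)
        if (mean(agree) > 0.6) { pick <- ci; break }
      }
      if (is.na(pick)) {
        if (side == "left") left_open <- FALSE else right_open <- FALSE
        next
      }
      i <- cand[pick]
      r <- oriented(i)
      # splice at the supporting alignment so junk end bases are replaced
      if (side == "left") {
        contig <- paste0(substring(r, 1L, oqs[i]),
                         substring(contig, hits$t_start[i] + 1L))
      } else {
        contig <- paste0(substring(contig, 1L, hits$t_end[i]),
                         substring(r, oqe[i] + 1L, nchar(r)))
      }
      unused[idx[hits$read[i]]] <- FALSE
      extended <- TRUE
      break # remap against the longer contig before extending again
    }
    if (!extended && !any(interior)) {
      # nothing extends and nothing was consumed: ends are exhausted
      break
    }
  }
  list(contig = contig, unused = unused)
}

# Per-column plurality consensus over all member reads aligning to the
# contig; also returns mean read depth (aligned bp / contig length).
polish_contig <- function(contig, member_seq, min_identity) {
  hits <- cpp_map_reads(member_seq, contig, min_identity, 30L, 11L)
  L <- nchar(contig)
  if (nrow(hits) == 0)
    return(list(sequence = contig, depth = 1, n_reads = 0L))
  rc_all <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(member_seq)))
  base_idx <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  rl <- nchar(member_seq[hits$read])
  oqs <- ifelse(hits$strand == "+", hits$q_start, rl - hits$q_end)
  vote_idx <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    r <- if (hits$strand[i] == "+") member_seq[hits$read[i]] else
      rc_all[hits$read[i]]
    frag <- strsplit(substring(r, oqs[i] + 1L, oqs[i] + hits$length[i]), "",
                     fixed = TRUE)[[1]]
    cols <- (hits$t_start[i] + 1L):(hits$t_end[i])
    b <- base_idx[frag]
    ok <- !is.na(b)
    vote_idx[[i]] <- (cols[ok] - 1L) * 4L + b[ok]
  }
  counts <- tabulate(unlist(vote_idx), nbins = 4L * L)
  votes <- matrix(counts, nrow = 4L,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  covered <- colSums(votes) > 0
  chars <- strsplit(contig, "", fixed = TRUE)[[1]]
  if (any(covered)) {
    # plurality with alphabetical tie-break (which.max takes first = A<C<G<T)
    win <- apply(votes[, covered, drop = FALSE], 2, which.max)
    chars[covered] <- rownames(votes)[win]
  }
  out <- paste(chars, collapse = "")
  # trim ends whose support falls far below the contig's typical read
  # depth (private flanking sequence of single copies is carried in by one
  # or two boundary reads, while genuine repeat sequence is covered at the
  # cluster's depth); clusters too shallow for any 2x column keep the full
  # contig
  support <- colSums(votes)
  thr <- max(2, ceiling(0.1 * stats::median(support[support > 0])))
  if (any(support >= thr)) {
    lo <- which(support >= thr)[1]
    hi <- utils::tail(which(support >= thr), 1)
    out <- substring(out, lo, hi)
  } else if (any(support >= 2)) {
    lo <- which(support >= 2)[1]
    hi <- utils::tail(which(support >= 2), 1)
    out <- substring(out, lo, hi)
  }
  list(sequence = out,
       depth = max(1, sum(hits$length) / max(1L, nchar(out))),
       n_reads = length(unique(hits$read)))
}

#' @export
tidy.read_clusters <- function(x, ...) {
  tibble::as_tibble(x[, c("cluster_id", "size", "genome_proportion")])
}

#' @export
glance.read_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x),
                 total_reads = attr(x, "total_reads"),
                 clustered_reads = sum(x$size),
                 clustered_fraction = sum(x$size) / attr(x, "total_reads"))
}

#' Write a cluster table as TSV
#' @param clusters A `read_clusters` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_table <- function(clusters, path) {
  readr::write_tsv(tidy.read_clusters(clusters), path)
  invisible(path)
}
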