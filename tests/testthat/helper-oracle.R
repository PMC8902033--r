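# Independent all-diagonals alignment oracle.
#
# Scans EVERY diagonal of query x target (both strands) -- no k-mer
# seeding -- and reports the best-scoring ungapped run per diagonal under
# the same scoring (match +1 / mismatch -2), tie rule (first maximum in a
# left-to-right scan) and filters as the compiled engine. A vectorized
# best-score bound prunes diagonals that cannot possibly hold a passing
# hit before the exact scan replays the run bookkeeping.

oracle_scan_diagonal <- function(qch, tch, d) {
  n <- length(qch); m <- length(tch)
  lo <- max(0L, -d); hi <- min(n, m - d) # 0-based half-open query range
  if (lo >= hi) return(NULL)
  ks <- (lo + 1L):hi
  is_match <- qch[ks] == tch[ks + d] & qch[ks] %in% c("A", "C", "G", "T")
  cur <- 0; cur_start <- lo; cur_matches <- 0L
  best <- 0; bqs <- 0L; bqe <- 0L; bm <- 0L; found <- FALSE
  for (k in seq_along(ks)) {
    i0 <- lo + k - 1L
    add <- if (is_match[k]) 1 else -2
    if (cur <= 0 && add > 0) { cur <- 0; cur_start <- i0; cur_matches <- 0L }
    cur <- cur + add
    if (is_match[k]) cur_matches <- cur_matches + 1L
    if (cur < 0) {
      cur <- 0; cur_matches <- 0L; cur_start <- i0 + 1L
    } else if (cur > best) {
      best <- cur; bqs <- cur_start; bqe <- i0 + 1L; bm <- cur_matches
      found <- TRUE
    }
  }
  if (!found) return(NULL)
  list(q_start = bqs, q_end = bqe, matches = bm)
}

oracle_best_gain <- function(qch, tch, d) {
  n <- length(qch); m <- length(tch)
  lo <- max(0L, -d); hi <- min(n, m - d)
  if (lo >= hi) return(-Inf)
  ks <- (lo + 1L):hi
  s <- ifelse(qch[ks] == tch[ks + d] &
                qch[ks] %in% c("A", "C", "G", "T"), 1, -2)
  S <- cumsum(s)
  max(S - cummin(c(0, S[-length(S)])))
}

oracle_align <- function(query, target, min_identity = 0.7,
                         min_coverage = 0.7, min_hit_len = 30L) {
  n <- nchar(query)
  tch <- strsplit(target, "", fixed = TRUE)[[1]]
  m <- length(tch)
  # a passing hit has length >= max(min_hit_len, min_coverage*n) and
  # identity > min_identity, hence score > L*(3*min_identity - 2)
  need_len <- max(min_hit_len, min_coverage * n)
  thr <- need_len * (3 * min_identity - 2) - 1
  rows <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp_chr(query)
    qch <- strsplit(qs, "", fixed = TRUE)[[1]]
    for (d in (-(n - 1L)):(m - 1L)) {
      if (oracle_best_gain(qch, tch, d) < thr) next
      seg <- oracle_scan_diagonal(qch, tch, d)
      if (is.null(seg)) next
      len <- seg$q_end - seg$q_start
      identity <- seg$matches / len
      if (len < min_hit_len) next
      if (!(identity > min_identity)) next
      if (!(len / n > min_coverage)) next
      qa <- if (strand == "+") seg$q_start else n - seg$q_end
      qb <- if (strand == "+") seg$q_end else n - seg$q_start
      rows[[length(rows) + 1L]] <- tibble::tibble(
        q_start = qa, q_end = qb,
        t_start = seg$q_start + d, t_end = seg$q_end + d,
        length = len, matches = seg$matches, identity = identity,
        strand = strand)
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(q_start = integer(0), q_end = integer(0),
                          t_start = integer(0), t_end = integer(0),
                          length = integer(0), matches = integer(0),
                          identity = numeric(0), strand = character(0)))
  out <- dplyr::bind_rows(rows)
  out[order(out$t_start, out$strand, out$q_start), ]
}

hit_key <- function(h) {
  if (nrow(h) == 0) return(character(0))
  sort(paste(h$strand, h$q_start, h$q_end, h$t_start, h$t_end, h$matches))
}

# randomized planted-copy instances shared by the oracle checks
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(80:250, 1)
  m <- sample(600:2500, 1)
  target <- rand_dna(m)
  query <- rand_dna(n)
  n_copies <- sample(0:3, 1)
  if (n_copies > 0) {
    starts <- sort(sample.int(m - n, n_copies))
    # keep planted copies apart so they stay on distinct diagonals
    starts <- starts[c(TRUE, diff(starts) > n)]
    for (s in starts) {
      div <- stats::runif(1, 0, 0.15)
      cp <- mutate_copy(query, div)
      if (stats::runif(1) < 0.5) cp <- revcomp_chr(cp)
      # sometimes truncate to probe the coverage threshold
      keep <- if (stats::runif(1) < 0.3)
        floor(n * stats::runif(1, 0.55, 1)) else n
      substring(target, s + 1, s + keep) <- substring(cp, 1, keep)
    }
  }
  list(query = query, target = target)
}

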