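#' Windowed genomic distribution profile of alignment hits
#'
#' Accumulates target-side aligned bp of a contig's assembly hits into
#' fixed non-overlapping windows per chromosome (0-based window indices;
#' hits spanning several windows are split proportionally), the same
#' quantity the copy estimator sums, so the profile total equals the
#' estimate's total aligned length.
#'
#' @param hits Hit tibble with `chrom`, `t_start`, `t_end` columns (e.g.
#'   the `"hits"` attribute of [assembly_copy_number()]).
#' @param chromosome_lengths Named vector of chromosome lengths.
#' @param window_bp Window size in bp (default 10000; scale down for toy
#'   genomes).
#' @param contig_id Identifier carried in the profile.
#' @return A `distribution_profile`: list with `windows` (tibble: chrom,
#'   window, start, end, aligned_bp), `n_hits`, `total_aligned_bp`,
#'   `window_bp`, `chromosome_lengths`, `hits`, `contig_id`, and
#'   yet-unset classification fields.
#' @export
profile_hits <- function(hits, chromosome_lengths, window_bp = 10000L,
                         contig_id = "contig") {
  stopifnot(!is.null(names(chromosome_lengths)))
  if (nrow(hits) > 0) {
    if (!all(hits$chrom %in% names(chromosome_lengths)))
      stop("hits target unknown chromosomes: ",
           paste(setdiff(hits$chrom, names(chromosome_lengths)),
                 collapse = ", "))
    over <- hits$t_end > chromosome_lengths[hits$chrom]
    if (any(over))
      stop("hit beyond chromosome end on ",
           paste(unique(hits$chrom[over]), collapse = ", "))
  }
  # empty grid over all chromosomes
  grid <- purrr::map_dfr(names(chromosome_lengths), function(ch) {
    nw <- ceiling(chromosome_lengths[[ch]] / window_bp)
    tibble::tibble(chrom = ch, window = seq_len(nw) - 1L)
  }) |>
    dplyr::mutate(start = .data$window * window_bp,
                  end = pmin(.data$start + window_bp,
                             chromosome_lengths[.data$chrom]),
                  aligned_bp = 0)
  if (nrow(hits) > 0) {
    pieces <- purrr::pmap_dfr(
      list(hits$chrom, hits$t_start, hits$t_end),
      function(ch, s, e) {
        w0 <- s %/% window_bp
        w1 <- (e - 1L) %/% window_bp
        w <- w0:w1
        tibble::tibble(
          chrom = ch, window = w,
          bp = pmin(e, (w + 1) * window_bp) - pmax(s, w * window_bp))
      })
    agg <- pieces |>
      dplyr::group_by(.data$chrom, .data$window) |>
      dplyr::summarise(bp = sum(.data$bp), .groups = "drop")
    grid <- grid |>
      dplyr::left_join(agg, by = c("chrom", "window")) |>
      dplyr::mutate(aligned_bp = dplyr::coalesce(.data$bp, 0),
                    bp = NULL)
  }
  structure(list(windows = grid, n_hits = nrow(hits),
                 total_aligned_bp = sum(grid$aligned_bp),
                 window_bp = window_bp,
                 chromosome_lengths = chromosome_lengths,
                 hits = hits, contig_id = contig_id,
                 dispersion_class = NA_character_,
                 terminal_enriched = NA,
                 enriched_windows = NULL),
            class = "distribution_profile")
}

#' @export
print.distribution_profile <- function(x, ...) {
  cat("<distribution_profile> ", x$contig_id, ": ", x$n_hits, " hits, ",
      x$total_aligned_bp, " aligned bp",
      if (!is.na(x$dispersion_class)) paste0("; ", x$dispersion_class),
      if (isTRUE(x$terminal_enriched)) "; terminal-enriched", "\n", sep = "")
  invisible(x)
}

#' Classify a profile as dispersed or non-dispersed
#'
#' Quantitative form of the dispersed / non-dispersed distinction: a repeat
#' is non-dispersed when at least `concentration_fraction` of its aligned
#' bp lies in the smallest set of windows jointly covering at most
#' `span_fraction` of the genome (windows taken greedily by descending
#' aligned bp; both comparisons inclusive). The qualifying windows are
#' recorded as the profile's enriched windows.
#'
#' @param profile A `distribution_profile` with at least one hit.
#' @param concentration_fraction Signal fraction that must concentrate
#'   (default 0.5).
#' @param span_fraction Maximum genome fraction it may occupy
#'   (default 0.01).
#' @return The profile, with `dispersion_class` and `enriched_windows` set.
#' @export
classify_dispersion <- function(profile, concentration_fraction = 0.5,
                                span_fraction = 0.01) {
  stopifnot(inherits(profile, "distribution_profile"))
  if (profile$n_hits < 1 || profile$total_aligned_bp == 0)
    stop("classification undefined for a profile with no hits")
  w <- profile$windows[profile$windows$aligned_bp > 0, , drop = FALSE]
  w <- w[order(-w$aligned_bp, w$chrom, w$window), , drop = FALSE]
  need <- concentration_fraction * profile$total_aligned_bp
  cum <- cumsum(w$aligned_bp)
  k <- which(cum >= need)[1]
  sel <- w[seq_len(k), , drop = FALSE]
  genome_size <- sum(profile$chromosome_lengths)
  span <- sum(sel$end - sel$start)
  profile$enriched_windows <- sel[, c("chrom", "window")]
  profile$dispersion_class <-
    if (span <= span_fraction * genome_size) "non_dispersed" else "dispersed"
  profile
}

#' Terminal (distal-end) enrichment of a profile
#'
#' `TRUE` when at least `min_fraction` of the aligned bp falls within
#' `terminal_bp` of either end of any chromosome, computed exactly from the
#' hits rather than from the window grid.
#'
#' @param profile A `distribution_profile`.
#' @param terminal_bp Size of the distal-end region (default 50000 bp;
#'   must be below half the shortest chromosome).
#' @param min_fraction Signal fraction required (default 0.5).
#' @return Logical.
#' @export
terminal_enrichment <- function(profile, terminal_bp = 50000L,
                                min_fraction = 0.5) {
  stopifnot(inherits(profile, "distribution_profile"))
  lens <- profile$chromosome_lengths
  if (terminal_bp >= min(lens) / 2)
    stop("terminal_bp must be smaller than half the shortest chromosome")
  if (profile$total_aligned_bp == 0 || nrow(profile$hits) == 0)
    return(FALSE)
  h <- profile$hits
  clen <- lens[h$chrom]
  left <- pmax(0, pmin(h$t_end, terminal_bp) - h$t_start)
  right <- pmax(0, h$t_end - pmax(h$t_start, clen - terminal_bp))
  sum(pmin(left + right, h$t_end - h$t_start)) / profile$total_aligned_bp >=
    min_fraction
}

#' Colocalization of two repeats' enriched regions
#'
#' Jaccard index of the two profiles' enriched-window sets (run
#' [classify_dispersion()] first); both profiles must share the window
#' grid.
#'
#' @param a,b `distribution_profile`s with enriched windows set.
#' @return Jaccard index in \[0, 1\].
#' @export
colocalization <- function(a, b) {
  stopifnot(inherits(a, "distribution_profile"),
            inherits(b, "distribution_profile"))
  if (a$window_bp != b$window_bp ||
      !identical(a$chromosome_lengths, b$chromosome_lengths))
    stop("profiles use different window grids")
  if (is.null(a$enriched_windows) || is.null(b$enriched_windows))
    stop("run classify_dispersion() on both profiles first")
  ka <- paste(a$enriched_windows$chrom, a$enriched_windows$window)
  kb <- paste(b$enriched_windows$chrom, b$enriched_windows$window)
  if (length(ka) == 0 && length(kb) == 0) return(0)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Export a profile as bedGraph
#'
#' @param profile A `distribution_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_bedgraph <- function(profile, path) {
  w <- profile$windows
  utils::write.table(
    data.frame(w$chrom, w$start, w$end, w$aligned_bp),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
tidy.distribution_profile <- function(x, ...) x$windows

#' @export
glance.distribution_profile <- function(x, ...) {
  tibble::tibble(contig_id = x$contig_id, n_hits = x$n_hits,
                 total_aligned_bp = x$total_aligned_bp,
                 window_bp = x$window_bp,
                 dispersion_class = x$dispersion_class,
                 terminal_enriched = x$terminal_enriched,
                 n_enriched_windows =
                   if (is.null(x$enriched_windows)) NA_integer_
                   else nrow(x$enriched_windows))
}

#' Plot a distribution profile along the chromosomes
#'
#' @param object A `distribution_profile`.
#' @param ... Unused.
#' @return A ggplot object: aligned bp per window, faceted by chromosome.
#' @export
autoplot.distribution_profile <- function(object, ...) {
  ggplot2::ggplot(object$windows,
                  ggplot2::aes(x = .data$start / 1e3,
                               y = .data$aligned_bp)) +
    ggplot2::geom_col(width = object$window_bp / 1e3, fill = "steelblue") +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "position (kb)", y = "aligned bp per window",
                  title = object$contig_id) +
    ggplot2::theme_minimal()
}
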