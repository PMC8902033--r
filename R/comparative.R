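#' Read-based abundance matrix across accessions
#'
#' Computational analog of a comparative FISH survey: every repeat contig
#' is scored in every sample by [read_copy_number()] on that sample's
#' 1x read set, giving a families-by-samples copy matrix.
#'
#' @param contigs Named character vector of repeat contig sequences.
#' @param samples Named list of `read_set`s, each subsampled to 1x of its
#'   own genome.
#' @param min_identity,min_coverage Hit filters passed through
#'   (defaults 0.7/0.7).
#' @param merge_overlaps Per-read union semantics (default FALSE).
#' @return A `presence_matrix`: list with `copies` (families x samples
#'   numeric matrix), `present` (logical matrix, unset until
#'   [call_presence()]), `presence_threshold`, `pattern_type`.
#' @export
abundance_matrix <- function(contigs, samples, min_identity = 0.7,
                             min_coverage = 0.7, merge_overlaps = FALSE) {
  stopifnot(length(contigs) > 0, length(samples) > 0,
            !is.null(names(contigs)), !is.null(names(samples)))
  copies <- matrix(NA_real_, nrow = length(contigs), ncol = length(samples),
                   dimnames = list(names(contigs), names(samples)))
  for (f in names(contigs)) {
    for (s in names(samples)) {
      est <- read_copy_number(contigs[[f]], samples[[s]],
                              min_identity = min_identity,
                              min_coverage = min_coverage,
                              merge_overlaps = merge_overlaps,
                              contig_id = f)
      copies[f, s] <- est$copies
    }
  }
  structure(list(copies = copies, present = NULL,
                 presence_threshold = NA_real_, pattern_type = NULL),
            class = "presence_matrix")
}

#' Call presence/absence from an abundance matrix
#'
#' A family is present in a sample when its read-based copy number reaches
#' `min_copies` (inclusive); cytological detectability implies many copies,
#' so presence is abundance-thresholded rather than any-hit.
#'
#' @param matrix A `presence_matrix` from [abundance_matrix()].
#' @param min_copies Presence threshold in copies (default 10).
#' @return The `presence_matrix` with `present` and `presence_threshold`
#'   set.
#' @export
call_presence <- function(matrix, min_copies = 10) {
  stopifnot(inherits(matrix, "presence_matrix"))
  matrix$present <- matrix$copies >= min_copies
  matrix$presence_threshold <- min_copies
  matrix
}

#' Classify a presence/absence pattern across accessions
#'
#' Patterns follow the four types seen for centromeric repeats surveyed
#' across related accessions: type1 = present in every sample including
#' the outgroup; type2 = present in all ingroup samples but absent from
#' the outgroup; type3 = present in a proper nonempty subset of the
#' ingroup (outgroup state free); type4 = absent everywhere except
#' possibly the reference accession. Rows matching none are labelled
#' `"other"`. Precedence: type1 > type2 > type3 > type4 > other.
#'
#' @param matrix A `presence_matrix` with presence called, or a named
#'   logical vector (one row).
#' @param reference_sample Sample the repeats were discovered in.
#' @param outgroup_sample The outgroup accession.
#' @return For a matrix: the `presence_matrix` with `pattern_type` set
#'   (named character). For a vector: a single label.
#' @export
classify_pattern <- function(matrix, reference_sample, outgroup_sample) {
  classify_row <- function(row) {
    samples <- names(row)
    stopifnot(reference_sample %in% samples, outgroup_sample %in% samples)
    ingroup <- setdiff(samples, c(reference_sample, outgroup_sample))
    if (length(ingroup) < 2)
      stop("need at least two ingroup samples besides reference and outgroup")
    ing <- row[ingroup]
    outg <- row[[outgroup_sample]]
    if (all(row)) return("type1")
    if (all(ing) && !outg && row[[reference_sample]]) return("type2")
    if (any(ing) && !all(ing)) return("type3")
    if (!any(ing) && !outg) return("type4")
    "other"
  }
  if (is.logical(matrix) && !inherits(matrix, "presence_matrix"))
    return(classify_row(matrix))
  stopifnot(inherits(matrix, "presence_matrix"))
  if (is.null(matrix$present))
    stop("call_presence() must be run before classify_pattern()")
  labs <- apply(matrix$present, 1, classify_row)
  matrix$pattern_type <- labs
  matrix
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> ", nrow(x$copies), " family(ies) x ",
      ncol(x$copies), " sample(s)\n", sep = "")
  print(round(x$copies, 1))
  if (!is.null(x$pattern_type)) {
    cat("patterns: ",
        paste(names(x$pattern_type), x$pattern_type, sep = "=",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.presence_matrix <- function(x, ...) {
  out <- tibble::as_tibble(x$copies, rownames = "family") |>
    tidyr::pivot_longer(-"family", names_to = "sample",
                        values_to = "copies")
  if (!is.null(x$present)) {
    pr <- tibble::as_tibble(x$present, rownames = "family") |>
      tidyr::pivot_longer(-"family", names_to = "sample",
                          values_to = "present")
    out <- dplyr::left_join(out, pr, by = c("family", "sample"))
  }
  if (!is.null(x$pattern_type))
    out <- dplyr::mutate(out,
                         pattern_type = x$pattern_type[.data$family])
  out
}

#' @export
glance.presence_matrix <- function(x, ...) {
  tibble::tibble(n_families = nrow(x$copies), n_samples = ncol(x$copies),
                 presence_threshold = x$presence_threshold,
                 patterns_called = !is.null(x$pattern_type))
}

#' Tile plot of a presence/abundance matrix
#'
#' @param object A `presence_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.presence_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy.presence_matrix(object),
                  ggplot2::aes(x = .data$sample, y = .data$family,
                               fill = .data$copies)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "copies") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
}
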