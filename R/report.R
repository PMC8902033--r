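#' Assemble the summary report table
#'
#' One row per repeat contig, joining its annotation, distribution
#' classification and the two copy-number estimates, with the read/assembly
#' fold change rounded to one decimal. Rows are ordered by descending
#' read-based copies; missing upstream records yield `NA` fields and a
#' warning.
#'
#' @param estimates Tibble of `copy_estimate` rows (both methods,
#'   `dplyr::bind_rows()` of estimates).
#' @param annotations Annotation tibble from [annotate_contigs()].
#' @param profiles List of classified `distribution_profile`s (optional).
#' @return A tibble: `repeat_id`, `cluster_id`, `classification`,
#'   `distribution`, `localization`, `assembly_copies`, `read_copies`,
#'   `fold_change`, `params`.
#' @export
build_report <- function(estimates, annotations, profiles = NULL) {
  est <- tibble::as_tibble(estimates)
  ids <- unique(c(est$contig_id, annotations$contig_id))
  if (length(ids) == 0) {
    return(tibble::tibble(repeat_id = character(0), cluster_id = character(0),
                          classification = character(0),
                          distribution = character(0),
                          localization = character(0),
                          assembly_copies = numeric(0),
                          read_copies = numeric(0), fold_change = numeric(0),
                          params = character(0)))
  }
  prof_tbl <- if (!is.null(profiles) && length(profiles) > 0)
    purrr::map_dfr(profiles, glance.distribution_profile) else
    tibble::tibble(contig_id = character(0),
                   dispersion_class = character(0),
                   terminal_enriched = logical(0))

  rows <- purrr::map_dfr(ids, function(id) {
    a <- est[est$contig_id == id & est$method == "assembly", , drop = FALSE]
    r <- est[est$contig_id == id & est$method == "read_1x", , drop = FALSE]
    ann <- annotations[annotations$contig_id == id, , drop = FALSE]
    pr <- prof_tbl[prof_tbl$contig_id == id, , drop = FALSE]
    if (nrow(a) == 0 || nrow(r) == 0 || nrow(ann) == 0)
      warning("incomplete upstream records for ", id, call. = FALSE)
    ac <- if (nrow(a) == 1) a$copies else NA_real_
    rc <- if (nrow(r) == 1) r$copies else NA_real_
    fc <- if (!is.na(ac) && !is.na(rc) && ac > 0) round(rc / ac, 1)
          else NA_real_
    loc <- c(
      if (nrow(pr) == 1 && isTRUE(pr$terminal_enriched)) "terminal",
      if (!is.na(ac) && ac == 0) "absent-from-assembly")
    params <- if (nrow(r) == 1)
      sprintf("id>%.2f;cov>%.2f;%s", r$min_identity, r$min_coverage,
              if (r$merged) "merged" else "unmerged") else NA_character_
    tibble::tibble(
      repeat_id = id,
      cluster_id = if (nrow(ann) == 1 && "cluster_id" %in% names(ann))
        ann$cluster_id else NA_character_,
      classification = if (nrow(ann) == 1) ann$label else NA_character_,
      distribution = if (nrow(pr) == 1) pr$dispersion_class
        else NA_character_,
      localization = if (length(loc) > 0) paste(loc, collapse = ",")
        else "",
      assembly_copies = ac, read_copies = rc, fold_change = fc,
      params = params)
  })
  dplyr::arrange(rows, dplyr::desc(.data$read_copies))
}

#' Run the full repeat-characterization pipeline
#'
#' Executes simulate -> reads -> cluster -> representative contigs ->
#' annotate -> estimate (assembly and 1x reads) -> profile -> report on a
#' synthetic study defined by a configuration, writing every intermediate
#' artifact plus a JSON manifest (parameters and md5 of each file) to
#' `outdir`. Re-running with the same configuration is byte-identical.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `seed`; `chromosome_lengths` (named); `families` (list of
#'   [repeat_family()] argument lists); optional `collapse_factors`;
#'   `sample_reads` (reads clustered, default 5000); optional thresholds
#'   `min_identity`, `min_coverage`, `similarity_threshold`,
#'   `min_cluster_size`, `min_proportion`, `window_bp`,
#'   `concentration_fraction`, `span_fraction`, `background_gc`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- list(sample_reads = 5000L, min_identity = 0.7,
                   min_coverage = 0.7, similarity_threshold = 0.55,
                   cluster_min_identity = 0.8, min_cluster_size = 10L,
                   min_proportion = 1e-4, window_bp = 2000L,
                   concentration_fraction = 0.5, span_fraction = 0.01,
                   background_gc = 0.44, read_length = 150L,
                   error_rate = 0.001)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config must provide a seed")
  if (is.null(cfg$chromosome_lengths) || is.null(cfg$families))
    stop("config must provide chromosome_lengths and families")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)

  fams <- lapply(cfg$families, function(f) do.call(repeat_family, f))
  spec <- genome_spec(unlist(cfg$chromosome_lengths), fams,
                      background_gc = cfg$background_gc, seed = cfg$seed)
  genome <- build_genome(spec)
  write_genome(genome, p("genome.fasta"), p("genome_truth.bed"))

  assembly <- if (!is.null(cfg$collapse_factors))
    collapse_assembly(genome, unlist(cfg$collapse_factors)) else genome
  write_genome(assembly, p("assembly.fasta"), p("assembly_truth.bed"))

  gsize <- sum(Biostrings::width(genome$sequences))
  reads_1x <- simulate_reads(genome, 1.0, cfg$read_length, cfg$error_rate,
                             seed = cfg$seed + 1L)
  write_reads(reads_1x, p("reads_1x.fastq"))
  sample_n <- min(cfg$sample_reads, length(reads_1x$reads))
  sample_reads <- subsample_reads(reads_1x, sample_n, seed = cfg$seed + 2L)

  clusters <- cluster_reads(sample_reads,
                            similarity_threshold = cfg$similarity_threshold,
                            min_identity = cfg$cluster_min_identity,
                            min_cluster_size = cfg$min_cluster_size)
  enriched <- enriched_clusters(clusters, cfg$min_proportion)
  write_cluster_table(enriched, p("clusters.tsv"))

  contigs <- character(0)
  cluster_of <- character(0)
  for (cid in enriched$cluster_id) {
    rc <- build_representative_contig(clusters, sample_reads, cid)
    contigs[rc$contig_id] <- rc$sequence
    cluster_of[rc$contig_id] <- cid
  }
  if (length(contigs) > 0) {
    cs <- Biostrings::DNAStringSet(contigs)
    Biostrings::writeXStringSet(cs, p("representative_contigs.fasta"),
                                width = 60L)
  }

  annotations <- if (length(contigs) > 0)
    annotate_contigs(contigs, library = cfg$library) else
    tibble::tibble(contig_id = character(0), label = character(0),
                   detail = character(0), match_identity = numeric(0),
                   match_coverage = numeric(0))
  annotations$cluster_id <- cluster_of[annotations$contig_id]
  readr::write_tsv(annotations, p("annotations.tsv"))

  chrom_lens <- stats::setNames(Biostrings::width(assembly$sequences),
                                names(assembly$sequences))
  estimates <- list()
  profiles <- list()
  for (id in names(contigs)) {
    ae <- assembly_copy_number(contigs[[id]], assembly,
                               cfg$min_identity, cfg$min_coverage,
                               contig_id = id)
    re <- read_copy_number(contigs[[id]], reads_1x,
                           cfg$min_identity, cfg$min_coverage,
                           contig_id = id)
    estimates[[length(estimates) + 1L]] <- ae
    estimates[[length(estimates) + 1L]] <- re
    hits <- attr(ae, "hits")
    if (nrow(hits) > 0)
      write_hits_outfmt6(hits, id, p(paste0(id, "_assembly_hits.tsv")))
    prof <- profile_hits(hits, chrom_lens, cfg$window_bp, contig_id = id)
    if (prof$n_hits > 0) {
      prof <- classify_dispersion(prof, cfg$concentration_fraction,
                                  cfg$span_fraction)
      tb <- min(50000L, floor(min(chrom_lens) / 2) - 1L)
      prof$terminal_enriched <- terminal_enrichment(prof, tb)
      export_bedgraph(prof, p(paste0(id, "_profile.bedgraph")))
      profiles[[id]] <- prof
    }
  }
  est_tbl <- dplyr::bind_rows(estimates)
  readr::write_tsv(est_tbl, p("copy_estimates.tsv"))
  report <- build_report(est_tbl, annotations, profiles)
  readr::write_tsv(report, p("report.tsv"))

  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "repeatscape",
    version = as.character(utils::packageVersion("repeatscape")),
    parameters = cfg[order(names(cfg))],
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, files))), files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' md5 fingerprint of a pipeline manifest
#'
#' @param outdir Pipeline output directory.
#' @return The md5 hash of `manifest.json`.
#' @export
manifest_hash <- function(outdir) {
  unname(tools::md5sum(file.path(outdir, "manifest.json")))
}

#' Fold-change overview plot for a report
#'
#' @param report Report tibble from [build_report()].
#' @return A ggplot object: fold change per repeat, coloured by
#'   distribution class.
#' @export
plot_fold_change <- function(report) {
  df <- report[!is.na(report$fold_change), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$repeat_id, .data$fold_change),
    y = .data$fold_change, fill = .data$distribution)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "read / assembly copy-number fold change") +
    ggplot2::theme_minimal()
}
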