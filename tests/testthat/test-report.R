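test_that("report rows join estimates, annotations and profiles", {
  est <- dplyr::bind_rows(
    tibble::tibble(contig_id = "rep1", method = "assembly", copies = 18174,
                   total_aligned_length = 1L, contig_length = 1L,
                   min_identity = 0.7, min_coverage = 0.7, merged = FALSE),
    tibble::tibble(contig_id = "rep1", method = "read_1x", copies = 44408,
                   total_aligned_length = 1L, contig_length = 1L,
                   min_identity = 0.7, min_coverage = 0.7, merged = FALSE),
    tibble::tibble(contig_id = "rep2", method = "assembly", copies = 0,
                   total_aligned_length = 0L, contig_length = 1L,
                   min_identity = 0.7, min_coverage = 0.7, merged = FALSE),
    tibble::tibble(contig_id = "rep2", method = "read_1x", copies = 12,
                   total_aligned_length = 12L, contig_length = 1L,
                   min_identity = 0.7, min_coverage = 0.7, merged = FALSE))
  ann <- tibble::tibble(contig_id = c("rep1", "rep2"),
                        label = c("Simple/Sat", "Unknown"),
                        detail = NA_character_, match_identity = NA_real_,
                        match_coverage = NA_real_,
                        cluster_id = c("CL1", "CL2"))
  rep <- build_report(est, ann)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$repeat_id, c("rep1", "rep2")) # descending read copies
  expect_equal(rep$fold_change[1], 2.4) # one-decimal rounding of the ratio
  expect_true(is.na(rep$fold_change[2]))
  expect_match(rep$localization[2], "absent-from-assembly")
  # missing upstream record warns and yields NA fields
  expect_warning(r2 <- build_report(est[1:2, ], ann), "incomplete")
  expect_true(is.na(r2$assembly_copies[r2$repeat_id == "rep2"]))
  empty <- build_report(est[0, ], ann[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("report TSV round-trips losslessly", {
  est <- dplyr::bind_rows(
    tibble::tibble(contig_id = "x", method = "assembly", copies = 100,
                   total_aligned_length = 100L, contig_length = 1L,
                   min_identity = 0.7, min_coverage = 0.7, merged = FALSE),
    tibble::tibble(contig_id = "x", method = "read_1x", copies = 250,
                   total_aligned_length = 250L, contig_length = 1L,
                   min_identity = 0.7, min_coverage = 0.7, merged = FALSE))
  ann <- tibble::tibble(contig_id = "x", label = "Simple/Sat",
                        detail = "monomer 140 bp", match_identity = NA_real_,
                        match_coverage = NA_real_, cluster_id = "CL1")
  rep <- build_report(est, ann)
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(rep, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back[, c("repeat_id", "fold_change",
                                      "assembly_copies", "read_copies")]),
               as.data.frame(rep[, c("repeat_id", "fold_change",
                                     "assembly_copies", "read_copies")]))
})

test_that("tidiers and plots cover the main result types", {
  spec <- example_genome_spec(seed = 91, layout = "distribution")
  g <- build_genome(spec)
  expect_s3_class(tidy(g), "tbl_df")
  expect_equal(nrow(glance(g)), 4)
  est <- assembly_copy_number(unname(g$consensus["satCEN"]), g,
                              contig_id = "satCEN")
  prof <- classify_dispersion(profile_hits(
    attr(est, "hits"),
    stats::setNames(Biostrings::width(g$sequences), names(g$sequences)),
    window_bp = 2000))
  expect_s3_class(autoplot(prof), "ggplot")
  expect_equal(glance(prof)$dispersion_class, "non_dispersed")
  m <- structure(list(copies = rbind(f = c(a = 20, b = 0, c = 5)),
                      present = NULL, presence_threshold = NA_real_,
                      pattern_type = NULL), class = "presence_matrix")
  expect_s3_class(autoplot(m), "ggplot")
  expect_equal(nrow(tidy(m)), 3)
})
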