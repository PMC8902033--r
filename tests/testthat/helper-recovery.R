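# One full recovery run on the standard 2-Mb cohort: read-based copy
# numbers for the four planted families (interval-union semantics) and the
# read/assembly fold change for the satellite after a 10x assembly
# collapse. Cached so several acceptance checks share the same runs.
.recovery_cache <- new.env(parent = emptyenv())

recovery_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  spec <- example_genome_spec(seed = seed, layout = "recovery")
  genome <- build_genome(spec)
  queries <- example_query_contigs(genome)
  reads <- simulate_reads(genome, 1.0, seed = seed * 7L + 1L)
  read_copies <- vapply(names(queries), function(id)
    read_copy_number(queries[[id]], reads, merge_overlaps = TRUE,
                     contig_id = id)$copies, 0)
  collapsed <- collapse_assembly(genome, c(satCEN = 10))
  asm_est <- assembly_copy_number(queries[["satCEN"]], collapsed,
                                  contig_id = "satCEN")
  out <- list(read_copies = read_copies,
              sat_assembly_collapsed = asm_est$copies,
              sat_fold = read_copies[["satCEN"]] / asm_est$copies)
  .recovery_cache[[key]] <- out
  out
}

# planted copy numbers of the recovery layout, in query-contig units
recovery_truth <- c(satCEN = 1000, rdnaU = 50, gypsyL = 100,
                    teloA = 3200 * 7 / 140)
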