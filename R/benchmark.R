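#' Build the haplotype graph for a simulated founder panel
#'
#' Runs the full construction path -- reference ranges from the simulated
#' gene models, gVCF-style ingestion of every founder, consensus collapsing,
#' sequence realization and k-mer indexing -- and returns the pieces the
#' imputation step needs.
#'
#' @param ref A [simulate_reference()] result.
#' @param founders Named list from [simulate_founders()] (founders may be
#'   dropped from the list to emulate an incomplete panel).
#' @param params A [consensus_params()].
#' @param k K-mer length for the read-mapping index.
#' @return List with `ranges`, `graph`, `index`.
#' @export
build_panel_graph <- function(ref, founders, params = consensus_params(),
                              k = 21L) {
  ranges <- build_reference_ranges(ref$genes, ref$chrom_lengths)
  calls <- purrr::imap(founders, function(v, f) {
    ingest_taxon_calls(as_gvcf_records(v, ref$chrom_lengths), ranges, f)
  })
  db <- build_haplotype_db(unname(calls), ranges)
  graph <- collapse_haplotypes(db, params, reference = ref$genome)
  list(ranges = ranges, graph = graph, index = index_haplotypes(graph, k))
}

#' Impute a simulated family and score concordance against truth
#'
#' For each requested line: realize its haplotype genome, simulate a read
#' set under the given protocol and coverage, impute through the graph, and
#' score genotype concordance against the simulated truth.
#'
#' @param panel Result of [build_panel_graph()].
#' @param ref The [simulate_reference()] result the panel came from.
#' @param rils A `phg_sim_rils` family.
#' @param config The [sim_config()] driving read simulation.
#' @param lines Line names to impute (default: all).
#' @param protocol Read protocol (`"capture"`, `"gbs"`, `"skim"`).
#' @param coverage Depth passed to [simulate_reads()].
#' @param n_reads Optional explicit read count overriding `coverage`.
#' @param digest_sites Digest sites (needed for `"gbs"`).
#' @param hmm An [hmm_params()].
#' @param seed Base seed for read simulation; each line uses an offset
#'   stream.
#' @return Tibble `line`, `accuracy`, `n_overlap`, `n_reads_assigned`.
#' @export
impute_family <- function(panel, ref, rils, config, lines = NULL,
                          protocol = "capture", coverage = NULL,
                          n_reads = NULL, digest_sites = NULL,
                          hmm = hmm_params(), seed = 1L) {
  lines <- lines %||% colnames(rils$truth$geno)
  purrr::map_dfr(seq_along(lines), function(i) {
    ln <- lines[i]
    sg <- sample_sequence(ref, ril_variants(rils, ln))
    reads <- simulate_reads(sg, protocol, config, ranges = panel$ranges,
                            digest_sites = digest_sites,
                            coverage = coverage, n_reads = n_reads,
                            seed = derive_seed(seed, 1000L + i))
    imp <- phg_impute(panel$graph, panel$index, reads, params = hmm,
                      taxon = ln)
    cc <- concordance(imp, rils$truth, accession = ln, sample = ln)
    ev <- attr(imp, "evidence")
    tibble(line = ln, accuracy = accuracy(cc),
           n_overlap = attr(cc, "n_overlap"),
           n_reads_assigned = attr(ev, "counts")$assigned)
  })
}
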