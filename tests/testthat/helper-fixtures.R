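# Shared fixtures. Everything is generated in code; the pipeline fixture is
# cached per seed so several test files can reuse one graph build.

.pipeline_cache <- new.env(parent = emptyenv())

# Full synthetic study for one master seed: reference, founders, ranges,
# raw db, collapsed graph with sequences, k-mer index, panel site catalog.
pipeline_fixture <- function(seed = 1L, config = NULL) {
  key <- paste0("s", seed, "_", if (is.null(config)) "default" else "custom")
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  cfg <- config %||% sim_config(seed = seed)
  ref <- simulate_reference(cfg)
  founders <- simulate_founders(ref)
  ranges <- build_reference_ranges(ref$genes, ref$chrom_lengths)
  calls <- purrr::imap(founders, function(v, f) {
    ingest_taxon_calls(as_gvcf_records(v, ref$chrom_lengths), ranges, f)
  })
  db <- build_haplotype_db(unname(calls), ranges)
  graph <- collapse_haplotypes(db, consensus_params(), reference = ref$genome)
  fx <- list(cfg = cfg, ref = ref, founders = founders, ranges = ranges,
             db = db, graph = graph,
             index = index_haplotypes(graph, 21),
             sites = panel_sites(founders, names(ref$chrom_lengths)))
  if (is.null(config)) .pipeline_cache[[key]] <- fx
  fx
}

`%||%` <- rlang::`%||%`

# Hand-built toy graph for HMM tests: explicit ranges, haplotypes with taxa
# sets, and consensus alleles. hap_tbl: list per range of list(taxa=list of
# char vecs). Site-free (emission driven purely by supplied evidence).
toy_graph <- function(taxa_per_range, chrom = "chr1") {
  n_r <- length(taxa_per_range)
  ranges <- tibble::tibble(
    chrom = chrom, start = (seq_len(n_r) - 1L) * 1000L,
    end = seq_len(n_r) * 1000L, range_id = seq_len(n_r), informative = TRUE
  )
  haps <- purrr::imap_dfr(taxa_per_range, function(taxa, rid) {
    tibble::tibble(range_id = as.integer(rid),
                   hap_id = seq_along(taxa),
                   n_taxa = lengths(taxa), taxa = taxa)
  }) |>
    dplyr::mutate(hap_key = dplyr::row_number())
  sites <- tibble::tibble(site_id = integer(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), range_id = integer())
  structure(
    list(ranges = ranges, sites = sites, haps = haps,
         hap_geno = matrix(NA_integer_, 0, nrow(haps)),
         taxa = unique(unlist(purrr::flatten(taxa_per_range)))),
    class = "phg_graph"
  )
}

# Evidence object assembled by hand: ev_tbl has range_id, hap_id, n_hits;
# nr_tbl has range_id, n_reads.
toy_evidence <- function(ev_tbl, nr_tbl) {
  structure(tibble::as_tibble(ev_tbl),
            n_reads = tibble::as_tibble(nr_tbl),
            counts = list(input = sum(nr_tbl$n_reads),
                          assigned = sum(nr_tbl$n_reads), no_hits = 0L,
                          too_short = 0L, multi_range = 0L,
                          pair_conflict = 0L),
            class = c("phg_evidence", "tbl_df", "tbl", "data.frame"))
}

# Independent scorer for toy graphs: enumerates every state sequence and
# scores it directly from the model formulas (uniform start, taxa-overlap
# transition weights, read-count emissions). Used as the oracle for
# Viterbi / forward.
enumerate_paths <- function(graph, evidence, params, chrom) {
  rr <- dplyr::filter(graph$ranges, chrom == !!chrom)
  st <- purrr::map(rr$range_id, function(rid) {
    dplyr::arrange(dplyr::filter(graph$haps, range_id == rid), hap_id)
  })
  nr_tbl <- evidence_read_counts(evidence)
  emis <- function(r, j) {
    rid <- rr$range_id[r]
    nr <- nr_tbl$n_reads[match(rid, nr_tbl$range_id)]
    if (is.na(nr) || nr == 0 || nr < params$min_reads) return(0)
    hid <- st[[r]]$hap_id[j]
    hit <- evidence$n_hits[evidence$range_id == rid & evidence$hap_id == hid]
    hit <- if (length(hit)) hit else 0L
    hit * log(1 - params$eps) + (nr - hit) * log(params$eps)
  }
  trans <- function(r, i, j) {
    # from state i of range r-1 to state j of range r
    tx_from <- st[[r - 1]]$taxa[[i]]
    tx_all <- st[[r]]$taxa
    n <- length(tx_all)
    w <- vapply(tx_all, function(tt)
      if (length(intersect(tx_from, tt))) 1 - params$switch_p
      else params$switch_p / n, numeric(1))
    log(w[j] / sum(w))
  }
  grid <- expand.grid(purrr::map(st, ~ seq_len(nrow(.x))))
  scores <- apply(grid, 1, function(idx) {
    s <- -log(nrow(st[[1]])) + emis(1, idx[1])
    for (r in seq_along(st)[-1])
      s <- s + trans(r, idx[r - 1], idx[r]) + emis(r, idx[r])
    s
  })
  paths <- apply(grid, 1, function(idx)
    purrr::map2_int(seq_along(st), idx, ~ st[[.x]]$hap_id[.y]),
    simplify = FALSE)
  list(scores = scores, paths = paths,
       forward = {m <- max(scores); m + log(sum(exp(scores - m)))})
}

# random toy graph + evidence for the oracle sweeps
random_toy_case <- function(max_ranges = 4, max_states = 3, all_taxa = letters[1:4]) {
  n_r <- sample(1:max_ranges, 1)
  taxa_per_range <- purrr::map(seq_len(n_r), function(i) {
    n_s <- sample(1:max_states, 1)
    purrr::map(seq_len(n_s), ~ sort(sample(all_taxa, sample(1:2, 1))))
  })
  g <- toy_graph(taxa_per_range)
  ev <- purrr::map_dfr(seq_len(n_r), function(rid) {
    if (stats::runif(1) < 0.3) return(tibble::tibble())  # uncovered range
    haps <- g$haps$hap_id[g$haps$range_id == rid]
    nr <- sample(1:12, 1)
    hits <- stats::rmultinom(1, nr, prob = stats::runif(length(haps)) + 0.1)[, 1]
    tibble::tibble(range_id = rid, hap_id = haps, n_hits = as.integer(hits))
  })
  nr_tbl <- if (nrow(ev)) {
    dplyr::summarise(dplyr::group_by(ev, range_id),
                     n_reads = sum(n_hits), .groups = "drop")
  } else tibble::tibble(range_id = integer(), n_reads = integer())
  list(graph = g, evidence = toy_evidence(ev, nr_tbl))
}
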