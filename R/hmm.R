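#' HMM decoding parameters
#'
#' @param eps Per-read mismatch probability: the chance a read assigned to a
#'   range is not consistent with the haplotype actually present (default
#'   0.01). Must lie in (0, 0.5).
#' @param switch_p Per-range-boundary probability of a taxon discontinuity:
#'   transitions between haplotypes sharing no member taxon are down-weighted
#'   by this amount (default 0.001).
#' @param min_reads Minimum reads a range needs before its evidence is used
#'   in emission; below it the range is traversed with a flat emission, so
#'   with the default 0 every catalogued site is imputed regardless of
#'   coverage.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(eps = 0.01, switch_p = 0.001, min_reads = 0L) {
  assert_that(eps > 0 && eps < 0.5, "eps must be in (0, 0.5)")
  assert_that(switch_p > 0 && switch_p < 1, "switch_p must be in (0, 1)")
  assert_that(min_reads >= 0, "min_reads must be >= 0")
  structure(list(eps = eps, switch_p = switch_p,
                 min_reads = as.integer(min_reads)),
            class = "hmm_params")
}

# per-range state table: haps of one chromosome keyed by range, ordered by
# hap_id so that which.max tie-breaks to the lowest id
chrom_states <- function(graph, chrom) {
  rr <- graph$ranges |>
    filter(.data$chrom == !!chrom, .data$informative) |>
    arrange(.data$start)
  assert_that(nrow(rr) >= 1, paste0("no ranges on chromosome ", chrom))
  purrr::map(rr$range_id, function(rid) {
    h <- filter(graph$haps, .data$range_id == rid) |> arrange(.data$hap_id)
    list(range_id = rid, hap_id = h$hap_id, hap_key = h$hap_key,
         taxa = h$taxa)
  })
}

# emission log-likelihood vector for one range given evidence
emission_vector <- function(hap_ids, range_id, evidence, params) {
  nr_tbl <- evidence_read_counts(evidence)
  nr <- nr_tbl$n_reads[match(range_id, nr_tbl$range_id)] %+na% 0L
  if (nr == 0L || nr < params$min_reads) return(rep(0, length(hap_ids)))
  ev <- evidence[evidence$range_id == range_id, , drop = FALSE]
  hits <- ev$n_hits[match(hap_ids, ev$hap_id)] %+na% 0L
  hits * log(1 - params$eps) + (nr - hits) * log(params$eps)
}

#' Emission log-likelihood of read evidence given a haplotype
#'
#' `hits * log(1 - eps) + (n_reads - hits) * log(eps)`, where `hits` is the
#' number of assigned reads consistent with the haplotype. A range with fewer
#' than `min_reads` reads (in particular zero) emits 0 for every haplotype,
#' so the range is still traversed and imputed.
#'
#' @param graph A `phg_graph`.
#' @param evidence A `phg_evidence` from [map_reads()].
#' @param range_id Range whose evidence to score.
#' @param hap_id Haplotype id within the range.
#' @param params An [hmm_params()] object.
#' @return Log-likelihood (scalar).
#' @export
emission_loglik <- function(graph, evidence, range_id, hap_id,
                            params = hmm_params()) {
  hap_ids <- sort(graph$haps$hap_id[graph$haps$range_id == range_id])
  assert_that(hap_id %in% hap_ids,
              paste0("hap_id ", hap_id, " absent from range ", range_id))
  emission_vector(hap_ids, range_id, evidence, params)[match(hap_id, hap_ids)]
}

#' Transition log-probabilities between consecutive ranges
#'
#' Successor haplotypes sharing at least one member taxon with the current
#' haplotype get unnormalized weight `1 - switch_p`; disjoint-taxa successors
#' share `switch_p` spread uniformly over the successor states. Weights are
#' renormalized so each row sums to one.
#'
#' @param taxa_from Character vector: member taxa of the current haplotype.
#' @param taxa_next List of character vectors: member taxa of each successor
#'   haplotype, in successor state order.
#' @param switch_p Taxon-discontinuity probability.
#' @return Numeric vector of log transition probabilities over successors.
#' @export
transition_logprob <- function(taxa_from, taxa_next, switch_p = 0.001) {
  n <- length(taxa_next)
  shared <- purrr::map_lgl(taxa_next, ~ length(intersect(taxa_from, .x)) > 0)
  w <- ifelse(shared, 1 - switch_p, switch_p / n)
  log(w / sum(w))
}

#' Decode the maximum-probability haplotype path of one chromosome
#'
#' Viterbi decoding over the chromosome's ordered reference ranges: states
#' are consensus haplotypes, the initial distribution is uniform, emissions
#' and transitions follow [emission_loglik()] and [transition_logprob()].
#' Ties are broken toward the lowest `hap_id`.
#'
#' @param graph A `phg_graph`.
#' @param evidence A `phg_evidence` from [map_reads()].
#' @param params An [hmm_params()] object.
#' @param chrom Chromosome to decode.
#' @return A `phg_path` tibble (`chrom`, `range_id`, `hap_id`, `log_score`)
#'   with attribute `total_loglik`, the log-probability of the decoded path.
#' @export
viterbi_path <- function(graph, evidence, params = hmm_params(), chrom) {
  st <- chrom_states(graph, chrom)
  n_r <- length(st)
  delta <- vector("list", n_r)
  psi <- vector("list", n_r)

  e1 <- emission_vector(st[[1]]$hap_id, st[[1]]$range_id, evidence, params)
  delta[[1]] <- -log(length(st[[1]]$hap_id)) + e1

  for (r in seq_len(n_r)[-1]) {
    prev <- st[[r - 1]]; cur <- st[[r]]
    em <- emission_vector(cur$hap_id, cur$range_id, evidence, params)
    d <- numeric(length(cur$hap_id))
    p <- integer(length(cur$hap_id))
    # scores[from, to]
    scores <- vapply(seq_along(prev$hap_id), function(i) {
      delta[[r - 1]][i] +
        transition_logprob(prev$taxa[[i]], cur$taxa, params$switch_p)
    }, numeric(length(cur$hap_id)))
    scores <- matrix(scores, nrow = length(cur$hap_id))
    for (jj in seq_along(cur$hap_id)) {
      p[jj] <- which.max(scores[jj, ])
      d[jj] <- scores[jj, p[jj]] + em[jj]
    }
    delta[[r]] <- d
    psi[[r]] <- p
  }

  idx <- integer(n_r)
  idx[n_r] <- which.max(delta[[n_r]])
  if (n_r > 1) {
    for (r in (n_r - 1):1) idx[r] <- psi[[r + 1]][idx[r + 1]]
  }

  out <- tibble(
    chrom = chrom,
    range_id = purrr::map_int(st, "range_id"),
    hap_id = purrr::map2_int(st, idx, ~ .x$hap_id[.y]),
    log_score = purrr::map2_dbl(delta, idx, ~ .x[.y])
  )
  structure(out, total_loglik = delta[[n_r]][idx[n_r]],
            class = c("phg_path", class(out)))
}

#' Total log-probability of the evidence over all paths
#'
#' Forward-algorithm log-likelihood under the same model as [viterbi_path()];
#' always at least the Viterbi path log-probability. Mainly a diagnostic and
#' testing hook.
#'
#' @inheritParams viterbi_path
#' @return Scalar log-probability.
#' @export
forward_loglik <- function(graph, evidence, params = hmm_params(), chrom) {
  st <- chrom_states(graph, chrom)
  alpha <- -log(length(st[[1]]$hap_id)) +
    emission_vector(st[[1]]$hap_id, st[[1]]$range_id, evidence, params)
  for (r in seq_along(st)[-1]) {
    prev <- st[[r - 1]]; cur <- st[[r]]
    em <- emission_vector(cur$hap_id, cur$range_id, evidence, params)
    trans <- vapply(seq_along(prev$hap_id), function(i) {
      transition_logprob(prev$taxa[[i]], cur$taxa, params$switch_p)
    }, numeric(length(cur$hap_id)))
    trans <- matrix(trans, nrow = length(cur$hap_id))
    alpha <- vapply(seq_along(cur$hap_id), function(jj) {
      logsumexp(alpha + trans[jj, ]) + em[jj]
    }, numeric(1))
  }
  logsumexp(alpha)
}

#' Impute genotypes from decoded haplotype paths
#'
#' For every site in the graph's catalog, the imputed genotype is the chosen
#' consensus haplotype's allele at that site (emitted as a homozygous call:
#' the panels are inbred). A missing consensus allele yields a missing
#' genotype. Because ranges without reads are still traversed, the number of
#' emitted records always equals the size of the site catalog.
#'
#' @param paths A `phg_path` or a list of them (one per chromosome), or a
#'   bound tibble with columns `chrom`, `range_id`, `hap_id`.
#' @param graph A `phg_graph`.
#' @param taxon Sample name attached to the output.
#' @return Tibble `chrom`, `pos` (1-based), `ref`, `alt`, `gt` (0/1/`NA`)
#'   sorted by position, with attribute `taxon`.
#' @export
emit_genotypes <- function(paths, graph, taxon = "imputed") {
  if (inherits(paths, "phg_path")) paths <- list(paths)
  if (is.list(paths) && !is.data.frame(paths)) paths <- bind_rows(paths)
  key <- paste(graph$haps$range_id, graph$haps$hap_id)
  hk <- graph$haps$hap_key[match(paste(paths$range_id, paths$hap_id), key)]
  assert_that(!anyNA(hk), "path refers to unknown haplotype")

  gt <- rep(NA_integer_, nrow(graph$sites))
  for (i in seq_len(nrow(paths))) {
    rows <- which(graph$sites$range_id == paths$range_id[i])
    gt[rows] <- graph$hap_geno[rows, hk[i]]
  }
  covered <- graph$sites$range_id %in% paths$range_id
  assert_that(all(covered), "site catalog contains sites outside the decoded paths")

  out <- graph$sites |>
    transmute(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    mutate(gt = gt)
  attr(out, "taxon") <- taxon
  out
}

#' Run the full imputation step for one sample
#'
#' Maps reads, decodes one path per chromosome, and emits genotypes for the
#' whole site catalog.
#'
#' @param graph A `phg_graph` with realized sequences.
#' @param index A `phg_kmer_index` over the graph.
#' @param reads,reads2 Read sequences (see [map_reads()]).
#' @param params An [hmm_params()] object.
#' @param taxon Sample name for the output.
#' @return Imputed genotype tibble from [emit_genotypes()], with the mapping
#'   evidence attached as attribute `evidence`.
#' @export
phg_impute <- function(graph, index, reads, reads2 = NULL,
                       params = hmm_params(), taxon = "imputed") {
  ev <- map_reads(index, reads, reads2)
  chroms <- unique(graph$ranges$chrom[graph$ranges$informative])
  paths <- purrr::map(chroms, ~ viterbi_path(graph, ev, params, .x))
  out <- emit_genotypes(paths, graph, taxon)
  attr(out, "evidence") <- ev
  out
}
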