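#' Index consensus haplotype sequences by canonical k-mers
#'
#' Builds a hash from every canonical k-mer (the lexicographic minimum of a
#' k-mer and its reverse complement) occurring in any realized consensus
#' haplotype sequence to the haplotypes containing it. This index drives the
#' pseudo-mapper that stands in for a full read aligner: at the read lengths
#' and error rates targeted here, shared k-mer counts are enough to decide
#' which haplotypes a read is consistent with.
#'
#' @param graph A `phg_graph` with realized sequences (see
#'   [realize_sequences()]).
#' @param k Odd k-mer length between 11 and 31 (default 21).
#' @return A `phg_kmer_index`: list with `k`, the hash environment, and
#'   haplotype lookup vectors (`hap_range`, `hap_id`).
#' @export
index_haplotypes <- function(graph, k = 21L) {
  k <- as.integer(k)
  assert_that(k %% 2L == 1L && k >= 11L && k <= 31L,
              "k must be odd and in [11, 31]")
  assert_that(nrow(graph$haps) == 0 || !is.null(graph$haps$seq),
              "graph has no realized sequences; call realize_sequences()")

  km_list <- vector("list", nrow(graph$haps))
  for (i in seq_len(nrow(graph$haps))) {
    s <- graph$haps$seq[i]
    if (nchar(s) < k) {
      warn(sprintf("haplotype %d (range %d) shorter than k; skipped",
                   graph$haps$hap_id[i], graph$haps$range_id[i]))
      km_list[[i]] <- character(0)
      next
    }
    km_list[[i]] <- unique(canonical_kmers(s, k))
  }
  kmers <- unlist(km_list, use.names = FALSE)
  owners <- rep.int(graph$haps$hap_key, lengths(km_list))

  env <- new.env(hash = TRUE, size = max(length(kmers), 1L))
  if (length(kmers)) {
    by_kmer <- split(owners, kmers)
    list2env(by_kmer, envir = env)
  }

  structure(
    list(
      k = k, env = env,
      hap_range = graph$haps$range_id,
      hap_id = graph$haps$hap_id,
      n_kmers = length(env)
    ),
    class = "phg_kmer_index"
  )
}

# All canonical k-mers of one sequence, in order, as hash keys. A k-mer is
# encoded as its base-4 value (A=0, C=1, G=2, T=3; exact in doubles for
# k <= 26) and the canonical form is the smaller of the k-mer and its
# reverse complement -- identical to the lexicographic rule, compared
# numerically. K-mers touching a non-ACGT base are dropped.
canonical_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  code <- kmer_base_codes[strsplit(s, "", fixed = TRUE)[[1]]]
  n <- L - k + 1L
  fwd <- numeric(n)
  rev <- numeric(n)
  comp <- 3 - code
  for (j in 0:(k - 1L)) {
    sl <- code[(1L + j):(n + j)]
    fwd <- fwd + sl * 4^(k - 1L - j)
    rev <- rev + comp[(1L + j):(n + j)] * 4^j
  }
  v <- pmin(fwd, rev)
  as.character(v[!is.na(v)])
}

kmer_base_codes <- c(A = 0, C = 1, G = 2, T = 3)

#' Map reads to reference ranges through the k-mer index
#'
#' Each read's canonical k-mers are looked up in the index. A read whose hits
#' touch more than one reference range is discarded as non-unique (mirroring
#' a uniquely-mapped-reads policy); otherwise it is assigned to that range
#' and its consistent haplotype set is the haplotypes achieving the maximum
#' k-mer hit count. Paired reads are processed as two reads; if both mates
#' map they must agree on the range or the pair is discarded, and a mate
#' without hits is individually discarded.
#'
#' @param index A `phg_kmer_index`.
#' @param reads Character vector of read sequences, or a tibble with columns
#'   `seq1` (and `seq2` for pairs).
#' @param reads2 Optional character vector of mate sequences.
#' @return A `phg_evidence` tibble (`range_id`, `hap_id`, `n_hits`) with
#'   attributes `n_reads` (per-range assigned read counts) and `counts`
#'   (totals: input, assigned, no_hits, too_short, multi_range,
#'   pair_conflict).
#' @export
map_reads <- function(index, reads, reads2 = NULL) {
  if (is.data.frame(reads)) {
    reads2 <- if ("seq2" %in% names(reads)) reads$seq2 else NULL
    reads <- reads$seq1
  }
  paired <- !is.null(reads2)
  if (paired) assert_that(length(reads) == length(reads2),
                          "mate vectors differ in length")

  counts <- c(input = length(reads) * (1L + paired), assigned = 0L,
              no_hits = 0L, too_short = 0L, multi_range = 0L,
              pair_conflict = 0L)

  acc_range <- integer(0)
  acc_hap <- list()

  classify <- function(sq) {
    # returns list(status, range, haps)
    if (is.na(sq) || nchar(sq) < index$k)
      return(list(status = "too_short"))
    km <- canonical_kmers(sq, index$k)
    hits <- unlist(mget(unique(km), envir = index$env,
                        ifnotfound = list(NULL)), use.names = FALSE)
    if (!length(hits)) return(list(status = "no_hits"))
    rg <- unique(index$hap_range[hits])
    if (length(rg) > 1L) return(list(status = "multi_range"))
    tb <- table(hits)
    best <- as.integer(names(tb)[tb == max(tb)])
    list(status = "ok", range = rg, haps = best)
  }

  for (i in seq_along(reads)) {
    a <- classify(reads[[i]])
    if (!paired) {
      if (a$status == "ok") {
        counts["assigned"] <- counts["assigned"] + 1L
        acc_range <- c(acc_range, a$range)
        acc_hap <- c(acc_hap, list(a$haps))
      } else counts[a$status] <- counts[a$status] + 1L
      next
    }
    b <- classify(reads2[[i]])
    oka <- a$status == "ok"; okb <- b$status == "ok"
    if (oka && okb && a$range != b$range) {
      counts["pair_conflict"] <- counts["pair_conflict"] + 2L
      next
    }
    for (m in list(a, b)) {
      if (m$status == "ok") {
        counts["assigned"] <- counts["assigned"] + 1L
        acc_range <- c(acc_range, m$range)
        acc_hap <- c(acc_hap, list(m$haps))
      } else counts[m$status] <- counts[m$status] + 1L
    }
  }

  # aggregate: per-range read totals and per-haplotype consistent counts
  n_reads <- tibble(range_id = acc_range) |>
    count(.data$range_id, name = "n_reads")
  hit_tbl <- tibble(
    range_id = rep.int(acc_range, lengths(acc_hap)),
    hap_key = unlist(acc_hap) %||% integer(0)
  )
  ev <- if (nrow(hit_tbl)) {
    hit_tbl |>
      mutate(hap_id = index$hap_id[.data$hap_key]) |>
      count(.data$range_id, .data$hap_id, name = "n_hits") |>
      arrange(.data$range_id, .data$hap_id)
  } else {
    tibble(range_id = integer(), hap_id = integer(), n_hits = integer())
  }
  structure(ev, n_reads = n_reads, counts = as.list(counts),
            class = c("phg_evidence", class(ev)))
}

#' Per-range read totals of a mapping result
#'
#' @param evidence A `phg_evidence` object.
#' @return Tibble `range_id`, `n_reads`; ranges without reads are absent
#'   (they count as zero).
#' @export
evidence_read_counts <- function(evidence) {
  attr(evidence, "n_reads") %||% tibble(range_id = integer(),
                                        n_reads = integer())
}

#' Write mapping evidence as TSV
#' @param evidence A `phg_evidence` tibble.
#' @param path Output path.
#' @export
write_evidence <- function(evidence, path) {
  utils::write.table(as.data.frame(evidence), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
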