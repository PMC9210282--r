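#' Assemble per-taxon calls into a raw haplotype database
#'
#' Combines the ingested calls of all panel taxa into a site catalog (the
#' union of variant positions, bi-allelic by construction) and a site-by-taxon
#' allele matrix. For every informative range each taxon contributes one raw
#' haplotype: the called allele where a variant record covers the position,
#' the reference allele where a reference block covers it, missing elsewhere.
#'
#' @param calls_list List of tibbles from [ingest_taxon_calls()], one per
#'   taxon.
#' @param ranges Reference ranges from [build_reference_ranges()].
#' @return An object of class `phg_rawdb`: a list with `ranges`, `sites`
#'   (tibble `site_id`, `chrom`, `pos`, `ref`, `alt`, `range_id`), `geno`
#'   (integer matrix sites x taxa, `NA` = missing) and `taxa`.
#' @export
build_haplotype_db <- function(calls_list, ranges) {
  assert_that(length(calls_list) >= 1, "need calls for at least one taxon")
  taxa <- purrr::map_chr(calls_list, function(x) {
    attr(x, "taxon") %||% x$taxon[1] %||% NA_character_
  })
  taxa[is.na(taxa)] <- paste0("taxon", which(is.na(taxa)))
  assert_that(!anyDuplicated(taxa), "duplicate taxon names")

  all_calls <- bind_rows(calls_list)
  chrom_levels <- unique(ranges$chrom)
  sites <- all_calls |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$range_id) |>
    arrange(factor(.data$chrom, levels = chrom_levels), .data$pos)
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    abort("conflicting alleles at one position across taxa (multi-allelic)")
  sites <- mutate(sites, site_id = dplyr::row_number(), .before = 1)

  geno <- matrix(NA_integer_, nrow = nrow(sites), ncol = length(taxa),
                 dimnames = list(NULL, taxa))
  key <- paste(sites$chrom, sites$pos)
  for (j in seq_along(calls_list)) {
    calls <- calls_list[[j]]
    cov <- attr(calls, "covered")
    # reference-block coverage -> ref allele
    if (!is.null(cov) && nrow(cov)) {
      for (cc in unique(sites$chrom)) {
        ss <- which(sites$chrom == cc)
        rr <- ranges$range_id[ranges$chrom == cc]
        cv <- cov[cov$range_id %in% rr, ]
        if (!nrow(cv)) next
        cv <- cv[order(cv$cov_start), ]
        idx <- findInterval(sites$pos[ss] - 1L, cv$cov_start)
        inside <- idx >= 1 & idx <= nrow(cv)
        inside[inside] <- (sites$pos[ss][inside] - 1L) < cv$cov_end[idx[inside]]
        geno[ss[inside], j] <- 0L
      }
    }
    # explicit variant calls override
    m <- match(paste(calls$chrom, calls$pos), key)
    ok <- !is.na(m)
    geno[m[ok], j] <- calls$allele[ok]
  }

  structure(
    list(ranges = ranges, sites = sites, geno = geno, taxa = taxa),
    class = "phg_rawdb"
  )
}

#' Consensus clustering parameters
#'
#' @param mxdiv Maximum divergence in differences per bp below which raw
#'   haplotypes are merged (default `1e-4`, i.e. merging requires fewer than
#'   1 variant per 10,000 bp).
#' @param min_taxa Minimum number of member accessions a cluster must have to
#'   be retained (default 1, keeping singleton haplotypes so rare haplotypes
#'   remain imputable).
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(mxdiv = 1e-4, min_taxa = 1L) {
  assert_that(mxdiv >= 0, "mxdiv must be >= 0")
  assert_that(min_taxa >= 1, "min_taxa must be >= 1")
  structure(list(mxdiv = mxdiv, min_taxa = as.integer(min_taxa)),
            class = "consensus_params")
}

#' Collapse the raw haplotypes of one range into consensus haplotypes
#'
#' Pairwise divergence between two raw haplotypes is the count of sites where
#' both are non-missing and the alleles differ, divided by the full range
#' length in bp. Average-linkage agglomerative clustering merges the closest
#' pair of clusters while their average divergence is strictly below `mxdiv`
#' (identical haplotypes always merge, so `mxdiv = 0` collapses exact
#' duplicates only).
#' The consensus allele at a site is the majority among non-missing members,
#' ties resolved to the reference allele; a site missing in all members stays
#' missing.
#'
#' @param geno Integer matrix (sites in this range x taxa); may have zero
#'   rows when the range carries no variants.
#' @param range_length_bp Full length of the range in bp (the divergence
#'   denominator).
#' @param params A [consensus_params()] object.
#' @return List with `haps` (tibble `hap_id`, `n_taxa`, `taxa` list-column,
#'   ordered by descending taxa count then lexicographic member names) and
#'   `consensus` (integer matrix sites x haplotypes).
#' @export
collapse_range <- function(geno, range_length_bp, params = consensus_params()) {
  assert_that(is.matrix(geno), "geno must be a matrix")
  n <- ncol(geno)
  assert_that(n >= 1, "empty input: no raw haplotypes")
  assert_that(range_length_bp > 0, "range_length_bp must be > 0")
  taxa <- colnames(geno) %||% paste0("t", seq_len(n))

  # pairwise divergence: both non-missing and different, per bp of range
  D <- matrix(0, n, n)
  if (nrow(geno) && n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        both <- !is.na(geno[, i]) & !is.na(geno[, j])
        d <- sum(geno[both, i] != geno[both, j]) / range_length_bp
        D[i, j] <- D[j, i] <- d
      }
    }
  }

  members <- cluster_average_linkage(D, params$mxdiv)
  sizes <- lengths(members)
  members <- members[sizes >= params$min_taxa]
  assert_that(length(members) >= 1,
              "all clusters dropped by min_taxa; nothing to retain")

  member_taxa <- purrr::map(members, ~ sort(taxa[.x]))
  ord <- order(-lengths(member_taxa),
               purrr::map_chr(member_taxa, paste, collapse = ","))
  members <- members[ord]
  member_taxa <- member_taxa[ord]

  consensus <- matrix(NA_integer_, nrow = nrow(geno), ncol = length(members))
  for (h in seq_along(members)) {
    sub <- geno[, members[[h]], drop = FALSE]
    consensus[, h] <- apply(sub, 1, function(a) {
      a <- a[!is.na(a)]
      if (!length(a)) return(NA_integer_)
      n1 <- sum(a == 1L)
      n0 <- length(a) - n1
      if (n1 > n0) 1L else 0L  # tie -> reference
    })
  }

  list(
    haps = tibble(
      hap_id = seq_along(members),
      n_taxa = lengths(member_taxa),
      taxa = member_taxa
    ),
    consensus = consensus
  )
}

# average-linkage agglomerative merge with strict threshold; returns a list
# of member index vectors
cluster_average_linkage <- function(D, threshold) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  if (n == 1L) return(members)
  dist <- D
  diag(dist) <- Inf
  repeat {
    if (length(members) == 1L) break
    m <- which(dist == min(dist), arr.ind = TRUE)[1, ]
    i <- min(m); j <- max(m)
    # identical haplotypes (d = 0) always merge, even at threshold 0;
    # otherwise the strict inequality applies (1 variant per 10 kb does
    # not merge at mxdiv = 1e-4)
    if (!(dist[i, j] == 0 || dist[i, j] < threshold)) break
    ni <- length(members[[i]]); nj <- length(members[[j]])
    # Lance-Williams update for (pair-count weighted) average linkage
    new_d <- (ni * dist[i, ] + nj * dist[j, ]) / (ni + nj)
    dist[i, ] <- new_d
    dist[, i] <- new_d
    dist <- dist[-j, -j, drop = FALSE]
    diag(dist) <- Inf
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
  }
  members
}

#' Collapse every range of a raw database and build the haplotype graph
#'
#' @param db A `phg_rawdb` from [build_haplotype_db()].
#' @param params A [consensus_params()] object.
#' @param reference Optional named character vector of chromosome sequences;
#'   when supplied, each consensus haplotype's realized sequence (the
#'   reference over the range edited with its alleles) is attached, which
#'   [index_haplotypes()] requires.
#' @return A `phg_graph` object: list with `ranges`, `sites`, `haps`
#'   (tibble `range_id`, `hap_id`, `hap_key`, `n_taxa`, `taxa`, optionally
#'   `seq`), `hap_geno` (sites x global haplotype key matrix of consensus
#'   alleles) and `taxa`.
#' @export
collapse_haplotypes <- function(db, params = consensus_params(),
                                reference = NULL) {
  assert_that(inherits(db, "phg_rawdb"), "db must be a phg_rawdb")
  per_range <- vector("list", nrow(db$ranges))
  for (i in seq_len(nrow(db$ranges))) {
    rid <- db$ranges$range_id[i]
    rows <- which(db$sites$range_id == rid)
    res <- collapse_range(
      db$geno[rows, , drop = FALSE],
      db$ranges$end[i] - db$ranges$start[i],
      params
    )
    per_range[[i]] <- list(rid = rid, rows = rows, res = res)
  }

  haps <- purrr::map_dfr(per_range, function(x) {
    mutate(x$res$haps, range_id = x$rid, .before = 1)
  }) |>
    mutate(hap_key = dplyr::row_number())

  hap_geno <- matrix(NA_integer_, nrow = nrow(db$sites), ncol = nrow(haps))
  for (x in per_range) {
    keys <- haps$hap_key[haps$range_id == x$rid]
    if (length(x$rows))
      hap_geno[x$rows, keys] <- x$res$consensus
  }

  g <- structure(
    list(ranges = db$ranges, sites = db$sites, haps = haps,
         hap_geno = hap_geno, taxa = db$taxa, params = params),
    class = "phg_graph"
  )
  if (!is.null(reference)) g <- realize_sequences(g, reference)
  validate_graph(g)
  g
}

validate_graph <- function(g) {
  counts <- table(factor(g$haps$range_id, levels = g$ranges$range_id))
  if (any(counts == 0))
    abort("graph invariant violated: range with zero consensus haplotypes")
  invisible(g)
}

#' Realize consensus haplotype sequences
#'
#' Edits the reference sequence over each range with the haplotype's
#' non-reference alleles (SNP substitution; indel alleles are spliced).
#'
#' @param graph A `phg_graph`.
#' @param reference Named character vector of chromosome sequences.
#' @return The graph with a `seq` column on `haps`.
#' @export
realize_sequences <- function(graph, reference) {
  ranges <- graph$ranges
  seqs <- character(nrow(graph$haps))
  for (i in seq_len(nrow(graph$haps))) {
    rid <- graph$haps$range_id[i]
    rr <- ranges[ranges$range_id == rid, ]
    base <- substr(reference[[rr$chrom]], rr$start + 1L, rr$end)
    rows <- which(graph$sites$range_id == rid)
    alleles <- graph$hap_geno[rows, graph$haps$hap_key[i]]
    edit <- rows[!is.na(alleles) & alleles == 1L]
    if (length(edit)) {
      st <- graph$sites$pos[edit] - rr$start  # 1-based offset within range
      o <- order(-st)                          # splice right to left
      for (e in o) {
        site <- graph$sites[edit[e], ]
        base <- paste0(
          substr(base, 1L, st[e] - 1L),
          site$alt,
          substr(base, st[e] + nchar(site$ref), nchar(base))
        )
      }
    }
    seqs[i] <- base
  }
  graph$haps$seq <- seqs
  graph
}

#' Site frequencies in the graph database
#'
#' Alternate-allele and minor-allele frequency of every catalogued site,
#' computed over the panel taxa through their consensus haplotype membership
#' (each haplotype's allele weighted by its number of member taxa).
#'
#' @param graph A `phg_graph`.
#' @return Tibble `site_id`, `chrom`, `pos`, `ref`, `alt`, `p_alt`, `maf`.
#' @export
graph_site_maf <- function(graph) {
  n1 <- numeric(nrow(graph$sites))
  nn <- numeric(nrow(graph$sites))
  for (i in seq_len(nrow(graph$haps))) {
    rows <- which(graph$sites$range_id == graph$haps$range_id[i])
    a <- graph$hap_geno[rows, graph$haps$hap_key[i]]
    w <- graph$haps$n_taxa[i]
    ok <- !is.na(a)
    n1[rows[ok]] <- n1[rows[ok]] + w * (a[ok] == 1L)
    nn[rows[ok]] <- nn[rows[ok]] + w
  }
  p <- ifelse(nn > 0, n1 / nn, NA_real_)
  graph$sites |>
    mutate(p_alt = p, maf = pmin(p, 1 - p))
}

#' Mean haplotypes per informative reference range
#'
#' @param n_haplotypes Total consensus haplotypes in the database.
#' @param n_ranges Total informative reference ranges.
#' @return The ratio `n_haplotypes / n_ranges`.
#' @export
haplotypes_per_range <- function(n_haplotypes, n_ranges) {
  assert_that(n_ranges > 0, "n_ranges must be > 0")
  n_haplotypes / n_ranges
}

#' Mean reference ranges per chromosome
#'
#' @param n_ranges Total reference ranges.
#' @param n_chroms Number of chromosomes.
#' @return The ratio `n_ranges / n_chroms`.
#' @export
ranges_per_chromosome <- function(n_ranges, n_chroms) {
  assert_that(n_chroms > 0, "n_chroms must be > 0")
  n_ranges / n_chroms
}

#' Persist a haplotype graph as a plain-text directory
#'
#' Writes `ranges.bed`, a per-chromosome haplotype table
#' (`haplotypes_<chrom>.tsv`: range, haplotype, member taxa, and the allele
#' at every catalogued site) and a `summary.txt` with the [glance()] totals.
#'
#' @param graph A `phg_graph`.
#' @param dir Output directory (created if needed).
#' @export
write_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ranges_bed(graph$ranges, file.path(dir, "ranges.bed"))
  for (cc in unique(graph$ranges$chrom)) {
    rids <- graph$ranges$range_id[graph$ranges$chrom == cc]
    hh <- graph$haps[graph$haps$range_id %in% rids, ]
    rows <- which(graph$sites$range_id %in% rids)
    tab <- purrr::map_dfr(seq_len(nrow(hh)), function(i) {
      srows <- which(graph$sites$range_id == hh$range_id[i])
      tibble(
        range_id = hh$range_id[i], hap_id = hh$hap_id[i],
        taxa = paste(hh$taxa[[i]], collapse = ","),
        pos = graph$sites$pos[srows],
        ref = graph$sites$ref[srows], alt = graph$sites$alt[srows],
        allele = graph$hap_geno[srows, hh$hap_key[i]]
      )
    })
    utils::write.table(tab, file.path(dir, paste0("haplotypes_", cc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  g <- glance(graph)
  writeLines(paste(names(g), unlist(g), sep = "\t"),
             file.path(dir, "summary.txt"))
  invisible(dir)
}
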