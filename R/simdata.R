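#' Synthetic study configuration
#'
#' Defines the conditions the generator emulates: a small multi-chromosome
#' genome of gene islands in a repeat-rich background, a founder panel whose
#' genome groups differ in diversity (mirroring the A/B vs D subgenome
#' contrast of bread wheat), one deeply divergent introgression donor,
#' biparental recombinant inbred lines, and capture-, GBS- or skim-style
#' read sets. All randomness flows from `seed`; every artifact is
#' reproducible per seed.
#'
#' @param seed Master integer seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_genes Gene models per chromosome.
#' @param gene_len_range Min/max gene length in bp.
#' @param gene_gc GC content of gene islands (default 0.60): grass genes are
#'   markedly GC-rich, which also concentrates GC-rich restriction sites
#'   (e.g. PstI) in gene space the way methylation-sensitive GBS assays
#'   exploit.
#' @param repeat_fraction Fraction of intergenic sequence tiled from a small
#'   repeated-motif library.
#' @param n_founders Panel size including the donor.
#' @param genome_groups Group labels recycled over chromosomes.
#' @param divergence Named per-group founder-vs-reference mutation rate
#'   (substitutions per gene bp).
#' @param introgression List: `multiplier` (donor divergence relative to its
#'   group background), `chrom` (index), `interval` (0-based half-open bp
#'   interval carrying the divergent donor haplotype).
#' @param ril List: `n_lines`, `xo_mean` (Poisson mean crossovers per
#'   chromosome per line), `selfing_generations` (residual heterozygosity
#'   `2^-generations`, masked to missing).
#' @param reads List of protocol defaults: `coverage`, `read_len`,
#'   `error_rate`, `paired`, `insert`, `gbs_read_len`.
#' @return A list of class `phg_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_len = 200000L,
                       n_genes = 30L,
                       gene_len_range = c(1000L, 3000L),
                       gene_gc = 0.60,
                       repeat_fraction = 0.4,
                       n_founders = 6L,
                       genome_groups = c("A", "D"),
                       divergence = c(A = 0.005, D = 0.002),
                       introgression = list(),
                       ril = list(),
                       reads = list()) {
  introgression <- utils::modifyList(
    list(multiplier = 10, chrom = 1L,
         interval = as.integer(round(c(0.25, 0.6) * chrom_len))),
    introgression)
  ril <- utils::modifyList(
    list(n_lines = 20L, xo_mean = 2, selfing_generations = 6L), ril)
  reads <- utils::modifyList(
    list(coverage = 0.1, read_len = 150L, error_rate = 0.002, paired = TRUE,
         insert = 300L, gbs_read_len = 100L), reads)
  assert_that(repeat_fraction >= 0 && repeat_fraction <= 1,
              "repeat_fraction must be in [0, 1]")
  assert_that(all(divergence >= 0 & divergence <= 1),
              "divergence rates must be in [0, 1]")
  assert_that(introgression$interval[2] <= chrom_len,
              "introgression interval outside chromosome")
  groups <- rep_len(genome_groups, n_chroms)
  assert_that(all(groups %in% names(divergence)),
              "every genome group needs a divergence rate")
  structure(
    list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
         chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
         gene_len_range = gene_len_range, gene_gc = gene_gc,
         repeat_fraction = repeat_fraction,
         n_founders = as.integer(n_founders),
         genome_groups = groups, divergence = divergence,
         introgression = introgression, ril = ril, reads = reads),
    class = "phg_sim_config"
  )
}

sim_bases <- c("A", "C", "G", "T")

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(sim_bases, n, replace = TRUE, prob = p), collapse = "")
}

# deterministic alternate allele for a position, so the panel stays
# bi-allelic no matter which founders hit the same site
alt_for <- function(ref, pos) {
  others <- rbind(
    A = c("C", "G", "T"), C = c("A", "G", "T"),
    G = c("A", "C", "T"), T = c("A", "C", "G")
  )
  others[cbind(match(ref, rownames(others)), pos %% 3L + 1L)]
}

#' Simulate the reference genome and gene models
#'
#' Chromosomes are random sequence with `n_genes` gene islands placed one
#' per equal-width slot (guaranteeing non-overlap); a `repeat_fraction`
#' share of each intergenic stretch is overwritten with tiled copies of
#' motifs from a small library, giving the repeat-rich background that makes
#' reads outside gene space ambiguous.
#'
#' @param config A [sim_config()].
#' @return List of class `phg_sim_reference`: `genome` (named chromosome
#'   strings), `genes` (tibble `chrom`, `start`, `end`, 0-based half-open),
#'   `chrom_lengths`, `genome_groups`, `config`.
#' @export
simulate_reference <- function(config = sim_config()) {
  withr::with_seed(derive_seed(config$seed, 1L), {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    motifs <- replicate(3, random_seq(300))
    genes <- list()
    repeats <- list()
    genome <- character(config$n_chroms)
    names(genome) <- chroms
    for (ci in seq_len(config$n_chroms)) {
      len <- config$chrom_len
      seq_raw <- charToRaw(random_seq(len))
      slot <- floor(len / config$n_genes)
      glen <- sample(config$gene_len_range[1]:config$gene_len_range[2],
                     config$n_genes, replace = TRUE)
      margin <- 600L  # keeps flanked ranges inside the slot most of the time
      gstart <- (seq_len(config$n_genes) - 1L) * slot +
        floor(runif(config$n_genes) * pmax(slot - glen - 2L * margin, 1L)) +
        margin
      gend <- pmin(gstart + glen, len)
      genes[[ci]] <- tibble(chrom = chroms[ci], start = as.integer(gstart),
                            end = as.integer(gend))
      # GC-rich gene islands
      for (gi in seq_along(gstart)) {
        gseq <- charToRaw(random_seq(gend[gi] - gstart[gi], config$gene_gc))
        seq_raw[(gstart[gi] + 1L):gend[gi]] <- gseq
      }
      # repeat blocks in intergenic stretches
      bounds <- rbind(c(0L, gstart[1]),
                      cbind(gend[-config$n_genes], gstart[-1]),
                      c(gend[config$n_genes], len))
      for (b in seq_len(nrow(bounds))) {
        ilen <- bounds[b, 2] - bounds[b, 1]
        nrep <- floor(ilen * config$repeat_fraction)
        if (nrep < 1) next
        m <- motifs[[sample.int(length(motifs), 1)]]
        tiles <- strrep(m, ceiling(nrep / nchar(m)))
        block <- charToRaw(substr(tiles, 1L, nrep))
        at <- bounds[b, 1] + seq_len(nrep)
        seq_raw[at] <- block
        repeats[[length(repeats) + 1L]] <- tibble(
          chrom = chroms[ci], start = bounds[b, 1],
          end = bounds[b, 1] + nrep)
      }
      genome[ci] <- rawToChar(seq_raw)
    }
    structure(
      list(genome = genome,
           genes = bind_rows(genes),
           repeats = bind_rows(repeats),
           chrom_lengths = stats::setNames(rep(config$chrom_len,
                                               config$n_chroms), chroms),
           genome_groups = stats::setNames(config$genome_groups, chroms),
           config = config),
      class = "phg_sim_reference"
    )
  })
}

#' Simulate the founder panel
#'
#' Each founder accumulates substitutions within gene space at its genome
#' group's per-bp rate; the last founder (`donor`) additionally carries an
#' elevated-divergence haplotype over the configured introgression interval,
#' emulating a segment introgressed from a wild relative. Alternate alleles
#' are a deterministic function of position, keeping every site bi-allelic
#' across the panel.
#'
#' @param ref A [simulate_reference()] result.
#' @param config A [sim_config()]; defaults to the one inside `ref`.
#' @return Named list of founder variant tibbles (`chrom`, `pos` 1-based,
#'   `ref`, `alt`), the last named `"donor"`.
#' @export
simulate_founders <- function(ref, config = ref$config) {
  chroms <- names(ref$chrom_lengths)
  founder_names <- c(sprintf("founder%02d", seq_len(config$n_founders - 1L)),
                     "donor")
  withr::with_seed(derive_seed(config$seed, 2L), {
    out <- purrr::map(seq_len(config$n_founders), function(fi) {
      purrr::map_dfr(seq_along(chroms), function(ci) {
        cc <- chroms[ci]
        rate <- config$divergence[[ref$genome_groups[[cc]]]]
        gg <- filter(ref$genes, .data$chrom == cc)
        gene_pos <- unlist(purrr::map2(gg$start, gg$end,
                                       ~ seq.int(.x + 1L, .y)))  # 1-based
        hit <- runif(length(gene_pos)) < rate
        if (fi == config$n_founders && ci == config$introgression$chrom) {
          iv <- config$introgression$interval
          inside <- gene_pos > iv[1] & gene_pos <= iv[2]
          extra <- rate * (config$introgression$multiplier - 1)
          hit <- hit | (inside & runif(length(gene_pos)) < extra)
        }
        pos <- gene_pos[hit]
        if (!length(pos)) return(tibble(chrom = character(), pos = integer(),
                                        ref = character(), alt = character()))
        rb <- substring(ref$genome[[cc]], pos, pos)
        tibble(chrom = cc, pos = pos, ref = rb, alt = alt_for(rb, pos))
      })
    })
    stats::setNames(out, founder_names)
  })
}

#' Simulate a biparental RIL family
#'
#' Per line and chromosome the crossover count is Poisson, breakpoints are
#' uniform, and alleles are copied from the active parent; residual
#' heterozygosity after the configured selfing generations (`2^-g` per site)
#' is masked to missing, consistent with how heterozygous calls are ingested
#' into the graph. The parental-origin painting is recorded as truth.
#'
#' @param parent_a,parent_b Founder variant tibbles from
#'   [simulate_founders()].
#' @param sites Site catalog to genotype (tibble `chrom`, `pos`, `ref`,
#'   `alt`), typically the union over the founder panel.
#' @param ref A [simulate_reference()] result.
#' @param config A [sim_config()].
#' @param names_ab Labels of the two parents in the painting.
#' @param seed Seed; defaults to a stream derived from the config seed.
#' @return List of class `phg_sim_rils`: `truth` (a [genotype_matrix()] of
#'   the lines over `sites`), `painting` (tibble `line`, `chrom`, `start`,
#'   `end`, `parent`, 0-based half-open), `crossovers` (tibble `line`,
#'   `chrom`, `n_xo`).
#' @export
simulate_rils <- function(parent_a, parent_b, sites, ref,
                          config = ref$config,
                          names_ab = c("A", "B"), seed = NULL) {
  seed <- seed %||% derive_seed(config$seed, 3L)
  chrom_levels <- names(ref$chrom_lengths)
  sites <- arrange(as_tibble(sites),
                   factor(.data$chrom, levels = chrom_levels), .data$pos)
  key <- paste(sites$chrom, sites$pos)
  in_a <- key %in% paste(parent_a$chrom, parent_a$pos)
  in_b <- key %in% paste(parent_b$chrom, parent_b$pos)
  if (identical(parent_a, parent_b))
    warn("identical parents: no segregating sites")
  n <- config$ril$n_lines
  lines <- sprintf("ril%03d", seq_len(n))
  p_het <- 2^(-config$ril$selfing_generations)

  withr::with_seed(seed, {
    geno <- matrix(NA_integer_, nrow = nrow(sites), ncol = n,
                   dimnames = list(NULL, lines))
    paint <- list()
    xo <- list()
    for (li in seq_len(n)) {
      for (cc in names(ref$chrom_lengths)) {
        len <- ref$chrom_lengths[[cc]]
        k <- stats::rpois(1, config$ril$xo_mean)
        brk <- sort(floor(runif(k) * len))
        first <- sample(1:2, 1)
        edges <- c(0, brk, len)
        par_seq <- rep_len(c(first, 3L - first), k + 1L)
        paint[[length(paint) + 1L]] <- tibble(
          line = lines[li], chrom = cc,
          start = utils::head(edges, -1), end = utils::tail(edges, -1),
          parent = names_ab[par_seq]
        )
        xo[[length(xo) + 1L]] <- tibble(line = lines[li], chrom = cc,
                                        n_xo = k)
        rows <- which(sites$chrom == cc)
        if (!length(rows)) next
        seg <- findInterval(sites$pos[rows] - 1L, edges,
                            rightmost.closed = TRUE)
        seg[seg > length(par_seq)] <- length(par_seq)
        from_a <- par_seq[seg] == 1L
        geno[rows, li] <- ifelse(from_a, in_a[rows], in_b[rows])
      }
      het <- runif(nrow(sites)) < p_het
      geno[het, li] <- NA_integer_
    }
    structure(
      list(truth = genotype_matrix(sites, geno,
                                   genome_groups = ref$genome_groups),
           painting = bind_rows(paint),
           crossovers = bind_rows(xo)),
      class = "phg_sim_rils"
    )
  })
}

#' Realize a sample's haplotype genome
#'
#' Applies a set of homozygous SNP substitutions to the reference genome.
#'
#' @param ref A [simulate_reference()] result.
#' @param variants Tibble `chrom`, `pos` (1-based), `alt` (single base).
#' @return Named character vector of chromosome sequences.
#' @export
sample_sequence <- function(ref, variants) {
  genome <- ref$genome
  for (cc in unique(variants$chrom)) {
    vv <- variants[variants$chrom == cc, ]
    raw <- charToRaw(genome[[cc]])
    raw[vv$pos] <- charToRaw(paste(vv$alt, collapse = ""))
    genome[[cc]] <- rawToChar(raw)
  }
  genome
}

#' Variants carried by one simulated line
#'
#' @param rils A `phg_sim_rils`.
#' @param line Line name.
#' @return Tibble `chrom`, `pos`, `ref`, `alt` of the sites where the line
#'   carries the alternate allele (missing sites are treated as reference).
#' @export
ril_variants <- function(rils, line) {
  g <- rils$truth$geno[, line]
  rils$truth$sites[!is.na(g) & g == 1L, ]
}

#' In-silico restriction digest site list
#'
#' Finds all occurrences of `motif_a` on both strands and retains those with
#' a `motif_b` occurrence whose start lies within `max_dist` bp -- the
#' classic two-enzyme GBS site definition (PstI/MspI by default). Both
#' default motifs are palindromic, but the scan is strand-aware for
#' generality.
#'
#' @param genome Named character vector of chromosome sequences (or a
#'   `phg_sim_reference`).
#' @param motif_a Anchoring recognition motif (default PstI, `CTGCAG`).
#' @param motif_b Companion motif (default MspI, `CCGG`).
#' @param max_dist Maximum distance between motif starts (default 250).
#' @param exclude Optional tibble of 0-based half-open intervals (`chrom`,
#'   `start`, `end`); retained sites falling inside them are dropped. Passing
#'   the simulated repeat intervals emulates a methylation-sensitive enzyme
#'   that leaves the (methylated) repetitive fraction uncut -- the reason
#'   PstI-based GBS targets low-copy DNA in large plant genomes.
#' @return Tibble `chrom`, `pos` (1-based start of the retained `motif_a`
#'   occurrence), `toward` (+1/-1: direction from the site to its nearest
#'   companion motif, i.e. into the digestion fragment), sorted.
#' @export
digest_genome <- function(genome, motif_a = "CTGCAG", motif_b = "CCGG",
                          max_dist = 250L, exclude = NULL) {
  if (inherits(genome, "phg_sim_reference")) genome <- genome$genome
  assert_that(nchar(motif_a) > 0 && nchar(motif_b) > 0,
              "motifs must be non-empty")
  both_strand_starts <- function(seq, motif) {
    s <- Biostrings::DNAString(seq)
    fwd <- Biostrings::start(Biostrings::matchPattern(motif, s))
    rev <- Biostrings::start(Biostrings::matchPattern(revcomp(motif), s))
    sort(unique(c(fwd, rev)))
  }
  purrr::map_dfr(names(genome), function(cc) {
    a <- both_strand_starts(genome[[cc]], motif_a)
    b <- both_strand_starts(genome[[cc]], motif_b)
    if (!length(a) || !length(b))
      return(tibble(chrom = character(), pos = integer(),
                    toward = integer()))
    nearest <- vapply(a, function(p) b[which.min(abs(b - p))], numeric(1))
    keep <- abs(nearest - a) <= max_dist
    # fragment runs from the anchoring site toward its companion site
    tibble(chrom = cc, pos = as.integer(a[keep]),
           toward = as.integer(sign(nearest[keep] - a[keep])))
  }) |>
    arrange(.data$chrom, .data$pos) -> sites
  if (!is.null(exclude) && nrow(sites)) {
    masked <- purrr::map_lgl(seq_len(nrow(sites)), function(i) {
      ex <- exclude[exclude$chrom == sites$chrom[i], ]
      any(sites$pos[i] - 1L >= ex$start & sites$pos[i] - 1L < ex$end)
    })
    sites <- sites[!masked, ]
  }
  sites
}

#' Simulate a read set for one sample
#'
#' Protocols: `capture` draws paired fragments whose start is uniform within
#' the informative reference ranges only (exome-capture-like); `gbs` anchors
#' single-end reads at restriction digest sites (random strand); `skim`
#' draws paired fragments uniformly genome-wide, repeat background included.
#' Per-base substitution errors at `error_rate`. The read count comes from
#' [reads_for_coverage()] of the protocol's own target size (total range bp,
#' site count times read length, or genome size) unless `n_reads` overrides
#' it.
#'
#' @param sample_genome Named chromosome sequences from [sample_sequence()].
#' @param protocol `"capture"`, `"gbs"` or `"skim"`.
#' @param config A [sim_config()].
#' @param ranges Reference ranges (required for `capture`).
#' @param digest_sites Digest site tibble (required for `gbs`).
#' @param coverage Depth; defaults to `config$reads$coverage`.
#' @param n_reads Optional explicit read (pair) count.
#' @param seed Seed; defaults to a stream derived from the config seed.
#' @return Read tibble `id`, `seq1`, `qual1` (and `seq2`, `qual2` for paired
#'   protocols) with attribute `target_bp`.
#' @export
simulate_reads <- function(sample_genome, protocol = c("capture", "gbs", "skim"),
                           config, ranges = NULL, digest_sites = NULL,
                           coverage = NULL, n_reads = NULL, seed = NULL) {
  protocol <- match.arg(protocol)
  seed <- seed %||% derive_seed(config$seed, 4L)
  coverage <- coverage %||% config$reads$coverage
  rl <- if (protocol == "gbs") config$reads$gbs_read_len else config$reads$read_len
  paired <- protocol != "gbs" && isTRUE(config$reads$paired)
  insert <- max(config$reads$insert, rl)
  chrom_len <- nchar(sample_genome)

  target <- switch(protocol,
    capture = {
      assert_that(!is.null(ranges), "capture protocol needs ranges")
      sum(ranges$end - ranges$start)
    },
    gbs = {
      assert_that(!is.null(digest_sites), "gbs protocol needs digest_sites")
      gbs_target_size(nrow(digest_sites), rl)
    },
    skim = sum(chrom_len)
  )
  n <- n_reads %||% reads_for_coverage(target, coverage, rl, paired)
  if (n < 1) {
    warn("coverage yields zero reads")
    return(empty_reads(paired))
  }

  withr::with_seed(seed, {
    if (protocol == "capture") {
      w <- ranges$end - ranges$start
      ri <- sample.int(nrow(ranges), n, replace = TRUE, prob = w)
      chrom <- ranges$chrom[ri]
      start0 <- ranges$start[ri] +
        floor(runif(n) * pmax(w[ri] - 1L, 1L))  # 0-based fragment start
      start0 <- pmin(start0, chrom_len[chrom] - insert)
      start0 <- pmax(start0, 0L)
    } else if (protocol == "skim") {
      chrom <- sample(names(sample_genome), n, replace = TRUE,
                      prob = chrom_len)
      start0 <- floor(runif(n) * pmax(chrom_len[chrom] - insert, 1L))
    } else {
      si <- sample.int(nrow(digest_sites), n, replace = TRUE)
      chrom <- digest_sites$chrom[si]
      # reads run from the anchoring site into the fragment, toward the
      # companion site (minus reads are reported on the sequenced strand)
      minus <- (digest_sites$toward[si] %||% rep(1L, n)) < 0
      start0 <- ifelse(minus,
                       pmax(digest_sites$pos[si] - rl, 0L),
                       digest_sites$pos[si] - 1L)
      start0 <- pmin(start0, chrom_len[chrom] - rl)
      start0 <- pmax(start0, 0L)
    }

    seq1 <- substring(sample_genome[chrom], start0 + 1L, start0 + rl)
    if (protocol == "gbs")
      seq1 <- ifelse(minus, revcomp(seq1), seq1)
    seq1 <- add_read_errors(seq1, config$reads$error_rate)
    reads <- tibble(
      id = sprintf("%s_read%06d", protocol, seq_len(n)),
      seq1 = seq1, qual1 = strrep("I", nchar(seq1))
    )
    if (paired) {
      m_end <- start0 + insert
      seq2 <- revcomp(substring(sample_genome[chrom], m_end - rl + 1L, m_end))
      seq2 <- add_read_errors(seq2, config$reads$error_rate)
      reads$seq2 <- seq2
      reads$qual2 <- strrep("I", nchar(seq2))
    }
    attr(reads, "target_bp") <- target
    reads
  })
}

empty_reads <- function(paired) {
  out <- tibble(id = character(), seq1 = character(), qual1 = character())
  if (paired) {
    out$seq2 <- character()
    out$qual2 <- character()
  }
  out
}

add_read_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    raw <- charToRaw(seqs[i])
    at <- sample.int(length(raw), n_err[i])
    for (a in at) {
      cur <- rawToChar(raw[a])
      raw[a] <- charToRaw(sample(setdiff(sim_bases, cur), 1))
    }
    seqs[i] <- rawToChar(raw)
  }
  seqs
}

#' Write reads to FASTQ
#'
#' @param reads Read tibble from [simulate_reads()].
#' @param path1 First-mate FASTQ path (gzipped if ending in `.gz`).
#' @param path2 Optional mate path for paired tables.
#' @export
write_fastq <- function(reads, path1, path2 = NULL) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = grepl("\\.gz$", path))
  }
  wr(reads$seq1, reads$qual1, reads$id, path1)
  if (!is.null(path2) && "seq2" %in% names(reads))
    wr(reads$seq2, reads$qual2, reads$id, path2)
  invisible(path1)
}

#' Read FASTQ into a read tibble
#'
#' @param path1 First-mate FASTQ.
#' @param path2 Optional mate FASTQ.
#' @return Read tibble `id`, `seq1`, `qual1` (and mate columns).
#' @export
read_fastq <- function(path1, path2 = NULL) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  out <- tibble(
    id = names(r1),
    seq1 = unname(as.character(r1)),
    qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities))
  )
  if (!is.null(path2)) {
    r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                       with.qualities = TRUE)
    out$seq2 <- unname(as.character(r2))
    out$qual2 <- unname(as.character(S4Vectors::mcols(r2)$qualities))
  }
  out
}

#' Union site catalog of a founder panel
#'
#' @param founders Named list from [simulate_founders()].
#' @param chrom_order Chromosome ordering for the catalog.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, deduplicated and sorted.
#' @export
panel_sites <- function(founders, chrom_order = NULL) {
  out <- bind_rows(founders) |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
  lv <- chrom_order %||% sort(unique(out$chrom))
  arrange(out, factor(.data$chrom, levels = lv), .data$pos)
}
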