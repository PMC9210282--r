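test_that("the simulated reference is seed-deterministic with gene islands", {
  cfg <- sim_config(seed = 5, n_chroms = 2, n_genes = 10, chrom_len = 50000L)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$genome, r2$genome)
  expect_identical(r1$genes, r2$genes)
  # gene count and bounds
  expect_equal(nrow(r1$genes), 20L)
  expect_true(all(r1$genes$end <= 50000L & r1$genes$start >= 0L))
  # genes non-overlapping per chromosome
  for (cc in unique(r1$genes$chrom)) {
    gg <- dplyr::filter(r1$genes, chrom == cc)
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  # a different seed changes the sequence
  r3 <- simulate_reference(sim_config(seed = 6, n_chroms = 2, n_genes = 10,
                                      chrom_len = 50000L))
  expect_false(identical(r1$genome, r3$genome))
})

test_that("repeat_fraction zero leaves intergenic sequence unique", {
  cfg0 <- sim_config(seed = 5, n_chroms = 1, n_genes = 5, chrom_len = 30000L,
                     repeat_fraction = 0)
  cfg4 <- sim_config(seed = 5, n_chroms = 1, n_genes = 5, chrom_len = 30000L,
                     repeat_fraction = 0.5)
  dup_frac <- function(ref) {
    km <- canonical_kmers(ref$genome[[1]], 21)
    mean(duplicated(km))
  }
  expect_lt(dup_frac(simulate_reference(cfg0)), 0.001)
  expect_gt(dup_frac(simulate_reference(cfg4)), 0.2)
})

test_that("founder divergence follows configured rates and the donor stands out", {
  cfg <- sim_config(seed = 3)
  ref <- simulate_reference(cfg)
  founders <- simulate_founders(ref)
  expect_equal(names(founders)[cfg$n_founders], "donor")

  # zero divergence -> founders identical to the reference
  cfg0 <- sim_config(seed = 3, divergence = c(A = 0, D = 0),
                     introgression = list(multiplier = 1))
  f0 <- simulate_founders(simulate_reference(cfg0), cfg0)
  expect_true(all(vapply(f0, nrow, integer(1)) == 0L))

  # Poisson oracle: per-seed variant count near rate x that seed's gene bp
  dev <- vapply(1:10, function(s) {
    cfgs <- sim_config(seed = 100 + s)
    refs <- simulate_reference(cfgs)
    gene_bp <- refs$genes |>
      dplyr::mutate(len = end - start) |>
      dplyr::group_by(chrom) |>
      dplyr::summarise(bp = sum(len))
    lam <- sum(cfgs$divergence[unname(refs$genome_groups[gene_bp$chrom])] *
                 gene_bp$bp)
    c(nrow(simulate_founders(refs)$founder01) - lam, lam)
  }, numeric(2))
  expect_lt(abs(mean(dev[1, ])), 3 * sqrt(mean(dev[2, ]) / 10))

  # donor pairwise distance on the introgression interval exceeds background
  iv <- cfg$introgression$interval
  on_iv <- function(v) sum(v$chrom == "chr1" & v$pos > iv[1] & v$pos <= iv[2])
  donor_n <- on_iv(founders$donor)
  others_n <- vapply(founders[1:5], on_iv, numeric(1))
  expect_gt(donor_n, max(others_n) * 3)
})

test_that("RILs are parental mosaics with recorded painting", {
  cfg <- sim_config(seed = 4, ril = list(n_lines = 30L))
  ref <- simulate_reference(cfg)
  founders <- simulate_founders(ref)
  sites <- panel_sites(founders, names(ref$chrom_lengths))
  rils <- simulate_rils(founders$founder01, founders$founder02, sites, ref,
                        names_ab = c("founder01", "founder02"))

  # painting segment count = crossovers + 1
  segs <- rils$painting |>
    dplyr::count(line, chrom, name = "n_seg") |>
    dplyr::inner_join(rils$crossovers, by = c("line", "chrom"))
  expect_equal(segs$n_seg, segs$n_xo + 1L)

  # every genotype is one of the parents' alleles (mosaic property)
  in_a <- paste(sites$chrom, sites$pos) %in%
    paste(founders$founder01$chrom, founders$founder01$pos)
  in_b <- paste(sites$chrom, sites$pos) %in%
    paste(founders$founder02$chrom, founders$founder02$pos)
  g <- rils$truth$geno
  for (li in 1:5) {
    gl <- g[, li]
    ok <- is.na(gl) | gl == in_a | gl == in_b
    expect_true(all(ok))
  }

  # residual heterozygosity mask near 2^-generations
  expect_equal(mean(is.na(g)), 2^-cfg$ril$selfing_generations,
               tolerance = 0.3)

  # crossover mean zero -> whole-chromosome parental haplotypes
  cfg0 <- sim_config(seed = 4, ril = list(n_lines = 5L, xo_mean = 0))
  rils0 <- simulate_rils(founders$founder01, founders$founder02, sites, ref,
                         config = cfg0, names_ab = c("a", "b"))
  expect_true(all(rils0$crossovers$n_xo == 0L))
  expect_equal(nrow(rils0$painting), 5L * 2L)
})

test_that("segregating sites approach frequency one half in a large family", {
  cfg <- sim_config(seed = 8, ril = list(n_lines = 200L))
  ref <- simulate_reference(cfg)
  founders <- simulate_founders(ref)
  sites <- panel_sites(founders, names(ref$chrom_lengths))
  rils <- simulate_rils(founders$founder01, founders$founder02, sites, ref)
  seg <- paste(sites$chrom, sites$pos) %in%
    paste(founders$founder01$chrom, founders$founder01$pos)
  seg <- xor(seg, paste(sites$chrom, sites$pos) %in%
               paste(founders$founder02$chrom, founders$founder02$pos))
  freqs <- rowMeans(rils$truth$geno[seg, ] == 1L, na.rm = TRUE)
  # binomial tolerance: average allele frequency ~ 0.5, and the bulk of
  # sites inside a generous binomial band (sites on one chromosome are
  # correlated through shared crossovers, so no independence assumed)
  expect_equal(mean(freqs), 0.5, tolerance = 0.05)
  expect_gt(mean(abs(freqs - 0.5) < 4 * sqrt(0.25 / 200)), 0.8)
})

test_that("in-silico digestion matches a naive full-scan oracle", {
  # hand-built cases
  g1 <- c(chr1 = paste0(strrep("A", 30), "CTGCAG", strrep("A", 50), "CCGG",
                        strrep("A", 30)))
  expect_equal(nrow(digest_genome(g1)), 1L)
  g2 <- c(chr1 = paste0("CTGCAG", strrep("A", 400), "CCGG"))
  expect_equal(nrow(digest_genome(g2)), 0L)

  # random sequence vs brute-force scan
  withr::with_seed(51, {
    s <- paste(sample(c("A", "C", "G", "T"), 100000, TRUE,
                      prob = c(.3, .2, .2, .3)), collapse = "")
    got <- digest_genome(c(chrZ = s))
    scan <- function(seq, motif) {
      rc <- revcomp(motif)
      w <- nchar(motif)
      subs <- substring(seq, 1:(nchar(seq) - w + 1), w:nchar(seq))
      which(subs == motif | subs == rc)
    }
    a <- scan(s, "CTGCAG"); b <- scan(s, "CCGG")
    want <- a[vapply(a, function(p) any(abs(b - p) <= 250), logical(1))]
    expect_equal(got$pos, want)
  })
})

test_that("simulated reads honor protocol anchoring and the coverage formula", {
  fx <- pipeline_fixture(1)
  cfg0 <- sim_config(seed = 1, reads = list(error_rate = 0))
  sg <- sample_sequence(fx$ref, fx$founders$founder01)

  reads <- simulate_reads(sg, "capture", cfg0, ranges = fx$ranges)
  expect_equal(nrow(reads),
               reads_for_coverage(sum(fx$ranges$end - fx$ranges$start),
                                  0.1, 150, paired = TRUE))
  # error-free capture reads are exact substrings of the sample's genome
  joined <- paste(sg, collapse = "|")
  for (i in 1:20) expect_true(grepl(reads$seq1[i], joined, fixed = TRUE))
  expect_true(all(nchar(reads$seq1) == 150L))
  expect_true(!is.null(reads$seq2))

  # GBS reads anchor at digest sites
  dig <- digest_genome(fx$ref$genome)
  gbs <- simulate_reads(sg, "gbs", cfg0, digest_sites = dig, n_reads = 50)
  expect_false("seq2" %in% names(gbs))
  expect_true(all(nchar(gbs$seq1) == 100L))
  anchored <- vapply(gbs$seq1, function(rd) {
    hit <- grepl(rd, joined, fixed = TRUE) ||
      grepl(revcomp(rd), joined, fixed = TRUE)
    hit
  }, logical(1))
  expect_true(all(anchored))

  # skim reads draw genome-wide
  skim <- simulate_reads(sg, "skim", cfg0, n_reads = 40)
  expect_equal(nrow(skim), 40L)

  # determinism per seed
  r1 <- simulate_reads(sg, "capture", cfg0, ranges = fx$ranges, seed = 9)
  r2 <- simulate_reads(sg, "capture", cfg0, ranges = fx$ranges, seed = 9)
  expect_identical(r1, r2)
})

test_that("FASTQ round trip preserves reads", {
  withr::with_seed(52, {
    reads <- tibble::tibble(
      id = sprintf("r%02d", 1:8),
      seq1 = vapply(1:8, function(i)
        paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""),
        character(1)),
      qual1 = strrep("I", 30))
    f <- withr::local_tempfile(fileext = ".fq.gz")
    write_fastq(reads, f)
    back <- read_fastq(f)
    expect_equal(back, reads)
  })
})
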