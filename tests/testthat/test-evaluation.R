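test_that("coverage arithmetic reproduces the published read counts", {
  expect_equal(reads_for_coverage(170e6, 0.01, 150, paired = TRUE), 5667L)
  expect_equal(reads_for_coverage(170e6, 0.1, 150, paired = TRUE), 56667L)
  expect_equal(reads_for_coverage(170e6, 0.5, 150, paired = TRUE), 283333L)
  # single-end doubles the count
  expect_equal(reads_for_coverage(170e6, 0.01, 150, paired = FALSE), 11333L)
  expect_error(reads_for_coverage(0, 0.1, 150), "positive")
})

test_that("read requirements grow with coverage and target size", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      t1 <- stats::runif(1, 1e6, 1e9); c1 <- stats::runif(1, 0.01, 2)
      expect_lte(reads_for_coverage(t1, c1, 150),
                 reads_for_coverage(t1, c1 * 1.5, 150))
      expect_lte(reads_for_coverage(t1, c1, 150),
                 reads_for_coverage(t1 * 2, c1, 150))
    }
  })
})

test_that("GBS target size arithmetic matches the published estimate", {
  expect_equal(gbs_target_size(1960000, 100), 196e6)
  expect_equal(gbs_target_size(0, 100), 0)
  expect_equal(gbs_target_size(3, 100), 300)
})

test_that("down-sampling is deterministic, order-preserving and bounded", {
  reads <- tibble::tibble(
    id = sprintf("r%03d", 1:50),
    seq1 = strrep("ACGT", 10), qual1 = strrep("I", 40),
    seq2 = strrep("TGCA", 10), qual2 = strrep("I", 40))

  expect_identical(downsample_reads(reads, 50, seed = 1), reads)
  expect_equal(nrow(downsample_reads(reads, 0, seed = 1)), 0L)
  s1 <- downsample_reads(reads, 20, seed = 7)
  s2 <- downsample_reads(reads, 20, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(diff(match(s1$id, reads$id)) > 0))  # order preserved
  expect_error(downsample_reads(reads, 51, seed = 1), "only 50")

  # file-level wrapper keeps pairs together and is byte-identical per seed
  d <- withr::local_tempdir()
  write_fastq(reads, file.path(d, "in_1.fq"), file.path(d, "in_2.fq"))
  downsample_fastq(file.path(d, "in_1.fq"), file.path(d, "a_1.fq"), 10, 3,
                   in2 = file.path(d, "in_2.fq"), out2 = file.path(d, "a_2.fq"))
  downsample_fastq(file.path(d, "in_1.fq"), file.path(d, "b_1.fq"), 10, 3,
                   in2 = file.path(d, "in_2.fq"), out2 = file.path(d, "b_2.fq"))
  expect_identical(readLines(file.path(d, "a_1.fq")),
                   readLines(file.path(d, "b_1.fq")))
  a1 <- read_fastq(file.path(d, "a_1.fq"), file.path(d, "a_2.fq"))
  expect_equal(nrow(a1), 10L)
  # pairs stay together: mate columns match the originals for each id
  orig <- reads[match(a1$id, reads$id), ]
  expect_equal(a1$seq2, orig$seq2)
})

test_that("concordance counts matches over non-missing overlapped calls", {
  imp <- tibble::tibble(chrom = "chr1", pos = 1:10, ref = "A", alt = "T",
                        gt = c(rep(1L, 9), 0L))
  tru <- dplyr::mutate(imp, gt = rep(1L, 10))
  cc <- concordance(imp, tru, accession = "x")
  expect_equal(accuracy(cc), 0.9)
  expect_equal(glance(cc)$n_overlap, 10L)

  expect_equal(accuracy(concordance(imp, imp)), 1)

  # missing on either side drops the site from both counts
  imp2 <- dplyr::mutate(imp, gt = dplyr::if_else(pos <= 2, NA_integer_, 1L))
  cc2 <- concordance(imp2, tru)
  expect_equal(glance(cc2)$n_overlap, 8L)

  # alleles must match, not just positions
  tru_swap <- dplyr::mutate(tru, ref = "T", alt = "A")
  expect_error(concordance(imp, tru_swap), "no overlapping")
  expect_error(concordance(imp, dplyr::mutate(tru, pos = pos + 100L)),
               "no overlapping")
})

test_that("stratified accuracy partitions the overlap and flags empty strata", {
  imp <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 10),
                        pos = rep(1:10, 2), ref = "A", alt = "T",
                        gt = 1L)
  tru <- dplyr::mutate(imp,
                       gt = dplyr::if_else(dplyr::row_number() <= 2, 0L, 1L))
  maf <- dplyr::mutate(imp[, 1:4],
                       maf = rep(c(0.05, 0.45), 10))
  cc <- concordance(imp, tru)
  st <- stratified_accuracy(cc, maf,
                            genome_groups = c(chr1 = "A", chr2 = "D"))
  bins <- dplyr::filter(st, stratum_type == "maf", stratum != ">0.1")
  expect_equal(sum(bins$n_overlap), glance(cc)$n_overlap)
  grp <- dplyr::filter(st, stratum_type == "genome")
  expect_equal(sum(grp$n_overlap), glance(cc)$n_overlap)
  # empty strata are undefined, not zero
  expect_true(all(is.na(bins$accuracy[bins$n_overlap == 0])))
  expect_true(all(bins$n_overlap[bins$stratum %in%
                                   c("0.1-0.2", "0.2-0.3", "0.3-0.4")] == 0))
  # single-bin degenerate case: stratum accuracy equals overall accuracy
  maf_one <- dplyr::mutate(maf, maf = 0.05)
  st1 <- stratified_accuracy(cc, maf_one)
  expect_equal(st1$accuracy[st1$stratum == "0-0.1"], accuracy(cc))
})

test_that("errors injected at rare sites depress the rare-bin accuracy", {
  withr::with_seed(42, {
    n_sites <- 400
    maf_vals <- rep(c(0.05, 0.3), each = n_sites / 2)
    truth_gt <- sample(0:1, n_sites, TRUE)
    # imputation errs on 30% of rare sites, 5% of common sites
    err <- ifelse(maf_vals < 0.1, stats::runif(n_sites) < 0.3,
                  stats::runif(n_sites) < 0.05)
    sites <- tibble::tibble(chrom = "chr1", pos = seq_len(n_sites),
                            ref = "A", alt = "T")
    imp <- dplyr::mutate(sites, gt = ifelse(err, 1L - truth_gt, truth_gt))
    tru <- dplyr::mutate(sites, gt = truth_gt)
    st <- stratified_accuracy(concordance(imp, tru),
                              dplyr::mutate(sites, maf = maf_vals))
    acc <- function(b) st$accuracy[st$stratum == b]
    expect_lt(acc("0-0.1"), acc("0.2-0.3"))
    expect_lt(acc("0-0.1"), acc(">0.1"))
  })
})

test_that("high-quality SNP filtering applies MAF and missingness rules", {
  # site 1: MAF 0.01 -> removed; site 2: exactly 10% missing -> removed;
  # site 3: passes
  g <- rbind(
    c(1L, rep(0L, 99)),
    c(rep(0L, 10) * NA, rep(c(0L, 1L), 45)),
    rep(c(0L, 1L), 50)
  )
  g[2, 1:10] <- NA_integer_
  colnames(g) <- paste0("s", 1:100)
  gm <- genotype_matrix(
    tibble::tibble(chrom = "chr1", pos = 1:3, ref = "A", alt = "T"), g)
  kept <- filter_hq_snps(gm, maf_min = 0.015, max_missing = 0.10)
  expect_equal(kept$sites$pos, 3L)

  # recount oracle over a random fixture
  withr::with_seed(43, {
    n_sites <- 100; n_samp <- 40
    geno <- matrix(sample(c(0L, 1L, NA), n_sites * n_samp, TRUE,
                          c(.6, .3, .1)), nrow = n_sites,
                   dimnames = list(NULL, paste0("s", 1:n_samp)))
    pos <- sort(sample.int(1e5, n_sites))
    gm2 <- genotype_matrix(
      tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "T"), geno)
    kept2 <- filter_hq_snps(gm2)
    oracle <- sum(vapply(seq_len(n_sites), function(i) {
      a <- geno[i, ]; ns <- sum(!is.na(a))
      if (ns == 0) return(FALSE)
      p <- sum(a == 1L, na.rm = TRUE) / ns
      min(p, 1 - p) >= 0.015 && (n_samp - ns) / n_samp < 0.10
    }, logical(1)))
    expect_equal(nrow(kept2$sites), oracle)
  })
})
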