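test_that("pi reproduces hand-computable cases and the pairwise oracle", {
  # 2 samples differing at 1 site over a 100 bp span -> 0.01
  calls <- rbind(c(0L, 1L), c(0L, 0L))
  expect_equal(nucleotide_diversity(calls, c(1L, 100L)), 0.01)
  # identical samples -> 0
  expect_equal(nucleotide_diversity(rbind(c(1L, 1L)), c(5L, NA)[1]), 0)

  withr::with_seed(31, {
    for (rep in 1:10) {
      calls <- matrix(sample(c(0L, 1L, NA), 20 * 6, TRUE, c(.45, .45, .1)),
                      nrow = 20)
      pos <- sort(sample.int(5000L, 20))
      expect_equal(nucleotide_diversity(calls, pos), pi_oracle(calls, pos),
                   tolerance = 1e-12)
      expect_gte(nucleotide_diversity(calls, pos), 0)
      # invariant under sample reordering
      expect_equal(nucleotide_diversity(calls[, sample(6)], pos),
                   nucleotide_diversity(calls, pos), tolerance = 1e-12)
    }
  })
})

test_that("Tajima's D matches the direct-formula oracle", {
  # no segregating sites -> undefined
  expect_true(is.na(tajimas_d(matrix(0L, 5, 6))))
  # fewer than 4 sequences -> undefined
  expect_true(is.na(tajimas_d(matrix(c(0L, 1L), 2, 3))))

  withr::with_seed(32, {
    for (rep in 1:10) {
      calls <- matrix(sample(c(0L, 1L), 50 * 8, TRUE, c(.7, .3)), nrow = 50)
      expect_equal(tajimas_d(calls), tajima_oracle(calls), tolerance = 1e-9)
    }
    # with scattered missing data the same definition is applied
    calls <- matrix(sample(c(0L, 1L, NA), 50 * 8, TRUE, c(.6, .3, .1)),
                    nrow = 50)
    expect_equal(tajimas_d(calls), tajima_oracle(calls), tolerance = 1e-9)
  })
})

test_that("D vanishes when pairwise diversity equals S over a1", {
  # n=4, a1 = 1 + 1/2 + 1/3; one site with one singleton: khat = S/a1
  # requires khat = 2p(1-p)n/(n-1); construct: 2 haplotype pairs at freq 1/2
  calls <- matrix(c(0L, 0L, 1L, 1L), nrow = 1)  # p = .5: khat = 2/3
  # S = 1, S/a1 = 1/1.8333 = 0.5454...; not zero -> just check sign logic
  d <- tajimas_d(calls)
  expect_true(d > 0)  # khat 0.667 > S/a1 0.545
  # and a singleton-heavy fixture drives D negative
  calls2 <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
                  c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L),
                  c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_true(tajimas_d(calls2) < 0)
})

test_that("sliding windows are defined by SNP count with bp-span pi", {
  withr::with_seed(33, {
    geno <- matrix(sample(c(0L, 1L), 25 * 6, TRUE), nrow = 25,
                   dimnames = list(NULL, paste0("s", 1:6)))
    sites <- tibble::tibble(chrom = "chr1", pos = sort(sample.int(9000L, 25)),
                            ref = "A", alt = "T")
    gm <- genotype_matrix(sites, geno)
    w <- diversity_windows(gm, window_snps = 10L, step_snps = 5L)
    expect_equal(w$first, c(1L, 6L, 11L, 16L))
    expect_equal(w$n_snps, rep(10L, 4))
    expect_equal(w$pi[1],
                 nucleotide_diversity(geno[1:10, ], sites$pos[1:10]))
    expect_equal(w$tajima_d[2], tajimas_d(geno[6:15, ]), tolerance = 1e-12)
  })
})

test_that("MAF spectrum bins fold frequencies and count exclusions", {
  calls <- rbind(
    c(1L, rep(0L, 9)),        # MAF 0.1 -> first bin
    c(rep(1L, 5), rep(0L, 5)),# MAF 0.5 -> last bin
    rep(0L, 10),              # monomorphic, MAF 0
    rep(NA_integer_, 10)      # all missing -> excluded
  )
  sp <- maf_spectrum(calls)
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$maf, c(0.1, 0.5, 0))
  expect_equal(as.character(sp$bin), c("0-0.1", "0.4-0.5", "0-0.1"))
  expect_equal(attr(sp, "n_excluded"), 1L)
})

test_that("r2 matches the contingency-table oracle", {
  withr::with_seed(34, {
    for (rep in 1:10) {
      geno <- matrix(sample(c(0L, 1L, NA), 5 * 20, TRUE, c(.5, .4, .1)),
                     nrow = 5)
      for (i in 1:4) for (j in (i + 1):5) {
        got <- r2_one_vs_many(geno[i, ], cbind(geno[j, ]))
        want <- r2_oracle(geno[i, ], geno[j, ])
        if (is.na(want)) expect_true(is.na(got))
        else expect_equal(got, want, tolerance = 1e-9)
      }
    }
  })
})

test_that("LD decay reports duplicated sites at r2 one and finds half-decay", {
  withr::with_seed(35, {
    n_samp <- 20
    base <- sample(c(0L, 1L), n_samp, TRUE)
    # tight block of identical sites + far-away independent noise
    sites <- tibble::tibble(
      chrom = "chr1",
      pos = c(100L, 200L, 300L, 700000L, 800000L, 900000L),
      ref = "A", alt = "T")
    geno <- rbind(base, base, base,
                  sample(c(0L, 1L), n_samp, TRUE),
                  sample(c(0L, 1L), n_samp, TRUE),
                  sample(c(0L, 1L), n_samp, TRUE))
    dimnames(geno) <- list(NULL, paste0("s", seq_len(n_samp)))
    gm <- genotype_matrix(sites, geno)
    ld <- ld_decay(gm, max_dist = 1e6, bin_width = 1e5)
    expect_equal(ld$mean_r2[1], 1)  # the identical-site bin
    expect_equal(attr(ld, "initial_r2"), 1)
    expect_false(is.na(attr(ld, "half_decay_bp")))
    # orthogonal sites: r2 = 0
    x <- c(rep(0L, 10), rep(1L, 10))
    y <- rep(c(0L, 1L), 10)
    expect_equal(r2_one_vs_many(x, cbind(y)), 0, tolerance = 1e-12)
  })
})

test_that("LD pruning removes later correlated sites and survives an audit", {
  withr::with_seed(36, {
    # two adjacent identical sites: the second goes
    base <- sample(c(0L, 1L), 12, TRUE)
    gm <- genotype_matrix(
      tibble::tibble(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T"),
      rbind(s = base, base) |> `colnames<-`(paste0("x", 1:12)) |> `rownames<-`(NULL))
    expect_equal(ld_prune(gm), 1L)

    # orthogonal sites all survive
    gm2 <- genotype_matrix(
      tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                     ref = "A", alt = "T"),
      matrix(c(0L,0L,1L,1L, 0L,1L,0L,1L, 0L,1L,1L,0L, 1L,1L,1L,1L),
             nrow = 4, byrow = TRUE,
             dimnames = list(NULL, paste0("x", 1:4))))
    expect_equal(ld_prune(gm2), 1:4)

    # 120 correlated sites against an exhaustive per-window re-scan oracle
    n_samp <- 30
    blocks <- purrr::map(1:12, function(b) {
      anchor <- sample(c(0L, 1L), n_samp, TRUE)
      purrr::map(1:10, function(i) {
        flip <- stats::runif(n_samp) < 0.15
        ifelse(flip, 1L - anchor, anchor)
      })
    })
    geno <- do.call(rbind, purrr::flatten(blocks))
    gm3 <- genotype_matrix(
      tibble::tibble(chrom = "chr1", pos = seq_len(120L) * 50L,
                     ref = "A", alt = "T"),
      `colnames<-`(geno, paste0("x", 1:n_samp)))
    got <- ld_prune(gm3, 0.6, 50L, 10L)

    keep <- rep(TRUE, 120)
    for (s in seq(1L, 119L, by = 10L)) {
      win <- s:min(s + 49L, 120L)
      for (i in win) {
        if (!keep[i]) next
        for (j in win[win > i]) {
          if (!keep[j]) next
          r2 <- r2_oracle(geno[i, ], geno[j, ])
          if (!is.na(r2) && r2 >= 0.6) keep[j] <- FALSE
        }
      }
    }
    expect_equal(got, which(keep))

    # postcondition audit: no surviving within-window pair at or above 0.6
    for (s in seq(1L, 119L, by = 10L)) {
      win <- intersect(s:min(s + 49L, 120L), got)
      if (length(win) < 2) next
      for (a in seq_along(win)[-length(win)]) {
        r2 <- r2_one_vs_many(geno[win[a], ],
                             t(geno[win[-(1:a)], , drop = FALSE]))
        expect_true(all(is.na(r2) | r2 < 0.6))
      }
    }
  })
})
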