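#' Nucleotide diversity of a window
#'
#' Per-bp pairwise diversity: for each site the average pairwise difference
#' among the non-missing samples, `2 p (1 - p) n / (n - 1)` with per-site
#' non-missing count `n` and alternate frequency `p`, summed over sites and
#' divided by the spanned bp (`last - first + 1`). Sites with fewer than two
#' non-missing calls contribute nothing.
#'
#' @param calls Integer matrix, sites x samples (0/1/`NA`).
#' @param positions 1-based positions of the sites (same order).
#' @return Pi per bp (scalar).
#' @export
nucleotide_diversity <- function(calls, positions) {
  assert_that(nrow(calls) == length(positions),
              "calls and positions disagree")
  span <- max(positions) - min(positions) + 1
  assert_that(span > 0, "window span must be positive")
  per_site <- site_pairwise_diversity(calls)
  sum(per_site) / span
}

# per-site average pairwise difference among non-missing calls
site_pairwise_diversity <- function(calls) {
  n1 <- rowSums(calls == 1L, na.rm = TRUE)
  ns <- rowSums(!is.na(calls))
  out <- numeric(nrow(calls))
  ok <- ns >= 2
  p <- n1[ok] / ns[ok]
  out[ok] <- 2 * p * (1 - p) * ns[ok] / (ns[ok] - 1)
  out
}

#' Tajima's D of a window
#'
#' The classical neutrality statistic contrasting the mean pairwise
#' difference with the segregating-sites estimator of theta, using the
#' standard a1, a2, b1, b2, c1, c2, e1, e2 constants for `n` sequences
#' (`n = ncol(calls)`). Returns `NA` when there are no segregating sites or
#' fewer than four sequences.
#'
#' @param calls Integer matrix, sites x samples (0/1/`NA`).
#' @return Tajima's D, or `NA` when undefined.
#' @export
tajimas_d <- function(calls) {
  n <- ncol(calls)
  if (n < 4) return(NA_real_)
  n1 <- rowSums(calls == 1L, na.rm = TRUE)
  ns <- rowSums(!is.na(calls))
  seg <- n1 > 0 & n1 < ns & ns >= 2
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  khat <- sum(site_pairwise_diversity(calls))

  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Sliding-window diversity summaries
#'
#' Windows are defined by SNP count, not bp: `window_snps` sites per window
#' stepping `step_snps` sites, per chromosome. Pi is reported per bp of the
#' window's spanned positions. A chromosome with fewer sites than one window
#' yields a single window over all its sites.
#'
#' @param gm A [genotype_matrix()].
#' @param window_snps Sites per window (default 2000).
#' @param step_snps Step between window starts in sites (default 1000).
#' @return Tibble `chrom`, `first`, `last` (site indices within chromosome),
#'   `start`, `end` (bp), `n_snps`, `S`, `pi`, `tajima_d`, of class
#'   `phg_divwin`.
#' @export
diversity_windows <- function(gm, window_snps = 2000L, step_snps = 1000L) {
  out <- purrr::map_dfr(unique(gm$sites$chrom), function(cc) {
    idx <- which(gm$sites$chrom == cc)
    ns <- length(idx)
    starts <- if (ns <= window_snps) 1L
              else seq(1L, ns - window_snps + 1L, by = step_snps)
    purrr::map_dfr(starts, function(s) {
      e <- min(s + window_snps - 1L, ns)
      rows <- idx[s:e]
      calls <- gm$geno[rows, , drop = FALSE]
      pos <- gm$sites$pos[rows]
      n1 <- rowSums(calls == 1L, na.rm = TRUE)
      nn <- rowSums(!is.na(calls))
      tibble(
        chrom = cc, first = s, last = e,
        start = min(pos), end = max(pos), n_snps = e - s + 1L,
        S = sum(n1 > 0 & n1 < nn & nn >= 2),
        pi = nucleotide_diversity(calls, pos),
        tajima_d = tajimas_d(calls)
      )
    })
  })
  class(out) <- c("phg_divwin", class(out))
  out
}

#' Minor allele frequency spectrum
#'
#' Per-site MAF over non-missing calls, with the binned summary used for
#' stratified reporting: bins `[0, 0.1]`, `(0.1, 0.2]`, ..., `(0.4, 0.5]`.
#' All-missing sites are excluded and counted.
#'
#' @param calls Integer matrix, sites x samples, or a [genotype_matrix()].
#' @return Tibble `site`, `maf`, `bin` with attribute `bin_counts` (named
#'   vector) and `n_excluded`.
#' @export
maf_spectrum <- function(calls) {
  if (inherits(calls, "phg_geno")) calls <- calls$geno
  n1 <- rowSums(calls == 1L, na.rm = TRUE)
  ns <- rowSums(!is.na(calls))
  keep <- ns > 0
  p <- n1[keep] / ns[keep]
  maf <- pmin(p, 1 - p)
  bin <- maf_bin(maf)
  out <- tibble(site = which(keep), maf = maf, bin = bin)
  attr(out, "bin_counts") <- table(bin)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

maf_bin_levels <- c("0-0.1", "0.1-0.2", "0.2-0.3", "0.3-0.4", "0.4-0.5")

maf_bin <- function(maf) {
  cut(maf, breaks = seq(0, 0.5, by = 0.1), include.lowest = TRUE,
      right = TRUE, labels = maf_bin_levels)
}

# squared Pearson correlation between one site and several, over samples
# non-missing at both sites; monomorphic pairs give NA
r2_one_vs_many <- function(x, Y) {
  suppressWarnings(
    as.numeric(stats::cor(x, Y, use = "pairwise.complete.obs"))^2
  )
}

#' LD decay with half-decay distance
#'
#' Computes r-squared (squared Pearson correlation of allele codes over
#' samples non-missing at both sites) for all intra-chromosomal site pairs
#' within `max_dist`, bins pairs by distance, and reports the distance at
#' which mean r-squared first drops to half of its initial value -- the
#' initial value being the mean of the first distance bin.
#'
#' @param gm A [genotype_matrix()].
#' @param max_dist Maximum pair distance in bp (default 1e6).
#' @param bin_width Distance bin width in bp (default 1e5).
#' @return Tibble `bin_mid`, `mean_r2`, `n_pairs` of class `phg_ld`, with
#'   attributes `initial_r2` and `half_decay_bp` (`NA` if never reached).
#' @export
ld_decay <- function(gm, max_dist = 1e6, bin_width = 1e5) {
  dists <- numeric(0)
  r2s <- numeric(0)
  for (cc in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == cc)
    if (length(idx) < 2) next
    pos <- gm$sites$pos[idx]
    X <- t(gm$geno[idx, , drop = FALSE])
    hi <- findInterval(pos + max_dist, pos)
    for (i in seq_along(idx)[-length(idx)]) {
      j <- if (hi[i] > i) (i + 1):hi[i] else integer(0)
      if (!length(j)) next
      r2 <- r2_one_vs_many(X[, i], X[, j, drop = FALSE])
      dists <- c(dists, pos[j] - pos[i])
      r2s <- c(r2s, r2)
    }
  }
  keep <- !is.na(r2s)
  dists <- dists[keep]; r2s <- r2s[keep]
  bin <- pmin(floor(dists / bin_width), ceiling(max_dist / bin_width) - 1)
  out <- tibble(bin = bin, r2 = r2s) |>
    group_by(.data$bin) |>
    summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$bin) |>
    transmute(bin_mid = (.data$bin + 0.5) * bin_width,
              mean_r2 = .data$mean_r2, n_pairs = .data$n_pairs)
  initial <- out$mean_r2[1] %||% NA_real_
  below <- which(out$mean_r2 <= initial / 2)
  half <- if (length(below)) out$bin_mid[below[1]] else NA_real_
  structure(out, initial_r2 = initial, half_decay_bp = half,
            class = c("phg_ld", class(out)))
}

#' LD-based marker pruning
#'
#' Greedy window scan: within each `window_snps`-site window (per
#' chromosome, stepping by `step_snps`), pairs are scanned in order and the
#' later site of any pair with r-squared at or above the threshold is
#' removed; removals persist across windows.
#'
#' @param gm A [genotype_matrix()].
#' @param r2_threshold Removal threshold (default 0.6).
#' @param window_snps Window size in sites (default 50).
#' @param step_snps Step in sites (default 10).
#' @return Integer vector of retained site indices (rows of `gm$sites`).
#' @export
ld_prune <- function(gm, r2_threshold = 0.6, window_snps = 50L,
                     step_snps = 10L) {
  keep <- rep(TRUE, nrow(gm$sites))
  for (cc in unique(gm$sites$chrom)) {
    idx <- which(gm$sites$chrom == cc)
    n <- length(idx)
    X <- t(gm$geno[idx, , drop = FALSE])
    starts <- seq(1L, max(n - 1L, 1L), by = step_snps)
    for (s in starts) {
      win <- s:min(s + window_snps - 1L, n)
      for (a in seq_along(win)[-length(win)]) {
        i <- win[a]
        if (!keep[idx[i]]) next
        js <- win[(a + 1):length(win)]
        js <- js[keep[idx[js]]]
        if (!length(js)) next
        r2 <- r2_one_vs_many(X[, i], X[, js, drop = FALSE])
        drop <- js[!is.na(r2) & r2 >= r2_threshold]
        keep[idx[drop]] <- FALSE
      }
    }
  }
  which(keep)
}
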