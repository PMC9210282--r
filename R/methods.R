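#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.phg_graph <- function(x, ...) {
  g <- glance(x)
  cat("<phg_graph>\n")
  cat(sprintf("  %d informative ranges on %d chromosome(s), %d taxa\n",
              g$n_ranges, g$n_chroms, g$n_taxa))
  cat(sprintf("  %d consensus haplotypes (%.1f per range), %d catalogued sites\n",
              g$n_haplotypes, g$mean_haps_per_range, g$n_sites))
  invisible(x)
}

#' Graph-level summary statistics
#'
#' @param x A `phg_graph`.
#' @param ... Unused.
#' @return One-row tibble: range, haplotype, site and taxa totals plus the
#'   mean haplotypes per informative range and mean ranges per chromosome.
#' @export
glance.phg_graph <- function(x, ...) {
  n_ranges <- sum(x$ranges$informative)
  n_chroms <- dplyr::n_distinct(x$ranges$chrom)
  tibble(
    n_ranges = n_ranges,
    n_chroms = n_chroms,
    n_haplotypes = nrow(x$haps),
    n_sites = nrow(x$sites),
    n_taxa = length(x$taxa),
    mean_haps_per_range = haplotypes_per_range(nrow(x$haps), n_ranges),
    mean_ranges_per_chrom = ranges_per_chromosome(nrow(x$ranges), n_chroms)
  )
}

#' Haplotype table of a graph
#'
#' @param x A `phg_graph`.
#' @param ... Unused.
#' @return Tibble with one row per consensus haplotype: `range_id`,
#'   `hap_id`, `n_taxa` and comma-separated member `taxa`.
#' @export
tidy.phg_graph <- function(x, ...) {
  x$haps |>
    transmute(.data$range_id, .data$hap_id, .data$n_taxa,
              taxa = purrr::map_chr(.data$taxa, paste, collapse = ","))
}

#' @export
print.phg_evidence <- function(x, ...) {
  ct <- attr(x, "counts")
  cat(sprintf("<phg_evidence> %d reads in: %d assigned, %d no-hit, %d multi-range, %d short, %d pair-conflict\n",
              ct$input, ct$assigned, ct$no_hits, ct$multi_range,
              ct$too_short, ct$pair_conflict))
  NextMethod()
}

#' Mapping summary counts
#' @param x A `phg_evidence`.
#' @param ... Unused.
#' @return One-row tibble of read-fate totals.
#' @export
glance.phg_evidence <- function(x, ...) {
  as_tibble(attr(x, "counts"))
}

#' Path summary
#' @param x A `phg_path`.
#' @param ... Unused.
#' @return One-row tibble: chromosome, ranges traversed, distinct
#'   haplotypes, total path log-probability.
#' @export
glance.phg_path <- function(x, ...) {
  tibble(
    chrom = x$chrom[1],
    n_ranges = nrow(x),
    n_distinct_haps = dplyr::n_distinct(x$hap_id),
    total_loglik = attr(x, "total_loglik")
  )
}

#' @export
print.phg_accuracy <- function(x, ...) {
  cat(sprintf("<phg_accuracy> %s: %d/%d concordant (%.4f)\n",
              attr(x, "accession") %||% "sample",
              attr(x, "n_match"), attr(x, "n_overlap"),
              attr(x, "accuracy")))
  invisible(x)
}

#' Concordance summary
#' @param x A `phg_accuracy`.
#' @param ... Unused.
#' @return One-row tibble `accession`, `n_overlap`, `n_match`, `accuracy`.
#' @export
glance.phg_accuracy <- function(x, ...) {
  tibble(
    accession = attr(x, "accession") %||% NA_character_,
    n_overlap = attr(x, "n_overlap"),
    n_match = attr(x, "n_match"),
    accuracy = attr(x, "accuracy")
  )
}

#' @rdname glance.phg_accuracy
#' @export
accuracy <- function(x) attr(x, "accuracy")

#' Plot LD decay
#'
#' Mean r-squared per distance bin with the half-decay distance marked.
#'
#' @param object A `phg_ld` from [ld_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phg_ld <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$bin_mid, y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Distance (bp)", y = expression(mean ~ r^2),
                  title = "LD decay")
  hd <- attr(object, "half_decay_bp")
  if (!is.na(hd))
    p <- p + ggplot2::geom_vline(xintercept = hd, linetype = "dashed")
  p
}

#' Plot sliding-window diversity
#'
#' @param object A `phg_divwin` from [diversity_windows()].
#' @param statistic `"pi"` or `"tajima_d"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phg_divwin <- function(object, statistic = c("pi", "tajima_d"), ...) {
  statistic <- match.arg(statistic)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data[[statistic]])) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Window midpoint (bp)",
                  y = if (statistic == "pi") expression(pi ~ "per bp")
                      else "Tajima's D")
}

#' Plot a MAF spectrum
#'
#' @param maf_tbl Output of [maf_spectrum()].
#' @return A ggplot object.
#' @export
plot_maf_spectrum <- function(maf_tbl) {
  ggplot2::ggplot(as_tibble(maf_tbl), ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "Minor allele frequency bin", y = "Sites")
}

#' Plot stratified accuracy
#'
#' @param strata Output of [stratified_accuracy()].
#' @return A ggplot object.
#' @export
plot_stratified_accuracy <- function(strata) {
  ggplot2::ggplot(dplyr::filter(strata, !is.na(.data$accuracy)),
                  ggplot2::aes(x = .data$stratum, y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~stratum_type, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Concordance accuracy")
}

#' @export
ggplot2::autoplot
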