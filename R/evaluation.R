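#' Read count needed for a target coverage
#'
#' Number of reads (read pairs when `paired`) whose total bases give the
#' requested depth over a sequencing target, rounded to the nearest integer:
#' `coverage * target_bp / (read_len * 2)` for paired-end data. With a
#' 170 Mb exome-capture target and 2 x 150 bp reads this yields 5,667 /
#' 56,667 / 283,333 pairs for 0.01x / 0.1x / 0.5x.
#'
#' @param target_bp Size of the sequenced target space in bp.
#' @param coverage Desired depth (x).
#' @param read_len Bases per read.
#' @param paired Whether a sequencing unit is a read pair (2 reads).
#' @return Integer read (pair) count.
#' @export
reads_for_coverage <- function(target_bp, coverage, read_len, paired = TRUE) {
  assert_that(target_bp > 0 && coverage > 0 && read_len > 0,
              "target_bp, coverage and read_len must be positive")
  as.integer(round_half_up(coverage * target_bp /
                             (read_len * (if (paired) 2 else 1))))
}

#' GBS sequencing target size
#'
#' Estimated target space of a restriction-site-anchored (GBS) assay: the
#' number of retained recognition sites times the read length (1.96 million
#' retained PstI sites x 100 bp reads gives the 196 Mb wheat estimate).
#'
#' @param n_sites Number of retained restriction sites.
#' @param read_len Read length in bp.
#' @return Target size in bp.
#' @export
gbs_target_size <- function(n_sites, read_len) {
  assert_that(n_sites >= 0, "n_sites must be >= 0")
  n_sites * read_len
}

#' Down-sample a read table
#'
#' Uniform sampling without replacement, preserving input order; paired
#' tables (columns `seq2`/`qual2`) are sampled as pairs. Deterministic for a
#' given `(seed, input)`.
#'
#' @param reads Read tibble (from [simulate_reads()] or [read_fastq()]).
#' @param n Number of reads (pairs) to keep.
#' @param seed Integer seed.
#' @return The subset tibble.
#' @export
downsample_reads <- function(reads, n, seed) {
  total <- nrow(reads)
  if (n > total)
    abort(sprintf("requested %d reads but input has only %d", n, total))
  if (n == total) return(reads)
  idx <- sort(withr::with_seed(seed, sample.int(total, n)))
  reads[idx, , drop = FALSE]
}

#' Down-sample FASTQ files
#'
#' File-level wrapper around [downsample_reads()]; mate files are sampled
#' with the same indices.
#'
#' @param in1,out1 Input/output FASTQ for the first mate.
#' @param n Number of reads (pairs) to keep.
#' @param seed Integer seed.
#' @param in2,out2 Optional mate FASTQ paths.
#' @export
downsample_fastq <- function(in1, out1, n, seed, in2 = NULL, out2 = NULL) {
  reads <- read_fastq(in1, in2)
  sub <- downsample_reads(reads, n, seed)
  write_fastq(sub, out1, out2)
  invisible(out1)
}

#' Genotype concordance between imputed and truth calls
#'
#' Joins the two call sets on (chrom, pos, ref, alt) -- site identity
#' requires matching alleles, not just position -- keeps sites non-missing
#' in both, and scores the fraction of identical genotype calls.
#'
#' @param imputed Tibble `chrom`, `pos`, `ref`, `alt`, `gt` (e.g. from
#'   [emit_genotypes()]).
#' @param truth Same layout, or a `phg_geno` plus `sample`.
#' @param accession Label carried into the report.
#' @param sample Sample to extract when `truth` is a `phg_geno`.
#' @return A `phg_accuracy` object: the per-site comparison tibble
#'   (`chrom`, `pos`, `ref`, `alt`, `gt_imputed`, `gt_truth`, `match`) with
#'   attributes `accession`, `n_overlap`, `n_match`, `accuracy`.
#' @export
concordance <- function(imputed, truth, accession = NULL, sample = NULL) {
  if (inherits(truth, "phg_geno"))
    truth <- geno_calls(truth, sample %||% accession)
  cmp <- inner_join(
    imputed |> select("chrom", "pos", "ref", "alt", gt_imputed = "gt"),
    truth |> select("chrom", "pos", "ref", "alt", gt_truth = "gt"),
    by = c("chrom", "pos", "ref", "alt")
  ) |>
    filter(!is.na(.data$gt_imputed), !is.na(.data$gt_truth)) |>
    mutate(match = .data$gt_imputed == .data$gt_truth)
  if (!nrow(cmp)) abort("no overlapping genotype calls")
  structure(cmp,
            accession = accession %||% attr(imputed, "taxon"),
            n_overlap = nrow(cmp),
            n_match = sum(cmp$match),
            accuracy = mean(cmp$match),
            class = c("phg_accuracy", class(cmp)))
}

#' Accuracy stratified by database MAF and genome group
#'
#' Recomputes concordance within minor-allele-frequency bins (frequencies
#' taken from the graph database, see [graph_site_maf()]), including the
#' pooled `>0.1` stratum, and within genome groups when a chromosome-group
#' mapping is given. Empty strata report `NA` accuracy, not zero.
#'
#' @param conc A `phg_accuracy` from [concordance()].
#' @param site_maf Tibble `chrom`, `pos`, `ref`, `alt`, `maf` (e.g.
#'   [graph_site_maf()] output). Every overlapped site must be present.
#' @param genome_groups Optional named character vector chromosome -> group.
#' @return Tibble `stratum_type`, `stratum`, `n_overlap`, `n_match`,
#'   `accuracy`.
#' @export
stratified_accuracy <- function(conc, site_maf, genome_groups = NULL) {
  joined <- conc |>
    as_tibble() |>
    left_join(site_maf |> select("chrom", "pos", "ref", "alt", "maf"),
              by = c("chrom", "pos", "ref", "alt"))
  assert_that(!anyNA(joined$maf), "MAF missing for some overlapped sites")
  joined$bin <- maf_bin(joined$maf)

  by_bin <- joined |>
    group_by(bin = factor(.data$bin, levels = maf_bin_levels)) |>
    summarise(n_overlap = dplyr::n(), n_match = sum(.data$match),
              .groups = "drop") |>
    tidyr::complete(bin = factor(maf_bin_levels, levels = maf_bin_levels),
                    fill = list(n_overlap = 0L, n_match = 0L)) |>
    transmute(stratum_type = "maf", stratum = as.character(.data$bin),
              .data$n_overlap, .data$n_match)
  gt01 <- joined |> filter(.data$maf > 0.1)
  by_bin <- bind_rows(
    by_bin,
    tibble(stratum_type = "maf", stratum = ">0.1",
           n_overlap = nrow(gt01), n_match = sum(gt01$match))
  )

  out <- by_bin
  if (!is.null(genome_groups)) {
    by_grp <- joined |>
      mutate(group = unname(genome_groups[.data$chrom])) |>
      group_by(.data$group) |>
      summarise(n_overlap = dplyr::n(), n_match = sum(.data$match),
                .groups = "drop") |>
      transmute(stratum_type = "genome", stratum = .data$group,
                .data$n_overlap, .data$n_match)
    out <- bind_rows(out, by_grp)
  }
  out |>
    mutate(accuracy = ifelse(.data$n_overlap > 0,
                             .data$n_match / .data$n_overlap, NA_real_))
}

#' Filter to high-quality SNPs
#'
#' Retains sites with minor allele frequency at or above `maf_min` and a
#' missing-call fraction strictly below `max_missing` -- the filter used to
#' define a truth set for concordance scoring.
#'
#' @param gm A `phg_geno`.
#' @param maf_min Minimum MAF (default 0.015).
#' @param max_missing Missing fraction must be `<` this value (default 0.10).
#' @return The filtered `phg_geno`.
#' @export
filter_hq_snps <- function(gm, maf_min = 0.015, max_missing = 0.10) {
  n1 <- rowSums(gm$geno == 1L, na.rm = TRUE)
  ns <- rowSums(!is.na(gm$geno))
  miss <- (ncol(gm$geno) - ns) / ncol(gm$geno)
  p <- ifelse(ns > 0, n1 / ns, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min & miss < max_missing
  genotype_matrix(gm$sites[keep, ], gm$geno[keep, , drop = FALSE],
                  gm$genome_groups)
}
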