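#' Genotype matrix container
#'
#' Light container for multi-sample bi-allelic genotypes: a site table plus
#' an integer site-by-sample matrix of allele codes (0 = ref, 1 = alt,
#' `NA` = missing). Positions are 1-based and strictly increasing within
#' chromosome. An optional genome-group label per chromosome (e.g. the A/B/D
#' subgenomes of wheat) supports stratified summaries.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @param geno Integer matrix, `nrow(sites)` x samples, with sample names as
#'   column names.
#' @param genome_groups Optional named character vector mapping chromosome
#'   name to group label.
#' @return An object of class `phg_geno`.
#' @export
genotype_matrix <- function(sites, geno, genome_groups = NULL) {
  sites <- as_tibble(sites)
  assert_that(nrow(sites) == nrow(geno), "sites and geno disagree in length")
  assert_that(!is.null(colnames(geno)), "geno needs sample column names")
  ok <- sites |>
    group_by(.data$chrom) |>
    summarise(sorted = all(diff(.data$pos) > 0), .groups = "drop")
  assert_that(all(ok$sorted),
              "positions must be strictly increasing within chromosome")
  structure(
    list(sites = sites, geno = geno, samples = colnames(geno),
         genome_groups = genome_groups),
    class = "phg_geno"
  )
}

#' Extract one sample's calls as a site-call tibble
#'
#' @param gm A `phg_geno`.
#' @param sample Sample name.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `gt`.
#' @export
geno_calls <- function(gm, sample) {
  assert_that(sample %in% gm$samples, paste0("unknown sample ", sample))
  gm$sites |>
    mutate(gt = unname(gm$geno[, sample]))
}

#' Write genotypes to VCF
#'
#' Accepts either a single-sample imputed genotype tibble (from
#' [emit_genotypes()]) or a `phg_geno` matrix. Genotypes are written as
#' homozygous diploid calls (`0/0`, `1/1`, `./.`): the panels are inbred.
#'
#' @param x Genotype tibble or `phg_geno`.
#' @param path Output path (written gzipped, `.vcf.gz`).
#' @param sample Sample name for the single-sample form.
#' @param chrom_lengths Optional named vector for `##contig` headers.
#' @export
write_vcf <- function(x, path, sample = NULL, chrom_lengths = NULL) {
  if (inherits(x, "phg_geno")) {
    sites <- x$sites
    gt <- x$geno
  } else {
    sites <- x[, c("chrom", "pos", "ref", "alt")]
    gt <- matrix(x$gt, ncol = 1,
                 dimnames = list(NULL, sample %||% attr(x, "taxon") %||% "SAMPLE"))
  }
  code <- function(a) dplyr::case_when(is.na(a) ~ "./.",
                                       a == 0L ~ "0/0",
                                       TRUE ~ "1/1")
  gtc <- apply(gt, 2, code)
  if (is.null(dim(gtc))) gtc <- matrix(gtc, ncol = ncol(gt),
                                       dimnames = list(NULL, colnames(gt)))
  write_vcf_table(sites$chrom, sites$pos, sites$ref, sites$alt,
                  info = ".", gt = gtc, path = path,
                  chrom_lengths = chrom_lengths)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Keeps bi-allelic records; heterozygous and missing calls both become
#' `NA` allele codes.
#'
#' @param path Path to `.vcf`/`.vcf.gz`.
#' @param genome_groups Optional chromosome-to-group mapping.
#' @return A `phg_geno`.
#' @export
read_vcf_genotypes <- function(path, genome_groups = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT) & fix$ALT != "."
  gt_raw <- vcfR::extract.gt(v)
  gt <- apply(gt_raw[keep, , drop = FALSE], 2, parse_gt)
  if (is.null(dim(gt)))
    gt <- matrix(gt, ncol = ncol(gt_raw), dimnames = list(NULL, colnames(gt_raw)))
  sites <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  genotype_matrix(sites, gt, genome_groups)
}
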