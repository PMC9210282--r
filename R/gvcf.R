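#' gVCF-style record tables
#'
#' Per-taxon variant calls are carried as plain tibbles with one row per
#' record and columns:
#' \describe{
#'   \item{chrom}{chromosome name}
#'   \item{pos}{1-based position (VCF convention)}
#'   \item{ref}{reference allele}
#'   \item{alt}{alternate allele, `NA` for a reference block}
#'   \item{end}{1-based inclusive end of a reference block (`NA` for variants)}
#'   \item{gt}{allele code: 0 = ref, 1 = alt, `NA` = missing or heterozygous}
#' }
#' Reference blocks assert that the taxon matches the reference over
#' `[pos, end]`. Heterozygous source calls are stored as missing: the panels
#' this graph targets are inbred lines, where residual heterozygous calls are
#' most likely artifacts.
#'
#' @name gvcf_records
NULL

#' Read a gVCF-like VCF into a record table
#'
#' Honors the `END` INFO key for reference blocks. Heterozygous and missing
#' genotypes both become `NA` allele codes.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file with one sample.
#' @return A [gvcf_records] tibble.
#' @export
read_gvcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  end <- suppressWarnings(as.integer(vcfR::extract.info(v, "END")))
  gt_raw <- vcfR::extract.gt(v)[, 1]
  gt <- unname(parse_gt(gt_raw))
  tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = ifelse(fix$ALT %in% c(".", "", "<NON_REF>") | is.na(fix$ALT),
                 NA_character_, fix$ALT),
    end = end,
    gt = gt
  )
}

# "0/0" -> 0, "1/1" or "1|1" -> 1, het or missing -> NA
parse_gt <- function(x) {
  a <- sub("^([0-9.]+)[/|]([0-9.]+)$", "\\1,\\2", x)
  parts <- strsplit(a, ",", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1L) p <- c(p, p)  # haploid call
    if (any(p == ".") || anyNA(p)) return(NA_integer_)
    p <- suppressWarnings(as.integer(p))
    if (anyNA(p) || p[1] != p[2]) return(NA_integer_)
    p[1]
  }, integer(1))
}

#' Convert a variant list to gVCF-style records with reference blocks
#'
#' Fills the gaps between a taxon's variant positions with reference blocks
#' spanning each chromosome end to end, yielding the record table
#' [ingest_taxon_calls()] expects for a fully genotyped taxon.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`;
#'   every row is a homozygous alternate call.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return A [gvcf_records] tibble sorted by (chrom, pos).
#' @export
as_gvcf_records <- function(variants, chrom_lengths) {
  purrr::map_dfr(names(chrom_lengths), function(cc) {
    len <- chrom_lengths[[cc]]
    vv <- variants |>
      filter(.data$chrom == cc) |>
      arrange(.data$pos)
    bounds <- c(0L, vv$pos, len + 1L)
    blocks <- tibble(
      chrom = cc,
      pos = utils::head(bounds, -1) + 1L,
      ref = "N", alt = NA_character_,
      end = utils::tail(bounds, -1) - 1L,
      gt = 0L
    ) |>
      filter(.data$end >= .data$pos)
    vars <- tibble(chrom = cc, pos = vv$pos, ref = vv$ref, alt = vv$alt,
                   end = NA_integer_, gt = 1L)
    bind_rows(blocks, vars) |> arrange(.data$pos)
  })
}

#' Write gVCF-style records to a VCF file
#'
#' @param records A [gvcf_records] tibble.
#' @param path Output path (`.vcf.gz`).
#' @param taxon Sample name for the single genotype column.
#' @param chrom_lengths Named vector used to emit `##contig` headers.
#' @export
write_gvcf <- function(records, path, taxon = "SAMPLE", chrom_lengths = NULL) {
  rec <- arrange(as_tibble(records), .data$chrom, .data$pos)
  is_block <- !is.na(rec$end)
  info <- ifelse(is_block, paste0("END=", rec$end), ".")
  gtc <- dplyr::case_when(
    is.na(rec$gt) ~ "./.",
    rec$gt == 0L ~ "0/0",
    TRUE ~ "1/1"
  )
  write_vcf_table(
    chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
    alt = ifelse(is.na(rec$alt), ".", rec$alt),
    info = info, gt = matrix(gtc, ncol = 1, dimnames = list(NULL, taxon)),
    path = path, chrom_lengths = chrom_lengths
  )
}

# shared low-level VCF writer built on vcfR
write_vcf_table <- function(chrom, pos, ref, alt, info, gt, path,
                            chrom_lengths = NULL) {
  meta <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End of reference block">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(chrom_lengths)) {
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(chrom_lengths), as.integer(chrom_lengths)))
  }
  fix <- cbind(
    CHROM = as.character(chrom), POS = as.character(pos),
    ID = ".", REF = ref, ALT = alt, QUAL = ".", FILTER = "PASS", INFO = info
  )
  gt_mat <- cbind(FORMAT = "GT", gt)
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt_mat)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Ingest one taxon's calls into per-range raw haplotypes
#'
#' Assigns variant records to the informative reference range containing
#' them and records reference-block coverage per range. Records overlapping
#' no informative range are skipped and counted. Downstream, a position in a
#' range is read as: the called allele if a variant record covers it, the
#' reference allele if a reference block covers it, missing otherwise.
#'
#' @param records A [gvcf_records] tibble, sorted by position within
#'   chromosome.
#' @param ranges Reference ranges from [build_reference_ranges()].
#' @param taxon Accession name.
#' @return A tibble of variant calls with columns `taxon`, `range_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `allele`, carrying attributes
#'   `covered` (per-range 0-based coverage intervals) and `n_skipped`.
#' @export
ingest_taxon_calls <- function(records, ranges, taxon) {
  rec <- arrange(as_tibble(records), .data$chrom, .data$pos)
  vars <- filter(rec, is.na(.data$end))
  blocks <- filter(rec, !is.na(.data$end))

  if (nrow(vars)) {
    bad <- !grepl("^[ACGTN]+$", vars$alt) | !grepl("^[ACGTN]+$", vars$ref)
    if (any(bad))
      abort(paste0("malformed allele in record at ",
                   vars$chrom[bad][1], ":", vars$pos[bad][1]))
  }

  rid <- locate_ranges(vars$chrom, vars$pos - 1L, ranges)
  n_skipped <- sum(is.na(rid))
  calls <- tibble(
    taxon = as.character(taxon),
    range_id = as.integer(rid[!is.na(rid)]),
    chrom = as.character(vars$chrom[!is.na(rid)]),
    pos = as.integer(vars$pos[!is.na(rid)]),
    ref = as.character(vars$ref[!is.na(rid)]),
    alt = as.character(vars$alt[!is.na(rid)]),
    allele = as.integer(vars$gt[!is.na(rid)])
  )

  # intersect reference blocks with ranges (0-based half-open)
  cov <- purrr::map_dfr(unique(blocks$chrom), function(cc) {
    bb <- filter(blocks, .data$chrom == cc)
    rr <- filter(ranges, .data$chrom == cc)
    if (!nrow(rr) || !nrow(bb)) return(tibble())
    hits <- purrr::map_dfr(seq_len(nrow(rr)), function(i) {
      s <- pmax(bb$pos - 1L, rr$start[i])
      e <- pmin(bb$end, rr$end[i])
      keep <- s < e
      tibble(range_id = rr$range_id[i], cov_start = s[keep], cov_end = e[keep])
    })
    hits
  })
  if (!nrow(cov))
    cov <- tibble(range_id = integer(), cov_start = integer(),
                  cov_end = integer())
  block_hit <- if (nrow(blocks)) {
    # count blocks touching no range
    touched <- purrr::map_lgl(seq_len(nrow(blocks)), function(i) {
      rr <- ranges[ranges$chrom == blocks$chrom[i], ]
      any(pmax(blocks$pos[i] - 1L, rr$start) < pmin(blocks$end[i], rr$end))
    })
    sum(!touched)
  } else 0L
  attr(calls, "covered") <- mutate(cov, taxon = taxon)
  attr(calls, "n_skipped") <- n_skipped + block_hit
  attr(calls, "taxon") <- as.character(taxon)
  calls
}
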