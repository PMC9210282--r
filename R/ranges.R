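#' Build gene-anchored reference ranges
#'
#' Extends each gene model by `flank_bp` in both directions, clamps the
#' extended intervals to the chromosome, and merges intervals that overlap or
#' whose boundaries lie within `merge_gap_bp` of each other. The resulting
#' disjoint intervals are the informative reference ranges -- the columns of
#' the haplotype graph. Intergenic sequence is not stored: reads landing
#' outside informative ranges are ignored downstream.
#'
#' All coordinates are 0-based, half-open. Chromosomes are ordered as they
#' appear in `chrom_lengths`.
#'
#' @param gene_models Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open gene intervals).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param flank_bp Bases added on each side of a gene model (default 500).
#' @param merge_gap_bp Extended intervals separated by at most this many bases
#'   are merged into one range (default 500).
#' @return A tibble with columns `chrom`, `start`, `end`, `range_id`
#'   (dense integer ordered by chromosome then start) and `informative`.
#' @examples
#' build_reference_ranges(
#'   tibble::tibble(chrom = "chr1", start = c(1000, 2400), end = c(2000, 3000)),
#'   c(chr1 = 10000)
#' )
#' @export
build_reference_ranges <- function(gene_models, chrom_lengths,
                                   flank_bp = 500, merge_gap_bp = 500) {
  gm <- as_tibble(gene_models)
  assert_that(all(c("chrom", "start", "end") %in% names(gm)),
              "gene_models needs columns chrom, start, end")
  assert_that(flank_bp >= 0 && merge_gap_bp >= 0,
              "flank_bp and merge_gap_bp must be non-negative")
  if (any(gm$end <= gm$start))
    abort("gene model with end <= start")
  bad <- setdiff(unique(gm$chrom), names(chrom_lengths))
  if (length(bad))
    abort(paste0("gene models on unknown chromosome(s): ",
                 paste(bad, collapse = ", ")))
  lens <- chrom_lengths[gm$chrom]
  if (any(gm$start < 0) || any(gm$end > lens))
    abort("gene model outside chromosome bounds")

  ext <- gm |>
    mutate(
      start = pmax(.data$start - flank_bp, 0),
      end = pmin(.data$end + flank_bp, unname(chrom_lengths[.data$chrom])),
      chrom = factor(.data$chrom, levels = names(chrom_lengths))
    ) |>
    arrange(.data$chrom, .data$start, .data$end)

  merged <- ext |>
    group_by(.data$chrom) |>
    mutate(
      grp = cumsum(.data$start >
                     dplyr::lag(cummax(.data$end), default = -Inf) + merge_gap_bp)
    ) |>
    group_by(.data$chrom, .data$grp) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    transmute(
      chrom = as.character(.data$chrom),
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      range_id = dplyr::row_number(),
      informative = TRUE
    )
  merged
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 import keeps records of type `"gene"` and converts to 0-based
#' half-open coordinates; BED is taken as-is (already 0-based half-open,
#' first three columns).
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"gff3"` or `"bed"`; guessed from the extension by default.
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "gff3"
  }
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      abort("rtracklayer is required to read GFF3")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[!is.na(gr$type) & gr$type == "gene"]
    tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    )
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    tibble(chrom = as.character(df[[1]]),
           start = as.integer(df[[2]]),
           end = as.integer(df[[3]]))
  }
}

#' Write reference ranges as BED
#'
#' @param ranges Range tibble from [build_reference_ranges()].
#' @param path Output path.
#' @export
write_ranges_bed <- function(ranges, path) {
  utils::write.table(
    ranges[, c("chrom", "start", "end", "range_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# locate containing range for 0-based positions; returns range_id or NA
locate_ranges <- function(chrom, pos0, ranges) {
  out <- rep(NA_integer_, length(pos0))
  for (cc in unique(chrom)) {
    rr <- ranges[ranges$chrom == cc, ]
    sel <- which(chrom == cc)
    if (!nrow(rr)) next
    idx <- findInterval(pos0[sel], rr$start)
    hit <- idx >= 1 & idx <= nrow(rr)
    hit[hit] <- pos0[sel][hit] < rr$end[idx[hit]]
    out[sel[hit]] <- rr$range_id[idx[hit]]
  }
  out
}
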