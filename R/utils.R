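#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom methods new
#' @importClassesFrom vcfR vcfR
#' @import dplyr
NULL

# round half away from zero; R's round() is banker's
round_half_up <- function(x) floor(x + 0.5)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# derive a stream seed from a master seed; keeps within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}

`%+na%` <- function(a, b) ifelse(is.na(a), b, a)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
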