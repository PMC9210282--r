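# Direct-formula oracles shared by the popgen unit tests and the
# acceptance checks.

# explicit pair-enumeration oracle for pi
pi_oracle <- function(calls, positions) {
  span <- max(positions) - min(positions) + 1
  total <- 0
  for (s in seq_len(nrow(calls))) {
    a <- calls[s, ]
    a <- a[!is.na(a)]
    if (length(a) < 2) next
    diffs <- 0; pairs <- 0
    for (i in seq_along(a)[-length(a)]) for (j in (i + 1):length(a)) {
      pairs <- pairs + 1
      diffs <- diffs + (a[i] != a[j])
    }
    total <- total + diffs / pairs
  }
  total / span
}

# direct transcription of the published D formula
tajima_oracle <- function(calls) {
  n <- ncol(calls)
  S <- 0; khat <- 0
  for (s in seq_len(nrow(calls))) {
    a <- calls[s, ]; a <- a[!is.na(a)]
    if (length(a) < 2) next
    if (length(unique(a)) > 1) S <- S + 1
    diffs <- 0; pairs <- 0
    for (i in seq_along(a)[-length(a)]) for (j in (i + 1):length(a)) {
      pairs <- pairs + 1; diffs <- diffs + (a[i] != a[j])
    }
    khat <- khat + diffs / pairs
  }
  if (S == 0 || n < 4) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# 2x2 contingency-table r2 oracle: D^2 / (p1 q1 p2 q2)
r2_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  p1 <- mean(x); p2 <- mean(y)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(NA_real_)
  D <- mean(x == 1 & y == 1) - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

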