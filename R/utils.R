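# Internal helpers shared across modules.

# Single-linkage clustering of 1-D positions: members joined while the gap to
# the previous (sorted) position is <= max_gap. Returns an integer cluster id
# per input element (original order preserved).
cluster_1d <- function(pos, max_gap) {
  if (length(pos) == 0L) return(integer(0L))
  o <- order(pos)
  id_sorted <- cumsum(c(1L, as.integer(diff(pos[o]) > max_gap)))
  id <- integer(length(pos))
  id[o] <- id_sorted
  id
}

# Overlap length of 1-based inclusive intervals (vectorised).
overlap_len <- function(a_lo, a_hi, b_lo, b_hi) {
  pmax(0L, pmin(a_hi, b_hi) - pmax(a_lo, b_lo) + 1L)
}

# Distance from a point to a 1-based inclusive interval; 0 when inside.
point_interval_dist <- function(pos, lo, hi) {
  pmax(0L, pmax(lo - pos, pos - hi))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Truncated-at-zero normal draws via inverse CDF.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

# Wilson score interval for a binomial proportion (no continuity correction).
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Phred-scale conversions for genotype qualities
#'
#' `phred()` converts an error probability to the phred scale
#' (\eqn{-10 \log_{10} p}); `phred_to_accuracy()` gives the accuracy implied
#' by a phred-scaled genotype quality, \eqn{1 - 10^{-GQ/10}} (e.g. GQ 10
#' implies 90\% accuracy).
#'
#' @param p_err error probability in \[0, 1\].
#' @param gq phred-scaled quality (non-negative).
#' @return numeric vector.
#' @examples
#' phred_to_accuracy(c(7, 10))
#' @export
phred <- function(p_err) -10 * log10(p_err)

#' @rdname phred
#' @export
phred_to_accuracy <- function(gq) 1 - 10^(-gq / 10)

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.frame <-> GRanges for 1-based inclusive interval tables.
df_to_granges <- function(df, start_col = "start", end_col = "end") {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df[[start_col]], end = df[[end_col]])
  )
}
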