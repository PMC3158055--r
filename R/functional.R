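# MEI counts in annotated functional regions and random-placement
# suppression statistics.

#' Count MEI contained in annotated regions
#'
#' A locus counts toward a region class only when its insertion-position
#' confidence interval `[ci_lo, ci_hi]` lies entirely within one interval
#' of that class; loci straddling a boundary are ambiguous and excluded.
#' Only non-reference MEI are eligible (an embedded reference MEI
#' precludes the annotation itself), and loci flagged as invalidated are
#' dropped first.
#'
#' @param loci `MeiLocus` table with `ci_lo`, `ci_hi`, `detection_mode`
#'   and optionally a logical `invalidated` column.
#' @param regions interval table (`chrom`, `start`, `end`, `class`),
#'   1-based inclusive.
#' @param l_tot accessible genome length in bp.
#' @param classes region classes to report.
#' @return data.frame with one row per class: `region_label`, `l_obs`
#'   (total class length), `n_obs`, `n_tot`, `l_tot`.
#' @export
count_by_region <- function(loci, regions, l_tot = 2.85e9,
                            classes = c("gene", "UTR", "CDS")) {
  stopifnot(all(regions$end >= regions$start))
  eligible <- loci[loci$detection_mode == "non_reference", , drop = FALSE]
  if (!is.null(eligible$invalidated)) {
    eligible <- eligible[!eligible$invalidated, , drop = FALSE]
  }
  n_tot <- nrow(eligible)
  gr_loci <- if (n_tot) df_to_granges(eligible, "ci_lo", "ci_hi") else NULL
  out <- do.call(rbind, lapply(classes, function(cl) {
    r <- regions[regions$class == cl, , drop = FALSE]
    gr_r <- GenomicRanges::reduce(df_to_granges(r))
    n_obs <- if (n_tot && length(gr_r)) {
      length(unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr_loci, gr_r, type = "within")
      )))
    } else 0L
    data.frame(region_label = cl, l_obs = sum(GenomicRanges::width(gr_r)),
               n_obs = n_obs, n_tot = n_tot, l_tot = l_tot,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Suppression factor and placement p-value for a region class
#'
#' Under random placement the expected count is
#' `n_tot * l_obs / l_tot` and the observed count is binomial. The
#' suppression factor is expected/observed (values below 1 indicate a
#' boost); with zero observed loci a lower bound using one observation is
#' reported. The one-sided binomial tail p-value (depletion or excess,
#' chosen by the sign of observed - expected) is computed in log space so
#' extreme depletion does not underflow.
#'
#' @param n_obs observed loci entirely within the region class.
#' @param n_tot total eligible loci.
#' @param l_obs total region length (bp), > 0.
#' @param l_tot accessible genome length (bp).
#' @return data.frame with `expected`, `suppression`, `is_lower_bound`,
#'   `direction`, `p_value`, `log10_p`.
#' @export
suppression_stats <- function(n_obs, n_tot, l_obs, l_tot = 2.85e9) {
  if (l_obs <= 0) stop("l_obs must be positive")
  stopifnot(n_obs >= 0, n_obs <= n_tot, n_tot > 0, l_obs <= l_tot)
  p0 <- l_obs / l_tot
  expected <- n_tot * p0
  is_lb <- n_obs == 0
  suppression <- expected / max(n_obs, 1L)
  if (n_obs <= expected) {
    direction <- "depletion"
    log_p <- stats::pbinom(n_obs, n_tot, p0, log.p = TRUE)
  } else {
    direction <- "excess"
    log_p <- stats::pbinom(n_obs - 1L, n_tot, p0, lower.tail = FALSE,
                           log.p = TRUE)
  }
  data.frame(expected = expected, suppression = suppression,
             is_lower_bound = is_lb, direction = direction,
             p_value = exp(log_p), log10_p = log_p / log(10))
}

#' Region suppression table
#'
#' Convenience wrapper applying [suppression_stats()] to every row of a
#' [count_by_region()] table.
#'
#' @param counts a [count_by_region()] result.
#' @return the input with `expected`, `suppression`, `p_value`, `log10_p`
#'   columns appended.
#' @export
suppression_table <- function(counts) {
  stats <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    suppression_stats(counts$n_obs[i], counts$n_tot[i], counts$l_obs[i],
                      counts$l_tot[i])
  }))
  cbind(counts, stats)
}
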