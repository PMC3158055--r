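# False-detection rates, capture-recapture detection sensitivity, and
# sensitivity as a function of allele frequency.

#' Estimate a false-detection rate from a validation batch
#'
#' Rate = (tested - validated) / tested with a 95\% Wilson score interval
#' (chosen over the Wald interval for the small per-stratum counts typical
#' of PCR validation batches).
#'
#' @param n_tested,n_validated locus counts, `0 <= n_validated <= n_tested`.
#' @param conf confidence level.
#' @return data.frame with `rate`, `lower`, `upper`, `n_tested`,
#'   `n_failed`; rate is NA when nothing was tested.
#' @export
estimate_fdr <- function(n_tested, n_validated, conf = 0.95) {
  stopifnot(n_validated >= 0, n_validated <= n_tested)
  if (n_tested == 0) {
    return(data.frame(rate = NA_real_, lower = NA_real_, upper = NA_real_,
                      n_tested = 0L, n_failed = 0L))
  }
  x <- n_tested - n_validated
  ci <- wilson_interval(x, n_tested, conf)
  data.frame(rate = x / n_tested, lower = ci[["lower"]],
             upper = ci[["upper"]], n_tested = n_tested, n_failed = x)
}

#' Capture-recapture (Lincoln-Petersen) detection sensitivities
#'
#' The two detection methods act as independent capture samples of the
#' same underlying locus set, so the cross-method overlap estimates each
#' method's sensitivity. False calls inflate the per-method counts and are
#' deflated by the validated false-detection rates:
#' \deqn{\epsilon_{RP} = n_{both} / ((1 - f_{SR}) n_{SR}),\quad
#'       \epsilon_{SR} = n_{both} / ((1 - f_{RP}) n_{RP})}
#' and the combined sensitivity of running both methods is
#' \deqn{\epsilon = 1 - (1 - \epsilon_{RP})(1 - \epsilon_{SR}).}
#' Standard errors are binomial, propagated to the combination.
#'
#' @param n_rp,n_sr per-method locus counts in the sample.
#' @param n_both loci found by both methods.
#' @param f_rp,f_sr per-method false-detection rates.
#' @return data.frame with `eps_rp`, `eps_sr`, `eps_combined`, their
#'   standard errors, and `n_hat` (estimated true locus count). Estimates
#'   are NA with infinite errors when `n_both = 0`.
#' @export
lincoln_petersen <- function(n_rp, n_sr, n_both, f_rp = 0, f_sr = 0) {
  stopifnot(n_both <= min(n_rp, n_sr), f_rp >= 0, f_rp < 1, f_sr >= 0,
            f_sr < 1)
  if (n_both == 0) {
    return(data.frame(eps_rp = NA_real_, eps_sr = NA_real_,
                      eps_combined = NA_real_, se_rp = Inf, se_sr = Inf,
                      se_combined = Inf, n_hat = NA_real_))
  }
  m_sr <- (1 - f_sr) * n_sr # true loci captured by SR
  m_rp <- (1 - f_rp) * n_rp
  eps_rp <- n_both / m_sr
  eps_sr <- n_both / m_rp
  se_rp <- sqrt(eps_rp * (1 - eps_rp) / m_sr)
  se_sr <- sqrt(eps_sr * (1 - eps_sr) / m_rp)
  eps_c <- 1 - (1 - eps_rp) * (1 - eps_sr)
  se_c <- sqrt(((1 - eps_sr) * se_rp)^2 + ((1 - eps_rp) * se_sr)^2)
  data.frame(eps_rp = eps_rp, eps_sr = eps_sr, eps_combined = eps_c,
             se_rp = se_rp, se_sr = se_sr, se_combined = se_c,
             n_hat = m_rp / eps_rp)
}

#' Detection sensitivity as a function of allele frequency
#'
#' Gold-standard loci (e.g. PCR-validated loci selected from the
#' complementary method) are binned by allele frequency; per bin,
#' sensitivity is the fraction of gold loci present in the evaluated call
#' set, with one-sigma binomial errors. Empty bins are reported as NA, not
#' zero.
#'
#' @param gold_loci data.frame with `locus_id` and `af` (allele frequency
#'   in \[0, 1\]).
#' @param detected_ids locus ids found by the evaluated method.
#' @param breaks allele-frequency bin edges.
#' @return data.frame with per-bin `af_mid`, `n_gold`, `n_detected`,
#'   `sensitivity`, `se`.
#' @export
sensitivity_by_af <- function(gold_loci, detected_ids,
                              breaks = seq(0, 1, 0.1)) {
  stopifnot(all(gold_loci$af >= 0), all(gold_loci$af <= 1))
  bin <- cut(gold_loci$af, breaks = breaks, include.lowest = TRUE)
  hit <- gold_loci$locus_id %in% detected_ids
  out <- do.call(rbind, lapply(seq_along(levels(bin)), function(k) {
    sel <- bin == levels(bin)[k]
    n <- sum(sel)
    d <- sum(hit & sel)
    s <- if (n > 0) d / n else NA_real_
    data.frame(bin = levels(bin)[k],
               af_mid = (breaks[k] + breaks[k + 1]) / 2,
               n_gold = n, n_detected = d, sensitivity = s,
               se = if (n > 0) sqrt(s * (1 - s) / n) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Combine two method sensitivity curves
#'
#' Applies the union formula `1 - (1 - e1)(1 - e2)` bin-wise to two
#' [sensitivity_by_af()] curves on identical bins.
#'
#' @param curve_rp,curve_sr outputs of [sensitivity_by_af()].
#' @return data.frame with `af_mid`, `sensitivity`, `se`.
#' @export
combine_sensitivity <- function(curve_rp, curve_sr) {
  stopifnot(identical(curve_rp$bin, curve_sr$bin))
  e1 <- curve_rp$sensitivity; e2 <- curve_sr$sensitivity
  se <- sqrt(((1 - e2) * curve_rp$se)^2 + ((1 - e1) * curve_sr$se)^2)
  data.frame(af_mid = curve_rp$af_mid,
             sensitivity = 1 - (1 - e1) * (1 - e2), se = se)
}
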