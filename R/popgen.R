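# Allele-frequency spectra with ascertainment/efficiency corrections,
# neutral diversity (theta) fitting, corrected heterozygosity, mutation
# rates, and pairwise MEI differences.

#' Build allele-count spectra per detection mode
#'
#' Loci need at least `n_spectrum_samples` genotypes passing the
#' mode-specific GQ threshold (GQ >= 7 for non-reference MEI, GQ >= 10 for
#' reference MEI); for loci with more, a random subset of exactly
#' `n_spectrum_samples` is drawn so every locus contributes the same
#' haploid sample size 2N. The allele count i is the number of insertion
#' alleles among the 2N chromosomes; loci monomorphic in the subsample
#' (i = 0 or i = 2N) do not enter the counts.
#'
#' @param G samples x loci genotype matrix (0/1/2, NA = missing).
#' @param GQ matching genotype-quality matrix.
#' @param loci `MeiLocus` table with `locus_id` (matching `colnames(G)`)
#'   and `detection_mode`.
#' @param gq_nonref,gq_ref GQ thresholds per detection mode.
#' @param n_spectrum_samples diploid spectrum sample size N (2N = 50 by
#'   default).
#' @return list of class `mei_spectrum`: `counts` ((2N-1) x mode matrix),
#'   `n_samples`, `n_detected` and `n_included` per mode (their ratio is
#'   the genotyping efficiency), and the thresholds used.
#' @export
build_spectrum <- function(G, GQ, loci, gq_nonref = 7, gq_ref = 10,
                           n_spectrum_samples = 25) {
  stopifnot(all(loci$locus_id %in% colnames(G)), identical(dim(G), dim(GQ)))
  n2 <- 2L * n_spectrum_samples
  modes <- c("non_reference", "reference")
  thr <- c(non_reference = gq_nonref, reference = gq_ref)
  counts <- matrix(0L, n2 - 1L, 2L,
                   dimnames = list(seq_len(n2 - 1L), modes))
  n_detected <- stats::setNames(integer(2), modes)
  n_included <- stats::setNames(integer(2), modes)
  for (mode in modes) {
    ids <- loci$locus_id[loci$detection_mode == mode]
    n_detected[mode] <- length(ids)
    for (id in ids) {
      ok <- which(!is.na(G[, id]) & !is.na(GQ[, id]) & GQ[, id] >= thr[mode])
      if (length(ok) < n_spectrum_samples) next
      use <- if (length(ok) == n_spectrum_samples) ok
             else sample(ok, n_spectrum_samples)
      i <- sum(G[use, id])
      n_included[mode] <- n_included[mode] + 1L
      if (i >= 1L && i <= n2 - 1L) counts[i, mode] <- counts[i, mode] + 1L
    }
  }
  structure(list(counts = counts, n_samples = n_spectrum_samples,
                 n_detected = n_detected, n_included = n_included,
                 gq_thresholds = thr),
            class = "mei_spectrum")
}

#' Project an allele-count spectrum down by hypergeometric sampling
#'
#' For display spectra, loci genotyped in more than N samples are
#' projected down to `n_project` chromosomes with hypergeometric weights,
#' smoothing the spectrum while using all genotyped samples. (Projection
#' is not used for fitting: it correlates neighbouring count bins.)
#'
#' @param n_alt per-locus insertion-allele counts.
#' @param n_chrom per-locus genotyped chromosome counts (2 x samples).
#' @param n_project target haploid sample size.
#' @return expected counts indexed by projected allele count 0..n_project.
#' @export
project_spectrum <- function(n_alt, n_chrom, n_project = 50) {
  stopifnot(length(n_alt) == length(n_chrom), all(n_alt <= n_chrom),
            all(n_chrom >= n_project))
  j <- 0:n_project
  out <- stats::setNames(numeric(n_project + 1L), j)
  for (l in seq_along(n_alt)) {
    out <- out + stats::dhyper(j, n_alt[l], n_chrom[l] - n_alt[l], n_project)
  }
  out
}

#' Combine per-mode spectra with detection/genotyping corrections
#'
#' The combined spectrum is
#' `n_MEI(i) = K_REF * n_REF(i) + K_NREF * n_NREF(i)` with per-mode
#' scaling factors `K = 1 / (eps_det * eps_gen)` — the reciprocal of the
#' probability that a true locus is both detected and well enough
#' genotyped to enter the spectrum. Per-bin variances
#' (`K^2 * n` summed over modes) accompany the corrected counts for
#' downstream fitting.
#'
#' @param spectrum a [build_spectrum()] result.
#' @param eps_det,eps_gen named efficiencies in (0, 1\] per mode
#'   (`non_reference`, `reference`).
#' @return list with `counts` (corrected, per i), `var`, `k` (the two
#'   scaling factors), `n_samples`.
#' @export
correct_spectrum <- function(spectrum, eps_det, eps_gen) {
  modes <- c("non_reference", "reference")
  stopifnot(all(modes %in% names(eps_det)), all(modes %in% names(eps_gen)))
  ed <- unlist(eps_det[modes]); eg <- unlist(eps_gen[modes])
  if (any(ed <= 0) || any(eg <= 0)) stop("efficiencies must be positive")
  stopifnot(all(ed <= 1), all(eg <= 1))
  k <- 1 / (ed * eg)
  names(k) <- modes
  counts <- spectrum$counts[, "non_reference"] * k[["non_reference"]] +
    spectrum$counts[, "reference"] * k[["reference"]]
  v <- spectrum$counts[, "non_reference"] * k[["non_reference"]]^2 +
    spectrum$counts[, "reference"] * k[["reference"]]^2
  list(counts = counts, var = v, k = k, n_samples = spectrum$n_samples)
}

#' Fit the neutral diversity parameter theta to an allele-count spectrum
#'
#' Under the standard neutral model the expected locus count at allele
#' count i is theta/i, so the Poisson maximum-likelihood estimate over the
#' fitted bins is closed-form:
#' \deqn{\hat\theta = \sum_i n(i) \Big/ \sum_i 1/i .}
#' For raw (integer) spectra the 95\% CI is the exact Poisson interval on
#' the bin total; for corrected spectra, supply per-bin variances and a
#' normal interval is used. A chi-square goodness-of-fit against
#' theta-hat/i is reported with dof = bins - 1, and the insertion rate is
#' derived as mu = theta / (4 Ne).
#'
#' @param counts locus counts indexed by allele count i (names taken as i;
#'   otherwise i = position). May be a [correct_spectrum()] result.
#' @param fit_range inclusive allele-count fit window; the default 7..47
#'   excludes the low- and high-frequency bins where detection sensitivity
#'   is poor (frequencies 0.15-0.95 of 2N = 50 chromosomes).
#' @param var optional per-bin variances for corrected spectra.
#' @param n_e effective population size for the mu transform.
#' @param conf confidence level.
#' @return data.frame of class `theta_fit`: `theta`, `lower`, `upper`,
#'   `chi2`, `dof`, `mu_theta`, `mu_lower`, `mu_upper`.
#' @export
fit_theta <- function(counts, fit_range = c(7, 47), var = NULL, n_e = 1e4,
                      conf = 0.95) {
  if (is.list(counts) && !is.null(counts$counts)) {
    var <- counts$var
    counts <- counts$counts
  }
  i_all <- if (!is.null(names(counts))) as.integer(names(counts))
           else seq_along(counts)
  sel <- i_all >= fit_range[1] & i_all <= fit_range[2]
  if (!any(sel)) stop("fit_range contains no bins")
  i <- i_all[sel]
  n <- counts[sel]
  h <- sum(1 / i)
  total <- sum(n)
  theta <- total / h
  a <- (1 - conf) / 2
  if (is.null(var)) { # raw Poisson counts: exact interval on the total
    lo <- if (total > 0) stats::qgamma(a, total) / h else 0
    hi <- stats::qgamma(1 - a, total + 1) / h
  } else {
    se <- sqrt(sum(var[sel])) / h
    lo <- max(0, theta - stats::qnorm(1 - a) * se)
    hi <- theta + stats::qnorm(1 - a) * se
  }
  expected <- theta / i
  chi2 <- if (theta > 0) sum((n - expected)^2 / expected) else NA_real_
  out <- data.frame(theta = theta, lower = lo, upper = hi, chi2 = chi2,
                    dof = length(i) - 1L, mu_theta = theta / (4 * n_e),
                    mu_lower = lo / (4 * n_e), mu_upper = hi / (4 * n_e))
  class(out) <- c("theta_fit", "data.frame")
  out
}

#' Neutral-model spectrum expectations under reference ascertainment
#'
#' Conditioning on whether the reference genome (treated as a random
#' chromosome from the population) carries the derived allele reshapes
#' the neutral spectrum theta/i: reference MEI are flat at theta/2N,
#' non-reference MEI follow (theta/i)(2N-i)/(2N), and the two modes sum
#' back to theta/i at every i.
#'
#' @param theta diversity parameter.
#' @param n_samples diploid sample size N (2N chromosomes).
#' @param mode `"reference"`, `"non_reference"`, or `"combined"`.
#' @return expected locus counts, named by allele count i = 1..2N-1.
#' @export
ascertained_expectation <- function(theta, n_samples = 25,
                                    mode = c("reference", "non_reference",
                                             "combined")) {
  mode <- match.arg(mode)
  n2 <- 2 * n_samples
  i <- seq_len(n2 - 1)
  e <- switch(mode,
              reference = rep(theta / n2, n2 - 1),
              non_reference = (theta / i) * (n2 - i) / n2,
              combined = theta / i)
  stats::setNames(e, i)
}

#' Heterozygote-dropout correction factor
#'
#' At limited fragment coverage a heterozygous locus can by chance yield
#' only reference-supporting fragments (probability 0.5^NF) and be missed.
#' The correction is the reciprocal of the mean single-locus recovery
#' probability over the sample's genotyped loci:
#' \deqn{K_{HET} = N_{loci} \Big/ \sum_{loci} [1 - Binom(0; NF, 0.5)].}
#' It applies only to the non-reference component of heterozygosity
#' (reference-MEI genotypes draw on linkage information as well as
#' fragment counts).
#'
#' @param nf per-locus total fragment counts for one sample.
#' @return the correction factor (>= 1); NA with a warning if no locus has
#'   coverage.
#' @export
k_het <- function(nf) {
  stopifnot(all(nf >= 0))
  denom <- sum(1 - stats::dbinom(0, nf, 0.5))
  if (denom == 0) {
    warning("k_het undefined: all loci have zero fragments")
    return(NA_real_)
  }
  length(nf) / denom
}

#' Corrected per-sample MEI heterozygosity
#'
#' \deqn{\pi_{MEI}(s) = K_{HET}\,\pi_{NREF}(s) /
#'   (\epsilon_{DET}^{NREF} \epsilon_{GEN}^{NREF}(s)) +
#'   \pi_{REF}(s) / (\epsilon_{DET}^{REF} \epsilon_{GEN}^{REF}(s))}
#' in units of heterozygous loci per genome.
#'
#' @param pi_nref_raw,pi_ref_raw raw heterozygous-locus counts per
#'   detection mode.
#' @param k_het heterozygote-dropout correction (non-reference only).
#' @param eps_det_nref,eps_gen_nref,eps_det_ref,eps_gen_ref detection
#'   sensitivities and genotyping efficiencies in (0, 1\].
#' @return corrected heterozygosity (loci per genome).
#' @export
sample_pi <- function(pi_nref_raw, pi_ref_raw, k_het = 1,
                      eps_det_nref = 1, eps_gen_nref = 1,
                      eps_det_ref = 1, eps_gen_ref = 1) {
  eff <- c(eps_det_nref, eps_gen_nref, eps_det_ref, eps_gen_ref)
  if (any(eff <= 0)) stop("efficiencies must be positive")
  stopifnot(all(eff <= 1), pi_nref_raw >= 0, pi_ref_raw >= 0, k_het >= 1)
  k_het * pi_nref_raw / (eps_det_nref * eps_gen_nref) +
    pi_ref_raw / (eps_det_ref * eps_gen_ref)
}

#' MEI mutation rate and coalescent time from heterozygosity
#'
#' Long-term demography affects MEI and SNP heterozygosity identically,
#' so their ratio converts the (better-known) SNP mutation rate into an
#' MEI insertion rate per genome per generation:
#' \deqn{\mu_{MEI} = (\pi_{MEI}/\pi_{SNP})\,\mu_{SNP}\,L}
#' with L the accessible genome length. SNP heterozygosity also yields a
#' rough pairwise coalescent time
#' \deqn{T = \frac{\pi_{SNP}/L}{2 \mu_{SNP}}\, T_{GEN}.}
#'
#' @param pi_mei corrected MEI heterozygosity (loci per genome).
#' @param pi_snp SNP heterozygosity (sites per genome), > 0.
#' @param mu_snp_per_site SNP mutation rate per site per generation.
#' @param genome_length accessible genome length in bp.
#' @param t_gen generation time in years.
#' @return data.frame with `mu_mei` (insertions/genome/generation) and
#'   `t_coal_years`.
#' @export
mutation_rates <- function(pi_mei, pi_snp, mu_snp_per_site = 1.8e-8,
                           genome_length = 2.85e9, t_gen = 25) {
  if (any(pi_snp <= 0)) stop("pi_snp must be positive")
  stopifnot(all(pi_mei >= 0))
  data.frame(
    mu_mei = (pi_mei / pi_snp) * mu_snp_per_site * genome_length,
    t_coal_years = (pi_snp / genome_length) / (2 * mu_snp_per_site) * t_gen
  )
}

#' Corrected count of MEI presence/absence differences between two samples
#'
#' The raw count is the symmetric difference of the two samples' presence
#' sets per detection mode; each mode is corrected for detection
#' sensitivity and false detection as `raw * (1 - fdr) / eps`, and the
#' modes are summed. One-sigma errors treat the raw counts as Poisson.
#'
#' @param calls_a,calls_b per-sample call tables with `locus_id` and
#'   `detection_mode`, on shared catalog coordinates.
#' @param eps named detection sensitivities per mode.
#' @param fdr named false-detection rates per mode.
#' @return data.frame with one row per mode plus a `total` row: `raw`,
#'   `corrected`, `se`.
#' @export
pairwise_differences <- function(calls_a, calls_b,
                                 eps = c(non_reference = 1, reference = 1),
                                 fdr = c(non_reference = 0, reference = 0)) {
  modes <- c("non_reference", "reference")
  stopifnot(all(modes %in% names(eps)), all(eps > 0), all(eps <= 1),
            all(fdr >= 0), all(fdr < 1))
  rows <- lapply(modes, function(m) {
    a <- calls_a$locus_id[calls_a$detection_mode == m]
    b <- calls_b$locus_id[calls_b$detection_mode == m]
    raw <- length(setdiff(a, b)) + length(setdiff(b, a))
    scale <- (1 - fdr[[m]]) / eps[[m]]
    data.frame(mode = m, raw = raw, corrected = raw * scale,
               se = sqrt(raw) * scale)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(mode = "total", raw = sum(out$raw),
                               corrected = sum(out$corrected),
                               se = sqrt(sum(out$se^2))))
  rownames(out) <- NULL
  out
}
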