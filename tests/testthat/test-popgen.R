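# Spectra, ascertainment expectations, theta fitting, heterozygosity
# corrections, mutation rates, pairwise differences.

make_gt <- function(g_by_locus, gq = 99L) {
  n_s <- length(g_by_locus[[1]])
  g <- do.call(cbind, g_by_locus)
  dimnames(g) <- list(paste0("S", seq_len(n_s)),
                      paste0("L", seq_along(g_by_locus)))
  list(G = g, GQ = matrix(gq, nrow(g), ncol(g), dimnames = dimnames(g)))
}

test_that("spectrum requires 25 qualifying genotypes and counts alleles", {
  # locus 1: 25 heterozygotes; locus 2: only 24 genotyped
  g1 <- rep(1L, 30)
  g2 <- rep(1L, 30)
  gt <- make_gt(list(g1, g2))
  gt$GQ[, 1][26:30] <- 0L # locus 1: exactly 25 qualify
  gt$GQ[, 2][24:30] <- 0L # locus 2: 23 qualify -> excluded
  loci <- data.frame(locus_id = c("L1", "L2"),
                     detection_mode = "non_reference")
  sp <- build_spectrum(gt$G, gt$GQ, loci)
  expect_identical(sp$n_included[["non_reference"]], 1L)
  expect_identical(sp$counts["25", "non_reference"], 1L)
  # monomorphic subsamples never enter the counts
  g3 <- rep(0L, 30)
  sp0 <- build_spectrum(gt$G * 0L, gt$GQ,
                        data.frame(locus_id = "L1",
                                   detection_mode = "non_reference"))
  expect_identical(sum(sp0$counts), 0L)
})

test_that("hypergeometric projection preserves the expected allele count", {
  pr <- project_spectrum(30, 80, 50)
  expect_equal(sum(pr), 1)
  expect_equal(sum(as.integer(names(pr)) * pr), 30 * 50 / 80)
  expect_equal(unname(pr["19"]), stats::dhyper(19, 30, 50, 50))
})

test_that("correction factors are the reciprocal detection x genotyping rates", {
  counts <- matrix(5L, 49, 2,
                   dimnames = list(1:49, c("non_reference", "reference")))
  sp <- structure(list(counts = counts, n_samples = 25), class = "mei_spectrum")
  idc <- correct_spectrum(sp, c(non_reference = 1, reference = 1),
                          c(non_reference = 1, reference = 1))
  expect_equal(unname(idc$counts), rowSums(counts), ignore_attr = TRUE)
  cr <- correct_spectrum(sp, c(non_reference = 0.75, reference = 0.9),
                         c(non_reference = 0.4, reference = 0.8))
  expect_equal(unname(cr$k[["non_reference"]]), 10 / 3)
  expect_equal(unname(cr$k[["reference"]]), 1 / 0.72, tolerance = 1e-9)
  expect_error(correct_spectrum(sp, c(non_reference = 0, reference = 1),
                                c(non_reference = 1, reference = 1)))
})

test_that("theta fit is self-consistent on an exact theta/i spectrum", {
  theta <- 1000
  counts <- stats::setNames(round(theta / 1:49), 1:49)
  fit <- fit_theta(counts)
  expect_lt(abs(fit$theta - theta) / theta, 0.01)
  expect_lt(fit$chi2, 2) # rounding noise only
  expect_identical(fit$dof, 40L)
})

test_that("mu(theta) transform matches theta / (4 Ne)", {
  counts <- stats::setNames(round(1700 / 1:49), 1:49)
  fit <- fit_theta(counts)
  expect_equal(fit$mu_theta, fit$theta / 4e4)
  # at theta exactly 1700 the rate is 0.0425
  expect_equal(1700 / (4 * 1e4), 0.0425)
  expect_error(fit_theta(counts, fit_range = c(60, 70)))
})

test_that("ascertainment expectations partition the neutral spectrum", {
  theta <- 1860
  ref <- ascertained_expectation(theta, 25, "reference")
  nref <- ascertained_expectation(theta, 25, "non_reference")
  full <- ascertained_expectation(theta, 25, "combined")
  expect_equal(ref + nref, full, tolerance = 1e-12)
  expect_true(all(abs(ref - theta / 50) < 1e-12)) # flat
  expect_equal(unname(nref[1]), theta * 49 / 50)
  # the (2N - i) factor sends the non-reference expectation to 0 at i = 2N
  i <- as.integer(names(nref))
  expect_equal(unname((theta / 50) * (50 - 50) / 50), 0)
  expect_lt(nref[length(nref)], ref[1])
})

test_that("k_het matches closed forms and flags degenerate input", {
  expect_equal(k_het(rep(2L, 100)), 4 / 3)
  expect_lt(abs(k_het(rep(20L, 100)) - 1), 1e-5)
  expect_warning(expect_true(is.na(k_het(c(0L, 0L)))), "zero fragments")
})

test_that("sample_pi applies the per-mode corrections", {
  expect_equal(sample_pi(500, 600), 1100)
  got <- sample_pi(500, 600, k_het = 4 / 3,
                   eps_det_nref = 0.75, eps_gen_nref = 0.5,
                   eps_det_ref = 0.9, eps_gen_ref = 0.8)
  expect_equal(got, 500 * (4 / 3) / 0.375 + 600 / 0.72, tolerance = 1e-9)
  expect_equal(round(got, 1), 2611.1)
  expect_error(sample_pi(500, 600, eps_det_nref = 0))
})

test_that("mutation-rate and coalescent-time transforms are dimensionally right", {
  mr <- mutation_rates(pi_mei = 0, pi_snp = 1e6)
  expect_identical(mr$mu_mei, 0)
  mr2 <- mutation_rates(pi_mei = 2000, pi_snp = 9e-4 * 2.85e9)
  expect_equal(mr2$t_coal_years, 9e-4 / (2 * 1.8e-8) * 25)
  expect_equal(mr2$t_coal_years, 625000)
  expect_error(mutation_rates(100, 0))
})

test_that("pairwise differences are corrected for sensitivity and FDR", {
  a <- data.frame(locus_id = paste0("L", 1:50),
                  detection_mode = rep(c("non_reference", "reference"), 25))
  expect_identical(pairwise_differences(a, a)$corrected, rep(0, 3))
  set.seed(23)
  # two samples with 500 private loci each, thinned at eps with false calls
  eps <- 0.8; fdr <- 0.05
  mk <- function(prefix) {
    ids <- paste0(prefix, 1:500)
    kept <- ids[stats::runif(500) < eps]
    false <- paste0(prefix, "FP", seq_len(round(length(kept) * fdr / (1 - fdr))))
    data.frame(locus_id = c(kept, false), detection_mode = "non_reference")
  }
  d <- pairwise_differences(mk("A"), mk("B"),
                            eps = c(non_reference = eps, reference = 1),
                            fdr = c(non_reference = fdr, reference = 0))
  tot <- d[d$mode == "total", ]
  expect_lt(abs(tot$corrected - 1000), 2 * tot$se)
})

test_that("corrected pairwise counts scale linearly with divergence", {
  set.seed(24)
  eps <- 0.8
  corrected <- vapply(1:10, function(t) {
    n_diff <- 200L * t
    a <- data.frame(locus_id = paste0("T", t, "A", seq_len(n_diff / 2)),
                    detection_mode = "non_reference")
    b <- data.frame(locus_id = paste0("T", t, "B", seq_len(n_diff / 2)),
                    detection_mode = "non_reference")
    thin <- function(x) x[stats::runif(nrow(x)) < eps, , drop = FALSE]
    d <- pairwise_differences(thin(a), thin(b),
                              eps = c(non_reference = eps, reference = 1))
    d$corrected[d$mode == "total"]
  }, numeric(1))
  fit <- stats::lm(corrected ~ I(200 * (1:10)))
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("simulated equilibrium heterozygosity approximates theta", {
  cfg <- sim_config(theta_by_family = c(Alu = 2000),
                    n_samples_by_pop = c(CEU = 40), seed = 25)
  cat <- simulate_catalog(cfg)
  coh <- simulate_cohort(cat, cfg)
  het_per_sample <- rowSums(coh$genotypes == 1L)
  expect_lt(abs(mean(het_per_sample) / 2000 - 1), 0.15)
})
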