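# Synthetic cohort generator: neutral SFS, ascertainment flagging,
# Hardy-Weinberg genotypes, fragment evidence, deletion tracks.

test_that("zero theta for every family yields an empty catalog", {
  cfg <- sim_config(theta_by_family = c(Alu = 0, L1 = 0, SVA = 0), seed = 1)
  cat <- simulate_catalog(cfg)
  expect_identical(nrow(cat$loci), 0L)
  expect_gt(nrow(cat$elements), 0L) # annotation tracks still emitted
  expect_gt(nrow(cat$regions), 0L)
})

test_that("config validation rejects bad rates and negative theta", {
  expect_error(sim_config(theta_by_family = c(Alu = -5)))
  expect_error(sim_config(fdr_sim = 1.5))
  expect_error(sim_config(family_props = c(Alu = 0.5, L1 = 0.2, SVA = 0.2)))
  expect_error(sim_config(n_chrom_sampled = 1))
})

test_that("segregating locus count matches the harmonic-sum expectation", {
  cfg <- sim_config(theta_by_family = c(Alu = 1860), seed = 11)
  cat <- simulate_catalog(cfg)
  expected <- 1860 * sum(1 / seq_len(49)) # ~8330
  expect_lt(abs(nrow(cat$loci) - expected), 4 * sqrt(expected))
  # per-bin counts are Poisson(theta/i)
  obs <- tabulate(cat$loci$allele_count, nbins = 49)
  exp_i <- 1860 / seq_len(49)
  chi2 <- sum((obs - exp_i)^2 / exp_i)
  expect_gt(stats::pchisq(chi2, df = 49, lower.tail = FALSE), 0.001)
})

test_that("reference flagging probability equals i/2N", {
  cfg <- sim_config(theta_by_family = c(Alu = 40000), seed = 5)
  cat <- simulate_catalog(cfg)
  loci <- cat$loci
  # at i = N the reference carries the derived allele half the time
  at_n <- loci[loci$allele_count == 25L, ]
  p_hat <- mean(at_n$on_reference)
  expect_lt(abs(p_hat - 0.5), 4 * sqrt(0.25 / nrow(at_n)))
  # global regression of flag rate on i/2N
  rate_by_i <- tapply(loci$on_reference, loci$allele_count, mean)
  i <- as.integer(names(rate_by_i))
  expect_gt(stats::cor(rate_by_i, i / 50), 0.98)
})

test_that("cohort genotypes follow Hardy-Weinberg at f = 0.5", {
  cfg <- sim_config(theta_by_family = c(Alu = 30),
                    n_samples_by_pop = c(CEU = 10000), seed = 3)
  cat <- simulate_catalog(cfg)
  cat$loci <- cat$loci[1, , drop = FALSE]
  cat$loci$freq <- cat$loci$freq_CEU <- 0.5
  cat$loci$allele_count <- 25L
  coh <- simulate_cohort(cat, cfg)
  g <- coh$genotypes[!rownames(coh$genotypes) %in% coh$panel_samples, 1]
  expect_lt(abs(mean(g == 1L) - 0.5), 0.015)
  expect_lt(abs(mean(g) / 2 - 0.5), 0.015)
})

test_that("f = 0 and f = 1 give monomorphic genotypes", {
  cfg <- sim_config(theta_by_family = c(Alu = 30),
                    n_samples_by_pop = c(CEU = 50), seed = 4)
  cat <- simulate_catalog(cfg)
  cat$loci <- cat$loci[1:2, , drop = FALSE]
  cat$loci$freq <- cat$loci$freq_CEU <- c(0, 1)
  cat$loci$allele_count <- c(0L, 50L)
  cat$loci$on_reference <- c(FALSE, TRUE)
  coh <- simulate_cohort(cat, cfg)
  expect_true(all(coh$genotypes[, 1] == 0L))
  expect_true(all(coh$genotypes[, 2] == 2L))
})

test_that("spectrum panel carries the exact catalog allele counts", {
  cfg <- sim_config(theta_by_family = c(Alu = 300), seed = 9)
  cat <- simulate_catalog(cfg)
  coh <- simulate_cohort(cat, cfg)
  panel <- coh$genotypes[coh$panel_samples, ]
  expect_equal(unname(colSums(panel)), cat$loci$allele_count,
               ignore_attr = TRUE)
  # reference haplotype (chromosome 1 of sample 1) carries iff on_reference
  expect_true(all(panel[1, cat$loci$on_reference] >= 1L))
})

test_that("evidence counts follow the thinned-Poisson model", {
  cfg <- sim_config(theta_by_family = c(Alu = 30),
                    n_samples_by_pop = c(CEU = 20000), gt_error = 0,
                    coverage_mean = 4, seed = 6)
  cat <- simulate_catalog(cfg)
  cat$loci <- cat$loci[1, , drop = FALSE]
  coh <- simulate_cohort(cat, cfg)
  # genotype 0, error 0: every fragment supports the reference
  coh$genotypes[] <- 0L
  ev0 <- simulate_evidence(coh, cat, cfg, fragments = FALSE)
  expect_true(all(ev0$support$n_alt5 + ev0$support$n_alt3 == 0L))
  expect_lt(abs(mean(ev0$support$n_ref) - 4), 0.1)
  # heterozygote at coverage 4: P(no insertion-supporting fragment) = e^-2
  coh$genotypes[] <- 1L
  ev1 <- simulate_evidence(coh, cat, cfg, fragments = FALSE)
  n_alt <- ev1$support$n_alt5 + ev1$support$n_alt3
  p0 <- exp(-2)
  expect_lt(abs(mean(n_alt == 0L) - p0),
            4 * sqrt(p0 * (1 - p0) / length(n_alt)))
  # insertion-supporting fraction near 0.5 at het sites
  expect_lt(abs(sum(n_alt) / sum(n_alt + ev1$support$n_ref) - 0.5), 0.01)
})

test_that("identical seeds give identical outputs", {
  cfg <- sim_config(theta_by_family = c(Alu = 120), seed = 21)
  a <- simulate_catalog(cfg)
  b <- simulate_catalog(cfg)
  expect_identical(a$loci, b$loci)
  set.seed(99); ca <- simulate_cohort(a, cfg)
  set.seed(99); cb <- simulate_cohort(a, cfg)
  expect_identical(ca$genotypes, cb$genotypes)
  set.seed(99); ea <- simulate_evidence(ca, a, cfg)
  set.seed(99); eb <- simulate_evidence(ca, a, cfg)
  expect_identical(ea$support, eb$support)
  expect_identical(ea$fragments, eb$fragments)
})

test_that("clean deletions all pass reference-MEI selection", {
  cfg <- sim_config(theta_by_family = c(Alu = 400, L1 = 60), seed = 31)
  cat <- simulate_catalog(cfg)
  set.seed(31)
  dels <- simulate_deletions(cat, cfg, jitter_sd = 0, decoy_fraction = 0)
  sel <- select_reference_mei(dels$deletions, dels$elements, dels$gaps)
  expect_identical(nrow(sel), nrow(dels$deletions))
})

test_that("decoy deletions are rejected by the selection filters", {
  cfg <- sim_config(theta_by_family = c(Alu = 400), seed = 32)
  cat <- simulate_catalog(cfg)
  set.seed(32)
  dels <- simulate_deletions(cat, cfg, jitter_sd = 0, decoy_fraction = 0.5)
  sel <- select_reference_mei(dels$deletions, dels$elements, dels$gaps)
  true_ids <- dels$deletions$id[!dels$deletions$is_decoy]
  expect_setequal(sel$source_id, true_ids)
})

test_that("endpoint jitter rejects the Monte-Carlo-predicted fraction", {
  cfg <- sim_config(theta_by_family = c(Alu = 3000), seed = 33)
  cat <- simulate_catalog(cfg)
  set.seed(33)
  dels <- simulate_deletions(cat, cfg, jitter_sd = 30, decoy_fraction = 0)
  sel <- select_reference_mei(dels$deletions, dels$elements, dels$gaps)
  n <- nrow(dels$deletions)
  # Monte-Carlo oracle over the jitter distribution and the full rule set
  set.seed(1234)
  js <- round(stats::rnorm(2e5, 0, 30)); je <- round(stats::rnorm(2e5, 0, 30))
  len <- 300
  ov <- pmin(len - 1 + je, len - 1) - pmax(js, 0) + 1
  ok <- abs(js) <= 20 & abs(je) <= 20 &
    ov / (len + je - js) > 0.5 & ov / len > 0.5
  p_sel <- mean(ok)
  expect_lt(abs(nrow(sel) / n - p_sel), 4 * sqrt(p_sel * (1 - p_sel) / n))
})

test_that("simulate_callset thins at the requested sensitivity and FDR", {
  cfg <- sim_config(theta_by_family = c(Alu = 2000), seed = 41)
  cat <- simulate_catalog(cfg)
  set.seed(41)
  cs <- simulate_callset(cat$loci, sensitivity = 0.7, fdr = 0.1,
                         catalog = cat)
  n_true <- sum(cs$is_true)
  expect_lt(abs(n_true / nrow(cat$loci) - 0.7),
            4 * sqrt(0.21 / nrow(cat$loci)))
  expect_lt(abs(mean(!cs$is_true) - 0.1), 0.02)
})
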