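# RP/SR insertion calling and reference-MEI selection.

test_that("RP calling requires two fragments on each breakpoint side", {
  expect_identical(nrow(call_rp_insertions(rp_cluster(n5 = 2, n3 = 2),
                                           no_ann, 200)), 1L)
  expect_identical(nrow(call_rp_insertions(rp_cluster(n5 = 3, n3 = 0),
                                           no_ann, 200)), 0L)
  expect_identical(nrow(call_rp_insertions(rp_cluster(n5 = 1, n3 = 3),
                                           no_ann, 200)), 0L)
  expect_identical(nrow(call_rp_insertions(rp_cluster(0)[0, ], no_ann, 200)),
                   0L)
})

test_that("RP breakpoint is the leftmost position compatible with the cluster", {
  calls <- call_rp_insertions(rp_cluster(1000), no_ann, 200)
  expect_identical(calls$pos, 991L) # max 5' anchor 990 + 1
  expect_identical(calls$n_alt5, 2L)
  expect_identical(calls$n_alt3, 2L)
  expect_identical(calls$methods, "RP")
  expect_true(calls$ci_lo <= calls$pos && calls$pos <= calls$ci_hi)
})

test_that("annotation-proximity masking acts within one fragment length, same family only", {
  fr <- rp_cluster(1000)
  bp <- 991L
  near <- ann_df(bp + 50L, bp + 350L)
  far <- ann_df(bp + 250L, bp + 550L)
  expect_identical(nrow(call_rp_insertions(fr, near, 200)), 0L)
  expect_identical(nrow(call_rp_insertions(fr, far, 200)), 1L)
  # same distance but different family: not masked
  near_l1 <- ann_df(bp + 50L, bp + 350L, family = "L1")
  expect_identical(nrow(call_rp_insertions(fr, near_l1, 200)), 1L)
})

test_that("fragments with unknown families are rejected with a warning", {
  fr <- rbind(rp_cluster(1000), frag_row(1005, "5p", family = "HERV"))
  expect_warning(calls <- call_rp_insertions(fr, no_ann, 200), "unknown")
  expect_identical(nrow(calls), 1L)
})

test_that("a single split fragment is sufficient for an SR call", {
  fr <- frag_row(180, "5p", split = TRUE, ref_start = 100, ref_end = 180)
  calls <- call_sr_insertions(fr)
  expect_identical(nrow(calls), 1L)
  expect_true(is.na(calls$tsd_len))
  expect_identical(calls$methods, "SR")
})

test_that("SR TSD is the overlap of the 5' and 3' reference extents", {
  fr <- rbind(
    frag_row(180, "5p", split = TRUE, ref_start = 100, ref_end = 180),
    frag_row(165, "3p", split = TRUE, ref_start = 165, ref_end = 240)
  )
  calls <- call_sr_insertions(fr)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$tsd_len, 16L)
  expect_identical(calls$pos, 165L) # leftmost = start of the overlap
  expect_identical(c(calls$ci_lo, calls$ci_hi), c(165L, 180L))
})

test_that("disjoint SR extents give a zero-length TSD", {
  fr <- rbind(
    frag_row(160, "5p", split = TRUE, ref_start = 100, ref_end = 160),
    frag_row(180, "3p", split = TRUE, ref_start = 180, ref_end = 240)
  )
  calls <- call_sr_insertions(fr)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$tsd_len, 0L)
})

test_that("reference-MEI selection applies overlap, window, and gap rules", {
  ann_alu <- ann_df(1000, 1299)
  gap_all <- data.frame(chrom = "chr1", start = 1L, end = 10000L)
  # deletion exactly equal to the annotation, fully inside a gap
  del_exact <- data.frame(chrom = "chr1", start = 1000L, end = 1299L,
                          id = "d1")
  expect_identical(
    nrow(select_reference_mei(del_exact, ann_alu, gap_all)), 1L)
  # Alu start offset 25 bp exceeds the 20 bp window even with full gap
  del_off <- data.frame(chrom = "chr1", start = 1025L, end = 1299L,
                        id = "d2")
  expect_identical(
    nrow(select_reference_mei(del_off, ann_alu, gap_all)), 0L)
  # L1 offset 150 bp both ends, ~80% gap coverage: all thresholds pass
  ann_l1 <- ann_df(10000, 15999, family = "L1")
  del_l1 <- data.frame(chrom = "chr1", start = 10150L, end = 16149L,
                       id = "d3")
  gap80 <- data.frame(chrom = "chr1", start = 10150L,
                      end = 10150L + ceiling(0.8 * 6000) - 1L)
  sel <- select_reference_mei(del_l1, ann_l1, gap80)
  expect_identical(nrow(sel), 1L)
  expect_identical(sel$family, "L1")
  # same deletion with only 60% gap coverage fails the 75% rule
  gap60 <- data.frame(chrom = "chr1", start = 10150L,
                      end = 10150L + ceiling(0.6 * 6000) - 1L)
  expect_identical(nrow(select_reference_mei(del_l1, ann_l1, gap60)), 0L)
  # 40% reciprocal overlap is always rejected
  del40 <- data.frame(chrom = "chr1", start = 1180L, end = 1479L, id = "d4")
  expect_identical(
    nrow(select_reference_mei(del40, ann_df(1000, 1299), gap_all)), 0L)
  # malformed interval
  expect_error(select_reference_mei(
    data.frame(chrom = "chr1", start = 10L, end = 5L), ann_alu, gap_all),
    "malformed")
})

test_that("selection is invariant to input order and non-overlapping decoys", {
  cfg <- sim_config(theta_by_family = c(Alu = 300), seed = 51)
  cat <- simulate_catalog(cfg)
  set.seed(51)
  dels <- simulate_deletions(cat, cfg, jitter_sd = 5, decoy_fraction = 0.4)
  sel1 <- select_reference_mei(dels$deletions, dels$elements, dels$gaps)
  set.seed(52)
  perm <- sample(nrow(dels$deletions))
  sel2 <- select_reference_mei(dels$deletions[perm, ], dels$elements,
                               dels$gaps)
  expect_setequal(sel1$source_id, sel2$source_id)
})

test_that("RP recovers every well-supported simulated locus (perfect recall)", {
  cfg <- sim_config(theta_by_family = c(Alu = 150),
                    n_samples_by_pop = c(CEU = 30), gt_error = 0,
                    split_fraction = 0, bg_pairs_per_element = 0, seed = 61)
  cat <- simulate_catalog(cfg)
  coh <- simulate_cohort(cat, cfg)
  set.seed(61)
  ev <- simulate_evidence(coh, cat, cfg, fragments = TRUE)
  sup <- ev$support
  pooled5 <- tapply(sup$n_alt5, sup$locus_id, sum)
  pooled3 <- tapply(sup$n_alt3, sup$locus_id, sum)
  well <- names(pooled5)[pooled5 >= 2 & pooled3 >= 2]
  # linkage gap covering the library tail so one locus is one cluster
  gap <- cfg$frag_len_mean + 3 * cfg$frag_len_sd
  calls <- call_rp_insertions(ev$fragments, no_ann, gap)
  truth <- cat$loci[cat$loci$locus_id %in% well, ]
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(calls$chrom == truth$chrom[i] &
          abs(calls$pos - truth$pos[i]) <= gap)
  }, logical(1))
  expect_true(all(hit))
})

test_that("masking removes background-pair artifacts; unmasked they produce false calls", {
  cfg <- sim_config(theta_by_family = c(Alu = 30),
                    n_samples_by_pop = c(CEU = 30),
                    bg_pairs_per_element = 8,
                    n_annot_elements = c(Alu = 300, L1 = 0, SVA = 0),
                    seed = 62)
  cat <- simulate_catalog(cfg)
  coh <- simulate_cohort(cat, cfg)
  set.seed(62)
  bg <- meipop:::simulate_background_pairs(coh, cat, cfg)
  # cluster gap must span the annotated element for the artifact to form
  flm <- 400
  masked <- call_rp_insertions(bg, cat$elements, flm)
  unmasked <- call_rp_insertions(bg, no_ann, flm)
  expect_identical(nrow(masked), 0L)
  expect_gt(nrow(unmasked), 0L)
})
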