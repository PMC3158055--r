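# End-to-end pipeline driver over the simulator, detection, genotyping,
# and population-genetics stages.

#' Run the full MEI analysis pipeline on a simulated cohort
#'
#' Executes the stages in dependency order: catalog simulation, cohort
#' genotypes, fragment evidence, RP/SR insertion calling plus reference-MEI
#' selection, call-set merging, Bayesian genotyping, detection-thinned
#' spectra with efficiency corrections and a theta fit, per-sample
#' corrected heterozygosity with mutation-rate estimates, functional
#' suppression, and a genomic density scan. Identical `config` (including
#' its seed) gives identical results.
#'
#' @param config a [sim_config()]; its `seed` drives every stochastic
#'   stage.
#' @param out_dir optional directory for result files (catalog VCF,
#'   spectrum/fit/diversity/functional TSVs).
#' @param pi_snp_per_site reference per-site SNP heterozygosity used for
#'   the heterozygosity-based mutation-rate transform.
#' @param detect_fragments run the fragment-level RP/SR detection demo
#'   (the costliest stage; the statistical stages use the calibrated
#'   detection model either way).
#' @return list of class `mei_pipeline` with the stage artifacts.
#' @export
run_pipeline <- function(config = sim_config(seed = 1), out_dir = NULL,
                         pi_snp_per_site = 8e-4, detect_fragments = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) stop("pipeline requires a seeded config")
  catalog <- simulate_catalog(config)
  cohort <- simulate_cohort(catalog, config)
  evidence <- simulate_evidence(cohort, catalog, config,
                                fragments = detect_fragments)

  calls_rp <- calls_sr <- NULL
  if (detect_fragments) {
    calls_rp <- call_rp_insertions(evidence$fragments, catalog$elements,
                                   config$frag_len_mean)
    calls_sr <- call_sr_insertions(evidence$fragments)
  }
  dels <- simulate_deletions(catalog, config)
  calls_ref <- select_reference_mei(dels$deletions, dels$elements, dels$gaps)
  callsets <- list(DEL = calls_ref)
  if (detect_fragments) callsets <- c(list(RP = calls_rp, SR = calls_sr),
                                      callsets)
  merged <- merge_callsets(callsets, genome_length = config$genome_length)

  gt <- call_genotype_matrix(evidence$support)

  # detection model: per-mode thinning of the truth catalog at the
  # configured sensitivities, then spectra from the detected loci only
  eps_det <- c(non_reference = 1 - config$dropout_sim[["non_reference"]],
               reference = 1 - config$dropout_sim[["reference"]])
  loci <- catalog$loci
  loci$detection_mode <- ifelse(loci$on_reference, "reference",
                                "non_reference")
  detected <- loci[stats::runif(nrow(loci)) <
                     eps_det[loci$detection_mode], , drop = FALSE]
  spectrum <- build_spectrum(gt$G, gt$GQ, detected,
                             n_spectrum_samples = config$n_chrom_sampled %/% 2L)
  eps_gen <- pmax(spectrum$n_included / pmax(spectrum$n_detected, 1L), 1e-6)
  corrected <- correct_spectrum(spectrum, eps_det, eps_gen)
  fit <- fit_theta(corrected)

  diversity <- sample_diversity(gt, evidence$support, detected, eps_det,
                                pi_snp_per_site, config)
  functional <- suppression_table(
    count_by_region(make_detected_calls(detected, config), catalog$regions,
                    l_tot = config$genome_length)
  )
  density <- scan_density(merged$loci, catalog$chrom_lengths)

  result <- structure(list(
    catalog = catalog, cohort = cohort, support = evidence$support,
    calls_rp = calls_rp, calls_sr = calls_sr, calls_ref = calls_ref,
    merged = merged, genotypes = gt, spectrum = spectrum,
    corrected_spectrum = corrected, theta_fit = fit, diversity = diversity,
    functional = functional, density = density, eps_det = eps_det,
    eps_gen = eps_gen, seed = config$seed, config = config
  ), class = "mei_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# MeiLocus view of detected truth loci (point CIs widened to the RP
# precision for the containment counts).
make_detected_calls <- function(detected, config) {
  half <- as.integer(round(config$frag_len_mean / 2))
  mei_locus_df(
    chrom = detected$chrom, pos = detected$pos,
    ci_lo = pmax(1L, detected$pos - ifelse(detected$on_reference, 0L, half)),
    ci_hi = detected$pos + ifelse(detected$on_reference, 0L, half),
    family = detected$family,
    detection_mode = ifelse(detected$on_reference, "reference",
                            "non_reference"),
    methods = ifelse(detected$on_reference, "DEL", "RP")
  )
}

# Per-sample corrected heterozygosity and mutation-rate estimates.
sample_diversity <- function(gt, support, detected, eps_det,
                             pi_snp_per_site, config) {
  ids_nref <- detected$locus_id[detected$detection_mode == "non_reference"]
  ids_ref <- detected$locus_id[detected$detection_mode == "reference"]
  thr <- c(non_reference = 7, reference = 10)
  nf_mat <- with(support, {
    m <- matrix(NA_integer_, nrow(gt$G), ncol(gt$G),
                dimnames = dimnames(gt$G))
    m[cbind(match(sample_id, rownames(m)),
            match(locus_id, colnames(m)))] <- n_alt5 + n_alt3 + n_ref
    m
  })
  pi_snp <- pi_snp_per_site * config$genome_length
  rows <- lapply(rownames(gt$G), function(s) {
    pass_n <- !is.na(gt$GQ[s, ids_nref]) &
      gt$GQ[s, ids_nref] >= thr[["non_reference"]]
    pass_r <- !is.na(gt$GQ[s, ids_ref]) & gt$GQ[s, ids_ref] >= thr[["reference"]]
    het_n <- sum(gt$G[s, ids_nref][pass_n] == 1L, na.rm = TRUE)
    het_r <- sum(gt$G[s, ids_ref][pass_r] == 1L, na.rm = TRUE)
    kh <- if (any(pass_n)) k_het(nf_mat[s, ids_nref][pass_n]) else NA_real_
    eg_n <- max(1e-6, mean(pass_n))
    eg_r <- max(1e-6, mean(pass_r))
    pm <- sample_pi(het_n, het_r, k_het = max(1, kh, na.rm = TRUE),
                    eps_det_nref = eps_det[["non_reference"]],
                    eps_gen_nref = eg_n,
                    eps_det_ref = eps_det[["reference"]], eps_gen_ref = eg_r)
    mr <- mutation_rates(pm, pi_snp, genome_length = config$genome_length)
    data.frame(sample_id = s, pi_nref_raw = het_n, pi_ref_raw = het_r,
               k_het = kh, eps_gen_nref = eg_n, eps_gen_ref = eg_r,
               pi_mei = pm, mu_mei = mr$mu_mei,
               t_coal_years = mr$t_coal_years, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_mei_vcf(result$merged$loci, file.path(out_dir, "catalog.vcf.gz"))
  sp <- data.frame(i = seq_len(nrow(result$spectrum$counts)),
                   result$spectrum$counts,
                   corrected = result$corrected_spectrum$counts)
  tsv(sp, "spectrum.tsv")
  tsv(as.data.frame(result$theta_fit), "theta_fit.tsv")
  tsv(result$diversity, "diversity.tsv")
  tsv(result$functional, "functional.tsv")
  tsv(result$density$bins[result$density$bins$hotspot, , drop = FALSE],
      "hotspots.tsv")
  writeLines(c(paste("seed:", result$seed),
               paste("generated:", "meipop", as.character(utils::packageVersion("meipop")))),
             file.path(out_dir, "run_info.txt"))
  invisible(out_dir)
}
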