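# Cohort simulator: neutral-model MEI catalogs with reference-genome
# ascertainment, diploid genotypes, fragment-level evidence, and deletion
# calls for reference-MEI selection.

MEI_FAMILIES <- c("Alu", "L1", "SVA")

#' Simulation configuration
#'
#' Bundles every tunable of the MEI cohort simulator. Defaults are the study
#' conditions of the pilot-scale analysis this package models: per-family
#' diversity parameters theta (expected loci at derived-allele count i among
#' 2N chromosomes is theta/i), 2N = 50 spectrum chromosomes, a 2.85 Gb
#' accessible genome, mean fragment spanning coverage of 4 per sample,
#' target-site duplications of 15 +/- 7 bp, and family proportions of
#' roughly 85% Alu / 12% L1 / 2.5% SVA.
#'
#' @param theta_by_family named numeric, diversity parameter per family
#'   (loci scale).
#' @param n_samples_by_pop named integer, diploid samples per population.
#' @param n_chrom_sampled haploid spectrum sample size 2N (>= 2, even).
#' @param genome_length accessible genome length in bp.
#' @param coverage_mean mean informative fragments per sample and locus.
#' @param frag_len_mean,frag_len_sd sequencing library fragment length (bp).
#' @param tsd_mean,tsd_sd target-site duplication length (bp); drawn from a
#'   normal truncated at zero.
#' @param family_props named numeric family proportions summing to 1; used
#'   when drawing false calls and decoys.
#' @param fdr_sim simulated false-call rate in \[0, 1\].
#' @param dropout_sim named numeric, per-detection-mode dropout in \[0, 1\]
#'   (names `non_reference`, `reference`).
#' @param gt_error fragment misassignment rate: the expected
#'   insertion-supporting fraction is `gt_error` for genotype 0/0 and
#'   `1 - gt_error` for 1/1.
#' @param split_fraction fraction of insertion-supporting fragments carrying
#'   split-read (rather than read-pair) evidence.
#' @param bg_pairs_per_element mean number of background reference-spanning
#'   read pairs emitted per annotated element (the mapping artifact removed
#'   by annotation-proximity masking).
#' @param n_annot_elements named integer, fixed annotated elements per family
#'   for the masking track.
#' @param region_fracs named numeric genome fractions for `gene`, `UTR`,
#'   `CDS` annotation (UTR and CDS nested within genes).
#' @param region_gene_len generated gene footprint length (bp).
#' @param elem_len named integer, element length per family (bp).
#' @param pop_freq_sd per-population perturbation (sd, frequency scale) of
#'   the shared derived-allele frequency; 0 keeps frequencies identical
#'   across populations.
#' @param seed integer RNG seed or `NULL` (caller manages the RNG).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(theta_by_family = c(Alu = 1570, L1 = 224, SVA = 80),
                       n_samples_by_pop = c(CEU = 60),
                       n_chrom_sampled = 50,
                       genome_length = 2.85e9,
                       coverage_mean = 4,
                       frag_len_mean = 200,
                       frag_len_sd = 35,
                       tsd_mean = 15,
                       tsd_sd = 7,
                       family_props = c(Alu = 0.855, L1 = 0.12, SVA = 0.025),
                       fdr_sim = 0.05,
                       dropout_sim = c(non_reference = 0.3, reference = 0.1),
                       gt_error = 0.02,
                       split_fraction = 0.3,
                       bg_pairs_per_element = 2,
                       n_annot_elements = c(Alu = 400, L1 = 60, SVA = 15),
                       region_fracs = c(gene = 0.376, UTR = 0.0196, CDS = 0.0255),
                       region_gene_len = 6e4,
                       elem_len = c(Alu = 300L, L1 = 6000L, SVA = 1500L),
                       pop_freq_sd = 0,
                       seed = NULL) {
  cfg <- list(
    theta_by_family = theta_by_family, n_samples_by_pop = n_samples_by_pop,
    n_chrom_sampled = as.integer(n_chrom_sampled),
    genome_length = genome_length, coverage_mean = coverage_mean,
    frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
    tsd_mean = tsd_mean, tsd_sd = tsd_sd, family_props = family_props,
    fdr_sim = fdr_sim, dropout_sim = dropout_sim, gt_error = gt_error,
    split_fraction = split_fraction,
    bg_pairs_per_element = bg_pairs_per_element,
    n_annot_elements = n_annot_elements, region_fracs = region_fracs,
    region_gene_len = region_gene_len, elem_len = elem_len,
    pop_freq_sd = pop_freq_sd, seed = seed
  )
  stopifnot(
    all(cfg$theta_by_family >= 0),
    all(names(cfg$theta_by_family) %in% MEI_FAMILIES),
    cfg$n_chrom_sampled >= 2, cfg$n_chrom_sampled %% 2 == 0,
    cfg$genome_length > 0,
    abs(sum(cfg$family_props) - 1) <= 1e-9,
    cfg$fdr_sim >= 0, cfg$fdr_sim <= 1,
    all(cfg$dropout_sim >= 0), all(cfg$dropout_sim <= 1),
    cfg$gt_error >= 0, cfg$gt_error <= 0.5,
    cfg$split_fraction >= 0, cfg$split_fraction <= 1,
    all(cfg$region_fracs > 0), sum(cfg$region_fracs[c("gene")]) < 1,
    cfg$region_fracs[["UTR"]] + cfg$region_fracs[["CDS"]] <
      cfg$region_fracs[["gene"]],
    all(n_samples_by_pop >= 1)
  )
  if (cfg$coverage_mean <= 0) stop("coverage_mean must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# The accessible genome is carved into equal-length synthetic chromosomes so
# every coordinate stays within integer range for interval arithmetic.
sim_chrom_lengths <- function(genome_length) {
  n <- max(1L, ceiling(genome_length / 2e8))
  len <- floor(genome_length / n)
  stats::setNames(rep(len, n), paste0("chr", seq_len(n)))
}

sample_positions <- function(n, chrom_lengths) {
  chrom <- sample(names(chrom_lengths), n, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  pos <- floor(stats::runif(n) * chrom_lengths[chrom]) + 1
  data.frame(chrom = chrom, pos = as.integer(pos), stringsAsFactors = FALSE)
}

# Gene/UTR/CDS annotation: genes placed on a regular grid (one per slot, so
# they never overlap), each carrying a UTR block and a CDS block at its
# 5' end sized so the genome-wide class fractions match region_fracs.
make_region_track <- function(config, chrom_lengths) {
  gene_len <- config$region_gene_len
  fr <- config$region_fracs
  total <- sum(chrom_lengths)
  rows <- vector("list", length(chrom_lengths))
  utr_len <- max(1L, round(gene_len * fr[["UTR"]] / fr[["gene"]]))
  cds_len <- max(1L, round(gene_len * fr[["CDS"]] / fr[["gene"]]))
  for (ci in seq_along(chrom_lengths)) {
    clen <- chrom_lengths[ci]
    n_genes <- max(1L, round(clen * fr[["gene"]] / gene_len))
    slot <- floor(clen / n_genes)
    start <- as.integer((seq_len(n_genes) - 1) * slot +
      floor(stats::runif(n_genes, 0, pmax(1, slot - gene_len))) + 1)
    end <- as.integer(pmin(start + gene_len - 1, clen))
    ch <- names(chrom_lengths)[ci]
    rows[[ci]] <- rbind(
      data.frame(chrom = ch, start = start, end = end, class = "gene",
                 stringsAsFactors = FALSE),
      data.frame(chrom = ch, start = start, end = start + utr_len - 1L,
                 class = "UTR", stringsAsFactors = FALSE),
      data.frame(chrom = ch, start = start + utr_len,
                 end = start + utr_len + cds_len - 1L, class = "CDS",
                 stringsAsFactors = FALSE)
    )
  }
  do.call(rbind, rows)
}

classify_region <- function(chrom, pos, regions) {
  cls <- rep("intergenic", length(pos))
  for (class in c("gene", "UTR", "CDS")) { # later classes override
    r <- regions[regions$class == class, ]
    if (nrow(r) == 0L) next
    hit <- GenomicRanges::findOverlaps(
      df_to_granges(data.frame(chrom = chrom, start = pos, end = pos)),
      df_to_granges(r)
    )
    cls[unique(S4Vectors::queryHits(hit))] <- class
  }
  cls
}

#' Simulate a neutral-model MEI locus catalog with reference ascertainment
#'
#' For each element family the number of loci at derived-allele count
#' `i = 1..2N-1` among the `2N` spectrum chromosomes is Poisson with mean
#' `theta/i` (infinite-sites standard neutral model). Each locus is flagged
#' `on_reference` when a uniformly chosen reference chromosome carries the
#' derived allele (probability `i/2N`), splitting the catalog into reference
#' MEI (detected as deletions) and non-reference MEI (detected as
#' insertions). Positions are uniform over the accessible genome; TSD
#' lengths are truncated-normal; a gene/UTR/CDS region track and a fixed
#' element-annotation track (for detection masking) are generated alongside.
#'
#' @param config a [sim_config()].
#' @return list of class `mei_catalog` with elements `loci` (one row per
#'   polymorphic locus), `elements` (annotated-element track), `regions`
#'   (gene/UTR/CDS track), `chrom_lengths`, and `config`.
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n2 <- config$n_chrom_sampled
  chrom_lengths <- sim_chrom_lengths(config$genome_length)

  per_family <- lapply(names(config$theta_by_family), function(fam) {
    theta <- config$theta_by_family[[fam]]
    if (theta == 0) return(NULL)
    i_vals <- seq_len(n2 - 1L)
    n_i <- stats::rpois(n2 - 1L, theta / i_vals)
    allele_count <- rep(i_vals, n_i)
    k <- length(allele_count)
    if (k == 0L) return(NULL)
    data.frame(family = fam, allele_count = allele_count,
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, per_family)
  regions <- make_region_track(config, chrom_lengths)
  elements <- {
    n_el <- config$n_annot_elements
    fam <- rep(names(n_el), n_el)
    p <- sample_positions(length(fam), chrom_lengths)
    data.frame(chrom = p$chrom, start = p$pos,
               end = p$pos + as.integer(config$elem_len[fam]) - 1L,
               family = fam, stringsAsFactors = FALSE)
  }
  if (is.null(loci)) {
    loci <- data.frame(locus_id = character(0), chrom = character(0),
                       pos = integer(0), family = character(0),
                       strand = character(0), tsd_len = integer(0),
                       allele_count = integer(0), freq = numeric(0),
                       on_reference = logical(0), region_class = character(0),
                       stringsAsFactors = FALSE)
    return(structure(list(loci = loci, elements = elements, regions = regions,
                          chrom_lengths = chrom_lengths, config = config),
                     class = "mei_catalog"))
  }
  k <- nrow(loci)
  p <- sample_positions(k, chrom_lengths)
  loci$chrom <- p$chrom
  loci$pos <- p$pos
  loci$strand <- sample(c("+", "-"), k, replace = TRUE)
  loci$tsd_len <- as.integer(round(rtruncnorm0(k, config$tsd_mean,
                                               config$tsd_sd)))
  loci$freq <- loci$allele_count / n2
  loci$on_reference <- stats::rbinom(k, 1L, loci$allele_count / n2) == 1L
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  loci$locus_id <- sprintf("MEI%06d", seq_len(k))
  loci$region_class <- classify_region(loci$chrom, loci$pos, regions)
  for (pop in names(config$n_samples_by_pop)) {
    f <- loci$freq
    if (config$pop_freq_sd > 0) {
      f <- pmin(1, pmax(1 / n2, f + stats::rnorm(k, 0, config$pop_freq_sd)))
    }
    loci[[paste0("freq_", pop)]] <- f
  }
  rownames(loci) <- NULL
  structure(list(loci = loci, elements = elements, regions = regions,
                 chrom_lengths = chrom_lengths, config = config),
            class = "mei_catalog")
}

#' Simulate diploid genotypes for a cohort
#'
#' Samples outside the spectrum panel draw genotypes independently as
#' Binomial(2, f) per locus (Hardy-Weinberg proportions). The first N = 2N/2
#' samples of the first population form the spectrum panel: their 2N
#' chromosomes carry exactly the catalog's drawn derived-allele count per
#' locus, with chromosome 1 of the first sample designated as the reference
#' haplotype (it carries the derived allele iff the locus is flagged
#' `on_reference`). This makes the ascertainment split of the panel spectrum
#' exact rather than approximate.
#'
#' @param catalog a [simulate_catalog()] result.
#' @param config the [sim_config()] used for the catalog.
#' @return list of class `mei_cohort`: `genotypes` (samples x loci integer
#'   matrix of derived-allele copies), `samples` (sample_id, pop),
#'   `panel_samples`, `ref_sample`.
#' @export
simulate_cohort <- function(catalog, config) {
  loci <- catalog$loci
  pops <- names(config$n_samples_by_pop)
  samples <- do.call(rbind, lapply(pops, function(pop) {
    n <- config$n_samples_by_pop[[pop]]
    data.frame(sample_id = sprintf("%s_%03d", pop, seq_len(n)), pop = pop,
               stringsAsFactors = FALSE)
  }))
  n_s <- nrow(samples)
  n_l <- nrow(loci)
  g <- matrix(0L, n_s, n_l, dimnames = list(samples$sample_id, loci$locus_id))
  if (n_l > 0L) {
    for (pop in pops) {
      rows <- which(samples$pop == pop)
      f <- loci[[paste0("freq_", pop)]]
      stopifnot(all(f >= 0), all(f <= 1))
      g[rows, ] <- matrix(
        stats::rbinom(length(rows) * n_l, 2L, rep(f, each = length(rows))),
        length(rows), n_l
      )
    }
    # spectrum panel: exact allele counts conditional on the catalog draw
    n2 <- config$n_chrom_sampled
    n_panel <- n2 %/% 2L
    panel_rows <- which(samples$pop == pops[1])[seq_len(n_panel)]
    if (any(is.na(panel_rows))) {
      stop("first population must have at least n_chrom_sampled/2 samples")
    }
    for (l in seq_len(n_l)) {
      i <- loci$allele_count[l]
      carriers <- logical(n2)
      carriers[1L] <- loci$on_reference[l]
      extra <- i - as.integer(carriers[1L])
      if (extra > 0L) carriers[sample(2:n2, extra)] <- TRUE
      g[panel_rows, l] <- carriers[c(TRUE, FALSE)] + carriers[c(FALSE, TRUE)]
    }
  }
  structure(list(genotypes = g, samples = samples,
                 panel_samples = samples$sample_id[
                   which(samples$pop == pops[1])[seq_len(config$n_chrom_sampled %/% 2L)]],
                 ref_sample = samples$sample_id[1]),
            class = "mei_cohort")
}

#' Simulate fragment-level evidence
#'
#' Per sample and locus the number of informative fragments NF is
#' Poisson(`coverage_mean`); insertion-supporting fragments are
#' Binomial(NF, p_g) with p_g = `gt_error`, 0.5, `1 - gt_error` for
#' genotypes 0/1/2, and split between the 5' and 3' breakpoint sides as
#' Binomial(., 0.5). With `fragments = TRUE`, per-fragment mapped records
#' are emitted for the detection module (read-pair anchors or split-read
#' reference extents bracketing the TSD), together with background
#' reference-spanning pairs near annotated elements whose fragment lengths
#' sample the extreme tail of the library distribution -- the mapping
#' artifact that annotation-proximity masking removes.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param catalog the matching [simulate_catalog()] result.
#' @param config the [sim_config()].
#' @param fragments emit per-fragment records (may be large)?
#' @return list with `support` (locus_id, sample_id, n_alt5, n_alt3, n_ref)
#'   and `fragments` (NULL unless requested).
#' @export
simulate_evidence <- function(cohort, catalog, config, fragments = TRUE) {
  if (config$coverage_mean <= 0) stop("coverage_mean must be positive")
  g <- cohort$genotypes
  loci <- catalog$loci
  n_s <- nrow(g); n_l <- ncol(g)
  nf <- stats::rpois(n_s * n_l, config$coverage_mean)
  p_g <- c(config$gt_error, 0.5, 1 - config$gt_error)[as.vector(g) + 1L]
  n_alt <- stats::rbinom(n_s * n_l, nf, p_g)
  n_alt5 <- stats::rbinom(n_s * n_l, n_alt, 0.5)
  support <- data.frame(
    locus_id = rep(colnames(g), each = n_s),
    sample_id = rep(rownames(g), times = n_l),
    n_alt5 = n_alt5, n_alt3 = n_alt - n_alt5, n_ref = nf - n_alt,
    stringsAsFactors = FALSE
  )
  frag <- NULL
  if (fragments && n_l > 0L) {
    li <- rep(rep(seq_len(n_l), each = n_s), times = 2L)
    side <- rep(c("5p", "3p"), each = n_s * n_l)
    count <- c(n_alt5, n_alt - n_alt5)
    keep <- count > 0L
    li <- rep(li[keep], count[keep])
    side <- rep(side[keep], count[keep])
    sid <- rep(rep(rownames(g), times = 2L * n_l)[keep], count[keep])
    n_f <- length(li)
    flen <- pmax(50L, as.integer(round(stats::rnorm(n_f, config$frag_len_mean,
                                                    config$frag_len_sd))))
    split <- stats::runif(n_f) < config$split_fraction
    pos <- loci$pos[li]
    tsd <- loci$tsd_len[li]
    off <- as.integer(round(stats::runif(n_f, 0.15, 0.85) * flen))
    anchor <- ifelse(side == "5p", pos - off, pos + off)
    seg <- as.integer(round(stats::runif(n_f, 30, 150)))
    ref_start <- ifelse(split, ifelse(side == "5p", pos - seg, pos), NA_integer_)
    ref_end <- ifelse(split, ifelse(side == "5p", pos + tsd - 1L, pos + seg),
                      NA_integer_)
    anchor[split] <- ifelse(side[split] == "5p", ref_start[split],
                            ref_end[split])
    frag <- data.frame(
      sample_id = sid, chrom = loci$chrom[li], anchor_pos = anchor,
      side = side, frag_len = flen, family = loci$family[li], split = split,
      ref_start = ref_start, ref_end = ref_end, stringsAsFactors = FALSE
    )
    frag <- rbind(frag, simulate_background_pairs(cohort, catalog, config))
  }
  list(support = support, fragments = frag)
}

# Background read pairs bracketing annotated elements: library-tail fragment
# lengths make them look like insertion evidence of the element's family.
simulate_background_pairs <- function(cohort, catalog, config) {
  el <- catalog$elements
  nb <- stats::rpois(nrow(el), config$bg_pairs_per_element)
  ei <- rep(seq_len(nrow(el)), nb)
  n_f <- length(ei)
  if (n_f == 0L) return(NULL)
  side <- sample(c("5p", "3p"), n_f, replace = TRUE)
  gap <- as.integer(round(stats::runif(n_f, 1, 150)))
  anchor <- ifelse(side == "5p", el$start[ei] - gap, el$end[ei] + gap)
  flen <- as.integer(round(config$frag_len_mean +
    config$frag_len_sd * stats::qnorm(stats::runif(n_f, 0.9995, 1 - 1e-12))))
  data.frame(
    sample_id = sample(cohort$samples$sample_id, n_f, replace = TRUE),
    chrom = el$chrom[ei], anchor_pos = anchor, side = side, frag_len = flen,
    family = el$family[ei], split = FALSE, ref_start = NA_integer_,
    ref_end = NA_integer_, stringsAsFactors = FALSE
  )
}

#' Simulate deletion calls for reference-MEI selection
#'
#' Every `on_reference` catalog locus yields a deletion interval spanning
#' the inserted element, an element annotation at the exact position, and a
#' matching chimpanzee-assembly gap. Endpoints can be jittered, and decoy
#' deletions (insufficient reciprocal overlap, or no ancestral gap) can be
#' added to exercise the selection filters.
#'
#' @param catalog a [simulate_catalog()] result.
#' @param config the [sim_config()].
#' @param jitter_sd endpoint noise sd in bp (0 = exact).
#' @param decoy_fraction decoys added as a fraction of true deletions.
#' @return list with `deletions` (chrom, start, end, id, is_decoy),
#'   `elements`, `gaps` interval tables (1-based inclusive).
#' @export
simulate_deletions <- function(catalog, config, jitter_sd = 0,
                               decoy_fraction = 0) {
  refs <- catalog$loci[catalog$loci$on_reference, , drop = FALSE]
  if (nrow(refs) == 0L) stop("catalog has no on_reference loci")
  len <- as.integer(config$elem_len[refs$family])
  start <- refs$pos
  end <- refs$pos + len - 1L
  js <- as.integer(round(stats::rnorm(nrow(refs), 0, jitter_sd)))
  je <- as.integer(round(stats::rnorm(nrow(refs), 0, jitter_sd)))
  deletions <- data.frame(
    chrom = refs$chrom, start = pmax(1L, start + js),
    end = pmax(start + js + 1L, end + je),
    id = paste0("DEL_", refs$locus_id), is_decoy = FALSE,
    stringsAsFactors = FALSE
  )
  elements <- data.frame(chrom = refs$chrom, start = start, end = end,
                         family = refs$family, stringsAsFactors = FALSE)
  gaps <- data.frame(chrom = refs$chrom, start = pmax(1L, start - 50L),
                     end = end + 50L, stringsAsFactors = FALSE)
  n_d <- round(decoy_fraction * nrow(refs))
  if (n_d > 0L) {
    fam <- sample(names(config$family_props), n_d, replace = TRUE,
                  prob = config$family_props)
    dlen <- as.integer(config$elem_len[fam])
    p <- sample_positions(n_d, catalog$chrom_lengths)
    type <- rep_len(c("overlap", "nogap"), n_d)
    shift <- ifelse(type == "overlap", as.integer(round(0.6 * dlen)), 0L)
    deletions <- rbind(deletions, data.frame(
      chrom = p$chrom, start = p$pos + shift, end = p$pos + shift + dlen - 1L,
      id = sprintf("DECOY_%04d", seq_len(n_d)), is_decoy = TRUE,
      stringsAsFactors = FALSE
    ))
    elements <- rbind(elements, data.frame(
      chrom = p$chrom, start = p$pos, end = p$pos + dlen - 1L, family = fam,
      stringsAsFactors = FALSE
    ))
    keep_gap <- type == "overlap"
    if (any(keep_gap)) {
      gaps <- rbind(gaps, data.frame(
        chrom = p$chrom[keep_gap],
        start = pmax(1L, p$pos[keep_gap] + shift[keep_gap] - 50L),
        end = p$pos[keep_gap] + shift[keep_gap] + dlen[keep_gap] + 49L,
        stringsAsFactors = FALSE
      ))
    }
  }
  list(deletions = deletions, elements = elements, gaps = gaps)
}

#' Thin a locus set through a detection model
#'
#' Applies per-locus detection dropout and adds uniformly placed false
#' calls at a given false-detection rate, producing one observed call set
#' from a truth catalog (used for capture-recapture and leakage studies).
#'
#' @param loci truth loci (rows of `catalog$loci` or any table with
#'   `locus_id`, `chrom`, `pos`, `family`).
#' @param sensitivity per-locus retention probability in (0, 1\].
#' @param fdr fraction of the emitted call set that is false.
#' @param catalog the catalog (for chromosome lengths when placing false
#'   calls); optional when `fdr = 0`.
#' @return the thinned call table with an `is_true` flag.
#' @export
simulate_callset <- function(loci, sensitivity, fdr = 0, catalog = NULL) {
  stopifnot(sensitivity > 0, sensitivity <= 1, fdr >= 0, fdr < 1)
  kept <- loci[stats::runif(nrow(loci)) < sensitivity, , drop = FALSE]
  kept <- kept[, c("locus_id", "chrom", "pos", "family")]
  kept$is_true <- TRUE
  if (fdr > 0) {
    stopifnot(!is.null(catalog))
    n_false <- round(nrow(kept) * fdr / (1 - fdr))
    if (n_false > 0L) {
      p <- sample_positions(n_false, catalog$chrom_lengths)
      fam <- sample(names(catalog$config$family_props), n_false,
                    replace = TRUE, prob = catalog$config$family_props)
      kept <- rbind(kept, data.frame(
        locus_id = sprintf("FP%06d", seq_len(n_false)), chrom = p$chrom,
        pos = p$pos, family = fam, is_true = FALSE, stringsAsFactors = FALSE
      ))
    }
  }
  rownames(kept) <- NULL
  kept
}
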