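# Bayesian genotype calling from fragment support counts, with phred-scaled
# genotype qualities and concordance / HWE / Mendelian QC.

#' Genotype model parameters
#'
#' The posterior for genotype g given N_ALT insertion-supporting and N_REF
#' reference-supporting fragments is proportional to
#' `P(g) * Binomial(N_ALT; N_ALT + N_REF, p_g)`, where p_g is the expected
#' insertion-supporting fragment fraction: ~0 for 0/0, 0.5 for 0/1, ~1 for
#' 1/1. The default `p_hom_ref = 0.02` (hence `p_hom_alt = 0.98`) absorbs
#' fragment misassignment at homozygous sites and places two concordant
#' fragments just across the GQ 7 threshold.
#'
#' @param prior genotype prior over (0/0, 0/1, 1/1); flat by default.
#' @param p_hom_ref expected insertion-fragment fraction for 0/0.
#' @param p_het expected fraction for 0/1.
#' @param p_hom_alt expected fraction for 1/1 (default `1 - p_hom_ref`).
#' @param gq_cap phred cap for reported GQ.
#' @return list of class `genotype_model`.
#' @export
genotype_model <- function(prior = c(1, 1, 1) / 3, p_hom_ref = 0.02,
                           p_het = 0.5, p_hom_alt = 1 - p_hom_ref,
                           gq_cap = 99) {
  m <- list(prior = prior, p = c(p_hom_ref, p_het, p_hom_alt),
            gq_cap = gq_cap)
  stopifnot(length(prior) == 3, all(prior >= 0),
            abs(sum(prior) - 1) <= 1e-9,
            all(m$p >= 0), all(m$p <= 1), gq_cap > 0)
  class(m) <- "genotype_model"
  m
}

#' Call genotypes from fragment support counts
#'
#' Vectorised over loci/samples. The called genotype maximises the
#' posterior (ties broken toward 0/0 < 0/1 < 1/1); GQ is the phred-scaled
#' probability that the call is wrong, `-10 log10(1 - max posterior)`,
#' rounded to an integer as in VCF and capped. A site with zero fragments
#' has a flat posterior and is assigned GQ 0 (no genotype evidence).
#'
#' @param n_alt,n_ref non-negative counts of insertion- and
#'   reference-supporting fragments.
#' @param model a [genotype_model()].
#' @return data.frame with `g` (0/1/2 insertion-allele copies), `gt`
#'   (VCF-style string), posterior columns `p_g0`, `p_g1`, `p_g2`, `gq`,
#'   and the input counts.
#' @export
call_genotype <- function(n_alt, n_ref, model = genotype_model()) {
  stopifnot(inherits(model, "genotype_model"),
            all(n_alt >= 0), all(n_ref >= 0))
  n <- n_alt + n_ref
  ll <- vapply(1:3, function(k) {
    stats::dbinom(n_alt, n, model$p[k], log = TRUE) + log(model$prior[k])
  }, numeric(length(n_alt)))
  ll <- matrix(ll, ncol = 3L)
  m <- apply(ll, 1L, max)
  post <- exp(ll - m)
  post <- post / rowSums(post)
  g <- max.col(post, ties.method = "first") - 1L
  p_max <- post[cbind(seq_along(g), g + 1L)]
  p_err <- pmax(1 - p_max, 10^(-model$gq_cap / 10))
  gq <- as.integer(pmin(model$gq_cap, round(-10 * log10(p_err))))
  gq[n == 0L] <- 0L
  data.frame(g = g, gt = c("0/0", "0/1", "1/1")[g + 1L],
             p_g0 = post[, 1], p_g1 = post[, 2], p_g2 = post[, 3],
             gq = gq, n_alt = n_alt, n_ref = n_ref)
}

#' Genotype a support-count table into matrices
#'
#' Applies [call_genotype()] to a long support table and reshapes the
#' calls into samples x loci genotype and GQ matrices.
#'
#' @param support table with `locus_id`, `sample_id`, `n_alt5`, `n_alt3`,
#'   `n_ref`.
#' @param model a [genotype_model()].
#' @return list with integer matrix `G` (0/1/2) and integer matrix `GQ`.
#' @export
call_genotype_matrix <- function(support, model = genotype_model()) {
  calls <- call_genotype(support$n_alt5 + support$n_alt3, support$n_ref,
                         model)
  samples <- unique(support$sample_id)
  loci <- unique(support$locus_id)
  g <- matrix(NA_integer_, length(samples), length(loci),
              dimnames = list(samples, loci))
  gq <- g
  idx <- cbind(match(support$sample_id, samples),
               match(support$locus_id, loci))
  g[idx] <- calls$g
  gq[idx] <- calls$gq
  list(G = g, GQ = gq)
}

#' Genotype concordance against a truth set
#'
#' Builds the 3x3 contingency table of called vs true genotypes for calls
#' passing a GQ threshold; agreement is the diagonal fraction, efficiency
#' the fraction of site-sample pairs entering the table.
#'
#' @param calls,truth genotype vectors (0/1/2 or "0/0"-style strings) on
#'   identical site x sample keys.
#' @param gq per-call genotype qualities (optional).
#' @param gq_threshold minimum GQ for a call to enter the table.
#' @return list with `table`, `agreement`, `efficiency`, `n`.
#' @export
concordance <- function(calls, truth, gq = NULL, gq_threshold = 0) {
  as_gt <- function(x) {
    if (is.numeric(x)) x <- c("0/0", "0/1", "1/1")[x + 1L]
    factor(x, levels = c("0/0", "0/1", "1/1"))
  }
  stopifnot(length(calls) == length(truth))
  keep <- !is.na(calls) & !is.na(truth)
  if (!is.null(gq)) keep <- keep & !is.na(gq) & gq >= gq_threshold
  tab <- table(called = as_gt(calls[keep]), truth = as_gt(truth[keep]))
  n <- sum(tab)
  list(table = tab,
       agreement = if (n > 0) sum(diag(tab)) / n else NA_real_,
       efficiency = sum(keep) / length(calls),
       n = n)
}

#' Genotype QC: Hardy-Weinberg proportions and Mendelian errors
#'
#' Bins loci by insertion-allele frequency and compares observed genotype
#' proportions with the Hardy-Weinberg expectations (1-f)^2, 2f(1-f), f^2.
#' For trio pedigrees, counts child genotypes impossible under Mendelian
#' transmission of the insertion allele.
#'
#' @param G samples x loci genotype matrix (0/1/2, NA = missing).
#' @param pedigrees optional data.frame with `child`, `father`, `mother`
#'   sample ids (rownames of `G`).
#' @param n_bins number of allele-frequency bins.
#' @return list with `hwe` (per-bin observed and expected proportions) and
#'   `mendelian_errors` (NA without pedigrees).
#' @export
genotype_qc <- function(G, pedigrees = NULL, n_bins = 10) {
  n_gt <- colSums(!is.na(G))
  f <- colSums(G, na.rm = TRUE) / (2 * pmax(1L, n_gt))
  bin <- cut(f, breaks = seq(0, 1, length.out = n_bins + 1),
             include.lowest = TRUE)
  hwe <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- which(bin == b & n_gt > 0)
    if (!length(sel)) return(NULL)
    gsub <- G[, sel, drop = FALSE]
    counts <- c(sum(gsub == 0L, na.rm = TRUE), sum(gsub == 1L, na.rm = TRUE),
                sum(gsub == 2L, na.rm = TRUE))
    fb <- mean(f[sel])
    data.frame(bin = b, f = fb, n = sum(counts),
               obs_rr = counts[1] / sum(counts),
               obs_het = counts[2] / sum(counts),
               obs_aa = counts[3] / sum(counts),
               exp_rr = (1 - fb)^2, exp_het = 2 * fb * (1 - fb),
               exp_aa = fb^2)
  }))
  me <- NA_integer_
  if (!is.null(pedigrees)) {
    me <- 0L
    for (i in seq_len(nrow(pedigrees))) {
      me <- me + mendelian_errors(G[pedigrees$child[i], ],
                                  G[pedigrees$father[i], ],
                                  G[pedigrees$mother[i], ])
    }
  }
  list(hwe = hwe, mendelian_errors = me)
}

#' Count Mendelian-inconsistent child genotypes
#'
#' A child genotype is an error when it cannot be formed by one allele
#' transmitted from each parent (e.g. 0/1 child from 0/0 x 0/0 parents).
#' Missing genotypes in any trio member are skipped.
#'
#' @param child,father,mother genotype vectors (0/1/2 insertion-allele
#'   copies) over the same loci.
#' @return integer error count.
#' @export
mendelian_errors <- function(child, father, mother) {
  ok <- !is.na(child) & !is.na(father) & !is.na(mother)
  child <- child[ok]; father <- father[ok]; mother <- mother[ok]
  # transmissible allele range per parent genotype
  lo <- function(g) as.integer(g == 2L)
  hi <- function(g) as.integer(g >= 1L)
  bad <- child < lo(father) + lo(mother) | child > hi(father) + hi(mother)
  sum(bad)
}
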