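# Unified MEI catalog: merging call sets, cross-study matching, genomic
# density scanning, and trio de novo screening.

split_methods <- function(x) sort(unique(unlist(strsplit(x, ",", fixed = TRUE))))

#' Merge MEI call sets into a unified catalog
#'
#' Same-family loci within `window_bp` of each other are merged
#' transitively (single linkage). The merged record takes the split-read
#' coordinate when any member carries SR evidence (SR breakpoints are
#' base-pair precise through the target-site duplication), otherwise the
#' coordinate of the best-supported read-pair member; methods are unioned
#' and supporting-fragment counts summed. Merging is idempotent: merged
#' representatives always lie at least `window_bp + 1` apart.
#'
#' @param callsets a single `MeiLocus` table or a (optionally named) list
#'   of them.
#' @param window_bp merge window in bp (default 100).
#' @param genome_length optional accessible genome length carried on the
#'   catalog for density scans.
#' @return list of class `mei_catalog_set` with `loci` (merged, sorted),
#'   `provenance` (per merged locus, the contributing call sets), and
#'   `genome_length`.
#' @export
merge_callsets <- function(callsets, window_bp = 100, genome_length = NULL) {
  if (is.data.frame(callsets)) callsets <- list(callsets)
  if (is.null(names(callsets)) || any(names(callsets) == "")) {
    names(callsets) <- paste0("callset", seq_along(callsets))
  }
  std_cols <- names(mei_locus_df())
  all <- do.call(rbind, lapply(names(callsets), function(nm) {
    x <- callsets[[nm]][, std_cols, drop = FALSE]
    if (nrow(x)) x$source <- nm
    x
  }))
  if (is.null(all) || nrow(all) == 0L) {
    return(structure(list(loci = mei_locus_df(), provenance = list(),
                          genome_length = genome_length),
                     class = "mei_catalog_set"))
  }
  key <- paste(all$chrom, all$family, all$detection_mode)
  merged <- list()
  prov <- list()
  for (sub in split(all, key)) {
    cl <- cluster_1d(sub$pos, window_bp)
    for (ix in split(seq_len(nrow(sub)), cl)) {
      cc <- sub[ix, , drop = FALSE]
      has_sr <- vapply(cc$methods, function(m) "SR" %in% split_methods(m),
                       logical(1))
      pool <- if (any(has_sr)) cc[has_sr, , drop = FALSE] else cc
      support <- pool$n_alt5 + pool$n_alt3
      rep_row <- pool[order(-support, pool$pos)[1], , drop = FALSE]
      rep_row$methods <- paste(split_methods(cc$methods), collapse = ",")
      rep_row$n_alt5 <- sum(cc$n_alt5)
      rep_row$n_alt3 <- sum(cc$n_alt3)
      if (anyNA(rep_row$tsd_len) && !all(is.na(cc$tsd_len))) {
        rep_row$tsd_len <- cc$tsd_len[!is.na(cc$tsd_len)][1]
      }
      merged[[length(merged) + 1L]] <- rep_row
      prov[[length(prov) + 1L]] <- sort(unique(cc$source))
    }
  }
  loci <- do.call(rbind, merged)
  o <- order(loci$chrom, loci$pos)
  loci <- loci[o, , drop = FALSE]
  loci$source <- NULL
  loci$locus_id <- sprintf("CAT%06d", seq_len(nrow(loci)))
  rownames(loci) <- NULL
  structure(list(loci = loci, provenance = prov[o],
                 genome_length = genome_length),
            class = "mei_catalog_set")
}

#' Match loci between two catalogs
#'
#' One-to-one greedy nearest-first matching, restricted to same-family
#' pairs. `window200` matches insertion positions within a fixed window
#' (inclusive); `reciprocal50` matches intervals (`ci_lo`..`ci_hi`, e.g.
#' deletion coordinates) requiring strictly more than 50\% reciprocal
#' overlap. Ties break toward the lower coordinate, so matching is
#' deterministic and no locus is counted twice.
#'
#' @param catalog_a,catalog_b `MeiLocus` tables (or `mei_catalog_set`s).
#' @param mode `"window200"` or `"reciprocal50"`.
#' @param window matching window in bp for `window200`.
#' @return list with `matched` (idx_a, idx_b, distance), `only_a`,
#'   `only_b` (row indices), and the three counts.
#' @export
match_loci <- function(catalog_a, catalog_b,
                       mode = c("window200", "reciprocal50"), window = 200) {
  mode <- match.arg(mode)
  a <- if (inherits(catalog_a, "mei_catalog_set")) catalog_a$loci else catalog_a
  b <- if (inherits(catalog_b, "mei_catalog_set")) catalog_b$loci else catalog_b
  cand <- NULL
  if (nrow(a) && nrow(b)) {
    if (mode == "window200") {
      gr_a <- df_to_granges(data.frame(chrom = a$chrom, start = a$pos - window,
                                       end = a$pos + window))
      gr_b <- df_to_granges(data.frame(chrom = b$chrom, start = b$pos,
                                       end = b$pos))
      h <- GenomicRanges::findOverlaps(gr_a, gr_b)
      ia <- S4Vectors::queryHits(h); ib <- S4Vectors::subjectHits(h)
      ok <- a$family[ia] == b$family[ib]
      ia <- ia[ok]; ib <- ib[ok]
      score <- abs(a$pos[ia] - b$pos[ib])
    } else {
      gr_a <- df_to_granges(a, "ci_lo", "ci_hi")
      gr_b <- df_to_granges(b, "ci_lo", "ci_hi")
      h <- GenomicRanges::findOverlaps(gr_a, gr_b)
      ia <- S4Vectors::queryHits(h); ib <- S4Vectors::subjectHits(h)
      ov <- overlap_len(a$ci_lo[ia], a$ci_hi[ia], b$ci_lo[ib], b$ci_hi[ib])
      ro <- pmin(ov / (a$ci_hi[ia] - a$ci_lo[ia] + 1),
                 ov / (b$ci_hi[ib] - b$ci_lo[ib] + 1))
      ok <- ro > 0.5 & a$family[ia] == b$family[ib]
      ia <- ia[ok]; ib <- ib[ok]
      score <- 1 - ro[ok] # smaller is better
    }
    if (length(ia)) {
      o <- order(score, a$pos[ia], b$pos[ib])
      used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
      keep <- logical(length(ia))
      for (j in o) {
        if (!used_a[ia[j]] && !used_b[ib[j]]) {
          keep[j] <- TRUE
          used_a[ia[j]] <- TRUE
          used_b[ib[j]] <- TRUE
        }
      }
      cand <- data.frame(idx_a = ia[keep], idx_b = ib[keep],
                         distance = if (mode == "window200")
                           abs(a$pos[ia[keep]] - b$pos[ib[keep]])
                         else NA_real_)
    }
  }
  if (is.null(cand)) {
    cand <- data.frame(idx_a = integer(0), idx_b = integer(0),
                       distance = numeric(0))
  }
  list(matched = cand,
       only_a = setdiff(seq_len(nrow(a)), cand$idx_a),
       only_b = setdiff(seq_len(nrow(b)), cand$idx_b),
       n_matched = nrow(cand),
       n_only_a = nrow(a) - nrow(cand),
       n_only_b = nrow(b) - nrow(cand))
}

#' Scan MEI density along the genome
#'
#' Counts loci in non-overlapping bins and tests each against the uniform
#' null (Poisson with mean `n_loci * bin_bp / genome_length`), flagging
#' Bonferroni-significant hotspots. Also reports the mean inter-locus
#' spacing `genome_length / n_loci`.
#'
#' @param loci `MeiLocus` table or `mei_catalog_set`.
#' @param chrom_lengths named chromosome lengths in bp; a single unnamed
#'   value is treated as one chromosome spanning the accessible genome.
#' @param bin_bp bin width in bp.
#' @param alpha family-wise significance level for the hotspot flag.
#' @return list with `bins` (chrom, start, end, count, p, hotspot),
#'   `lambda`, `mean_spacing`, `n_loci`, `n_hotspots`.
#' @export
scan_density <- function(loci, chrom_lengths, bin_bp = 1e6, alpha = 0.05) {
  if (inherits(loci, "mei_catalog_set")) loci <- loci$loci
  if (is.null(names(chrom_lengths)) && length(chrom_lengths) == 1L) {
    chrom_lengths <- stats::setNames(chrom_lengths, unique(loci$chrom)[1] %||% "chr1")
  }
  genome_length <- sum(chrom_lengths)
  stopifnot(genome_length > 0)
  bins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    n_bins <- ceiling(chrom_lengths[[ch]] / bin_bp)
    start <- (seq_len(n_bins) - 1) * bin_bp + 1
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_bp - 1, chrom_lengths[[ch]]),
               stringsAsFactors = FALSE)
  }))
  counts <- integer(nrow(bins))
  for (ch in unique(loci$chrom)) {
    sel <- bins$chrom == ch
    idx <- findInterval(loci$pos[loci$chrom == ch], bins$start[sel])
    tab <- table(idx)
    counts[which(sel)[as.integer(names(tab))]] <- as.integer(tab)
  }
  n_loci <- nrow(loci)
  lambda <- n_loci * bin_bp / genome_length
  p <- stats::ppois(counts - 1L, lambda, lower.tail = FALSE)
  bins$count <- counts
  bins$p <- p
  bins$hotspot <- p * nrow(bins) < alpha
  list(bins = bins, lambda = lambda,
       mean_spacing = genome_length / n_loci, n_loci = n_loci,
       n_hotspots = sum(bins$hotspot))
}

#' Screen a trio child for candidate de novo insertions
#'
#' Candidates are child loci matching (200 bp window, same family) no
#' locus in either parent and none in any other cohort sample. Each
#' candidate carries the distance to the nearest parental or cohort locus
#' for triage: imperfect parental detection sensitivity, not new insertion
#' events, is the expected source of candidates.
#'
#' @param child_calls,father_calls,mother_calls `MeiLocus` tables on
#'   catalog coordinates.
#' @param cohort_calls list of `MeiLocus` tables for the remaining samples.
#' @param window matching window in bp.
#' @return the candidate subset of `child_calls` with a
#'   `nearest_other_bp` column.
#' @export
find_de_novo <- function(child_calls, father_calls, mother_calls,
                         cohort_calls = list(), window = 200) {
  others <- c(list(father_calls, mother_calls), cohort_calls)
  excluded <- logical(nrow(child_calls))
  for (ot in others) {
    m <- match_loci(child_calls, ot, mode = "window200", window = window)
    excluded[m$matched$idx_a] <- TRUE
  }
  cand <- child_calls[!excluded, , drop = FALSE]
  if (nrow(cand)) {
    pool <- do.call(rbind, lapply(others, function(x)
      x[, c("chrom", "pos", "family")]))
    cand$nearest_other_bp <- vapply(seq_len(nrow(cand)), function(i) {
      same <- pool[pool$chrom == cand$chrom[i] &
                     pool$family == cand$family[i], , drop = FALSE]
      if (nrow(same) == 0L) return(NA_real_)
      min(abs(same$pos - cand$pos[i]))
    }, numeric(1))
  }
  cand
}
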