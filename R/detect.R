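# Non-reference MEI calling from read-pair / split-read fragment evidence,
# and reference MEI selection from deletion calls.

mei_locus_df <- function(chrom = character(0), pos = integer(0),
                         ci_lo = integer(0), ci_hi = integer(0),
                         family = character(0), strand = NA_character_,
                         detection_mode = character(0), methods = character(0),
                         tsd_len = NA_integer_, n_alt5 = 0L, n_alt3 = 0L,
                         insertion_len = NA_integer_) {
  n <- length(chrom)
  r <- function(x, as = identity) as(rep_len(x, n))
  data.frame(chrom = chrom, pos = r(pos, as.integer),
             ci_lo = r(ci_lo, as.integer), ci_hi = r(ci_hi, as.integer),
             family = r(family, as.character), strand = r(strand, as.character),
             detection_mode = r(detection_mode, as.character),
             methods = r(methods, as.character),
             tsd_len = r(tsd_len, as.integer), n_alt5 = r(n_alt5, as.integer),
             n_alt3 = r(n_alt3, as.integer),
             insertion_len = r(insertion_len, as.integer),
             stringsAsFactors = FALSE)
}

check_fragment_families <- function(fragments) {
  bad <- !(fragments$family %in% MEI_FAMILIES) & fragments$family != ""
  if (any(bad)) {
    warning(sum(bad), " fragment(s) with unknown element family rejected")
    fragments <- fragments[!bad, , drop = FALSE]
  }
  fragments
}

#' Call non-reference MEI from read-pair evidence
#'
#' Element-supporting read-pair fragments are clustered per chromosome and
#' family by single linkage with a gap of at most one median fragment
#' length. A cluster becomes a call only when it contains at least two
#' fragments spanning into the element from the 5' side AND at least two
#' from the 3' side; one-sided support is never sufficient, because
#' reference-spanning pairs bracketing annotated elements can land on the
#' tails of the library fragment-length distribution and mimic one-sided
#' evidence. For the same reason, calls whose breakpoint lies within one
#' median fragment length of an annotated element of the same family are
#' masked. The reported position is the leftmost coordinate compatible with
#' the 5'/3' cluster extents.
#'
#' @param fragments mapped-fragment table (`sample_id`, `chrom`,
#'   `anchor_pos`, `side` in `5p`/`3p`, `frag_len`, `family`, `split`).
#'   Split records are ignored here.
#' @param annotations element annotation track (`chrom`, `start`, `end`,
#'   `family`), 1-based inclusive.
#' @param frag_len_median median library fragment length in bp; also the
#'   cluster linkage gap and the masking distance.
#' @return `MeiLocus` table (`detection_mode = "non_reference"`,
#'   `methods = "RP"`), one row per call.
#' @export
call_rp_insertions <- function(fragments, annotations, frag_len_median) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(mei_locus_df())
  fragments <- check_fragment_families(fragments)
  fr <- fragments[!fragments$split & fragments$family != "" &
                    fragments$side %in% c("5p", "3p"), , drop = FALSE]
  if (nrow(fr) == 0L) return(mei_locus_df())
  out <- list()
  for (sub in split(fr, paste(fr$chrom, fr$family))) {
    cl <- cluster_1d(sub$anchor_pos, frag_len_median)
    for (ix in split(seq_len(nrow(sub)), cl)) {
      cc <- sub[ix, , drop = FALSE]
      n5 <- sum(cc$side == "5p")
      n3 <- sum(cc$side == "3p")
      if (n5 < 2L || n3 < 2L) next
      bp <- min(max(cc$anchor_pos[cc$side == "5p"]) + 1L,
                min(cc$anchor_pos[cc$side == "3p"]))
      half <- as.integer(round(frag_len_median / 2))
      out[[length(out) + 1L]] <- mei_locus_df(
        chrom = cc$chrom[1], pos = bp, ci_lo = bp - half, ci_hi = bp + half,
        family = cc$family[1], detection_mode = "non_reference",
        methods = "RP", n_alt5 = n5, n_alt3 = n3
      )
    }
  }
  if (length(out) == 0L) return(mei_locus_df())
  calls <- do.call(rbind, out)
  # annotation-proximity masking, same family only
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    a <- annotations[annotations$chrom == calls$chrom[i] &
                       annotations$family == calls$family[i], , drop = FALSE]
    if (nrow(a) == 0L) return(TRUE)
    min(point_interval_dist(calls$pos[i], a$start, a$end)) > frag_len_median
  }, logical(1))
  calls <- calls[keep, , drop = FALSE]
  calls[order(calls$chrom, calls$pos), , drop = FALSE]
}

#' Call non-reference MEI from split-read evidence
#'
#' Split fragments carry a reference-mapped segment (`ref_start`,
#' `ref_end`) and the breakpoint side; a single supporting fragment is
#' sufficient for a call. Fragments are clustered by their split point with
#' a 35 bp single-linkage gap. When a cluster holds both 5' and 3' split
#' evidence, the target-site duplication length is the overlap of the 5'
#' and 3' reference-mapped extents (0 when disjoint) and the reported
#' position is the leftmost coordinate of that overlap.
#'
#' @param fragments mapped-fragment table; only rows with `split = TRUE`
#'   are used.
#' @param cluster_gap single-linkage gap in bp.
#' @return `MeiLocus` table (`methods = "SR"`).
#' @export
call_sr_insertions <- function(fragments, cluster_gap = 35) {
  if (is.null(fragments) || nrow(fragments) == 0L) return(mei_locus_df())
  fragments <- check_fragment_families(fragments)
  fr <- fragments[fragments$split & fragments$family != "", , drop = FALSE]
  if (nrow(fr) == 0L) return(mei_locus_df())
  stopifnot(!anyNA(fr$ref_start), !anyNA(fr$ref_end))
  fr$split_point <- ifelse(fr$side == "5p", fr$ref_end, fr$ref_start)
  out <- list()
  for (sub in split(fr, paste(fr$chrom, fr$family))) {
    cl <- cluster_1d(sub$split_point, cluster_gap)
    for (ix in split(seq_len(nrow(sub)), cl)) {
      cc <- sub[ix, , drop = FALSE]
      is5 <- cc$side == "5p"
      n5 <- sum(is5); n3 <- sum(!is5)
      if (n5 > 0L && n3 > 0L) {
        ext5 <- c(min(cc$ref_start[is5]), max(cc$ref_end[is5]))
        ext3 <- c(min(cc$ref_start[!is5]), max(cc$ref_end[!is5]))
        ov_lo <- max(ext5[1], ext3[1])
        ov_hi <- min(ext5[2], ext3[2])
        tsd <- max(0L, ov_hi - ov_lo + 1L)
        bp <- if (tsd > 0L) ov_lo else ext5[2] + 1L
        ci <- if (tsd > 0L) c(bp, bp + tsd - 1L) else c(bp, max(1L, ext3[1] - 1L))
      } else if (n5 > 0L) {
        tsd <- NA_integer_
        bp <- max(cc$ref_end[is5])
        ci <- c(bp - cluster_gap, bp + cluster_gap)
      } else {
        tsd <- NA_integer_
        bp <- min(cc$ref_start[!is5])
        ci <- c(bp - cluster_gap, bp + cluster_gap)
      }
      out[[length(out) + 1L]] <- mei_locus_df(
        chrom = cc$chrom[1], pos = bp, ci_lo = min(ci), ci_hi = max(ci),
        family = cc$family[1], detection_mode = "non_reference",
        methods = "SR", tsd_len = tsd, n_alt5 = n5, n_alt3 = n3
      )
    }
  }
  calls <- do.call(rbind, out)
  calls[order(calls$chrom, calls$pos), , drop = FALSE]
}

#' Select reference MEI from deletion calls
#'
#' A deletion is accepted as a reference MEI when (a) an annotated Alu, L1,
#' or SVA element matches it with strictly more than 50\% reciprocal
#' overlap AND both the start and end coordinates agree within a
#' family-specific window (20 bp for Alu, 200 bp for L1 and SVA), and (b)
#' at least 75\% of the deleted bases fall inside gaps of the chimpanzee
#' genome assembly, confirming that the element is a human-lineage
#' insertion rather than a chimpanzee deletion.
#'
#' @param deletions deletion intervals (`chrom`, `start`, `end`, optional
#'   `id`), 1-based inclusive.
#' @param element_annotations element track (`chrom`, `start`, `end`,
#'   `family`).
#' @param chimp_gaps ancestral-gap intervals (`chrom`, `start`, `end`).
#' @param match_windows named endpoint windows in bp per family.
#' @param min_reciprocal reciprocal-overlap threshold (strict).
#' @param min_gap_frac minimum fraction of deleted bases inside gaps.
#' @return `MeiLocus` table (`detection_mode = "reference"`,
#'   `methods = "DEL"`) with `insertion_len` = deletion width.
#' @export
select_reference_mei <- function(deletions, element_annotations, chimp_gaps,
                                 match_windows = c(Alu = 20, L1 = 200,
                                                   SVA = 200),
                                 min_reciprocal = 0.5, min_gap_frac = 0.75) {
  for (tab in list(deletions, element_annotations, chimp_gaps)) {
    if (nrow(tab) && any(tab$end < tab$start)) {
      stop("malformed interval: end < start")
    }
  }
  if (nrow(deletions) == 0L) return(mei_locus_df())
  gr_del <- df_to_granges(deletions)
  gr_el <- df_to_granges(element_annotations)
  hits <- GenomicRanges::findOverlaps(gr_del, gr_el)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- overlap_len(deletions$start[qi], deletions$end[qi],
                    element_annotations$start[si],
                    element_annotations$end[si])
  w_del <- deletions$end[qi] - deletions$start[qi] + 1
  w_el <- element_annotations$end[si] - element_annotations$start[si] + 1
  win <- match_windows[element_annotations$family[si]]
  pass <- ov / w_del > min_reciprocal & ov / w_el > min_reciprocal &
    abs(deletions$start[qi] - element_annotations$start[si]) <= win &
    abs(deletions$end[qi] - element_annotations$end[si]) <= win
  qi <- qi[pass]; si <- si[pass]
  ro <- pmin(ov / w_del, ov / w_el)[pass]
  # best-matching annotation per deletion
  best <- tapply(seq_along(qi), qi, function(ix) ix[which.max(ro[ix])])
  qi <- qi[unlist(best)]; si <- si[unlist(best)]
  if (length(qi) == 0L) return(mei_locus_df())
  # ancestral-gap coverage
  gr_gap <- GenomicRanges::reduce(df_to_granges(chimp_gaps))
  ghits <- GenomicRanges::findOverlaps(gr_del[qi], gr_gap)
  govl <- GenomicRanges::width(GenomicRanges::pintersect(
    gr_del[qi][S4Vectors::queryHits(ghits)],
    gr_gap[S4Vectors::subjectHits(ghits)]
  ))
  cov <- rep(0, length(qi))
  if (length(govl)) {
    agg <- tapply(govl, S4Vectors::queryHits(ghits), sum)
    cov[as.integer(names(agg))] <- agg
  }
  frac <- cov / (deletions$end[qi] - deletions$start[qi] + 1)
  keep <- frac >= min_gap_frac
  qi <- qi[keep]; si <- si[keep]
  if (length(qi) == 0L) return(mei_locus_df())
  res <- mei_locus_df(
    chrom = deletions$chrom[qi], pos = deletions$start[qi],
    ci_lo = deletions$start[qi], ci_hi = deletions$end[qi],
    family = element_annotations$family[si],
    detection_mode = "reference", methods = "DEL",
    insertion_len = deletions$end[qi] - deletions$start[qi] + 1L
  )
  if (!is.null(deletions$id)) res$source_id <- deletions$id[qi]
  res[order(res$chrom, res$pos), , drop = FALSE]
}
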