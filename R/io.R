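# File-format boundary: VCF 4.1 via vcfR, BED via rtracklayer, TSV via
# base utils. All coordinate-convention conversions (BED 0-based half-open
# <-> internal 1-based inclusive, leftmost insertion positions) happen
# here and nowhere else.

GT_STRINGS <- c("0/0", "0/1", "1/1")

#' Write an MEI catalog (optionally with genotypes) as VCF 4.1
#'
#' Loci are encoded as symbolic structural variants with INFO keys
#' `SVTYPE` (INS for non-reference, DEL for reference MEI), `FAMILY`,
#' `DET`, `METHODS`, `TSDLEN`, `NALT5`, `NALT3`, `CIPOS`. Genotypes are
#' written as `GT:GQ`. Output is bgzip/gzip-compressed (use a `.vcf.gz`
#' path).
#'
#' @param loci `MeiLocus` table.
#' @param path output path.
#' @param G,GQ optional samples x loci genotype / quality matrices
#'   (columns matching `loci$locus_id`).
#' @return the path, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_mei_vcf <- function(loci, path, G = NULL, GQ = NULL) {
  meta <- c(
    "##fileformat=VCFv4.1",
    "##source=meipop",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=FAMILY,Number=1,Type=String,Description=\"Element family\">",
    "##INFO=<ID=DET,Number=1,Type=String,Description=\"Detection mode: INS (non-reference) or DEL (reference)\">",
    "##INFO=<ID=METHODS,Number=1,Type=String,Description=\"Detection methods (|-separated)\">",
    "##INFO=<ID=TSDLEN,Number=1,Type=Integer,Description=\"Target site duplication length\">",
    "##INFO=<ID=NALT5,Number=1,Type=Integer,Description=\"5-prime insertion-supporting fragments\">",
    "##INFO=<ID=NALT3,Number=1,Type=Integer,Description=\"3-prime insertion-supporting fragments\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred-scaled genotype quality\">"
  )
  is_ref <- loci$detection_mode == "reference"
  info <- paste0(
    "SVTYPE=", ifelse(is_ref, "DEL", "INS"),
    ";FAMILY=", loci$family,
    ";DET=", ifelse(is_ref, "DEL", "INS"),
    ";METHODS=", gsub(",", "|", loci$methods, fixed = TRUE),
    ifelse(is.na(loci$tsd_len), "", paste0(";TSDLEN=", loci$tsd_len)),
    ";NALT5=", loci$n_alt5, ";NALT3=", loci$n_alt3,
    ";CIPOS=", loci$ci_lo - loci$pos, ",", loci$ci_hi - loci$pos
  )
  fix <- cbind(CHROM = loci$chrom, POS = as.character(loci$pos),
               ID = loci$locus_id, REF = "N",
               ALT = ifelse(is_ref, "<DEL:ME>", "<INS:ME>"),
               QUAL = ".", FILTER = "PASS", INFO = info)
  if (!is.null(G)) {
    stopifnot(all(loci$locus_id %in% colnames(G)))
    gstr <- matrix(".:.", nrow(loci), nrow(G))
    for (s in seq_len(nrow(G))) {
      g <- G[s, loci$locus_id]
      q <- if (is.null(GQ)) rep(0L, length(g)) else GQ[s, loci$locus_id]
      cell <- ifelse(is.na(g), "./.:.", paste0(GT_STRINGS[g + 1L], ":", q))
      gstr[, s] <- cell
    }
    colnames(gstr) <- rownames(G)
    gt <- cbind(FORMAT = "GT:GQ", gstr)
  } else {
    gt <- matrix(character(0), nrow = 0, ncol = 0)
  }
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read an MEI VCF back into catalog tables
#'
#' Inverse of [write_mei_vcf()]: reconstructs the `MeiLocus` table from
#' the INFO keys and, when FORMAT fields are present, the genotype and GQ
#' matrices. Records with a missing GT are returned as NA (treated as
#' un-genotyped downstream); malformed records are skipped with a
#' warning count.
#'
#' @param path a VCF (optionally gzipped) written by this package or
#'   following the same INFO conventions.
#' @return list with `loci`, `G`, `GQ` (matrices NULL when the VCF has no
#'   samples).
#' @export
read_mei_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- is.na(pos)
  if (any(bad)) {
    warning(sum(bad), " malformed VCF record(s) skipped")
    v <- v[!bad, ]
    fix <- fix[!bad, , drop = FALSE]
    pos <- pos[!bad]
  }
  info1 <- function(key, numeric = FALSE) {
    x <- vcfR::extract.info(v, element = key)
    if (numeric) suppressWarnings(as.numeric(x)) else x
  }
  det <- info1("DET")
  cipos <- strsplit(info1("CIPOS"), ",", fixed = TRUE)
  ci <- t(vapply(cipos, function(x) as.integer(x[1:2]), integer(2)))
  loci <- mei_locus_df(
    chrom = fix$CHROM, pos = pos,
    ci_lo = pos + ifelse(is.na(ci[, 1]), 0L, ci[, 1]),
    ci_hi = pos + ifelse(is.na(ci[, 2]), 0L, ci[, 2]),
    family = info1("FAMILY"),
    detection_mode = ifelse(det == "DEL", "reference", "non_reference"),
    methods = gsub("|", ",", info1("METHODS"), fixed = TRUE),
    tsd_len = info1("TSDLEN", numeric = TRUE),
    n_alt5 = info1("NALT5", numeric = TRUE),
    n_alt3 = info1("NALT3", numeric = TRUE)
  )
  loci$locus_id <- fix$ID
  g <- gq <- NULL
  if (ncol(v@gt) > 1L) {
    gt_chr <- vcfR::extract.gt(v, element = "GT")
    g <- t(matrix(match(gt_chr, GT_STRINGS) - 1L, nrow(gt_chr),
                  dimnames = dimnames(gt_chr)))
    colnames(g) <- loci$locus_id
    gq <- t(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    colnames(gq) <- loci$locus_id
  }
  list(loci = loci, G = g, GQ = gq)
}

#' Read and write BED interval tracks
#'
#' BED is 0-based half-open; internal tables are 1-based inclusive (the
#' leftmost-coordinate convention). The BED name column carries the
#' family or region class. Requires the rtracklayer package.
#'
#' @param df interval table (`chrom`, `start`, `end`, plus a name-like
#'   column `family` or `class`).
#' @param path file path.
#' @return `read_bed()`: interval data.frame; `write_bed()`: the path,
#'   invisibly.
#' @export
write_bed <- function(df, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for BED I/O")
  }
  gr <- df_to_granges(df)
  name_col <- intersect(c("family", "class", "id"), names(df))[1]
  if (!is.na(name_col)) names(gr) <- df[[name_col]]
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_bed
#' @param name_as return the BED name column under this column name.
#' @export
read_bed <- function(path, name_as = "name") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for BED I/O")
  }
  gr <- rtracklayer::import.bed(path)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), # rtracklayer already converts to 1-based
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  nm <- gr$name
  if (!is.null(nm)) out[[name_as]] <- nm
  out
}

#' Support-count TSV round trip
#'
#' Per-locus, per-sample fragment evidence with columns `locus_id`,
#' `sample_id`, `n_alt5`, `n_alt3`, `n_ref`.
#'
#' @param support support-count table.
#' @param path file path.
#' @return `read_support_tsv()`: the table; `write_support_tsv()`: the
#'   path, invisibly.
#' @export
write_support_tsv <- function(support, path) {
  utils::write.table(support, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_support_tsv
#' @export
read_support_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
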