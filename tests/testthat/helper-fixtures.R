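# Fixture builders shared across the suite (all data generated in code).

frag_row <- function(anchor_pos, side, chrom = "chr1", frag_len = 200,
                     family = "Alu", split = FALSE, ref_start = NA,
                     ref_end = NA, sample_id = "S1") {
  data.frame(sample_id = sample_id, chrom = chrom,
             anchor_pos = as.integer(anchor_pos), side = side,
             frag_len = as.integer(frag_len), family = family, split = split,
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             stringsAsFactors = FALSE)
}

rp_cluster <- function(bp = 1000, family = "Alu", n5 = 2, n3 = 2) {
  rbind(
    if (n5 > 0) do.call(rbind, lapply(seq_len(n5), function(k)
      frag_row(bp - 10L * k, "5p", family = family))),
    if (n3 > 0) do.call(rbind, lapply(seq_len(n3), function(k)
      frag_row(bp + 10L * k, "3p", family = family)))
  )
}

ann_df <- function(start, end, family = "Alu", chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             family = family, stringsAsFactors = FALSE)
}

no_ann <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), family = character(0),
                     stringsAsFactors = FALSE)

simple_call <- function(pos, family = "Alu", methods = "RP", chrom = "chr1",
                        mode = "non_reference", tsd = NA, n5 = 2L, n3 = 2L,
                        ci = 100L) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             ci_lo = as.integer(pos - ci), ci_hi = as.integer(pos + ci),
             family = family, strand = NA_character_, detection_mode = mode,
             methods = methods, tsd_len = as.integer(tsd), n_alt5 = n5,
             n_alt3 = n3, insertion_len = NA_integer_,
             stringsAsFactors = FALSE)
}

# Independent brute-force genotype posterior (three-term enumeration).
genotype_oracle <- function(n_alt, n_ref, p = c(0.02, 0.5, 0.98),
                            prior = c(1, 1, 1) / 3) {
  lik <- vapply(1:3, function(k)
    choose(n_alt + n_ref, n_alt) * p[k]^n_alt * (1 - p[k])^n_ref, numeric(1))
  post <- prior * lik
  post / sum(post)
}
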