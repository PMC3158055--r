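---
title: "Methods: simulating and analysing mobile element insertion polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing mobile element insertion polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meipop)
```

# The problem

Mobile element insertions (MEI) from the Alu, L1, and SVA retrotransposon
families segregate in human populations like point mutations do, but they
are observed through two asymmetric channels. An insertion absent from the
reference assembly (a *non-reference MEI*) appears in short-read data as
read pairs and split reads spanning from uniquely mapped anchors into
element sequence. An insertion carried by the reference but absent from a
sample (a *reference MEI*) appears as a deletion, and can be confirmed as
a human-lineage insertion by a gap at the orthologous position of the
chimpanzee assembly. Because the reference genome acts like one sampled
chromosome, splitting the catalog by channel imposes an ascertainment
condition that reshapes each channel's allele-frequency spectrum; any
population-genetic quantity computed from such a catalog must undo that
bias together with the losses from imperfect detection and genotyping.
`meipop` implements the full chain — simulation, detection, genotyping,
sensitivity estimation, corrected spectra and diversity estimates, and
functional suppression — as testable, reusable components.

# The neutral model and the ascertainment split

Under the standard neutral (infinite-sites, constant-size) model the
expected number of loci with derived-allele count $i$ among $2N$ sampled
chromosomes is $\theta/i$, where $\theta = 4 N_e \mu$ is the diversity
parameter on the locus scale. The simulator draws the per-$i$ locus counts
directly as independent Poisson$(\theta/i)$ variables for
$i = 1, \dots, 2N-1$ — exactly the model the fitting stage assumes —
rather than running a coalescent with an explicit population history. The
published analysis this package models used a coalescent simulation with
standard history parameters only as a qualitative check of the
ascertainment shapes; those history parameters are not part of the model
being fit, so the flat-density sampler is both sufficient and exactly
self-consistent. An external coalescent simulator can be substituted as an
oracle where desired.

Each locus is flagged `on_reference` with probability $i/2N$, i.e. a
uniformly chosen reference chromosome carries the derived allele. This
one line reproduces both ascertained spectra: reference MEI are flat,
$(\theta/i)(i/2N) = \theta/2N$, non-reference MEI follow
$(\theta/i)(2N-i)/2N$, and the two channels sum back to $\theta/i$
(`ascertained_expectation()` exposes all three curves, and the partition
identity is exact).

Two simulator choices deserve explanation:

* **Population structure.** All populations share one locus set and one
  derived-allele frequency $f = i/2N$ per locus, with an optional
  per-population Gaussian perturbation (`pop_freq_sd`). Fully independent
  per-population locus sets would require per-population `on_reference`
  flags and break the single shared catalog that detection, merging, and
  genotyping operate on; the shared-frequency mode is the default, and the
  perturbation mode exists for experiments that need PCA-like structure.
* **The spectrum panel.** The first $N = 2N/2$ samples of the first
  population form a panel whose $2N$ chromosomes carry *exactly* the drawn
  allele count, with chromosome 1 of sample 1 designated the reference
  haplotype (it carries the derived allele iff the locus is
  `on_reference`). Samples outside the panel draw genotypes
  Binomial$(2, f)$ (Hardy–Weinberg). The conditional placement makes the
  ascertainment-partition property exact in every simulated panel instead
  of holding only in expectation, which is what the spectrum-shape tests
  verify.

# What the generator emulates, and what it does not

The generator reproduces the statistical structure the analysis depends
on: neutral allele-frequency density $\propto 1/i$; HWE diploid genotypes
in up to three population groups; the reference-ascertainment split;
Poisson fragment coverage with binomial allele sampling split evenly
across the 5′/3′ breakpoint sides; element-family proportions
(defaults 85.5% Alu / 12% L1 / 2.5% SVA); truncated-normal TSD lengths
(mean 15 bp, sd 7 bp); uniform placement over a 2.85 Gb accessible
genome; configurable detection dropout and false-call rates; and the
read-pair background artifact — reference-spanning pairs bracketing
annotated elements whose fragment lengths sample the extreme library
tail, which is exactly what annotation-proximity masking removes.

It does *not* simulate read sequences (no FASTQ), linkage between loci,
selection, or demographic history; positions are independent and
uniform, so the density scan's null model is true by construction.
Passing tests therefore demonstrate that the estimators are correct
under their stated model, not that real cohorts satisfy that model:
in real data, mapping artifacts, coverage heterogeneity and reference
errors enter through the detection and genotyping efficiencies, which is
why every downstream quantity carries explicit
$\varepsilon_{DET}, \varepsilon_{GEN}$ corrections estimated from the
data rather than assumed.

# Detection rules

**Read-pair (RP) calling.** Element-supporting fragments are clustered
per chromosome and family by single linkage. A cluster is called only
with $\geq 2$ fragments on *each* of the 5′ and 3′ sides, and calls
within one median fragment length of a same-family annotated element are
masked. One-sided evidence is never sufficient because background pairs
on the library-length tail mimic it. The cluster linkage gap is the
median library fragment length — the natural scale of anchor scatter
around a breakpoint; no explicit value is fixed by the source analysis,
so this is a package commitment, as is the breakpoint rule (leftmost
position compatible with the cluster extents: one past the rightmost 5′
anchor, clipped by the leftmost 3′ anchor) and the $\pm$ half fragment
length confidence interval.

**Split-read (SR) calling.** A single split fragment suffices. Split
fragments are clustered on their split points with a 35 bp gap
(approximately the TSD mean plus three standard deviations, so both
breakpoint sides of one insertion join one cluster). With evidence from
both sides, the TSD is the overlap of the 5′ and 3′ reference-mapped
extents and the reported position is the leftmost coordinate of that
overlap; base-pair-precise SR coordinates take precedence when call sets
are merged (100 bp window, transitive closure).

**Reference-MEI selection.** A deletion becomes a reference MEI when an
Alu/L1/SVA annotation matches it with > 50% reciprocal overlap and both
endpoints within 20 bp (Alu) or 200 bp (L1/SVA), and at least 75% of the
deleted bases fall in chimpanzee-assembly gaps. Endpoint windows scale
with the sharpness of the element boundaries — Alu elements are short
and well-delimited, L1/SVA are long, truncated, and ragged.

# Genotyping

The genotype posterior is
$P(g \mid N_{ALT}, N_{REF}) \propto P(g)\,
 \mathrm{Bin}(N_{ALT};\, N_{ALT}+N_{REF},\, p_g)$
with a flat prior and expected insertion-fragment fractions
$p_g = p_0, 0.5, 1 - p_0$ for genotypes 0/0, 0/1, 1/1. The default
$p_0 = 0.02$ absorbs fragment misassignment at homozygous sites; it is a
tunable model parameter. GQ follows the phred convention,
$-10\log_{10}(1 - \max_g P(g \mid \cdot))$, reported as a rounded
integer (the VCF convention) and capped at 99. Three numerical details:

* With a flat prior, two concordant fragments reach a posterior of at
  most $1/(1+1/4) = 0.8$, i.e. un-rounded GQ $6.99$. Integer rounding is
  what makes the operational rule "GQ $\geq 7$ $\iff$ two or more
  supporting fragments" hold exactly — every two-fragment configuration
  rounds to GQ $\geq 7$, no single fragment does.
* A site with zero fragments is assigned GQ 0 by definition (a flat
  posterior would otherwise phred-round to 2), flagging the total absence
  of evidence.
* Ties break deterministically toward 0/0 < 0/1 < 1/1.

Thresholds GQ $\geq 7$ (non-reference) and GQ $\geq 10$ (reference) gate
all genotype-based analyses; reference-MEI genotyping itself (in the
source study, a linkage-aware external genotyper) is consumed as an
input channel, not re-implemented.

# Sensitivity and corrections

The two detection methods use independent libraries, so their overlap
acts as a two-sample capture–recapture experiment. With per-method
false-detection rates $f$ (from PCR-style validation counts, Wilson
95% intervals — chosen over Wald for small strata),
$$\varepsilon_{RP} = \frac{n_{RP \cdot SR}}{(1-f_{SR})\, n_{SR}}, \qquad
  \varepsilon_{SR} = \frac{n_{RP \cdot SR}}{(1-f_{RP})\, n_{RP}}, \qquad
  \varepsilon = 1 - (1-\varepsilon_{RP})(1-\varepsilon_{SR}),$$
with binomial standard errors propagated through the combination. The
estimator is validated by simulation (independent thinnings of a known
locus set with false calls added) rather than against a closed-form
reference, and it satisfies the internal identity
$\hat N \varepsilon_{RP} \varepsilon_{SR} = n_{RP \cdot SR}$ exactly.

Spectra are built per detection mode from loci with $\geq 25$
GQ-passing genotypes, drawing a random subset of exactly 25 samples per
locus so every locus contributes the same $2N = 50$ chromosomes;
hypergeometric projection (`project_spectrum()`) is available for
display spectra but is never used for fitting because it correlates
neighbouring bins. The combined spectrum is
$n_{MEI}(i) = K_{REF}\, n_{REF}(i) + K_{NREF}\, n_{NREF}(i)$ with
$K = (\varepsilon_{DET}\, \varepsilon_{GEN})^{-1}$.

$\theta$ is fit by Poisson maximum likelihood, which is closed-form for
the $\theta/i$ curve: $\hat\theta = \sum_i n(i) / \sum_i 1/i$ over the
fit window $7 \le i \le 47$ (frequencies 0.15–0.95, excluding the bins
where detection sensitivity collapses). For raw integer spectra the 95%
CI is the exact (Garwood) Poisson interval on the bin total; corrected
spectra carry per-bin variances $\sum K^2 n$ and get a normal interval.
A $\chi^2$ statistic against $\hat\theta/i$ with $\mathrm{bins}-1$
degrees of freedom is reported for comparability, but it is not the
fitting objective. The insertion rate follows as
$\mu = \theta / (4 N_e)$ with $N_e = 10{,}000$.

# Heterozygosity and mutation rates

Per-sample heterozygosity $\pi$ (count of heterozygous loci per genome)
gets three corrections: detection sensitivity, per-sample genotyping
efficiency, and the heterozygote-dropout factor
$$K_{HET} = N_{loci} \Big/ \sum_{loci} \left[1 -
  \mathrm{Bin}(0;\, NF,\, 0.5)\right],$$
the reciprocal mean probability that a heterozygous site with $NF$
fragments yields at least one insertion-supporting fragment. $K_{HET}$
is computed over all GQ-passing loci of the sample (their coverage
distribution matches that of the heterozygous loci) and applied only to
the non-reference component, whose genotypes rest on fragment counts
alone. With $K_{HET}$ over the full locus set, the corrected
heterozygote count is exactly unbiased for the all-reference dropout
channel, which the recovery tests exercise at Poisson(4) coverage.

Because long-term demography affects MEI and SNP heterozygosity
identically, their ratio transfers the SNP mutation rate to MEI:
$\mu_{MEI} = (\pi_{MEI}/\pi_{SNP})\, \mu_{SNP} L$ with
$\mu_{SNP} = 1.8 \times 10^{-8}$ per site per generation and
$L = 2.85$ Gb (the multiplication by $L$ converts the per-site SNP rate
to the per-genome units in which MEI rates are quoted). SNP
heterozygosity also yields a rough pairwise coalescent time
$T = \frac{\pi_{SNP}/L}{2\mu_{SNP}} T_{GEN}$ with $T_{GEN} = 25$ y —
the standard pairwise-coalescent form, committed here because only its
inputs and units are fixed by the surrounding analysis.

# Functional suppression

Non-reference loci whose position confidence interval lies *entirely*
within a gene/UTR/CDS interval are counted (straddling loci are
ambiguous and excluded; invalidated loci are dropped). Under uniform
placement the expected count is $N_{tot} L_{obs} / L_{tot}$ and the
observed count is binomial; the suppression factor is
expected/observed — the convention that makes a depleted class carry a
factor above 1 — with a lower bound reported at zero observations, and
a one-sided binomial tail p-value computed in log space (CDS-scale
depletions sit far below the double-precision underflow limit, around
$10^{-308}$). The pooled locus total is used as $N_{tot}$ for every
class. For density scanning, the same binomial/Poisson null gives
per-megabase upper-tail p-values with a Bonferroni hotspot flag, and the
hotspot enrichment is reported as the computed ratio of bin count to
genomic mean, never as a fixed constant.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `theta_by_family` | Alu 1570, L1 224, SVA 80 | loci | pooled-population fitted values; sum ≈ 1870 |
| `n_chrom_sampled` | 50 | chromosomes | spectrum sample size 2N (N = 25 diploids) |
| `genome_length` | 2.85e9 | bp | accessible genome |
| `coverage_mean` | 4 | fragments/site | spanning coverage where genotyping efficiency transitions |
| `frag_len_mean`, `frag_len_sd` | 200, 35 | bp | short-insert library scale; RP cluster gap and masking radius |
| `tsd_mean`, `tsd_sd` | 15, 7 | bp | TSD distribution (truncated at 0: lengths are non-negative and only mean/sd are constrained) |
| `fdr_sim`, `dropout_sim` | 0.05; 0.3/0.1 | rates | validated false-call rate; 1 − sensitivity per mode |
| `p_hom_ref` | 0.02 | fraction | homozygous-site fragment misassignment |
| `gq_nonref`, `gq_ref` | 7, 10 | phred | genotype gates per detection mode |
| `fit_range` | [7, 47] | allele count | 0.15–0.95 frequency window for θ |
| `n_e`, `mu_snp`, `t_gen` | 1e4, 1.8e-8, 25 | —, /site/gen, y | neutral-model transforms |
| `region_fracs` | gene .376, UTR .0196, CDS .0255 | genome fraction | annotation footprint matching the expected-count ratios the suppression analysis uses |

# Problem sizes and numerical choices in the test suite

The suite runs at desk scale by design: catalogs of a few hundred to a
few thousand loci, cohorts of 30–60 diploids, 500–1000 replicates for
recovery and calibration studies, and brute-force genotype enumeration
up to 30 fragments. These sizes put Monte-Carlo noise well below the
asserted tolerances (typically 2–4 standard errors under fixed seeds)
while keeping the whole suite around a minute. Degenerate inputs are
pinned by contract: zero θ gives an empty catalog, zero tested loci an
undefined FDR, zero cross-method overlap undefined sensitivities with
infinite intervals, all-zero coverage an undefined $K_{HET}$, and
malformed intervals are rejected at the boundary.

# Known limitations

* The simulator's independence assumptions (no linkage, no demography)
  make CI calibration exact but optimistic relative to real cohorts.
* RP breakpoint precision is limited to the fragment-length scale; only
  SR evidence recovers TSDs, so RP-only catalogs carry unknown TSDs.
* The shared-frequency population mode understates between-population
  differentiation unless `pop_freq_sd` is set.
* Reference-MEI genotype quality is taken at face value from its input
  channel; no imputation or phasing is attempted.
* The heterozygosity-based mutation rate inherits any bias in the
  supplied per-site SNP heterozygosity and SNP mutation rate.
* $K_{HET}$ corrects only the all-reference dropout channel, as the
  published correction does. A heterozygote can also fluctuate to all
  insertion-supporting fragments (the same $0.5^{NF}$ probability) and
  be genotyped 1/1; at spanning coverage 4 this leaves corrected
  $\pi_{MEI}$ roughly 15% below $\theta$ in end-to-end simulations.
  The symmetric channel is deliberately left uncorrected so the
  estimator matches its published definition; at trio-scale coverage
  the residual bias vanishes.
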