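---
title: "Models and methods behind ltrASE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ltrASE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrASE)
```

# The biological model

`ltrASE` analyses the expression consequences of an endogenous-retrovirus
LTR insertion inside a coding exon, in the configuration of the bovine
cholesterol-deficiency *APOB* locus: a 29-exon gene with the insertion in
exon 5, heterozygous carriers (CDC) and homozygous wild types (CDF). The
working model of the insertion haplotype has two components:

* **enhancer activity** of the LTR that multiplies transcription of the
  gene region upstream of (and including the upstream part of) the
  insertion exon by a factor `alpha`;
* **premature polyadenylation** inside the inserted element, so that only
  a residual *readthrough fraction* `rho` of transcription survives
  downstream of the breakpoint on that haplotype.

Wild-type haplotypes transcribe uniformly. Per haplotype and exon the
expected read count is `lambda * exon_kb * h`, where `h` is `alpha`
upstream, `rho` downstream and 1 on wild-type haplotypes; the insertion
exon is split at the breakpoint proportionally to length, `h = f*alpha +
(1-f)*rho` with `f` the upstream length fraction. This single algebraic
layer drives all downstream expectations: aggregate carrier/wild-type
expression ratios of `(1+alpha)/2` upstream and `(1+rho)/2` downstream,
and allelic-depth ratios of `alpha` (upstream) and `rho` (downstream) at
heterozygous SNPs in phase with the insertion.

# Stages and their statistical assumptions

## Exon expression

Counts are normalized to FPKM, `count / (exon_kb) / (library_total/1e6)`,
i.e. for each animal's transcriptome-wide assigned read total and each
exon's length. Contrasts fit ordinary least squares of normalized
expression on two fixed main effects, pathogen challenge group and carrier
genotype, with no interaction. Least-squares means average predicted cell
means over pathogen levels with *equal* weights (`emmeans` semantics), so
unbalanced challenge arms do not tilt the genotype means. The genotype
p-value is the two-sided t-test of the genotype coefficient; with a single
pathogen level the model degenerates to the pooled-variance two-sample
t-test. Expression is analysed untransformed; a `log2` option exists but
is off by default. Per-unit raw p-values are accompanied by
Benjamini–Hochberg adjusted values across all reported units, since the
per-exon family spans 29 tests. The error variance is pooled across the
whole design (one residual variance), which is the standard OLS choice;
group-wise variances are not modelled. A rank-deficient design (genotype
confounded with pathogen) is refused with an explanatory error rather than
silently dropped coefficients.

## Half-sib phasing

For a heterozygous carrier sire, each offspring's paternally transmitted
allele is deducible when the offspring is homozygous (or the sire is
homozygous and the offspring heterozygous). At every sire-heterozygous
marker, carrier offspring vote their paternal allele onto the mutation
haplotype and wild-type offspring vote theirs onto the wild-type
haplotype. The default call requires unanimity: in a region of tens of
kilobases, even single paternal recombinants are rare, so any dissenting
vote more plausibly indicates a genotyping error or a recombinant and the
marker is flagged `conflicted` rather than called. A `minAgreement`
fraction below 1 relaxes this to a majority call with dissents counted in
`n_conflicts`. Ties break to `conflicted` (a 50/50 vote can never reach a
majority threshold above 0.5). Carrier status is an input, not inferred
from markers; missing offspring genotypes are skipped, never imputed.
Offspring whose assigned-marker support is split between the two sire
haplotypes are reported as putative recombinants.

## Allelic ratios

At each phased heterozygous site the per-animal ratio is `depth(in-phase
allele) / depth(wild-type-phase allele)`, computed from pileup-derived
allele counts. Heterozygosity must come from genomic-DNA genotypes
supplied as input; the package never infers genotypes from the RNA depths
themselves, because allele-biased expression makes RNA-based heterozygote
calls circular (a fully silenced allele looks homozygous). Ratios are
analysed untransformed — the quantities of interest (e.g. near-zero ratios
at a silenced haplotype) live on the raw ratio scale — with a log-ratio
symmetric alternative available via transformation by the caller. Samples
below `minDepth` combined two-allele depth (default 10) are excluded for
ratio stability; a zero denominator with non-zero numerator is flagged
non-finite and excluded from model fits with a warning; `0/0` is excluded.
No pseudocount is added by default, so complete silencing yields ratios of
exactly 0; a `pseudocount` argument exists for degenerate data. The group
contrast is OLS on the genotype indicator (group means, pooled residual
variance); each group is additionally tested against the balanced
expectation of 1 by a two-sided one-sample t-test. Zero-variance groups
report p = 1 when the common value is exactly 1 and p = 0 otherwise,
flagged as degenerate rather than erroring.

One caveat for users of the original cattle data: the downstream exon-13
SNP is printed with two different coordinates in the source literature
(77,899,208 in the methods, 77,998,208 in the results/figure legend).
`ltrASE` treats site coordinates strictly as user input and takes no
position on which is correct.

## Segregation-compatibility screen

A variant can explain haplotype-biased expression only if it is
heterozygous in every carrier and homozygous in every wild type. "Homozygous"
means either homozygote class by default — the requirement is absence of
heterozygosity in unaffected animals — with a `uniformHom` option for the
stricter single-class reading. Missing genotypes default to the
conservative `drop` policy (a variant unverifiable in any required sample
cannot be declared compatible); a `permissive` policy treats missing calls
as compatible-unknown. Both policies are exposed because real
resequencing panels contain missing calls and the right choice depends on
how a candidate will be followed up. The nearest compatible variant to an
anchor coordinate (typically the insertion site) is reported with its
distance.

QC filters for array genotypes: minor allele frequency estimated from
genotype counts with a strict `>` threshold (0.05); an **exact**
conditional Hardy–Weinberg test (probability, given observed allele
counts, of heterozygote counts at least as improbable as observed, summed
over matching parity) rather than the chi-square approximation, because
screens often run on a few dozen animals where the asymptotic test is
anti-conservative; and a strict GenTrain score threshold (0.7) that fails
closed on missing scores. The three filters commute, so application order
is irrelevant.

# The synthetic-data generator

`simulateCohort()` draws: (1) exon counts per animal around the
closed-form means, Poisson or negative-binomial with variance
`m(1 + phi*m)`; (2) allele depths at one upstream (exon 3) and one
downstream (exon 13) heterozygous SNP — total depth around the haplotype
rate sum, alleles allocated binomially, with the alternative allele's
capture scaled by a mapping-bias factor `beta` and alleles flipped with
sequencing-error probability `epsilon`; (3) a half-sib pedigree of a
heterozygous carrier sire (7 carrier + 4 wild-type offspring by default)
whose marker panel includes the two expression SNPs with the alternative
allele on the mutation haplotype, so the phasing stage genuinely feeds
the allelic-ratio stage; (4) a regional variant table with
Hardy–Weinberg background genotypes and one spiked fully compatible
variant at the insertion coordinate. All draws come from a single seeded
stream in that fixed order, so identical seeds give bit-identical
cohorts.

Default parameter choices, and why:

| parameter | default | rationale |
|---|---|---|
| `nCarriers`, `nWildtype` | 8 + 8 | balanced two-group design at desk scale |
| `lambda` | 250 reads/kb/haplotype | gives wild-type FPKM of order 17 at a 3e7-read library, the magnitude expected for a highly expressed hepatic apolipoprotein gene, and site depths of ~100–130 |
| `alpha` | 19 | aggregate upstream carrier/wild-type ratio `(1+alpha)/2 = 10`, the "more than tenfold" regime; the allelic-ratio regime observed at phased SNPs is steeper (~54), and `alpha` is exposed so either regime can be simulated |
| `rho` | 0.01 | near-complete downstream silencing of the insertion haplotype (allelic ratios ~0.01) |
| `phi` | 0.1 | moderate RNA-seq overdispersion; no empirical estimate was available for this tissue, so this is a conventional choice, not data-derived |
| `epsilon`, `beta` | 0, 1 | clean sequencing by default; both exposed to study error/bias sensitivity (with `beta < 1` wild-type ratios centre on `beta` rather than 1, mimicking reference-mapping bias) |
| `markerMaf` | 0.3 | common-variant frequency typical of array markers passing MAF QC |
| `recombProb` | 0.001 per interval | ~1 cM/Mb at kb-scale marker spacing within one gene; recombinants in such a window are rare, matching the phasing model's assumption |

What the generator does **not** emulate: alignment artifacts and mapping
ambiguity (depths are drawn, not aligned), intronic/background
transcription, library-preparation batch effects, allele-specific splicing
(the alternatively spliced exon 2 of the real gene), and RNA editing.
Passing tests therefore demonstrate correctness of the inference given
pileup-level inputs, not robustness to upstream alignment pathologies.

# Numerical and interface conventions

All internal coordinates are 1-based inclusive; BED's 0-based half-open
intervals are converted only at the file boundary, and a BED round-trip
preserves coordinates exactly. Pileup base strings are decoded
character-by-character per the format (`^` + mapping quality, `$`, indel
runs consumed without counting); base/mapping-quality filtering is not
re-applied to pre-made pileups. Multi-allelic VCF records are decomposed
into bi-allelic rows (the genotype code counts copies of the row's
alternative allele) so the screen cannot silently lose candidates. The
exact HWE test is computed on the log scale and normalized over the
attainable heterozygote counts, with the `<=` comparison guarded by a
relative `1e-12` tolerance against floating-point ties.

# Problem sizes used by the test suite

The statistical checks run at deliberately modest scale chosen for stable
Monte-Carlo behaviour: 2,000 null cohorts for t-test calibration (the
rejection rate at 0.05 is required to fall in [0.03, 0.07]); 200
replicates for closed-form mean recovery (every group-by-exon cell within
3 Monte-Carlo standard errors); 100 replicates for the tenfold/half
structure; 500 random recombination-free pedigrees for phasing/oracle
equivalence; 200 random variant tables for screen/oracle equivalence; and
exhaustive enumeration of all genotype tables of up to 10 animals for the
HWE test.

# Known limitations

* The expression model fits only the two main effects used in the
  original design; random sire effects (half-sib covariance) are not
  modelled, which slightly understates standard errors when families are
  large.
* Ratio-scale inference is asymmetric around 1; the t-test against 1 is a
  deliberate reproduction of the field's standard analysis, not the most
  powerful test (a binomial or beta-binomial likelihood on depths would
  be, and is out of scope).
* The phasing algorithm assumes a single known carrier sire; dam
  genotypes and population LD phasing are out of scope.
* The screen tests exact genotype patterns; it does not model genotyping
  error in cases/controls beyond the missing-data policies.
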