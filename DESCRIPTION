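Package: ltrASE
Title: Allele-Biased Expression Analysis of an LTR-Disrupted Gene
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting allele-biased expression of a gene
    disrupted by an LTR retrotransposon insertion, modelled on the bovine
    APOB cholesterol-deficiency locus. Provides exon-wise expression
    quantification and carrier-versus-wild-type contrasts across the
    insertion breakpoint, pedigree-based phasing of marker alleles against
    the mutation from a heterozygous carrier sire's half-sib offspring,
    allelic-ratio inference from sequencing pileups at phased heterozygous
    SNPs, a genotype-segregation compatibility screen for alternative
    causal variants with SNP-array quality filters (minor allele
    frequency, exact Hardy-Weinberg test, GenTrain score), and a
    synthetic-cohort generator implementing the enhancer-plus-premature-
    polyadenylation model of the insertion haplotype so that every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
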