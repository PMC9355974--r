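#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CARRIER_LEVELS  <- c("CDC", "CDF")
.PATHOGEN_LEVELS <- c("S_aureus", "E_coli", "none")
.GT_CODES        <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)

#' GeneModel: ordered exons of one gene plus a mobile-element insertion site
#'
#' Holds the exon structure of a single gene on one reference sequence,
#' together with the 1-based coordinate of an LTR retrotransposon insertion.
#' All coordinates are 1-based inclusive; conversion from 0-based half-open
#' formats (BED) happens only at the file boundary.
#'
#' @slot exons A [GenomicRanges::GRanges] of non-overlapping exons sorted by
#'   start, with an `exon_id` metadata column, all on one seqname and strand.
#' @slot insertionPos Integer, 1-based coordinate of the insertion; must fall
#'   inside exactly one exon.
#'
#' @seealso [GeneModel()], [readGeneModel()], [apobGeneModel()]
#' @export
setClass("GeneModel",
  representation(exons = "GRanges", insertionPos = "integer"))

setValidity("GeneModel", function(object) {
  ex <- object@exons
  msg <- character()
  if (length(ex) < 1L) msg <- c(msg, "gene model must contain at least one exon")
  if (length(unique(as.character(seqnames(ex)))) > 1L)
    msg <- c(msg, "all exons must lie on a single reference sequence")
  if (length(unique(as.character(strand(ex)))) > 1L)
    msg <- c(msg, "all exons must share one strand")
  if (is.null(ex$exon_id) || anyDuplicated(ex$exon_id))
    msg <- c(msg, "exons need a unique 'exon_id' metadata column")
  if (any(start(ex) < 1L)) msg <- c(msg, "all coordinates must be >= 1")
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be sorted by start")
    ov <- which(start(ex)[-1L] <= end(ex)[-length(ex)])
    if (length(ov))
      msg <- c(msg, sprintf("exons '%s' and '%s' overlap",
                            ex$exon_id[ov[1L]], ex$exon_id[ov[1L] + 1L]))
  }
  hit <- which(start(ex) <= object@insertionPos & end(ex) >= object@insertionPos)
  if (length(hit) != 1L)
    msg <- c(msg, sprintf("insertion position %d does not fall inside exactly one exon",
                          object@insertionPos))
  if (length(msg)) msg else TRUE
})

#' ExonCountExperiment: per-exon read counts for a cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] with exons as rows and
#' animals as columns. The `"counts"` assay holds raw read counts; `rowData`
#' carries `exon_id` and `length_bp`; `colData` carries the sample sheet
#' (`carrier_status` in CDC/CDF, `pathogen`, optional `sire_id`) plus
#' `library_total`, the transcriptome-wide assigned read count used for
#' per-million normalization.
#'
#' @seealso [ExonCountExperiment()], [normalizeCounts()], [aggregateExons()]
#' @export
setClass("ExonCountExperiment",
  contains = "SummarizedExperiment")

setValidity("ExonCountExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("carrier_status", "pathogen", "library_total"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", col))
  for (col in c("exon_id", "length_bp"))
    if (!col %in% colnames(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", col))
  if (length(msg)) return(msg)
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!all(cd$carrier_status %in% .CARRIER_LEVELS))
    msg <- c(msg, "carrier_status must be 'CDC' or 'CDF'")
  if (!all(cd$pathogen %in% .PATHOGEN_LEVELS))
    msg <- c(msg, sprintf("pathogen must be one of %s",
                          paste(.PATHOGEN_LEVELS, collapse = "/")))
  if (any(rd$length_bp < 1)) msg <- c(msg, "exon lengths must be >= 1 bp")
  if (any(cd$library_total < colSums(cts)))
    msg <- c(msg, "library_total must be >= the gene-wise count sum per sample")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' PedigreeCohort: a carrier sire and his half-sib offspring at regional markers
#'
#' Genotypes of one heterozygous carrier sire and his half-sib offspring at an
#' ordered set of bi-allelic markers, with per-offspring carrier status
#' (CDC = heterozygous carrier, CDF = homozygous wild type). Genotypes are
#' coded 0 (hom ref), 1 (het), 2 (hom alt), NA (missing).
#'
#' @slot sireId Character sire identifier.
#' @slot markers A [S4Vectors::DataFrame] with columns `chrom`, `pos`, `ref`,
#'   `alt`, one row per marker, sorted by position.
#' @slot sireGT Integer vector of sire genotype codes, one per marker.
#' @slot offspring A [S4Vectors::DataFrame] with columns `sample_id` and
#'   `carrier_status`.
#' @slot offspringGT Integer matrix, markers x offspring.
#'
#' @seealso [PedigreeCohort()], [phaseAgainstMutation()], [simulatePedigree()]
#' @export
setClass("PedigreeCohort",
  representation(sireId = "character", markers = "DataFrame",
                 sireGT = "integer", offspring = "DataFrame",
                 offspringGT = "matrix"))

setValidity("PedigreeCohort", function(object) {
  msg <- character()
  m <- object@markers
  for (col in c("chrom", "pos", "ref", "alt"))
    if (!col %in% colnames(m)) msg <- c(msg, sprintf("markers lack '%s'", col))
  for (col in c("sample_id", "carrier_status"))
    if (!col %in% colnames(object@offspring))
      msg <- c(msg, sprintf("offspring lack '%s'", col))
  if (length(msg)) return(msg)
  if (length(object@sireGT) != nrow(m))
    msg <- c(msg, "sireGT length must equal the number of markers")
  if (!all(dim(object@offspringGT) == c(nrow(m), nrow(object@offspring))))
    msg <- c(msg, "offspringGT must be markers x offspring")
  if (is.unsorted(m$pos)) msg <- c(msg, "markers must be sorted by position")
  ok_codes <- function(g) all(g %in% c(.GT_CODES, NA))
  if (!ok_codes(object@sireGT) || !ok_codes(object@offspringGT))
    msg <- c(msg, "genotype codes must be 0/1/2/NA")
  if (!all(object@offspring$carrier_status %in% .CARRIER_LEVELS))
    msg <- c(msg, "offspring carrier_status must be CDC or CDF")
  if (anyDuplicated(object@offspring$sample_id))
    msg <- c(msg, "offspring sample ids must be unique")
  # Mendelian consistency: offspring must share an allele with the sire
  bad <- .mendelConflicts(object@sireGT, object@offspringGT)
  if (nrow(bad))
    msg <- c(msg, sprintf(
      "Mendelian inconsistency: offspring '%s' shares no allele with sire at marker %d",
      object@offspring$sample_id[bad$offspring[1L]], bad$marker[1L]))
  if (length(msg)) msg else TRUE
})

# marker/offspring index pairs where the offspring cannot have received a
# paternal allele: sire hom_ref (0) with offspring hom_alt (2) or vice versa
.mendelConflicts <- function(sireGT, offspringGT) {
  conf <- (sireGT == 0L & offspringGT == 2L) | (sireGT == 2L & offspringGT == 0L)
  conf[is.na(conf)] <- FALSE
  idx <- which(conf, arr.ind = TRUE)
  data.frame(marker = idx[, 1L], offspring = idx[, 2L])
}

#' VariantTable: regional variants with per-sample genotypes and QC scores
#'
#' Bi-allelic variants in one genomic region with genotype calls coded
#' 0 (hom ref), 1 (het), 2 (hom alt), NA (missing), and an optional per-variant
#' GenTrain cluster-quality score in \[0, 1\].
#'
#' @slot region A length-1 [GenomicRanges::GRanges] delimiting the screen region.
#' @slot variants A [S4Vectors::DataFrame] with columns `pos`, `ref`, `alt`,
#'   `gentrain` (NA when unavailable), sorted by `pos`.
#' @slot genotypes Integer matrix, variants x samples, with sample ids as
#'   column names.
#'
#' @seealso [VariantTable()], [readGenotypes()], [screenCompatible()]
#' @export
setClass("VariantTable",
  representation(region = "GRanges", variants = "DataFrame",
                 genotypes = "matrix"))

setValidity("VariantTable", function(object) {
  msg <- character()
  if (length(object@region) != 1L)
    msg <- c(msg, "region must be a single range")
  v <- object@variants
  for (col in c("pos", "ref", "alt", "gentrain"))
    if (!col %in% colnames(v)) msg <- c(msg, sprintf("variants lack '%s'", col))
  if (length(msg)) return(msg)
  if (nrow(v) != nrow(object@genotypes))
    msg <- c(msg, "genotype matrix rows must match variants")
  if (nrow(v)) {
    if (is.unsorted(v$pos)) msg <- c(msg, "variants must be sorted by position")
    if (any(v$pos < start(object@region) | v$pos > end(object@region)))
      msg <- c(msg, "all variant positions must lie within the region")
    if (!all(object@genotypes %in% c(.GT_CODES, NA)))
      msg <- c(msg, "genotype codes must be 0/1/2/NA")
    gt_ok <- is.na(v$gentrain) | (v$gentrain >= 0 & v$gentrain <= 1)
    if (!all(gt_ok)) msg <- c(msg, "gentrain scores must lie in [0, 1]")
  }
  if (is.null(colnames(object@genotypes)) && ncol(object@genotypes) > 0L)
    msg <- c(msg, "genotype matrix needs sample ids as column names")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohort: one simulated study cohort with ground truth
#'
#' Container returned by [simulateCohort()]: the gene model, sample sheet,
#' exon count experiment, allele depths at the two designated heterozygous
#' SNPs, the half-sib pedigree, the regional variant table with one spiked
#' segregation-compatible variant, and a `truth` list recording the generative
#' quantities (per-haplotype per-exon expected rates, haplotype phases, the
#' spiked position) for use in tests.
#'
#' @seealso [simulateCohort()], [generativeConfig()]
#' @export
setClass("SyntheticCohort",
  representation(geneModel = "GeneModel", samples = "DataFrame",
                 exonCounts = "ExonCountExperiment",
                 alleleDepths = "data.frame", pedigree = "PedigreeCohort",
                 variants = "VariantTable", truth = "list"))
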