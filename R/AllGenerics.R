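#' @rdname GeneModel-class
#' @param x A `GeneModel`.
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname GeneModel-class
#' @export
setGeneric("insertionPos", function(x) standardGeneric("insertionPos"))

#' @rdname GeneModel-class
#' @export
setGeneric("insertionExon", function(x) standardGeneric("insertionExon"))

#' @rdname GeneModel-class
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))

#' @rdname ExonCountExperiment-class
#' @param x An `ExonCountExperiment`.
#' @export
setGeneric("libraryTotals", function(x) standardGeneric("libraryTotals"))

#' @rdname ExonCountExperiment-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname PedigreeCohort-class
#' @param x A `PedigreeCohort` or `VariantTable`.
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname PedigreeCohort-class
#' @export
setGeneric("sireGenotypes", function(x) standardGeneric("sireGenotypes"))

#' @rdname PedigreeCohort-class
#' @export
setGeneric("offspringGenotypes", function(x) standardGeneric("offspringGenotypes"))

#' @rdname PedigreeCohort-class
#' @export
setGeneric("offspringInfo", function(x) standardGeneric("offspringInfo"))

#' @rdname VariantTable-class
#' @param x A `VariantTable`.
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname VariantTable-class
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname VariantTable-class
#' @export
setGeneric("screenRegion", function(x) standardGeneric("screenRegion"))

#' @rdname SyntheticCohort-class
#' @param x A `SyntheticCohort`.
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("exonCounts", function(x) standardGeneric("exonCounts"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("alleleDepths", function(x) standardGeneric("alleleDepths"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("geneModel", function(x) standardGeneric("geneModel"))

#' @rdname SyntheticCohort-class
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))
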