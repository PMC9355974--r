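#' Construct an ExonCountExperiment
#'
#' @param counts Integer matrix of raw read counts, exons x samples, with
#'   exon ids as row names and sample ids as column names.
#' @param exonLengths Numeric vector of exon lengths in bp (named by exon id
#'   or in row order).
#' @param samples A data.frame or [S4Vectors::DataFrame] with one row per
#'   sample: `sample_id`, `carrier_status` (CDC/CDF), `pathogen`
#'   (S_aureus/E_coli/none), optional `sire_id`.
#' @param libraryTotals Numeric vector of transcriptome-wide assigned read
#'   counts, one per sample.
#'
#' @return An [ExonCountExperiment-class].
#' @export
ExonCountExperiment <- function(counts, exonLengths, samples, libraryTotals) {
  counts <- as.matrix(counts)
  samples <- as(samples, "DataFrame")
  if (!is.null(names(exonLengths)) && !is.null(rownames(counts)))
    exonLengths <- exonLengths[rownames(counts)]
  rd <- DataFrame(exon_id = rownames(counts) %||% paste0("exon", seq_len(nrow(counts))),
                  length_bp = unname(exonLengths))
  cd <- samples
  cd$library_total <- unname(libraryTotals)
  rownames(cd) <- samples$sample_id
  colnames(counts) <- samples$sample_id
  rownames(counts) <- rd$exon_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  new("ExonCountExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname ExonCountExperiment-class
#' @export
setMethod("libraryTotals", "ExonCountExperiment", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$library_total, colnames(x)))

#' @rdname ExonCountExperiment-class
#' @export
setMethod("sampleInfo", "ExonCountExperiment", function(x)
  SummarizedExperiment::colData(x))

#' @rdname ExonCountExperiment-class
#' @export
setMethod("exonLengths", "ExonCountExperiment", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$length_bp, rownames(x)))

setMethod("show", "ExonCountExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("ExonCountExperiment: %d exons x %d samples (%d CDC, %d CDF)\n",
              nrow(object), ncol(object),
              sum(cd$carrier_status == "CDC"), sum(cd$carrier_status == "CDF")))
})

#' Read an ExonCountExperiment from tab-delimited tables
#'
#' `countsPath` holds an exon x sample matrix with exon ids in the first
#' column; `totalsPath` maps `sample_id` to `library_total`; `samplesPath` is
#' the sample sheet (`sample_id`, `carrier_status`, `pathogen`, optional
#' `sire_id`); `exonsPath` is a BED file giving exon lengths.
#'
#' @param countsPath,totalsPath,samplesPath,exonsPath File paths.
#' @param insertionPos Insertion coordinate forwarded to [readGeneModel()].
#' @return A list with elements `counts` (an [ExonCountExperiment-class]) and
#'   `geneModel` (a [GeneModel-class]).
#' @export
readExonCounts <- function(countsPath, totalsPath, samplesPath, exonsPath,
                           insertionPos) {
  cts <- utils::read.delim(countsPath, check.names = FALSE)
  mat <- as.matrix(cts[, -1L, drop = FALSE])
  rownames(mat) <- cts[[1L]]
  totals <- utils::read.delim(totalsPath, colClasses = c(sample_id = "character"))
  samples <- readSampleInfo(samplesPath)
  gm <- readGeneModel(exonsPath, insertionPos)
  miss <- setdiff(samples$sample_id, colnames(mat))
  if (length(miss))
    stop("samples missing from count matrix: ", paste(miss, collapse = ", "))
  mat <- mat[, samples$sample_id, drop = FALSE]
  lt <- totals$library_total[match(samples$sample_id, totals$sample_id)]
  if (anyNA(lt))
    stop("samples missing from totals table: ",
         paste(samples$sample_id[is.na(lt)], collapse = ", "))
  list(counts = ExonCountExperiment(mat, exonLengths(gm)[rownames(mat)],
                                    samples, lt),
       geneModel = gm)
}

#' Read / write the sample sheet
#'
#' Tab-delimited with header `sample_id carrier_status pathogen sire_id`;
#' `.` encodes a missing sire.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
readSampleInfo <- function(path) {
  df <- utils::read.delim(path, na.strings = ".",
                          colClasses = c(sample_id = "character"))
  need <- c("sample_id", "carrier_status", "pathogen")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(df$carrier_status), .CARRIER_LEVELS)
  if (length(bad)) stop("unknown carrier_status value(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$pathogen), .PATHOGEN_LEVELS)
  if (length(bad)) stop("unknown pathogen value(s): ", paste(bad, collapse = ", "))
  df
}

#' Write the count matrix, totals and sample sheet of an ExonCountExperiment
#'
#' @param x An [ExonCountExperiment-class].
#' @param countsPath,totalsPath,samplesPath Output paths.
#' @return Invisibly, the three paths.
#' @export
writeExonCounts <- function(x, countsPath, totalsPath, samplesPath) {
  cts <- SummarizedExperiment::assay(x, "counts")
  .writeTsv(data.frame(exon_id = rownames(cts), cts, check.names = FALSE),
            countsPath)
  .writeTsv(data.frame(sample_id = colnames(x),
                       library_total = unname(libraryTotals(x))), totalsPath)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cols <- intersect(c("sample_id", "carrier_status", "pathogen", "sire_id"),
                    colnames(cd))
  .writeTsv(cd[, cols, drop = FALSE], samplesPath)
  invisible(c(countsPath, totalsPath, samplesPath))
}
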