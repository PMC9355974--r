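#' Normalize exon counts to reads per kilobase per million (FPKM)
#'
#' value(s, e) = counts(s, e) / (length_e / 1000) / (library_total_s / 1e6):
#' normalized for the transcriptome-wide total read count of each animal and
#' for the length of the respective exon.
#'
#' @param x An [ExonCountExperiment-class].
#' @return Numeric matrix of normalized expression, exons x samples.
#' @examples
#' # count 100 on a 1 kb exon in a 1e6-read library -> 100.0
#' @export
normalizeCounts <- function(x) {
  lt <- libraryTotals(x)
  if (any(lt <= 0))
    stop("library_total must be positive; offending sample(s): ",
         paste(colnames(x)[lt <= 0], collapse = ", "))
  cts <- SummarizedExperiment::assay(x, "counts")
  kb <- exonLengths(x) / 1000
  sweep(cts / kb, 2L, lt / 1e6, "/")
}

#' Aggregate a set of exons into one combined unit
#'
#' Counts are summed per sample and the effective length is the sum of the
#' member lengths, so the combined unit's FPKM is the length-weighted mean of
#' the member exon FPKMs. Library totals are unchanged.
#'
#' @param x An [ExonCountExperiment-class].
#' @param exonIds Non-empty subset of exon ids to combine.
#' @param label Row name for the combined unit.
#' @return A one-row [ExonCountExperiment-class].
#' @export
aggregateExons <- function(x, exonIds, label = paste(exonIds, collapse = "+")) {
  miss <- setdiff(exonIds, rownames(x))
  if (length(miss)) stop("unknown exon id(s): ", paste(miss, collapse = ", "))
  if (!length(exonIds)) stop("exonIds must be non-empty")
  cts <- SummarizedExperiment::assay(x, "counts")[exonIds, , drop = FALSE]
  agg <- matrix(colSums(cts), nrow = 1L,
                dimnames = list(label, colnames(cts)))
  cd <- SummarizedExperiment::colData(x)
  ExonCountExperiment(agg, sum(exonLengths(x)[exonIds]),
                      cd[, setdiff(colnames(cd), "library_total")],
                      libraryTotals(x))
}

#' Carrier-versus-wild-type contrast of normalized expression for one unit
#'
#' Fits ordinary least squares of normalized expression on the fixed effects
#' of pathogen challenge group and carrier genotype (main effects only, no
#' interaction) and reports least-squares means per genotype: predicted cell
#' means averaged over pathogen levels with equal weight. When only one
#' pathogen level is present the model reduces to a genotype-only fit, whose
#' lsmeans are the raw group means and whose p-value equals the
#' pooled-variance two-sample t-test. The genotype p-value is the two-sided
#' test of the genotype coefficient.
#'
#' @param x An [ExonCountExperiment-class].
#' @param unit Exon id (row) to contrast.
#' @param log2 Analyse log2(value + 1) instead of the raw normalized value
#'   (off by default; expression is analysed untransformed).
#' @return A one-row data.frame: `unit`, `n_cdc`, `n_cdf`, `lsmean_cdc`,
#'   `se_cdc`, `lsmean_cdf`, `se_cdf`, `p_value`.
#' @export
contrastByGenotype <- function(x, unit, log2 = FALSE) {
  if (!unit %in% rownames(x)) stop("unknown unit: ", unit)
  vals <- normalizeCounts(x)[unit, ]
  if (log2) vals <- base::log2(vals + 1)
  cd <- SummarizedExperiment::colData(x)
  df <- data.frame(value = vals,
                   genotype = factor(cd$carrier_status, .CARRIER_LEVELS),
                   pathogen = factor(cd$pathogen))
  if (any(table(df$genotype) < 1L))
    stop("need at least one sample per genotype level")
  use_pathogen <- nlevels(droplevels(df$pathogen)) > 1L
  fml <- if (use_pathogen) value ~ pathogen + genotype else value ~ genotype
  fit <- stats::lm(fml, data = df)
  mm <- stats::model.matrix(fit)
  if (qr(mm)$rank < ncol(mm))
    stop("design is rank-deficient: genotype is confounded with pathogen group")
  em <- as.data.frame(emmeans::emmeans(fit, "genotype"))
  co <- stats::summary.lm(fit)$coefficients
  gi <- grep("^genotype", rownames(co))
  data.frame(unit = unit,
             n_cdc = sum(df$genotype == "CDC"),
             n_cdf = sum(df$genotype == "CDF"),
             lsmean_cdc = em$emmean[em$genotype == "CDC"],
             se_cdc = em$SE[em$genotype == "CDC"],
             lsmean_cdf = em$emmean[em$genotype == "CDF"],
             se_cdf = em$SE[em$genotype == "CDF"],
             p_value = unname(co[gi, "Pr(>|t|)"]))
}

#' Exon-wise and aggregated expression contrasts across the breakpoint
#'
#' Runs [contrastByGenotype()] for every exon and for the combined units
#' upstream of the insertion (exons before the insertion exon) and from the
#' insertion exon onwards, mirroring the conventional exon 1-4 / exon 5-29
#' split; per-unit raw p-values are accompanied by Benjamini-Hochberg
#' adjusted values computed across all reported units.
#'
#' @param x An [ExonCountExperiment-class].
#' @param geneModel Optional [GeneModel-class]; when supplied, the two
#'   combined units are added using the insertion exon as the split point.
#' @param log2 Passed to [contrastByGenotype()].
#' @return A data.frame with one row per unit and columns `unit`, `n_cdc`,
#'   `n_cdf`, `lsmean_cdc`, `se_cdc`, `lsmean_cdf`, `se_cdf`, `p_raw`,
#'   `p_bh`.
#' @export
exonContrasts <- function(x, geneModel = NULL, log2 = FALSE) {
  units <- lapply(rownames(x), function(u) contrastByGenotype(x, u, log2))
  if (!is.null(geneModel)) {
    side <- exonSide(geneModel)
    side <- side[names(side) %in% rownames(x)]
    up <- names(side)[side == "upstream"]
    down <- names(side)[side %in% c("insertion", "downstream")]
    if (length(up))
      units <- c(units, list(contrastByGenotype(
        aggregateExons(x, up, "upstream_combined"), "upstream_combined", log2)))
    if (length(down))
      units <- c(units, list(contrastByGenotype(
        aggregateExons(x, down, "insertion_downstream_combined"),
        "insertion_downstream_combined", log2)))
  }
  out <- do.call(rbind, units)
  names(out)[names(out) == "p_value"] <- "p_raw"
  out$p_bh <- stats::p.adjust(out$p_raw, "BH")
  rownames(out) <- NULL
  out
}
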