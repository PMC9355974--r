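.subsetVariants <- function(x, idx) {
  new("VariantTable", region = x@region,
      variants = x@variants[idx, , drop = FALSE],
      genotypes = x@genotypes[idx, , drop = FALSE])
}

#' Genotype-segregation compatibility screen for candidate causal variants
#'
#' A variant is compatible with causing the haplotype-biased expression when
#' every case (carrier) is heterozygous and every control (wild type) is
#' homozygous — either homozygote class by default, since the requirement is
#' absence of heterozygosity in unaffected animals; `uniformHom = TRUE`
#' additionally demands that all controls share one homozygote class.
#'
#' @param x A [VariantTable-class].
#' @param cases,controls Disjoint, non-empty character vectors of sample ids.
#' @param missingPolicy `"drop"` (default): a variant with any missing
#'   genotype among the required samples is dropped (it cannot be verified);
#'   `"permissive"`: missing calls do not disqualify.
#' @param anchor Optional coordinate (e.g. the insertion site); the nearest
#'   compatible variant and its distance are reported relative to it.
#' @param uniformHom Require all controls to share one homozygote class.
#' @return A list: `compatible` (a [VariantTable-class] of kept variants),
#'   `nearest` (data.frame `pos`, `distance_bp`, or NULL without an anchor or
#'   compatible variant), and `counts` (`n_input`, `n_compatible`,
#'   `n_dropped_missing`).
#' @export
screenCompatible <- function(x, cases, controls,
                             missingPolicy = c("drop", "permissive"),
                             anchor = NULL, uniformHom = FALSE) {
  missingPolicy <- match.arg(missingPolicy)
  if (!length(cases) || !length(controls))
    stop("cases and controls must be non-empty")
  if (length(intersect(cases, controls)))
    stop("cases and controls must be disjoint")
  unknown <- setdiff(c(cases, controls), colnames(x@genotypes))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  gca <- x@genotypes[, cases, drop = FALSE]
  gco <- x@genotypes[, controls, drop = FALSE]
  any_missing <- apply(is.na(gca), 1L, any) | apply(is.na(gco), 1L, any)
  case_ok <- apply(gca, 1L, function(g) all(g == 1L, na.rm = TRUE))
  ctrl_hom <- apply(gco, 1L, function(g) all(g %in% c(0L, 2L) | is.na(g)))
  if (uniformHom)
    ctrl_hom <- ctrl_hom & apply(gco, 1L, function(g)
      length(unique(g[!is.na(g)])) <= 1L)
  keep <- case_ok & ctrl_hom
  n_dropped_missing <- 0L
  if (missingPolicy == "drop") {
    n_dropped_missing <- sum(keep & any_missing)
    keep <- keep & !any_missing
  }
  keep[is.na(keep)] <- FALSE
  kept <- .subsetVariants(x, which(keep))
  nearest <- NULL
  if (!is.null(anchor) && nrow(kept@variants)) {
    d <- abs(kept@variants$pos - anchor)
    i <- which.min(d)
    nearest <- data.frame(pos = kept@variants$pos[i], distance_bp = d[i])
  }
  list(compatible = kept, nearest = nearest,
       counts = c(n_input = nrow(x@variants),
                  n_compatible = nrow(kept@variants),
                  n_dropped_missing = n_dropped_missing))
}

#' Minor-allele-frequency filter
#'
#' The alternative allele frequency is estimated from genotype counts,
#' p = (2 x hom_alt + het) / (2 x n_called); a variant is kept iff
#' min(p, 1 - p) is strictly greater than the threshold, so at the default
#' 0.05 a MAF of exactly 0.05 is dropped and at threshold 0 only
#' monomorphic variants are dropped.
#'
#' @param x A [VariantTable-class].
#' @param threshold Frequency threshold (default 0.05).
#' @return The filtered [VariantTable-class].
#' @export
mafFilter <- function(x, threshold = 0.05) {
  maf <- apply(x@genotypes, 1L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    p <- (2 * sum(g == 2L) + sum(g == 1L)) / (2 * length(g))
    min(p, 1 - p)
  })
  .subsetVariants(x, which(!is.na(maf) & maf > threshold))
}

#' Exact Hardy-Weinberg equilibrium test from genotype counts
#'
#' Exact conditional test: under random mating, conditional on the observed
#' allele counts, the probability of heterozygote counts at least as
#' improbable as the one observed, summed over all heterozygote counts of
#' matching parity. Preferred over the chi-square test because small cohorts
#' make the asymptotic test anti-conservative.
#'
#' @param nHomRef,nHet,nHomAlt Non-negative genotype counts.
#' @return Exact p-value in (0, 1]; monomorphic samples give p = 1.
#' @examples
#' hweExactTest(0, 2, 0)    # 2 + 2 alleles, only het counts 0 and 2 attainable
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  if (any(c(nHomRef, nHet, nHomAlt) < 0)) stop("genotype counts must be >= 0")
  n <- nHomRef + nHet + nHomAlt
  if (n < 1L) stop("at least one genotype call required")
  n_a <- 2L * nHomAlt + nHet           # alternative allele count
  n_b <- 2L * nHomRef + nHet
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)
  # P(het = h | allele counts) on the log scale, h over matching parity
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- vapply(hs, function(h) {
    haa <- (n_a - h) %/% 2L; hbb <- (n_b - h) %/% 2L
    lgamma(n + 1) - lgamma(haa + 1) - lgamma(h + 1) - lgamma(hbb + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1L))
  probs <- exp(logp - max(logp)); probs <- probs / sum(probs)
  p_obs <- probs[hs == nHet]
  if (!length(p_obs))
    stop("observed heterozygote count is inconsistent with the allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Apply the exact HWE filter to a variant table
#'
#' @param x A [VariantTable-class].
#' @param threshold Keep variants with exact HWE p strictly greater than
#'   this value (default 0.05).
#' @return The filtered [VariantTable-class].
#' @export
hweFilter <- function(x, threshold = 0.05) {
  p <- apply(x@genotypes, 1L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hweExactTest(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  .subsetVariants(x, which(!is.na(p) & p > threshold))
}

#' GenTrain cluster-quality filter
#'
#' Keeps variants whose GenTrain score is strictly greater than the
#' threshold; variants without a score fail closed (dropped, with a message
#' giving the count).
#'
#' @param x A [VariantTable-class].
#' @param threshold Score threshold (default 0.7).
#' @return The filtered [VariantTable-class].
#' @export
gentrainFilter <- function(x, threshold = 0.7) {
  sc <- x@variants$gentrain
  n_missing <- sum(is.na(sc))
  if (n_missing)
    message(n_missing, " variant(s) without a GenTrain score dropped (fail closed)")
  .subsetVariants(x, which(!is.na(sc) & sc > threshold))
}
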