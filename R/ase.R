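#' Per-sample allelic read-count ratio at a phased heterozygous site
#'
#' For each sample, r = depth(allele on the mutation haplotype) /
#' depth(allele on the wild-type haplotype). Samples whose combined
#' two-allele depth is below `minDepth` are excluded; a zero denominator
#' with a non-zero numerator yields a non-finite ratio that is flagged and
#' excluded from model fitting (with a warning); 0/0 is excluded.
#'
#' @param depths data.frame of site allele counts (columns `sample_id`,
#'   `ref`, `alt`, `n_ref`, `n_alt`) for one site.
#' @param inPhaseAllele The base on the mutation haplotype; must be the
#'   site's ref or alt allele.
#' @param minDepth Minimum combined two-allele read depth for inclusion
#'   (default 10, for ratio stability).
#' @param pseudocount Added to both allele depths before forming the ratio
#'   (default 0; no pseudocount, so fully silenced haplotypes yield ratios
#'   of exactly 0).
#' @return `depths` with added columns `ratio`, `total_depth`, `included`,
#'   `reason` (NA when included).
#' @export
siteRatio <- function(depths, inPhaseAllele, minDepth = 10, pseudocount = 0) {
  ok <- inPhaseAllele == depths$ref | inPhaseAllele == depths$alt
  if (!all(ok))
    stop("in-phase allele '", inPhaseAllele, "' is not among the site alleles")
  n_in <- ifelse(depths$ref == inPhaseAllele, depths$n_ref, depths$n_alt)
  n_out <- ifelse(depths$ref == inPhaseAllele, depths$n_alt, depths$n_ref)
  total <- depths$n_ref + depths$n_alt
  ratio <- (n_in + pseudocount) / (n_out + pseudocount)
  included <- rep(TRUE, nrow(depths))
  reason <- rep(NA_character_, nrow(depths))
  low <- total < minDepth
  included[low] <- FALSE; reason[low] <- "below_min_depth"
  nonfin <- !is.finite(ratio)
  if (any(nonfin & !low))
    warning(sum(nonfin & !low),
            " sample(s) with zero wild-type-phase depth excluded (non-finite ratio)")
  included[nonfin] <- FALSE
  reason[nonfin & is.nan(ratio)] <- "zero_total"
  reason[nonfin & !is.nan(ratio)] <- "zero_denominator"
  out <- depths
  out$ratio <- ratio; out$total_depth <- total
  out$included <- included; out$reason <- reason
  out
}

#' Compare allelic ratios between carrier and wild-type animals
#'
#' Ordinary least squares of the per-animal ratio on the carrier genotype as
#' the only fixed effect. Least-squares means are the group means; standard
#' errors use the pooled model residual variance; the two-sided p-value for
#' the genotype coefficient equals the pooled-variance two-sample t-test.
#' With fewer than two finite ratios in a group the contrast is reported as
#' not estimable (`p_group` NA) but the available group is still summarized.
#'
#' @param ratios Numeric vector of per-animal ratios (finite values only are
#'   used).
#' @param status Character vector of carrier status (`"CDC"`/`"CDF"`)
#'   parallel to `ratios`.
#' @return A list with `groups` (data.frame: `group`, `n`, `lsmean`, `se`,
#'   `min`, `max`) and `p_group`.
#' @export
compareRatioByGenotype <- function(ratios, status) {
  keep <- is.finite(ratios)
  ratios <- ratios[keep]; status <- status[keep]
  g <- factor(status, .CARRIER_LEVELS)
  groups <- do.call(rbind, lapply(.CARRIER_LEVELS, function(lev) {
    r <- ratios[g == lev]
    data.frame(group = lev, n = length(r),
               lsmean = if (length(r)) mean(r) else NA_real_,
               se = NA_real_,
               min = if (length(r)) min(r) else NA_real_,
               max = if (length(r)) max(r) else NA_real_)
  }))
  p_group <- NA_real_
  if (all(table(g) >= 2L)) {
    fit <- stats::lm(ratios ~ g)
    em <- as.data.frame(emmeans::emmeans(fit, "g"))
    groups$se <- em$SE[match(groups$group, as.character(em$g))]
    co <- stats::summary.lm(fit)$coefficients
    p_group <- unname(co[grep("^g", rownames(co)), "Pr(>|t|)"])
  }
  list(groups = groups, p_group = p_group)
}

#' One-sample t-test of the mean allelic ratio against 1
#'
#' Two-sided test of whether the group's mean ratio differs from the value
#' of 1 expected under balanced biallelic expression. Degenerate inputs are
#' reported rather than erroring: with zero variance the p-value is 1 when
#' the common value is exactly 1 and 0 otherwise (flagged).
#'
#' @param ratios Numeric vector of finite per-animal ratios.
#' @return A list with `p` (NA when fewer than two finite ratios),
#'   `mean`, `n`, and `zero_variance`.
#' @export
testVsExpectedOne <- function(ratios) {
  r <- ratios[is.finite(ratios)]
  if (length(r) < 2L)
    return(list(p = NA_real_, mean = if (length(r)) mean(r) else NA_real_,
                n = length(r), zero_variance = FALSE))
  if (stats::sd(r) == 0)
    return(list(p = if (r[1L] == 1) 1 else 0, mean = r[1L], n = length(r),
                zero_variance = TRUE))
  tt <- stats::t.test(r, mu = 1)
  list(p = tt$p.value, mean = mean(r), n = length(r), zero_variance = FALSE)
}

#' Allele-biased expression analysis at phased heterozygous sites
#'
#' For every phased site, forms per-animal ratios of the mutation-haplotype
#' allele depth to the wild-type-haplotype allele depth ([siteRatio()]),
#' restricts to animals heterozygous at the site by genomic-DNA genotype,
#' contrasts carriers against wild types ([compareRatioByGenotype()]) and
#' tests each group's mean ratio against the balanced expectation of 1
#' ([testVsExpectedOne()]).
#'
#' @param depths Allele-depth data.frame (`chrom`, `pos`, `sample_id`,
#'   `ref`, `alt`, `n_ref`, `n_alt`, `n_other`).
#' @param phase Phase table from [phaseAgainstMutation()] (only `assigned`
#'   sites are analysed).
#' @param samples Sample sheet data.frame (`sample_id`, `carrier_status`).
#' @param gdnaGenotypes Optional data.frame (`pos`, `sample_id`, `genotype`
#'   codes 0/1/2) of genomic-DNA genotypes; only samples with code 1 (het)
#'   enter the analysis. When NULL, every sample with depth data is taken as
#'   a pre-verified heterozygote — heterozygosity is never inferred from the
#'   RNA depths themselves.
#' @param minDepth,pseudocount Passed to [siteRatio()].
#' @return A data.frame with one row per (site, group): `chrom`, `pos`,
#'   `in_phase_allele`, `group`, `n`, `lsmean`, `se`, `min`, `max`,
#'   `p_group`, `p_vs_one`.
#' @export
aseAnalysis <- function(depths, phase, samples, gdnaGenotypes = NULL,
                        minDepth = 10, pseudocount = 0) {
  sites <- phase[phase$status == "assigned", , drop = FALSE]
  if (!nrow(sites)) stop("no assigned site in the phase table")
  out <- list()
  for (i in seq_len(nrow(sites))) {
    d <- depths[depths$pos == sites$pos[i], , drop = FALSE]
    if (!nrow(d)) next
    if (!is.null(gdnaGenotypes)) {
      het <- gdnaGenotypes$sample_id[gdnaGenotypes$pos == sites$pos[i] &
                                     gdnaGenotypes$genotype == 1L]
      d <- d[d$sample_id %in% het, , drop = FALSE]
    }
    if (!nrow(d)) next
    sr <- siteRatio(d, sites$in_phase_allele[i], minDepth, pseudocount)
    sr <- sr[sr$included, , drop = FALSE]
    status <- samples$carrier_status[match(sr$sample_id, samples$sample_id)]
    cmp <- compareRatioByGenotype(sr$ratio, status)
    g <- cmp$groups
    g$p_vs_one <- vapply(g$group, function(lev)
      testVsExpectedOne(sr$ratio[status == lev])$p, numeric(1L))
    out[[length(out) + 1L]] <-
      data.frame(chrom = sites$chrom[i], pos = sites$pos[i],
                 in_phase_allele = sites$in_phase_allele[i],
                 g[, c("group", "n", "lsmean", "se", "min", "max")],
                 p_group = cmp$p_group, p_vs_one = g$p_vs_one)
  }
  if (!length(out)) stop("no site had usable allele depths")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
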