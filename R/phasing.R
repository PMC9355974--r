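#' Deduce the paternally transmitted allele at one bi-allelic marker
#'
#' Elementary Mendelian step: a homozygous offspring fixes its paternal
#' allele; a heterozygous offspring of a homozygous sire received the sire's
#' allele; a heterozygous offspring of a heterozygous sire is uninformative
#' because the dam is unknown.
#'
#' @param sireGT,offspringGT Genotype codes (0 = hom ref, 1 = het,
#'   2 = hom alt, NA = missing).
#' @return One of `"ref"`, `"alt"`, `"ambiguous"`, `"inconsistent"` (the
#'   offspring shares no allele with the sire — flagged, never silent), or
#'   NA when either genotype is missing.
#' @export
deducePaternalAllele <- function(sireGT, offspringGT) {
  mapply(function(s, o) {
    if (is.na(s) || is.na(o)) return(NA_character_)
    if (o == 0L) { if (s == 2L) "inconsistent" else "ref" }
    else if (o == 2L) { if (s == 0L) "inconsistent" else "alt" }
    else { # offspring het
      if (s == 0L) "ref" else if (s == 2L) "alt" else "ambiguous"
    }
  }, sireGT, offspringGT, USE.NAMES = FALSE)
}

#' Phase marker alleles against the mutation from half-sib offspring
#'
#' For each marker at which the carrier sire is heterozygous, every offspring
#' with an unambiguously deducible paternal allele casts a vote: carrier
#' offspring place their paternal allele on the mutation haplotype;
#' wild-type offspring place theirs on the wild-type haplotype (equivalently,
#' the sire's other allele on the mutation haplotype). Under the default
#' strict rule the call requires unanimity; any disagreement marks the marker
#' `conflicted` (interpreted as recombination or genotyping error, double
#' recombinants in a short interval being considered extremely unlikely).
#' Sire-homozygous markers are `uninformative`.
#'
#' @param cohort A [PedigreeCohort-class].
#' @param minAgreement Fraction of votes that must agree for a call
#'   (default 1 = unanimity; lower values allow a majority call, with the
#'   dissenting votes reported in `n_conflicts`).
#' @return A data.frame, one row per marker: `chrom`, `pos`, `ref`, `alt`,
#'   `in_phase` (`"ref"`/`"alt"`/`"unknown"`), `in_phase_allele` (the base,
#'   or NA), `n_informative`, `n_conflicts`, `status`
#'   (`assigned`/`uninformative`/`conflicted`).
#' @export
phaseAgainstMutation <- function(cohort, minAgreement = 1) {
  stopifnot(minAgreement > 0.5, minAgreement <= 1)
  status <- cohort@offspring$carrier_status
  if (!any(status == "CDC") || !any(status == "CDF"))
    warning("phasing works best with at least one carrier and one wild-type offspring")
  mk <- as.data.frame(cohort@markers)
  out <- mk
  out$in_phase <- "unknown"; out$in_phase_allele <- NA_character_
  out$n_informative <- 0L; out$n_conflicts <- 0L
  out$status <- "uninformative"
  for (i in seq_len(nrow(mk))) {
    if (is.na(cohort@sireGT[i]) || cohort@sireGT[i] != 1L) next
    pat <- deducePaternalAllele(rep(1L, ncol(cohort@offspringGT)),
                                cohort@offspringGT[i, ])
    informative <- !is.na(pat) & pat %in% c("ref", "alt")
    if (!any(informative)) next
    # vote: which sire allele rides on the mutation haplotype
    vote <- ifelse(status == "CDC", pat,
                   ifelse(pat == "ref", "alt", "ref"))[informative]
    tab <- table(factor(vote, c("ref", "alt")))
    out$n_informative[i] <- sum(tab)
    winner <- names(tab)[which.max(tab)]
    out$n_conflicts[i] <- sum(tab) - max(tab)
    if (max(tab) / sum(tab) >= minAgreement && max(tab) > 0L) {
      out$status[i] <- "assigned"
      out$in_phase[i] <- winner
      out$in_phase_allele[i] <- if (winner == "ref") mk$ref[i] else mk$alt[i]
    } else {
      out$status[i] <- "conflicted"
    }
  }
  out
}

#' Classify each offspring by the inherited sire haplotype
#'
#' Uses the phase assignment to label every offspring by which sire
#' haplotype (mutation-bearing or wild-type) its paternal alleles support.
#' Mosaic support across markers is reported as a putative recombinant.
#'
#' @param cohort A [PedigreeCohort-class].
#' @param phase Output of [phaseAgainstMutation()] with at least one
#'   `assigned` marker.
#' @return A data.frame, one row per offspring: `sample_id`,
#'   `carrier_status`, `n_support_mut`, `n_support_wt`, `classification`
#'   (`mutation`/`wild_type`/`recombinant`/`unclassified`).
#' @export
haplotypeMatrix <- function(cohort, phase) {
  assigned <- which(phase$status == "assigned")
  if (!length(assigned)) stop("phase assignment contains no assigned marker")
  n_off <- nrow(cohort@offspring)
  mut <- wt <- integer(n_off)
  for (i in assigned) {
    pat <- deducePaternalAllele(rep(cohort@sireGT[i], n_off),
                                cohort@offspringGT[i, ])
    usable <- !is.na(pat) & pat %in% c("ref", "alt")
    mut <- mut + (usable & pat == phase$in_phase[i])
    wt <- wt + (usable & pat != phase$in_phase[i])
  }
  classification <- ifelse(mut > 0L & wt == 0L, "mutation",
                    ifelse(wt > 0L & mut == 0L, "wild_type",
                    ifelse(mut > 0L & wt > 0L, "recombinant", "unclassified")))
  data.frame(sample_id = cohort@offspring$sample_id,
             carrier_status = cohort@offspring$carrier_status,
             n_support_mut = mut, n_support_wt = wt,
             classification = classification)
}

#' Write a phase table
#'
#' @param phase Output of [phaseAgainstMutation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePhase <- function(phase, path) {
  .writeTsv(phase[, c("chrom", "pos", "in_phase_allele", "n_informative",
                      "n_conflicts", "status")], path)
}
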