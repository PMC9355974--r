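#' Generative configuration for synthetic cohorts
#'
#' Parameters of the generative model for a cohort segregating an LTR
#' retrotransposon insertion that combines enhancer activity upstream of the
#' breakpoint with premature polyadenylation downstream. Per haplotype and
#' exon, the expected read count is lambda x exon_kb x h, with h = alpha on
#' the insertion haplotype upstream of the breakpoint, h = rho (the
#' readthrough fraction) downstream, and h = 1 on wild-type haplotypes; the
#' insertion exon is split proportionally to length at the breakpoint.
#'
#' @param nCarriers,nWildtype Numbers of heterozygous carrier (CDC) and
#'   wild-type (CDF) animals (default 8 + 8).
#' @param lambda Baseline expression rate, expected reads per kb per
#'   haplotype (default 250, giving wild-type FPKM of the order seen for a
#'   highly expressed hepatic apolipoprotein gene at ~30 M assigned reads).
#' @param alpha Enhancer multiplier on the insertion haplotype upstream of
#'   the breakpoint (default 19, so the aggregate upstream carrier/wild-type
#'   expression ratio is (1 + alpha) / 2 = 10).
#' @param rho Readthrough fraction in \[0, 1\] surviving downstream of the
#'   premature polyadenylation site on the insertion haplotype
#'   (default 0.01).
#' @param phi Negative-binomial overdispersion, variance = m (1 + phi m);
#'   0 gives Poisson counts (default 0.1).
#' @param epsilon Sequencing error in \[0, 0.05\]: probability that a read's
#'   allele is flipped (default 0).
#' @param beta Mapping bias in (0, 1\]: relative capture of the alternative
#'   allele (default 1).
#' @param markerMaf Population frequency of the alternative allele for
#'   maternal gametes and background variants (default 0.3).
#' @param recombProb Per-interval paternal recombination probability
#'   (default 0.001, matching ~1 cM/Mb at the kb-scale marker spacing of a
#'   single-gene region, where even single recombinants are rare).
#' @param libraryTotal Transcriptome-wide assigned reads per animal
#'   (default 3e7).
#' @param nMarkers Markers in the simulated half-sib pedigree (default 8).
#' @param nCarrierOffspring,nWildtypeOffspring Half-sib family composition
#'   (default 7 + 4, a carrier-sire family with seven carrier and four
#'   wild-type offspring).
#' @param nBackgroundVariants Background variants in the regional table
#'   (default 50).
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#'
#' @return A validated list of class `GenerativeConfig`.
#' @export
generativeConfig <- function(nCarriers = 8L, nWildtype = 8L, lambda = 250,
                             alpha = 19, rho = 0.01, phi = 0.1, epsilon = 0,
                             beta = 1, markerMaf = 0.3, recombProb = 0.001,
                             libraryTotal = 3e7, nMarkers = 8L,
                             nCarrierOffspring = 7L, nWildtypeOffspring = 4L,
                             nBackgroundVariants = 50L, seed = 1L) {
  cfg <- list(nCarriers = as.integer(nCarriers),
              nWildtype = as.integer(nWildtype), lambda = lambda,
              alpha = alpha, rho = rho, phi = phi, epsilon = epsilon,
              beta = beta, markerMaf = markerMaf, recombProb = recombProb,
              libraryTotal = libraryTotal, nMarkers = as.integer(nMarkers),
              nCarrierOffspring = as.integer(nCarrierOffspring),
              nWildtypeOffspring = as.integer(nWildtypeOffspring),
              nBackgroundVariants = as.integer(nBackgroundVariants),
              seed = as.integer(seed))
  stopifnot(cfg$nCarriers >= 0, cfg$nWildtype >= 0,
            cfg$nCarriers + cfg$nWildtype >= 2,
            cfg$lambda >= 0, cfg$alpha >= 0, cfg$phi >= 0,
            cfg$rho >= 0, cfg$rho <= 1,
            cfg$epsilon >= 0, cfg$epsilon <= 0.05,
            cfg$beta > 0, cfg$beta <= 1,
            cfg$markerMaf > 0, cfg$markerMaf < 1,
            cfg$recombProb >= 0, cfg$recombProb <= 1,
            cfg$libraryTotal > 0, cfg$nMarkers >= 1)
  class(cfg) <- "GenerativeConfig"
  cfg
}

# per-exon multiplier h on the insertion haplotype; the insertion exon is
# split at the breakpoint proportionally to length
.insertionMultipliers <- function(geneModel, alpha, rho) {
  side <- exonSide(geneModel)
  f <- insertionSplitFraction(geneModel)
  h <- ifelse(side == "upstream", alpha,
       ifelse(side == "downstream", rho, f * alpha + (1 - f) * rho))
  stats::setNames(h, names(side))
}

.rcounts <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Expected per-group exon expression under a generative configuration
#'
#' Closed-form expectations of the generative model: per exon, carrier mean
#' count = lambda kb (1 + h) and wild-type mean = 2 lambda kb, with h the
#' insertion-haplotype multiplier.
#'
#' @param config A [generativeConfig()].
#' @param geneModel A [GeneModel-class] (default [apobGeneModel()]).
#' @return A data.frame: `exon_id`, `length_bp`, `mean_cdc`, `mean_cdf`.
#' @export
expectedExonCounts <- function(config, geneModel = apobGeneModel()) {
  kb <- exonLengths(geneModel) / 1000
  h <- .insertionMultipliers(geneModel, config$alpha, config$rho)
  data.frame(exon_id = names(kb), length_bp = exonLengths(geneModel),
             mean_cdc = config$lambda * kb * (1 + h),
             mean_cdf = 2 * config$lambda * kb,
             row.names = NULL)
}

# internal (no seeding): half-sib pedigree with truth. forceSites rows
# (pos/ref/alt) are added to the marker panel with the sire heterozygous and
# the alternative allele on the mutation haplotype, so the expression SNPs
# can be phased from the same family as in the real study.
.simPedigree <- function(config, geneModel, forceSites = NULL) {
  nm <- config$nMarkers
  chrom <- as.character(seqnames(exons(geneModel)))[1L]
  lo <- min(start(exons(geneModel))); hi <- max(end(exons(geneModel)))
  avoid <- c(insertionPos(geneModel), forceSites$pos)
  cand <- lo - 1L + sample.int(hi - lo + 1L, nm + length(avoid))
  pos <- sort(setdiff(cand, avoid)[seq_len(nm)])
  base_pairs <- matrix(c("A", "G", "C", "T", "T", "C", "G", "A"), ncol = 2L,
                       byrow = TRUE)
  bp <- base_pairs[sample(nrow(base_pairs), nm, replace = TRUE), , drop = FALSE]
  # sire haplotypes: alternative-allele indicators (1 = alt)
  hapM <- stats::rbinom(nm, 1L, config$markerMaf)  # mutation-bearing
  hapW <- stats::rbinom(nm, 1L, config$markerMaf)  # wild-type
  if (!is.null(forceSites)) {
    pos <- c(pos, forceSites$pos)
    bp <- rbind(bp, cbind(forceSites$ref, forceSites$alt))
    hapM <- c(hapM, rep(1L, nrow(forceSites)))
    hapW <- c(hapW, rep(0L, nrow(forceSites)))
    ord <- order(pos)
    pos <- pos[ord]; bp <- bp[ord, , drop = FALSE]
    hapM <- hapM[ord]; hapW <- hapW[ord]
    nm <- length(pos)
  }
  n_off <- config$nCarrierOffspring + config$nWildtypeOffspring
  status <- rep(c("CDC", "CDF"),
                c(config$nCarrierOffspring, config$nWildtypeOffspring))
  # paternal gamete: condition on the haplotype at the insertion locus and
  # walk outward, switching between sire haplotypes with prob recombProb
  ins_after <- findInterval(insertionPos(geneModel), pos)  # markers <= insertion
  origin <- matrix(0L, nm, n_off)  # 1 = mutation haplotype
  for (j in seq_len(n_off)) {
    cur <- as.integer(status[j] == "CDC")
    if (ins_after >= 1L)
      for (i in ins_after:1L) {
        if (stats::runif(1) < config$recombProb) cur <- 1L - cur
        origin[i, j] <- cur
      }
    cur <- as.integer(status[j] == "CDC")
    if (ins_after < nm)
      for (i in (ins_after + 1L):nm) {
        if (stats::runif(1) < config$recombProb) cur <- 1L - cur
        origin[i, j] <- cur
      }
  }
  pat_allele <- ifelse(origin == 1L, hapM, hapW)        # nm x n_off
  mat_allele <- matrix(stats::rbinom(nm * n_off, 1L, config$markerMaf),
                       nm, n_off)
  ids <- sprintf("OFF%02d_%s", seq_len(n_off), status)
  gt <- pat_allele + mat_allele
  colnames(gt) <- ids
  cohort <- PedigreeCohort(
    sireId = "SIRE1",
    markers = data.frame(chrom = chrom, pos = pos, ref = bp[, 1L],
                         alt = bp[, 2L]),
    sireGT = hapM + hapW,
    offspring = data.frame(sample_id = ids, carrier_status = status),
    offspringGT = gt)
  truth <- list(hapM = hapM, hapW = hapW, paternalOrigin = origin,
                inPhase = ifelse(hapM == 1L, "alt", "ref"))
  list(cohort = cohort, truth = truth)
}

#' Simulate a half-sib pedigree from a heterozygous carrier sire
#'
#' The sire is a heterozygous carrier with known phase; each offspring
#' receives one paternal gamete (recombined between adjacent loci with
#' probability `recombProb`, conditioned on the inherited haplotype at the
#' insertion locus so that carrier status equals presence of the paternal
#' insertion allele) and one maternal allele per marker drawn at the
#' population frequency `markerMaf`. Ground-truth sire haplotypes and
#' per-marker paternal origins are returned for testing.
#'
#' @param config A [generativeConfig()]; `nMarkers`, `nCarrierOffspring`,
#'   `nWildtypeOffspring`, `markerMaf`, `recombProb` and `seed` are used.
#' @param geneModel A [GeneModel-class] (default [apobGeneModel()]).
#' @return A list with `cohort` (a [PedigreeCohort-class]) and `truth`
#'   (sire haplotypes `hapM`/`hapW` as alt-allele indicators, the
#'   `paternalOrigin` matrix, and the true `inPhase` allele per marker).
#' @export
simulatePedigree <- function(config, geneModel = apobGeneModel()) {
  set.seed(config$seed)
  .simPedigree(config, geneModel)
}

# internal (no seeding): regional variant table with HWE background
.simVariantTable <- function(config, sampleIds, regionStart, regionEnd,
                             chrom, spikePos) {
  k <- config$nBackgroundVariants
  cand <- regionStart - 1L + sample.int(regionEnd - regionStart + 1L, k + 1L)
  pos <- sort(setdiff(cand, spikePos)[seq_len(k)])
  gt <- matrix(stats::rbinom(k * length(sampleIds), 2L, config$markerMaf),
               k, length(sampleIds), dimnames = list(NULL, sampleIds))
  gentrain <- round(stats::runif(k, 0.4, 1), 3)
  VariantTable(chrom, regionStart, regionEnd, pos,
               ref = rep("A", k), alt = rep("G", k),
               genotypes = gt, gentrain = gentrain)
}

#' Spike a fully segregation-compatible variant into a variant table
#'
#' Adds one variant that is heterozygous in every carrier (CDC) and
#' homozygous reference in every wild-type (CDF) sample — the genotype
#' pattern required of a variant causal for haplotype-biased expression.
#'
#' @param x A [VariantTable-class] (may be empty).
#' @param samples Sample sheet data.frame with `sample_id` and
#'   `carrier_status`; sample ids must match the table's columns when the
#'   table is non-empty.
#' @param pos Position of the spiked variant; must lie inside the region and
#'   not collide with an existing variant.
#' @return The augmented [VariantTable-class].
#' @export
spikeCompatibleVariant <- function(x, samples, pos) {
  if (pos < start(x@region) || pos > end(x@region))
    stop("spike position lies outside the table's region")
  if (pos %in% x@variants$pos)
    stop("spike position collides with an existing variant at ", pos)
  ids <- if (ncol(x@genotypes)) colnames(x@genotypes) else samples$sample_id
  status <- samples$carrier_status[match(ids, samples$sample_id)]
  g <- ifelse(status == "CDC", 1L, 0L)
  spike_row <- matrix(g, 1L, length(ids), dimnames = list(NULL, ids))
  gm <- if (ncol(x@genotypes)) rbind(x@genotypes, spike_row) else spike_row
  VariantTable(as.character(seqnames(x@region)), start(x@region),
               end(x@region),
               pos = c(x@variants$pos, pos),
               ref = c(x@variants$ref, "T"),
               alt = c(x@variants$alt, "C"),
               genotypes = gm,
               gentrain = c(x@variants$gentrain, 0.95))
}

#' Simulate a complete synthetic cohort
#'
#' Draws one cohort from the generative model: exon read counts per animal
#' (Poisson, or negative-binomial with variance m (1 + phi m)), allelic read
#' depths at one heterozygous SNP upstream (exon 3) and one downstream
#' (exon 13) of the insertion, a half-sib pedigree from a carrier sire, and
#' a regional variant table containing one spiked segregation-compatible
#' variant at the insertion coordinate. At the SNP sites the total depth is
#' drawn around the haplotype rate sum and alleles are allocated
#' binomially, with the alternative-allele capture scaled by `beta` and
#' reads flipped with probability `epsilon`. All draws come from a single
#' seeded stream in a fixed order (exon counts, allele depths, pedigree,
#' variants), so identical seeds give bit-identical cohorts.
#'
#' @param config A [generativeConfig()].
#' @param geneModel A [GeneModel-class] (default [apobGeneModel()]).
#' @return A [SyntheticCohort-class].
#' @export
simulateCohort <- function(config, geneModel = apobGeneModel()) {
  set.seed(config$seed)
  n <- config$nCarriers + config$nWildtype
  status <- rep(c("CDC", "CDF"), c(config$nCarriers, config$nWildtype))
  ids <- sprintf("%s%02d", status, c(seq_len(config$nCarriers),
                                     seq_len(config$nWildtype)))
  pathogen <- rep_len(c("S_aureus", "E_coli"), n)  # balanced challenge arms
  samples <- data.frame(sample_id = ids, carrier_status = status,
                        pathogen = pathogen, sire_id = "SIRE1")

  kb <- exonLengths(geneModel) / 1000
  h <- .insertionMultipliers(geneModel, config$alpha, config$rho)
  rate_wt <- config$lambda * kb
  rate_ins <- config$lambda * kb * h
  mu <- outer(rate_wt, rep(1, n)) +
    outer(rate_ins, as.numeric(status == "CDC")) +
    outer(rate_wt, as.numeric(status == "CDF"))
  counts <- matrix(.rcounts(length(mu), mu, config$phi), nrow(mu),
                   dimnames = list(names(kb), ids))
  ece <- ExonCountExperiment(counts, exonLengths(geneModel), samples,
                             rep(config$libraryTotal, n))

  # allelic depths at the two designated het SNPs (all animals het there;
  # the in-phase allele is the alternative allele at both sites)
  ie <- insertionExon(geneModel)
  site_def <- data.frame(
    exon = c(3L, 13L),
    pos = floor((start(exons(geneModel)) + end(exons(geneModel)))[c(3L, 13L)] / 2),
    ref = c("T", "C"), alt = c("C", "T"))
  chrom <- as.character(seqnames(exons(geneModel)))[1L]
  depth_rows <- list()
  for (k in seq_len(nrow(site_def))) {
    e <- site_def$exon[k]
    r_in <- config$lambda * kb[e] * h[e]   # insertion haplotype (alt allele)
    r_out <- config$lambda * kb[e]         # wild-type haplotype (ref allele)
    rate_alt <- ifelse(status == "CDC", r_in, r_out) * config$beta
    rate_ref <- r_out
    tot <- .rcounts(n, rate_ref + rate_alt, config$phi)
    p_alt <- rate_alt / (rate_ref + rate_alt)
    p_alt <- p_alt * (1 - config$epsilon) + (1 - p_alt) * config$epsilon
    n_alt <- stats::rbinom(n, tot, p_alt)
    depth_rows[[k]] <- data.frame(chrom = chrom, pos = site_def$pos[k],
                                  sample_id = ids, ref = site_def$ref[k],
                                  alt = site_def$alt[k],
                                  n_ref = tot - n_alt, n_alt = n_alt,
                                  n_other = 0L)
  }
  depths <- do.call(rbind, depth_rows)

  ped <- .simPedigree(config, geneModel,
                      forceSites = site_def[, c("pos", "ref", "alt")])

  region_start <- 77385988L
  region_end <- insertionPos(geneModel)
  vt <- .simVariantTable(config, ids, region_start, region_end, chrom,
                         spikePos = insertionPos(geneModel))
  vt <- spikeCompatibleVariant(vt, samples, insertionPos(geneModel))

  truth <- list(
    exonRateWt = rate_wt, exonRateIns = rate_ins,
    insertionMultipliers = h,
    haplotypes = ifelse(status == "CDC", "INS/WT", "WT/WT"),
    sites = data.frame(site_def,
                       in_phase_allele = site_def$alt,
                       rate_in_phase = config$lambda * kb[site_def$exon] *
                         h[site_def$exon],
                       rate_out_phase = config$lambda * kb[site_def$exon]),
    pedigree = ped$truth,
    spikedPos = insertionPos(geneModel))

  new("SyntheticCohort", geneModel = geneModel,
      samples = as(samples, "DataFrame"), exonCounts = ece,
      alleleDepths = depths, pedigree = ped$cohort, variants = vt,
      truth = truth)
}

#' @rdname SyntheticCohort-class
#' @export
setMethod("geneModel", "SyntheticCohort", function(x) x@geneModel)
#' @rdname SyntheticCohort-class
#' @export
setMethod("exonCounts", "SyntheticCohort", function(x) x@exonCounts)
#' @rdname SyntheticCohort-class
#' @export
setMethod("alleleDepths", "SyntheticCohort", function(x) x@alleleDepths)
#' @rdname SyntheticCohort-class
#' @export
setMethod("pedigree", "SyntheticCohort", function(x) x@pedigree)
#' @rdname SyntheticCohort-class
#' @export
setMethod("variantTable", "SyntheticCohort", function(x) x@variants)
#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
#' @rdname SyntheticCohort-class
#' @export
setMethod("sampleInfo", "SyntheticCohort", function(x) x@samples)

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d animals (%d CDC, %d CDF), %d exons\n",
              nrow(object@samples),
              sum(object@samples$carrier_status == "CDC"),
              sum(object@samples$carrier_status == "CDF"),
              nrow(object@exonCounts)))
  cat(sprintf("  allele depths at %d sites; %d pedigree markers; %d regional variants\n",
              length(unique(object@alleleDepths$pos)),
              nrow(markers(object@pedigree)),
              nrow(variants(object@variants))))
})

#' Write all components of a synthetic cohort to a directory
#'
#' Emits `exons.bed`, `counts.tsv`, `totals.tsv`, `samples.tsv`,
#' `allele_depths.tsv`, `gdna_genotypes.tsv` (all animals heterozygous at
#' the two test sites, mirroring the gDNA-confirmed genotypes the ratio
#' analysis requires), `pedigree.tsv`, `variants.vcf` and `truth.json`.
#'
#' @param x A [SyntheticCohort-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeGeneModelBed(x@geneModel, p("exons.bed"))
  writeExonCounts(x@exonCounts, p("counts.tsv"), p("totals.tsv"),
                  p("samples.tsv"))
  writeAlleleDepths(x@alleleDepths, p("allele_depths.tsv"))
  gdna <- unique(x@alleleDepths[, c("chrom", "pos", "sample_id")])
  gdna$genotype <- 1L
  .writeTsv(gdna, p("gdna_genotypes.tsv"))
  writePedigree(x@pedigree, p("pedigree.tsv"))
  writeVariantTableVcf(x@variants, p("variants.vcf"))
  tr <- x@truth
  tr$sites <- as.list(tr$sites)
  jsonlite::write_json(tr, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
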