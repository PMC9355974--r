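#' Construct a VariantTable
#'
#' @param chrom,start,end The screen region (1-based inclusive).
#' @param pos,ref,alt Per-variant position and alleles.
#' @param genotypes Integer matrix (variants x samples) of genotype codes
#'   0 = hom ref, 1 = het, 2 = hom alt, NA = missing, with sample ids as
#'   column names.
#' @param gentrain Optional numeric vector of GenTrain scores in \[0, 1\];
#'   NA where unavailable.
#' @return A [VariantTable-class].
#' @export
VariantTable <- function(chrom, start, end, pos = integer(), ref = character(),
                         alt = character(), genotypes = NULL, gentrain = NULL) {
  n <- length(pos)
  if (is.null(genotypes)) genotypes <- matrix(integer(), nrow = n, ncol = 0L)
  if (is.null(gentrain)) gentrain <- rep(NA_real_, n)
  ord <- order(pos)
  v <- DataFrame(pos = as.integer(pos)[ord], ref = as.character(ref)[ord],
                 alt = as.character(alt)[ord], gentrain = as.numeric(gentrain)[ord])
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  gm <- genotypes[ord, , drop = FALSE]
  new("VariantTable",
      region = GRanges(chrom, IRanges(start, end)),
      variants = v, genotypes = gm)
}

#' @rdname VariantTable-class
#' @export
setMethod("variants", "VariantTable", function(x) x@variants)

#' @rdname VariantTable-class
#' @export
setMethod("genotypeCalls", "VariantTable", function(x) x@genotypes)

#' @rdname VariantTable-class
#' @export
setMethod("screenRegion", "VariantTable", function(x) x@region)

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d variants, %d samples in %s:%s-%s\n",
              nrow(object@variants), ncol(object@genotypes),
              as.character(seqnames(object@region)),
              format(start(object@region), big.mark = ","),
              format(end(object@region), big.mark = ",")))
})

# GT string -> code; any two identical non-zero alleles are hom_alt only for
# the decomposed allele in question (handled by the caller)
.gtStringToCode <- function(gt, allele = 1L) {
  gt <- sub(":.*", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (any(a == ".") || length(a) != 2L) return(NA_integer_)
    sum(a == as.character(allele))
  }, integer(1L))
}

#' Read genotypes from a VCF into a VariantTable
#'
#' Reads a VCF 4.x file, keeps variants within the requested region, and
#' decomposes multi-allelic records into one bi-allelic row per alternative
#' allele (the genotype code counts copies of that allele). Genotypes are
#' taken from the GT field.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param chrom,start,end Region of interest, 1-based inclusive.
#' @param samples Optional character vector of required cohort samples; an
#'   error lists any that are absent from the VCF header.
#' @return A [VariantTable-class]; empty (no error) when no record overlaps
#'   the region.
#' @export
readGenotypes <- function(path, chrom, start, end, samples = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  hdr_samples <- colnames(vcf)
  if (!is.null(samples)) {
    miss <- setdiff(samples, hdr_samples)
    if (length(miss))
      stop("samples absent from VCF header: ", paste(miss, collapse = ", "))
    vcf <- vcf[, samples]
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  keep <- as.character(seqnames(rr)) == as.character(chrom) &
    start(rr) >= start & start(rr) <= end
  vcf <- vcf[keep, ]
  rr <- rr[keep]
  gt <- VariantAnnotation::geno(vcf)$GT
  pos <- integer(); refs <- alts <- character(); rows <- list()
  if (length(rr)) {
    altlist <- VariantAnnotation::alt(vcf)
    for (i in seq_along(rr)) {
      a_i <- as.character(altlist[[i]])
      for (k in seq_along(a_i)) {
        pos <- c(pos, start(rr)[i])
        refs <- c(refs, as.character(VariantAnnotation::ref(vcf)[i]))
        alts <- c(alts, a_i[k])
        rows[[length(rows) + 1L]] <- .gtStringToCode(gt[i, ], allele = k)
      }
    }
  }
  gm <- if (length(rows)) do.call(rbind, rows)
        else matrix(integer(), 0L, ncol(vcf),
                    dimnames = list(NULL, colnames(vcf)))
  if (is.null(colnames(gm))) colnames(gm) <- colnames(vcf)
  VariantTable(chrom, start, end, pos, refs, alts, gm)
}

#' Write a VariantTable as a minimal VCF
#'
#' Emits a minimal VCF 4.2 text file (GT field only) sufficient for
#' round-tripping through [readGenotypes()]; full header fidelity is not a
#' goal.
#'
#' @param x A [VariantTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeVariantTableVcf <- function(x, path) {
  v <- x@variants
  smp <- colnames(x@genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", as.character(seqnames(x@region))),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", smp), collapse = "\t")), con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(v))) {
    g <- x@genotypes[i, ]
    gs <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    writeLines(paste(c(as.character(seqnames(x@region)), v$pos[i], ".",
                       v$ref[i], v$alt[i], ".", "PASS", ".", "GT", gs),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Attach GenTrain scores to a VariantTable
#'
#' @param x A [VariantTable-class].
#' @param scores Named numeric vector, names are variant positions.
#' @return The table with its `gentrain` column filled where positions match.
#' @export
setGentrainScores <- function(x, scores) {
  idx <- match(as.character(x@variants$pos), names(scores))
  x@variants$gentrain <- ifelse(is.na(idx), NA_real_, unname(scores[idx]))
  validObject(x)
  x
}
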