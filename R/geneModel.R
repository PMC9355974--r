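#' Construct a GeneModel
#'
#' @param exons A [GenomicRanges::GRanges] with an `exon_id` metadata column,
#'   or a data.frame with columns `chrom`, `start`, `end`, `exon_id` (1-based
#'   inclusive coordinates).
#' @param insertionPos 1-based coordinate of the mobile-element insertion;
#'   must lie inside exactly one exon.
#' @param strand `"+"` or `"-"`; used only when `exons` is a data.frame.
#'
#' @return A [GeneModel-class] object with exons sorted by start.
#' @examples
#' gm <- GeneModel(data.frame(chrom = "11", start = c(100, 300), end = c(200, 500),
#'                            exon_id = c("E1", "E2")), insertionPos = 350)
#' insertionExon(gm)
#' @export
GeneModel <- function(exons, insertionPos, strand = "+") {
  if (is.data.frame(exons)) {
    exons <- GRanges(exons$chrom,
                     IRanges(start = exons$start, end = exons$end),
                     strand = strand, exon_id = as.character(exons$exon_id))
  }
  exons <- exons[order(start(exons))]
  new("GeneModel", exons = exons, insertionPos = as.integer(insertionPos))
}

#' @rdname GeneModel-class
#' @export
setMethod("exons", "GeneModel", function(x) x@exons)

#' @rdname GeneModel-class
#' @export
setMethod("insertionPos", "GeneModel", function(x) x@insertionPos)

#' @rdname GeneModel-class
#' @export
setMethod("insertionExon", "GeneModel", function(x) {
  which(start(x@exons) <= x@insertionPos & end(x@exons) >= x@insertionPos)
})

#' @rdname GeneModel-class
#' @export
setMethod("exonLengths", "GeneModel", function(x) {
  stats::setNames(width(x@exons), x@exons$exon_id)
})

setMethod("show", "GeneModel", function(object) {
  ex <- object@exons
  cat(sprintf("GeneModel: %d exons on %s (%s), %s-%s\n",
              length(ex), as.character(seqnames(ex))[1L],
              as.character(strand(ex))[1L],
              format(min(start(ex)), big.mark = ","),
              format(max(end(ex)), big.mark = ",")))
  cat(sprintf("  insertion at %s inside exon %d ('%s')\n",
              format(object@insertionPos, big.mark = ","),
              insertionExon(object), ex$exon_id[insertionExon(object)]))
})

#' Classify exons relative to the insertion breakpoint
#'
#' @param x A [GeneModel-class].
#' @return Character vector, one of `"upstream"`, `"insertion"`,
#'   `"downstream"` per exon (genomic orientation: upstream = lower
#'   coordinate than the insertion exon).
#' @export
exonSide <- function(x) {
  side <- rep("upstream", length(x@exons))
  ie <- insertionExon(x)
  side[ie] <- "insertion"
  side[seq_along(side) > ie] <- "downstream"
  stats::setNames(side, x@exons$exon_id)
}

#' Fraction of the insertion exon upstream of the breakpoint
#'
#' Length fraction of the insertion-containing exon that lies before the
#' insertion coordinate; used to split that exon's expected expression
#' between the enhancer-boosted upstream regime and the truncated
#' downstream regime on the insertion haplotype.
#'
#' @param x A [GeneModel-class].
#' @return A number in \[0, 1\].
#' @export
insertionSplitFraction <- function(x) {
  ie <- insertionExon(x)
  (x@insertionPos - start(x@exons)[ie]) / width(x@exons)[ie]
}

#' Read a gene model from BED or GFF3
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' coordinates at import; GFF3 coordinates are taken as-is. For GFF3, records
#' with `type == "exon"` are used when present. Exon identifiers come from the
#' BED name column or the GFF3 `Name`/`ID` attribute; missing identifiers are
#' generated as `exon1..exonN` in coordinate order.
#'
#' @param path Path to the file.
#' @param insertionPos 1-based insertion coordinate.
#' @param format `"BED"` or `"GFF3"` (default: guessed from the extension).
#'
#' @return A [GeneModel-class].
#' @export
readGeneModel <- function(path, insertionPos, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "GFF3" else "BED"
  }
  gr <- rtracklayer::import(path, format = tolower(format))
  if (format == "GFF3") {
    if ("type" %in% colnames(S4Vectors::mcols(gr)) && any(gr$type == "exon"))
      gr <- gr[gr$type == "exon"]
    ids <- if (!is.null(gr$Name) && !anyNA(gr$Name)) as.character(gr$Name)
           else if (!is.null(gr$ID) && !anyNA(gr$ID)) as.character(gr$ID)
           else NULL
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else NULL
  }
  gr <- gr[order(start(gr))]
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand = strand(gr))
  out$exon_id <- if (is.null(ids)) paste0("exon", seq_along(gr))
                 else ids[order(start(gr))]
  GeneModel(out, insertionPos)
}

#' Write a gene model's exons as BED
#'
#' Emits 0-based half-open BED with the exon identifier in the name column;
#' re-reading with [readGeneModel()] reproduces identical 1-based coordinates.
#'
#' @param x A [GeneModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelBed <- function(x, path) {
  ex <- x@exons
  df <- data.frame(chrom = as.character(seqnames(ex)),
                   start = start(ex) - 1L, end = end(ex),
                   name = ex$exon_id, score = 0L,
                   strand = as.character(strand(ex)))
  df$strand[df$strand == "*"] <- "+"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default gene model emulating the bovine APOB locus
#'
#' A 29-exon gene on chromosome 11 spanning 77,885,935-77,927,967 bp with an
#' LTR retrotransposon insertion at 77,891,739 inside exon 5, mirroring the
#' cholesterol-deficiency APOB locus layout. Exon sizes are synthetic but of
#' realistic magnitude (a large penultimate exon, as typical for APOB);
#' heterozygous marker SNPs used by the allelic-ratio stage sit in exon 3
#' (upstream of the insertion) and exon 13 (downstream).
#'
#' @return A [GeneModel-class] with 29 exons.
#' @export
apobGeneModel <- function() {
  n <- 29L
  # deterministic synthetic exon sizes (bp); exon 26 large, APOB-like
  sizes <- c(190L, 120L, 260L, 180L, 1400L, 160L, 140L, 180L, 150L, 170L,
             130L, 160L, 220L, 140L, 150L, 180L, 160L, 140L, 200L, 150L,
             160L, 170L, 140L, 180L, 210L, 7500L, 230L, 160L, 240L)
  stopifnot(length(sizes) == n)
  gene_start <- 77885935L
  gene_end   <- 77927967L
  gaps_needed <- gene_end - gene_start + 1L - sum(sizes)
  gap <- gaps_needed %/% (n - 1L)
  extra <- gaps_needed %% (n - 1L)
  starts <- integer(n); starts[1L] <- gene_start
  for (i in 2L:n)
    starts[i] <- starts[i - 1L] + sizes[i - 1L] + gap + (i - 1L <= extra)
  ends <- starts + sizes - 1L
  # anchor exon 5 so that it contains the insertion coordinate
  shift5 <- 77891739L - (starts[5L] + 400L)
  starts[5L] <- starts[5L] + shift5; ends[5L] <- ends[5L] + shift5
  gm <- GeneModel(data.frame(chrom = "11", start = starts, end = ends,
                             exon_id = paste0("exon", seq_len(n))),
                  insertionPos = 77891739L)
  stopifnot(insertionExon(gm) == 5L)
  gm
}
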