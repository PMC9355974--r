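#' Decode one samtools mpileup text record into allele counts
#'
#' Parses the per-sample base string of a pileup line and tallies reads
#' supporting the reference base (`.` and `,`), the stated alternative base
#' (case-insensitive), and anything else. Structural pileup marks are handled
#' per the format: `^` plus the following mapping-quality character opens a
#' read, `$` closes one, and `+N.../-N...` indel runs are consumed without
#' counting. Base-quality filtering is not re-applied; counts are taken as
#' produced upstream.
#'
#' @param line One mpileup text line (chrom, pos, ref base, then per-sample
#'   depth / bases / qualities column triplets).
#' @param sampleIndex Which sample's column triplet to decode (1-based).
#' @param altAllele The alternative allele (single base, A/C/G/T).
#' @param sampleId Optional sample identifier for the output row.
#'
#' @return A one-row data.frame with columns `chrom`, `pos`, `sample_id`,
#'   `ref`, `alt`, `n_ref`, `n_alt`, `n_other`.
#' @examples
#' parseMpileupLine("11\t77887611\tT\t6\t..,CCc\tIIIIII", 1, "C")
#' @export
parseMpileupLine <- function(line, sampleIndex, altAllele, sampleId = NA_character_) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  base_col <- 3L + 3L * (sampleIndex - 1L) + 2L
  if (length(fields) < base_col)
    stop("mpileup line has no sample column ", sampleIndex)
  ref <- toupper(fields[3L])
  alt <- toupper(altAllele)
  if (!alt %in% c("A", "C", "G", "T")) stop("altAllele must be A/C/G/T")
  if (alt == ref) stop("altAllele equals the reference base")
  counts <- .decodePileupBases(fields[base_col], ref, alt)
  data.frame(chrom = fields[1L], pos = as.integer(fields[2L]),
             sample_id = sampleId, ref = ref, alt = alt,
             n_ref = counts[["n_ref"]], n_alt = counts[["n_alt"]],
             n_other = counts[["n_other"]])
}

# character-by-character pileup base-string decoder; errors carry the
# 1-based column offset of the offending character
.decodePileupBases <- function(bases, ref, alt) {
  chars <- strsplit(bases, "")[[1L]]
  n <- length(chars)
  n_ref <- n_alt <- n_other <- 0L
  seen_base <- FALSE
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      if (i + 1L > n)
        stop("malformed pileup base string: dangling '^' at column ", i)
      i <- i + 2L                       # skip mapping-quality character
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      if (!seen_base)
        stop("malformed pileup base string: indel without anchor base at column ", i)
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      if (j == i + 1L)
        stop("malformed pileup base string: indel without length at column ", i)
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n)
        stop("malformed pileup base string: indel length overrun at column ", i)
      i <- j + len
    } else {
      up <- toupper(ch)
      if (ch == "." || ch == ",") n_ref <- n_ref + 1L
      else if (up == alt) n_alt <- n_alt + 1L
      else n_other <- n_other + 1L
      seen_base <- TRUE
      i <- i + 1L
    }
  }
  c(n_ref = n_ref, n_alt = n_alt, n_other = n_other)
}

#' Read allele depths for a cohort from an mpileup text file
#'
#' @param path Path to a samtools mpileup text file covering the sites of
#'   interest for all samples.
#' @param sampleIds Sample identifiers in the order of the pileup's sample
#'   column triplets.
#' @param altAlleles Named character vector mapping position (as character)
#'   to the alternative allele at that site; positions absent from the map
#'   are skipped.
#' @return A data.frame of site allele counts, one row per (site, sample).
#' @export
readMpileup <- function(path, sampleIds, altAlleles) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (line in lines) {
    pos <- strsplit(line, "\t", fixed = TRUE)[[1L]][2L]
    if (!pos %in% names(altAlleles)) next
    for (s in seq_along(sampleIds))
      out[[length(out) + 1L]] <-
        parseMpileupLine(line, s, altAlleles[[pos]], sampleIds[s])
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      sample_id = character(), ref = character(),
                      alt = character(), n_ref = integer(),
                      n_alt = integer(), n_other = integer()))
  do.call(rbind, out)
}

#' Read / write per-site allele depth tables
#'
#' Tab-delimited tables with header
#' `chrom pos sample_id ref alt n_ref n_alt n_other` and `.` for missing.
#'
#' @param path File path.
#' @return `readAlleleDepths` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
readAlleleDepths <- function(path) {
  df <- utils::read.delim(path, na.strings = ".",
                          colClasses = c(chrom = "character",
                                         sample_id = "character"))
  need <- c("chrom", "pos", "sample_id", "ref", "alt", "n_ref", "n_alt", "n_other")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("allele depth table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(df$n_ref < 0 | df$n_alt < 0 | df$n_other < 0, na.rm = TRUE))
    stop("allele depths must be non-negative")
  df
}

#' @rdname readAlleleDepths
#' @param x Allele-depth data.frame.
#' @export
writeAlleleDepths <- function(x, path) {
  .writeTsv(x, path)
}

.writeTsv <- function(x, path) {
  x <- as.data.frame(x)
  x[] <- lapply(x, function(col) { col[is.na(col)] <- "."; col })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
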