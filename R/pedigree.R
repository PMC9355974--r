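#' Construct a PedigreeCohort
#'
#' @param sireId Sire identifier; the sire is a heterozygous carrier of the
#'   mutation.
#' @param markers data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param sireGT Integer sire genotype codes (0/1/2/NA), one per marker.
#' @param offspring data.frame with columns `sample_id`, `carrier_status`.
#' @param offspringGT Integer matrix, markers x offspring.
#' @return A [PedigreeCohort-class]; markers are sorted by position.
#' @export
PedigreeCohort <- function(sireId, markers, sireGT, offspring, offspringGT) {
  ord <- order(markers$pos)
  new("PedigreeCohort", sireId = as.character(sireId),
      markers = as(markers, "DataFrame")[ord, ],
      sireGT = as.integer(sireGT)[ord],
      offspring = as(offspring, "DataFrame"),
      offspringGT = matrix(as.integer(offspringGT), nrow = nrow(markers),
                           dimnames = dimnames(offspringGT))[ord, , drop = FALSE])
}

#' @rdname PedigreeCohort-class
#' @export
setMethod("markers", "PedigreeCohort", function(x) x@markers)

#' @rdname PedigreeCohort-class
#' @export
setMethod("sireGenotypes", "PedigreeCohort", function(x) x@sireGT)

#' @rdname PedigreeCohort-class
#' @export
setMethod("offspringGenotypes", "PedigreeCohort", function(x) x@offspringGT)

#' @rdname PedigreeCohort-class
#' @export
setMethod("offspringInfo", "PedigreeCohort", function(x) x@offspring)

setMethod("show", "PedigreeCohort", function(object) {
  st <- table(factor(object@offspring$carrier_status, .CARRIER_LEVELS))
  cat(sprintf("PedigreeCohort: sire '%s', %d offspring (%d CDC, %d CDF), %d markers\n",
              object@sireId, nrow(object@offspring), st[["CDC"]], st[["CDF"]],
              nrow(object@markers)))
})

#' Read / write a pedigree genotype table
#'
#' Long tab-delimited format: one row per (marker, animal) with columns
#' `chrom pos ref alt sample_id carrier_status role genotype`, where `role`
#' is `sire` or `offspring` and `genotype` is 0/1/2 or `.` for missing.
#'
#' @param path File path.
#' @return `readPedigree` returns a [PedigreeCohort-class]; the writer
#'   returns `path` invisibly.
#' @export
readPedigree <- function(path) {
  df <- utils::read.delim(path, na.strings = ".",
                          colClasses = c(chrom = "character",
                                         sample_id = "character"))
  sire_rows <- df[df$role == "sire", ]
  off_rows <- df[df$role == "offspring", ]
  mk <- unique(df[order(df$pos), c("chrom", "pos", "ref", "alt")])
  key <- function(d) as.character(d$pos)
  sire_gt <- sire_rows$genotype[match(key(mk), key(sire_rows))]
  off_ids <- unique(off_rows$sample_id)
  gt <- sapply(off_ids, function(id) {
    rows <- off_rows[off_rows$sample_id == id, ]
    rows$genotype[match(key(mk), key(rows))]
  })
  gt <- matrix(gt, nrow = nrow(mk), dimnames = list(NULL, off_ids))
  status <- off_rows$carrier_status[match(off_ids, off_rows$sample_id)]
  PedigreeCohort(sireId = sire_rows$sample_id[1L], markers = mk,
                 sireGT = sire_gt,
                 offspring = data.frame(sample_id = off_ids,
                                        carrier_status = status),
                 offspringGT = gt)
}

#' @rdname readPedigree
#' @param x A [PedigreeCohort-class].
#' @export
writePedigree <- function(x, path) {
  mk <- as.data.frame(x@markers)
  sire <- data.frame(mk, sample_id = x@sireId, carrier_status = "CDC",
                     role = "sire", genotype = x@sireGT)
  off <- do.call(rbind, lapply(seq_len(nrow(x@offspring)), function(j)
    data.frame(mk, sample_id = x@offspring$sample_id[j],
               carrier_status = x@offspring$carrier_status[j],
               role = "offspring", genotype = x@offspringGT[, j])))
  .writeTsv(rbind(sire, off), path)
}
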