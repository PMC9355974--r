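# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity by direct enumeration/counting, staying independent
# of the package's implementation path.

# -- pileup: plain character-walk decoder kept as simple as possible --------
refDecodePileup <- function(bases, ref, alt) {
  n_ref <- n_alt <- n_other <- 0L
  i <- 1L
  chars <- strsplit(bases, "")[[1L]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "^") { i <- i + 2L; next }
    if (ch == "$") { i <- i + 1L; next }
    if (ch %in% c("+", "-")) {
      num <- ""
      j <- i + 1L
      while (j <= length(chars) && chars[j] %in% as.character(0:9)) {
        num <- paste0(num, chars[j]); j <- j + 1L
      }
      i <- j + as.integer(num); next
    }
    if (ch %in% c(".", ",")) n_ref <- n_ref + 1L
    else if (toupper(ch) == toupper(alt)) n_alt <- n_alt + 1L
    else n_other <- n_other + 1L
    i <- i + 1L
  }
  c(n_ref = n_ref, n_alt = n_alt, n_other = n_other)
}

# random valid pileup base string plus its symbol count
randomPileupString <- function(alt = "C") {
  k <- sample(0:12, 1L)
  pieces <- character()
  n_bases <- 0L
  for (i in seq_len(k)) {
    type <- sample(c("ref", "alt", "other", "start", "end", "indel"), 1L,
                   prob = c(0.4, 0.2, 0.1, 0.1, 0.1, 0.1))
    if (type == "indel" && n_bases == 0L) type <- "ref"
    piece <- switch(type,
      ref = sample(c(".", ","), 1L),
      alt = sample(c(alt, tolower(alt)), 1L),
      other = sample(c("G", "g", "N"), 1L),
      start = paste0("^", sample(c("I", "!", "F"), 1L), "."),
      end = ".$",
      indel = {
        len <- sample(1:12, 1L)
        paste0(sample(c("+", "-"), 1L), len,
               paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
      })
    pieces <- c(pieces, piece)
    if (type %in% c("ref", "alt", "other", "start", "end"))
      n_bases <- n_bases + 1L
  }
  paste(pieces, collapse = "")
}

# -- phasing: enumerate both candidate sire phases per marker ---------------
refPhaseOracle <- function(cohort) {
  mk <- as.data.frame(markers(cohort))
  sire <- sireGenotypes(cohort)
  gt <- offspringGenotypes(cohort)
  status <- offspringInfo(cohort)$carrier_status
  out <- character(nrow(mk))
  for (i in seq_len(nrow(mk))) {
    if (is.na(sire[i]) || sire[i] != 1L) { out[i] <- "uninformative"; next }
    # violations under hypothesis: in-phase allele is 'ref' or 'alt'
    viol <- c(ref = 0L, alt = 0L); informative <- 0L
    for (j in seq_len(ncol(gt))) {
      o <- gt[i, j]
      if (is.na(o) || o == 1L) next        # het offspring of het sire: no info
      pat <- if (o == 0L) "ref" else "alt"
      informative <- informative + 1L
      for (hyp in c("ref", "alt")) {
        expected <- if (status[j] == "CDC") hyp
                    else setdiff(c("ref", "alt"), hyp)
        if (pat != expected) viol[hyp] <- viol[hyp] + 1L
      }
    }
    if (informative == 0L) out[i] <- "uninformative"
    else if (sum(viol == 0L) == 1L) out[i] <- names(viol)[viol == 0L]
    else out[i] <- "conflicted"
  }
  out
}

# -- screen: exhaustive per-variant, per-sample double loop -----------------
refScreenOracle <- function(vt, cases, controls, missingPolicy = "drop") {
  gt <- genotypeCalls(vt)
  keep <- logical(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    ok <- TRUE; has_missing <- FALSE
    for (s in cases) {
      g <- gt[i, s]
      if (is.na(g)) has_missing <- TRUE
      else if (g != 1L) ok <- FALSE
    }
    for (s in controls) {
      g <- gt[i, s]
      if (is.na(g)) has_missing <- TRUE
      else if (g == 1L) ok <- FALSE
    }
    if (missingPolicy == "drop" && has_missing) ok <- FALSE
    keep[i] <- ok
  }
  variants(vt)$pos[keep]
}

# -- HWE: direct enumeration with choose(), no shared code path -------------
refHweOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  na <- 2L * nBB + nAB
  hs <- seq.int(na %% 2L, min(na, 2L * n - na), by = 2L)
  prob <- vapply(hs, function(h) {
    bb <- (na - h) / 2; aa <- n - h - bb
    choose(n, aa) * choose(n - aa, h) * 2^h / choose(2L * n, na)
  }, numeric(1L))
  prob <- prob / sum(prob)
  p_obs <- prob[hs == nAB]
  sum(prob[prob <= p_obs + 1e-12])
}

# -- small fixture builders -------------------------------------------------
tinyGeneModel <- function() {
  GeneModel(data.frame(chrom = "11",
                       start = c(100L, 400L, 900L),
                       end = c(200L, 700L, 1100L),
                       exon_id = c("E1", "E2", "E3")),
            insertionPos = 500L)
}

tinyCounts <- function(counts, totals = rep(1e6, ncol(counts)),
                       status = rep(c("CDC", "CDF"), each = ncol(counts) / 2),
                       pathogen = rep("S_aureus", ncol(counts)),
                       lengths = rep(1000, nrow(counts))) {
  ids <- sprintf("S%02d", seq_len(ncol(counts)))
  dimnames(counts) <- list(rownames(counts) %||%
                             paste0("E", seq_len(nrow(counts))), ids)
  ltrASE::ExonCountExperiment(
    counts, stats::setNames(lengths, rownames(counts)),
    data.frame(sample_id = ids, carrier_status = status, pathogen = pathogen),
    totals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

randomVariantTable <- function(n_var, sample_ids, p_missing = 0.05,
                               maf = 0.3) {
  gt <- matrix(stats::rbinom(n_var * length(sample_ids), 2L, maf),
               n_var, length(sample_ids), dimnames = list(NULL, sample_ids))
  gt[stats::runif(length(gt)) < p_missing] <- NA_integer_
  VariantTable("11", 1L, 10000L, pos = sample(10000L, n_var),
               ref = rep("A", n_var), alt = rep("G", n_var), genotypes = gt,
               gentrain = round(stats::runif(n_var), 3))
}
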