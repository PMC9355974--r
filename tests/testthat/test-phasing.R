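mk_ped <- function(sireGT, offGT, status) {
  nm <- length(sireGT)
  PedigreeCohort("SIRE", data.frame(chrom = "11", pos = seq_len(nm) * 100,
                                    ref = "C", alt = "T"),
                 sireGT,
                 data.frame(sample_id = paste0("o", seq_along(status)),
                            carrier_status = status),
                 matrix(offGT, nrow = nm))
}

test_that("paternal allele deduction covers the Mendelian cases", {
  # sire C/T (het), offspring C/C -> paternal C (ref)
  expect_equal(deducePaternalAllele(1L, 0L), "ref")
  expect_equal(deducePaternalAllele(1L, 2L), "alt")
  expect_equal(deducePaternalAllele(1L, 1L), "ambiguous")
  expect_equal(deducePaternalAllele(0L, 1L), "ref")   # hom sire forces it
  expect_equal(deducePaternalAllele(2L, 1L), "alt")
  expect_equal(deducePaternalAllele(0L, 2L), "inconsistent")
  expect_equal(deducePaternalAllele(2L, 0L), "inconsistent")
  expect_true(is.na(deducePaternalAllele(NA_integer_, 0L)))
})

test_that("unanimous votes assign the in-phase allele", {
  # 7 carriers paternal-ref, 4 non-carriers paternal-alt at a sire-het marker
  ped <- mk_ped(1L, c(rep(0L, 7), rep(2L, 4)),
                rep(c("CDC", "CDF"), c(7, 4)))
  ph <- phaseAgainstMutation(ped)
  expect_equal(ph$status, "assigned")
  expect_equal(ph$in_phase, "ref")
  expect_equal(ph$in_phase_allele, "C")
  expect_equal(ph$n_informative, 11L)
  expect_equal(ph$n_conflicts, 0L)
})

test_that("uninformative and conflicted markers are reported as such", {
  # all offspring het at a sire-het marker
  ped <- mk_ped(1L, rep(1L, 6), rep(c("CDC", "CDF"), each = 3))
  ph <- phaseAgainstMutation(ped)
  expect_equal(ph$status, "uninformative")
  expect_equal(ph$n_informative, 0L)
  # two carriers voting opposite alleles
  ped <- mk_ped(1L, c(0L, 2L, 1L, 1L), rep(c("CDC", "CDF"), each = 2))
  ph <- phaseAgainstMutation(ped)
  expect_equal(ph$status, "conflicted")
  # sire-homozygous marker
  ped <- mk_ped(0L, c(0L, 1L, 0L, 1L), rep(c("CDC", "CDF"), each = 2))
  expect_equal(phaseAgainstMutation(ped)$status, "uninformative")
})

test_that("a configurable majority can override strict unanimity", {
  ped <- mk_ped(1L, c(0L, 0L, 0L, 0L, 2L, 2L, 2L),
                rep(c("CDC", "CDF"), c(5, 2)))
  # 4 carriers vote ref, 1 carrier votes alt, 2 non-carriers vote ref
  strict <- phaseAgainstMutation(ped)
  expect_equal(strict$status, "conflicted")
  relaxed <- phaseAgainstMutation(ped, minAgreement = 0.8)
  expect_equal(relaxed$status, "assigned")
  expect_equal(relaxed$in_phase, "ref")
  expect_equal(relaxed$n_conflicts, 1L)
})

test_that("consistent ref/alt relabeling flips the phase call only", {
  set.seed(17)
  for (i in 1:25) {
    sim <- simulatePedigree(generativeConfig(recombProb = 0, seed = 600 + i))
    ped <- sim$cohort
    ph <- phaseAgainstMutation(ped)
    flipped <- PedigreeCohort(ped@sireId, as.data.frame(markers(ped)),
                              2L - sireGenotypes(ped),
                              as.data.frame(offspringInfo(ped)),
                              2L - offspringGenotypes(ped))
    ph2 <- phaseAgainstMutation(flipped)
    expect_equal(ph2$status, ph$status)
    assigned <- ph$status == "assigned"
    if (any(assigned)) {
      expect_equal(ph2$in_phase[assigned],
                   ifelse(ph$in_phase[assigned] == "ref", "alt", "ref"))
      # offspring classification is preserved
      hm1 <- haplotypeMatrix(ped, ph)
      hm2 <- haplotypeMatrix(flipped, ph2)
      expect_equal(hm1$classification, hm2$classification)
    }
  }
})

test_that("voting equals brute-force phase enumeration on random pedigrees", {
  set.seed(19)
  for (i in 1:100) {
    cfg <- generativeConfig(recombProb = 0, markerMaf = runif(1, 0.1, 0.9),
                            nMarkers = sample(3:12, 1),
                            nCarrierOffspring = sample(2:8, 1),
                            nWildtypeOffspring = sample(2:8, 1),
                            seed = 2000 + i)
    ped <- simulatePedigree(cfg)$cohort
    ph <- phaseAgainstMutation(ped)
    oracle <- refPhaseOracle(ped)
    got <- ifelse(ph$status == "assigned", ph$in_phase, ph$status)
    expect_equal(got, oracle)
  }
})

test_that("recombination-free haplotype classification matches carrier status", {
  sim <- simulatePedigree(generativeConfig(recombProb = 0, seed = 71))
  ped <- sim$cohort
  ph <- phaseAgainstMutation(ped)
  hm <- haplotypeMatrix(ped, ph)
  with_support <- hm$n_support_mut + hm$n_support_wt > 0
  expect_true(all(hm$classification[with_support & hm$carrier_status == "CDC"]
                  == "mutation"))
  expect_true(all(hm$classification[with_support & hm$carrier_status == "CDF"]
                  == "wild_type"))
})

test_that("an injected crossover is flagged as a putative recombinant", {
  sim <- simulatePedigree(generativeConfig(recombProb = 0, nMarkers = 10,
                                           markerMaf = 0.5, seed = 73))
  ped <- sim$cohort; tr <- sim$truth
  ph <- phaseAgainstMutation(ped)
  assigned <- which(ph$status == "assigned")
  stopifnot(length(assigned) >= 2)
  # pick the two best-supported markers; make carrier offspring 1 homozygous
  # for the mutation-haplotype allele at one and for the wild-type allele at
  # the other, so its paternal origins are unambiguous and split
  picks <- assigned[order(-ph$n_informative[assigned])][1:2]
  gt <- offspringGenotypes(ped)
  gt[picks[1L], 1L] <- 2L * tr$hapM[picks[1L]]
  gt[picks[2L], 1L] <- 2L * tr$hapW[picks[2L]]
  ped2 <- PedigreeCohort(ped@sireId, as.data.frame(markers(ped)),
                         sireGenotypes(ped),
                         as.data.frame(offspringInfo(ped)), gt)
  # re-phase without the tampered offspring's conflicting vote by majority
  ph2 <- phaseAgainstMutation(ped2, minAgreement = 0.7)
  hm <- haplotypeMatrix(ped2, ph2)
  expect_true(hm$n_support_mut[1L] > 0 && hm$n_support_wt[1L] > 0)
  expect_equal(hm$classification[1L], "recombinant")
})
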