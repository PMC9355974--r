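mk_depths <- function(n_ref, n_alt, ref = "T", alt = "C") {
  data.frame(chrom = "11", pos = 77887611L,
             sample_id = sprintf("s%02d", seq_along(n_ref)),
             ref = ref, alt = alt, n_ref = n_ref, n_alt = n_alt, n_other = 0L)
}

test_that("site ratios follow the in-phase / wild-type-phase definition", {
  d <- mk_depths(n_ref = c(50, 100, 0, 0, 3), n_alt = c(50, 0, 100, 0, 2))
  expect_warning(sr <- siteRatio(d, "C", minDepth = 10), "zero wild-type")
  expect_equal(sr$ratio[1], 1)            # balance
  expect_equal(sr$ratio[2], 0)            # one-sided extinction
  expect_true(is.infinite(sr$ratio[3]) && !sr$included[3])
  expect_equal(sr$reason[3], "zero_denominator")
  expect_false(sr$included[4])            # 0/0
  expect_false(sr$included[5])            # below min depth
  expect_equal(sr$reason[5], "below_min_depth")
  expect_error(siteRatio(d, "G", 10), "not among the site alleles")
})

test_that("swapping the in-phase allele inverts finite ratios only", {
  set.seed(23)
  d <- mk_depths(n_ref = rpois(20, 60), n_alt = rpois(20, 40))
  a <- siteRatio(d, "C", minDepth = 10)
  b <- siteRatio(d, "T", minDepth = 10)
  expect_equal(a$included, b$included)
  fin <- a$included & a$ratio > 0
  expect_equal(b$ratio[fin], 1 / a$ratio[fin])
})

test_that("group comparison equals the pooled t-test oracle", {
  # zero-residual fixtures make lm warn about a perfect fit; that is the point
  res <- suppressWarnings(
    compareRatioByGenotype(c(2, 2, 2, 1, 1, 1), rep(c("CDC", "CDF"), each = 3)))
  expect_equal(res$groups$lsmean, c(2, 1))
  # zero residual variance: difference but p from t is NaN-free via lm
  res2 <- compareRatioByGenotype(c(2.1, 1.9, 2.0, 1.2, 0.9, 0.9),
                                 rep(c("CDC", "CDF"), each = 3))
  tt <- t.test(c(2.1, 1.9, 2.0), c(1.2, 0.9, 0.9), var.equal = TRUE)
  expect_equal(res2$p_group, tt$p.value)
  expect_equal(res2$groups$lsmean, c(2, 1))
  # identical values in both groups: zero difference
  res3 <- suppressWarnings(
    compareRatioByGenotype(rep(1.3, 6), rep(c("CDC", "CDF"), each = 3)))
  expect_equal(diff(res3$groups$lsmean), 0)
})

test_that("one-group-only data are summarized but not contrasted", {
  res <- compareRatioByGenotype(c(3, 4, 5), rep("CDC", 3))
  expect_true(is.na(res$p_group))
  expect_equal(res$groups$n, c(3L, 0L))
  expect_equal(res$groups$lsmean[1], 4)
})

test_that("the t-test against 1 handles degenerate inputs", {
  expect_equal(testVsExpectedOne(c(1, 1, 1, 1))$p, 1)
  z <- testVsExpectedOne(c(2, 2, 2, 2))
  expect_equal(z$p, 0)
  expect_true(z$zero_variance)
  expect_true(is.na(testVsExpectedOne(c(2))$p))
  r <- c(1.2, 0.8, 1.1, 0.9, 1.05)
  expect_equal(testVsExpectedOne(r)$p, t.test(r, mu = 1)$p.value)
})

test_that("ASE recovers the allelic enhancer regime on synthetic cohorts", {
  ls_cdc_up <- ls_cdf_up <- ls_cdc_dn <- numeric(0)
  for (i in 1:30) {
    co <- simulateCohort(generativeConfig(alpha = 54, rho = 0.01,
                                          epsilon = 0, beta = 1,
                                          seed = 4000 + i))
    ph <- phaseAgainstMutation(pedigree(co))
    res <- aseAnalysis(alleleDepths(co), ph, as.data.frame(sampleInfo(co)))
    up <- res[res$pos == min(res$pos), ]
    dn <- res[res$pos == max(res$pos), ]
    ls_cdc_up <- c(ls_cdc_up, up$lsmean[up$group == "CDC"])
    ls_cdf_up <- c(ls_cdf_up, up$lsmean[up$group == "CDF"])
    ls_cdc_dn <- c(ls_cdc_dn, dn$lsmean[dn$group == "CDC"])
  }
  expect_equal(median(ls_cdc_up), 54, tolerance = 0.1)
  expect_equal(median(ls_cdf_up), 1, tolerance = 0.1)
  expect_equal(median(ls_cdc_dn), 0.01, tolerance = 0.5)
})

test_that("mapping bias shifts the wild-type lsmean to beta", {
  # beta < 1 under-captures the alternative allele; the in-phase allele is
  # the alternative at both sites, so wild-type ratios centre on beta
  r <- numeric(0)
  for (i in 1:20) {
    co <- simulateCohort(generativeConfig(alpha = 1, rho = 1, beta = 0.8,
                                          phi = 0, seed = 4500 + i))
    d <- alleleDepths(co)
    st <- sampleInfo(co)$carrier_status[match(d$sample_id,
                                              sampleInfo(co)$sample_id)]
    r <- c(r, (d$n_alt / d$n_ref)[st == "CDF"])
  }
  expect_equal(mean(r), 0.8, tolerance = 0.05)
})

test_that("gDNA heterozygosity restricts which samples enter the model", {
  co <- simulateCohort(generativeConfig(seed = 81))
  ph <- phaseAgainstMutation(pedigree(co))
  samples <- as.data.frame(sampleInfo(co))
  d <- alleleDepths(co)
  gdna <- unique(d[, c("pos", "sample_id")])
  gdna$genotype <- 1L
  # declare two animals homozygous at every site: they must drop out
  gdna$genotype[gdna$sample_id %in% c("CDC01", "CDF01")] <- 0L
  res <- aseAnalysis(d, ph, samples, gdna)
  full <- aseAnalysis(d, ph, samples)
  expect_true(all(res$n == full$n - 1L))
})
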