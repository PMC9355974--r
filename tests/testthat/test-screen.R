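test_that("compatibility requires het cases and homozygous controls", {
  gt <- rbind(c(1, 1, 1, 1, 0, 0),   # compatible (controls hom ref)
              c(1, 1, 1, 1, 2, 0),   # compatible (either homozygote class)
              c(1, 1, 1, 1, 1, 0),   # control het -> dropped
              c(1, 1, 0, 1, 0, 0),   # case not het -> dropped
              c(1, 1, 1, 1, NA, 0))  # unverifiable under drop policy
  ids <- c(paste0("C", 1:4), paste0("F", 1:2))
  colnames(gt) <- ids
  vt <- VariantTable("11", 1, 1000, pos = 1:5 * 100, ref = rep("A", 5),
                     alt = rep("G", 5), genotypes = gt)
  rep <- screenCompatible(vt, paste0("C", 1:4), paste0("F", 1:2),
                          anchor = 450)
  expect_equal(variants(rep$compatible)$pos, c(100L, 200L))
  expect_equal(unname(rep$counts),  c(5L, 2L, 1L))
  expect_equal(rep$nearest$pos, 200L)
  expect_equal(rep$nearest$distance_bp, 250L)
  # permissive policy admits the unverifiable variant
  rep2 <- screenCompatible(vt, paste0("C", 1:4), paste0("F", 1:2),
                           missingPolicy = "permissive")
  expect_true(500L %in% variants(rep2$compatible)$pos)
  # strict uniform-homozygote option drops the mixed-hom variant
  rep3 <- screenCompatible(vt, paste0("C", 1:4), paste0("F", 1:2),
                           uniformHom = TRUE)
  expect_equal(variants(rep3$compatible)$pos, 100L)
  expect_error(screenCompatible(vt, "C1", character(0)), "non-empty")
  expect_error(screenCompatible(vt, "C1", "C1"), "disjoint")
  expect_error(screenCompatible(vt, "C1", "ZZ"), "unknown sample")
})

test_that("the screen is invariant to sample order and allele relabeling", {
  set.seed(29)
  ids <- sprintf("s%d", 1:8)
  vt <- randomVariantTable(60, ids)
  cases <- ids[1:5]; controls <- ids[6:8]
  a <- screenCompatible(vt, cases, controls)
  b <- screenCompatible(vt, rev(cases), rev(controls))
  expect_equal(variants(a$compatible)$pos, variants(b$compatible)$pos)
  # ref/alt swap: het stays het, hom classes exchange
  gt <- genotypeCalls(vt)
  vt2 <- VariantTable("11", 1, 10000, variants(vt)$pos,
                      variants(vt)$alt, variants(vt)$ref,
                      genotypes = 2L - gt, gentrain = variants(vt)$gentrain)
  c2 <- screenCompatible(vt2, cases, controls)
  expect_equal(variants(c2$compatible)$pos, variants(a$compatible)$pos)
})

test_that("MAF filtering uses genotype-count allele frequencies strictly", {
  gt <- rbind(rep(0L, 10),                    # MAF 0
              c(rep(1L, 5), rep(0L, 5)),      # p = 0.25
              c(1L, rep(0L, 9)),              # p = 0.05 -> dropped at 0.05
              c(rep(2L, 5), rep(0L, 5)))      # p = 0.5
  colnames(gt) <- sprintf("s%d", 1:10)
  vt <- VariantTable("11", 1, 500, pos = 1:4 * 100, ref = rep("A", 4),
                     alt = rep("G", 4), genotypes = gt)
  expect_equal(variants(mafFilter(vt, 0.05))$pos, c(200L, 400L))
  # threshold 0 drops only monomorphic variants
  expect_equal(variants(mafFilter(vt, 0))$pos, c(200L, 300L, 400L))
})

test_that("GenTrain filtering is strict and fails closed on missing scores", {
  vt <- VariantTable("11", 1, 500, pos = c(100L, 200L, 300L),
                     ref = rep("A", 3), alt = rep("G", 3),
                     genotypes = matrix(1L, 3, 2,
                                        dimnames = list(NULL, c("a", "b"))),
                     gentrain = c(0.71, 0.70, NA))
  expect_message(out <- gentrainFilter(vt, 0.7), "fail closed")
  expect_equal(variants(out)$pos, 100L)
})

test_that("exact HWE agrees with direct enumeration for all small tables", {
  for (n in 1:10)
    for (aa in 0:n) for (ab in 0:(n - aa)) {
      bb <- n - aa - ab
      expect_equal(hweExactTest(aa, ab, bb), refHweOracle(aa, ab, bb),
                   tolerance = 1e-12,
                   info = sprintf("(%d,%d,%d)", aa, ab, bb))
    }
  expect_equal(hweExactTest(5, 0, 0), 1)  # monomorphic
  expect_error(hweExactTest(-1, 0, 2), "must be >= 0")
})

test_that("exact HWE is symmetric under allele swap", {
  set.seed(37)
  for (i in 1:50) {
    g <- as.vector(stats::rmultinom(1, sample(2:40, 1), c(0.3, 0.4, 0.3)))
    expect_equal(hweExactTest(g[1], g[2], g[3]),
                 hweExactTest(g[3], g[2], g[1]))
  }
})

test_that("exact HWE approaches the chi-square test for large balanced counts", {
  exact <- hweExactTest(250, 500, 250)
  chs <- stats::chisq.test(
    x = c(250, 500, 250),
    p = c(0.25, 0.5, 0.25))$p.value
  expect_lt(abs(exact - chs), 0.02)
  # a large sample away from equilibrium: both tests reject
  expect_lt(hweExactTest(300, 400, 300), 0.01)
})

test_that("QC filter composition is order-independent", {
  set.seed(41)
  vt <- randomVariantTable(80, sprintf("s%d", 1:12), p_missing = 0)
  f1 <- gentrainFilter(hweFilter(mafFilter(vt)))
  f2 <- mafFilter(gentrainFilter(hweFilter(vt)))
  f3 <- hweFilter(mafFilter(gentrainFilter(vt)))
  expect_equal(variants(f1)$pos, variants(f2)$pos)
  expect_equal(variants(f2)$pos, variants(f3)$pos)
})

test_that("screen matches the exhaustive oracle and always finds the spike", {
  set.seed(43)
  for (i in 1:60) {
    ids <- sprintf("s%d", 1:6)
    samples <- data.frame(sample_id = ids,
                          carrier_status = rep(c("CDC", "CDF"), c(4, 2)))
    vt <- randomVariantTable(sample(5:40, 1), ids,
                             p_missing = runif(1, 0, 0.15),
                             maf = runif(1, 0.1, 0.5))
    spike_pos <- setdiff(1:10000, variants(vt)$pos)[1]
    vt <- spikeCompatibleVariant(vt, samples, spike_pos)
    for (policy in c("drop", "permissive")) {
      rep <- screenCompatible(vt, ids[1:4], ids[5:6], missingPolicy = policy)
      expect_equal(variants(rep$compatible)$pos,
                   sort(refScreenOracle(vt, ids[1:4], ids[5:6], policy)))
      expect_true(spike_pos %in% variants(rep$compatible)$pos)
    }
  }
})
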