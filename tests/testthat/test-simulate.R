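test_that("generative config validates its domains", {
  expect_s3_class(generativeConfig(), "GenerativeConfig")
  expect_error(generativeConfig(rho = 1.5))
  expect_error(generativeConfig(epsilon = 0.2))
  expect_error(generativeConfig(beta = 0))
  expect_error(generativeConfig(nCarriers = 1, nWildtype = 0))
})

test_that("closed-form expectations follow the generative algebra", {
  gm <- apobGeneModel()
  cfg <- generativeConfig(alpha = 19, rho = 0)
  ex <- expectedExonCounts(cfg, gm)
  side <- exonSide(gm)
  up <- side == "upstream"; down <- side == "downstream"
  # upstream carrier/wild-type ratio (1 + alpha) / 2; downstream (1 + rho) / 2
  expect_equal(sum(ex$mean_cdc[up]) / sum(ex$mean_cdf[up]), 10)
  expect_equal(sum(ex$mean_cdc[down]) / sum(ex$mean_cdf[down]), 0.5)
  # wild-type mean is 2 lambda kb regardless of alpha/rho
  expect_equal(ex$mean_cdf, 2 * cfg$lambda * ex$length_bp / 1000)
})

test_that("identical seeds give bit-identical cohorts", {
  a <- simulateCohort(generativeConfig(seed = 11))
  b <- simulateCohort(generativeConfig(seed = 11))
  expect_identical(SummarizedExperiment::assay(exonCounts(a)),
                   SummarizedExperiment::assay(exonCounts(b)))
  expect_identical(alleleDepths(a), alleleDepths(b))
  expect_identical(offspringGenotypes(pedigree(a)),
                   offspringGenotypes(pedigree(b)))
  expect_identical(genotypeCalls(variantTable(a)),
                   genotypeCalls(variantTable(b)))
  d <- simulateCohort(generativeConfig(seed = 12))
  expect_false(identical(alleleDepths(a), alleleDepths(d)))
})

test_that("simulated exon counts match closed-form means over replicates", {
  cfg <- generativeConfig(nCarriers = 4, nWildtype = 4, phi = 0.1)
  gm <- apobGeneModel()
  ex <- expectedExonCounts(cfg, gm)
  n_rep <- 200
  sum_cdc <- sum_cdf <- matrix(0, nrow(ex), n_rep)
  for (r in seq_len(n_rep)) {
    co <- simulateCohort(generativeConfig(nCarriers = 4, nWildtype = 4,
                                          phi = 0.1, seed = 3000 + r), gm)
    cts <- SummarizedExperiment::assay(exonCounts(co))
    st <- sampleInfo(exonCounts(co))$carrier_status
    sum_cdc[, r] <- rowMeans(cts[, st == "CDC"])
    sum_cdf[, r] <- rowMeans(cts[, st == "CDF"])
  }
  for (grp in list(list(obs = sum_cdc, mu = ex$mean_cdc),
                   list(obs = sum_cdf, mu = ex$mean_cdf))) {
    m <- rowMeans(grp$obs)
    mcse <- apply(grp$obs, 1, stats::sd) / sqrt(n_rep)
    expect_true(all(abs(m - grp$mu) <= 3 * mcse + 1e-9),
                info = "every (group, exon) mean within 3 Monte-Carlo SE")
  }
})

test_that("negative-binomial overdispersion follows var = m(1 + phi m)", {
  set.seed(42)
  mu <- 200; phi <- 0.3
  x <- ltrASE:::.rcounts(2e5, mu, phi)
  expect_equal(mean(x), mu, tolerance = 0.02)
  expect_equal(stats::var(x) / mean(x), 1 + phi * mu, tolerance = 0.05)
  y <- ltrASE:::.rcounts(2e5, mu, 0)
  expect_equal(stats::var(y) / mean(y), 1, tolerance = 0.05)
})

test_that("allele-depth ratios centre on alpha for carriers and 1 for wild types", {
  n_rep <- 120
  r_cdc <- r_cdf <- numeric(0)
  for (r in seq_len(n_rep)) {
    co <- simulateCohort(generativeConfig(alpha = 19, epsilon = 0, beta = 1,
                                          phi = 0, seed = 500 + r))
    d <- alleleDepths(co)
    up <- d[d$pos == min(d$pos), ]
    st <- sampleInfo(co)$carrier_status[match(up$sample_id,
                                              sampleInfo(co)$sample_id)]
    ratio <- up$n_alt / up$n_ref
    r_cdc <- c(r_cdc, ratio[st == "CDC"]); r_cdf <- c(r_cdf, ratio[st == "CDF"])
  }
  expect_equal(mean(r_cdc), 19, tolerance = 0.05)
  expect_equal(mean(r_cdf), 1, tolerance = 0.05)
})

test_that("pedigrees honour the no-recombination limit", {
  cfg <- generativeConfig(recombProb = 0, seed = 21)
  sim <- simulatePedigree(cfg)
  ped <- sim$cohort; tr <- sim$truth
  status <- offspringInfo(ped)$carrier_status
  # every carrier's paternal haplotype equals the sire's mutation haplotype
  expect_true(all(tr$paternalOrigin[, status == "CDC"] == 1L))
  expect_true(all(tr$paternalOrigin[, status == "CDF"] == 0L))
  expect_equal(sum(status == "CDC"), 7L)
  expect_equal(sum(status == "CDF"), 4L)
  # genotypes are paternal + maternal allele
  pat <- ifelse(tr$paternalOrigin == 1L, tr$hapM, tr$hapW)
  gt <- offspringGenotypes(ped)
  expect_true(all(gt - pat >= 0L & gt - pat <= 1L))
})

test_that("spiked compatible variants are constructed as specified", {
  samples <- data.frame(sample_id = c(paste0("C", 1:4), paste0("F", 1:2)),
                        carrier_status = rep(c("CDC", "CDF"), c(4, 2)))
  empty <- VariantTable("11", 1, 1000)
  sp <- spikeCompatibleVariant(empty, samples, 500)
  expect_equal(nrow(variants(sp)), 1L)
  g <- genotypeCalls(sp)[1, samples$sample_id]
  expect_equal(unname(g), c(1L, 1L, 1L, 1L, 0L, 0L))
  expect_error(spikeCompatibleVariant(sp, samples, 500), "collides")
  expect_error(spikeCompatibleVariant(sp, samples, 5000), "outside")
})
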