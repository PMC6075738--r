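test_that("mixBeta matches the two-component mixture arithmetic", {
  expect_equal(mixBeta(0, 0.5, 1.0), 0.5)
  expect_equal(mixBeta(0.8, 0, 0.9), 0.8)
  expect_equal(mixBeta(0.4, 0.25, 0.8), 0.5)
  expect_error(mixBeta(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(mixBeta(0.5, -0.1, 0.5), "\\[0, 1\\]")
})

test_that("infeasible configurations are rejected", {
  expect_error(simConfig(n_samples = 0), "config error")
  expect_error(simConfig(histology_mix = c(seminoma = 0.9, EC = 0.3,
                                           teratoma = 0, yolk_sac = 0,
                                           mixed = 0)), "sum to 1")
  expect_error(simConfig(purity_range_seminoma = c(0.8, 0.2)), "range")
  expect_error(simConfig(n_probes = 100), "n_probes")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- simConfig(n_samples = 12, n_probes = 700, rng_seed = 77)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(sampleMeta(a), sampleMeta(b))
  expect_identical(segments(a), segments(b))
  expect_identical(mutations(a), mutations(b))
  expect_identical(betaValues(betaSet(a)), betaValues(betaSet(b)))
  expect_identical(exprMatrix(a), exprMatrix(b))
  expect_identical(cohortTruth(a)$samples, cohortTruth(b)$samples)
})

test_that("zero lymphocyte noise with fixed purity forces f = 1 - purity", {
  co <- generateCohort(simConfig(n_samples = 10, n_probes = 700,
                                 purity_range_seminoma = c(0.6, 0.6),
                                 purity_range_nsgct = c(0.6, 0.6),
                                 lymph_noise_sd = 0, rng_seed = 5))
  expect_equal(cohortTruth(co)$samples$true_lymph_fraction,
               rep(0.4, 10), tolerance = 1e-12)
})

test_that("true lymphocyte fraction is anti-correlated with purity", {
  co <- generateCohort(simConfig(n_samples = 200, n_probes = 700,
                                 rng_seed = 1))
  tr <- cohortTruth(co)$samples
  expect_lte(cor(tr$true_lymph_fraction, tr$true_purity), -0.95)
  # f never exceeds the non-tumor compartment by more than the noise
  expect_true(all(tr$true_lymph_fraction <=
                    1 - tr$true_purity + 5 * 0.03))
})

test_that("observed beta is exactly the mixture of the truth components", {
  co <- smallCohort()
  tr <- cohortTruth(co)
  remix <- sweep(tr$tumorBeta, 2, 1 - tr$samples$true_lymph_fraction, `*`) +
    outer(tr$lymphocyteRef, tr$samples$true_lymph_fraction)
  expect_lt(max(abs(betaValues(betaSet(co)) - remix)), 1e-12)
})

test_that("simulated TVAFs converge to the multiplicity model at high depth", {
  co <- generateCohort(simConfig(n_samples = 15, n_probes = 700,
                                 mean_depth = 1e5, rng_seed = 13))
  m <- mutations(co)
  tr <- cohortTruth(co)$mutations
  expect_true(all(abs(m$tvaf - tr$expected_tvaf) <= 0.01))
  # and the recorded expectation obeys the closed form
  meta <- sampleMeta(co)
  p <- meta$purity[match(tr$sample_id, meta$sample_id)]
  expect_equal(tr$expected_tvaf,
               expectedTvaf(tr$true_m, tr$total_cn, p), tolerance = 1e-12)
})

test_that("histology marginals follow the configured mix", {
  mix <- c(seminoma = 72, EC = 27, teratoma = 16, yolk_sac = 13,
           mixed = 9) / 137
  co <- generateCohort(simConfig(n_samples = 1000, n_probes = 700,
                                 rng_seed = 3))
  obs <- table(factor(sampleMeta(co)$histology, levels = names(mix))) / 1000
  se <- sqrt(mix * (1 - mix) / 1000)
  expect_true(all(abs(as.numeric(obs) - mix) < 4 * se + 1e-9))
})

test_that("genome structure honours the cohort archetypes", {
  co <- defaultCohort()
  meta <- sampleMeta(co)
  tr <- cohortTruth(co)$samples
  # every sample doubled at least once
  expect_true(all(tr$wgd_count >= 1))
  # seminoma ploidy exceeds NSGCT ploidy at the median
  isSem <- meta$histology == "seminoma"
  expect_gt(median(meta$ploidy[isSem]), median(meta$ploidy[!isSem]))
  # every NSGCT carries i(12p); i(12p)-negative samples are seminomas
  expect_true(all(tr$i12p_present[!isSem]))
  neg <- tr$sample_id[!tr$i12p_present]
  expect_true(all(meta$histology[match(neg, meta$sample_id)] == "seminoma"))
  # KIT mutations only in seminoma
  kitCarriers <- unique(mutations(co)$sample_id[mutations(co)$gene == "KIT"])
  expect_true(all(meta$histology[match(kitCarriers,
                                       meta$sample_id)] == "seminoma"))
})
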