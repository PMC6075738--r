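sigBetaSet <- function(values, ref = 0.9, nProbes = 25) {
  b <- matrix(rep(values, each = nProbes), nrow = nProbes,
              dimnames = list(sprintf("p%02d", seq_len(nProbes)),
                              sprintf("s%02d", seq_along(values))))
  BetaSet(b, makeProbes(rownames(b), lymphocyte_signature = TRUE,
                        lymphocyte_ref_beta = ref))
}

test_that("lymphocyte fraction is the ratio of signature means", {
  expect_equal(estimateLymphocyteFraction(sigBetaSet(0))$f, 0)
  expect_equal(estimateLymphocyteFraction(sigBetaSet(0.9))$f, 1)
  expect_equal(estimateLymphocyteFraction(sigBetaSet(0.45))$f, 0.5)
  expect_error(estimateLymphocyteFraction(sigBetaSet(0.4, nProbes = 10)),
               ">= 20")
})

test_that("beta correction inverts the mixture and clips the floor", {
  expect_equal(correctBeta(0.5, 0.5, 1.0), 0.0)
  expect_equal(correctBeta(0.8, 0, 0.3), 0.8)
  expect_equal(correctBeta(0.6, 0.4, 0.9), 0.4)
  expect_equal(correctBeta(0.1, 0.4, 0.9), 0.0)  # clipped negative mass
  expect_error(correctBeta(0.5, 1, 0.9), "tumor signal")
})

test_that("correctBeta(mixBeta(...)) is the identity within machine precision", {
  set.seed(31)
  t <- runif(1e4); f <- runif(1e4, 0, 0.99); r <- runif(1e4)
  expect_lt(max(abs(correctBeta(mixBeta(t, f, r), f, r) - t)), 1e-12)
})

test_that("estimated f recovers truth on the default cohort", {
  co <- defaultCohort()
  tr <- cohortTruth(co)$samples
  est <- estimateLymphocyteFraction(betaSet(co))
  f <- est$f[match(tr$sample_id, est$sample_id)]
  expect_lt(sqrt(mean((f - tr$true_lymph_fraction)^2)), 0.05)
  expect_lte(cor(f, tr$true_purity), -0.90)
})

test_that("density summaries recover the modal structure of methylomes", {
  set.seed(8)
  soma <- c(rbeta(1500, 0.5, 12), rbeta(1500, 12, 0.8))
  d <- densitySummary(soma)
  expect_equal(d$n_modes, 2)
  expect_lt(d$peak_positions[1], 0.15)
  expect_gt(d$peak_positions[2], 0.7)

  flat <- densitySummary(rep(0, 600))
  expect_equal(flat$n_modes, 1)
  expect_equal(flat$peak_positions, 0)
  expect_equal(flat$mass_above, 0)
  expect_error(densitySummary(runif(100)), ">= 500")
})

test_that("residual methylation counts recurrently methylated probes", {
  z <- matrix(0, 5000, 4, dimnames = list(sprintf("p%04d", 1:5000),
                                          sprintf("s%d", 1:4)))
  expect_equal(residualMethylationFraction(z), 0)
  z[1:50, ] <- 0.8
  expect_equal(residualMethylationFraction(z), 0.01)
  expect_error(residualMethylationFraction(z[, 1, drop = FALSE]),
               "2 samples")
})

test_that("CpH score recovers the embryonal-carcinoma archetype", {
  co <- defaultCohort()
  est <- estimateLymphocyteFraction(betaSet(co))
  sc <- cphScore(betaSet(co), est)
  meta <- sampleMeta(co)
  tr <- cohortTruth(co)$samples
  pureEC <- meta$sample_id[meta$histology == "EC"]
  expect_equal(mean(sc$cph_score[sc$sample_id %in% pureEC]), 0.25,
               tolerance = 0.03)
  sem <- meta$sample_id[meta$histology == "seminoma"]
  expect_lt(max(sc$cph_score[sc$sample_id %in% sem]), 0.05)
  expect_gte(cor(sc$cph_score, tr$ec_fraction[match(sc$sample_id,
                                                    tr$sample_id)]), 0.8)
})

test_that("imprinting states use the erased/biparental/methylated bands", {
  nDmr <- 5
  means <- c(0.02, 0.5, 0.8, 0.2, 0.3)
  b <- matrix(rep(means, each = nDmr), nrow = nDmr * length(means))
  rownames(b) <- sprintf("p%02d", seq_len(nrow(b)))
  colnames(b) <- "s1"
  pr <- makeProbes(rownames(b),
                   imprinted_dmr = rep(sprintf("D%d", seq_along(means)),
                                       each = nDmr))
  bs <- BetaSet(b, pr)
  out <- imprintingSurvey(bs, c(s1 = 0), correct = FALSE)
  out <- out[order(out$dmr), ]
  expect_equal(out$state, c("erased", "biparental", "methylated",
                            "erased", "biparental"))
  expect_equal(out$flagged, c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("lymphocyte correction erases the imprinted signal in seminoma", {
  co <- defaultCohort()
  meta <- sampleMeta(co)
  est <- estimateLymphocyteFraction(betaSet(co))
  sem <- meta$sample_id[meta$histology == "seminoma" &
                          cohortTruth(co)$samples$true_lymph_fraction > 0.3]
  raw <- imprintingSurvey(betaSet(co), est, correct = FALSE)
  cor_ <- imprintingSurvey(betaSet(co), est, correct = TRUE)
  rawSem <- raw[raw$sample_id %in% sem, ]
  corSem <- cor_[cor_$sample_id %in% sem, ]
  # before correction the contaminating biparental signal is visible
  expect_gt(mean(rawSem$mean_beta), 0.14)
  # after correction the imprints are erased
  expect_true(all(corSem$state == "erased"))
})

test_that("silencing calls need both promoter methylation and low expression", {
  nSamples <- 20
  pb <- c(0.7, 0.05, 0.7, rep(0.02, nSamples - 3))
  b <- matrix(rep(pb, each = 3), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"),
                              sprintf("s%02d", seq_len(nSamples))))
  bs <- BetaSet(b, makeProbes(rownames(b), region = "active_promoter",
                              promoter_of_gene = "TSG1"))
  expr <- matrix(c(2, 9, 14, 8 + rnorm(nSamples - 3, 0, 0.1)), 1,
                 dimnames = list("TSG1", colnames(b)))
  calls <- callEpigeneticSilencing(bs, expr)
  expect_true(calls$silenced[calls$sample_id == "s01"])   # meth + low expr
  expect_false(calls$silenced[calls$sample_id == "s02"])  # unmethylated
  expect_false(calls$silenced[calls$sample_id == "s03"])  # meth + high expr
})

test_that("genes without unmethylated reference samples are unknown", {
  b <- matrix(0.7, 2, 4, dimnames = list(c("p1", "p2"),
                                         sprintf("s%d", 1:4)))
  bs <- BetaSet(b, makeProbes(rownames(b), region = "active_promoter",
                              promoter_of_gene = "TSG1"))
  expr <- matrix(5, 1, 4, dimnames = list("TSG1", colnames(b)))
  calls <- callEpigeneticSilencing(bs, expr)
  expect_true(all(is.na(calls$silenced)))
})

test_that("planted silencing is recovered with perfect specificity", {
  co <- defaultCohort()
  meta <- sampleMeta(co)
  est <- estimateLymphocyteFraction(betaSet(co))
  corrected <- correctBetaSet(betaSet(co), est)
  calls <- callEpigeneticSilencing(corrected, exprMatrix(co))
  truth <- cohortTruth(co)$silenced
  pure <- meta$sample_id[meta$histology != "mixed"]
  sub <- calls[calls$sample_id %in% pure & !is.na(calls$silenced), ]
  planted <- mapply(function(g, s) truth[g, s], sub$gene, sub$sample_id)
  expect_equal(sub$silenced, unname(planted))
  # silencing is exclusive to NSGCT histologies
  silencedIn <- unique(sub$sample_id[sub$silenced])
  expect_false(any(meta$histology[match(silencedIn,
                                        meta$sample_id)] == "seminoma"))
})
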