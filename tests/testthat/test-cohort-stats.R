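test_that("spectrum fractions count substitution classes and CpG context", {
  muts <- data.frame(
    sample_id = "S1",
    substitution = c(rep("C>T", 4), rep("T>A", 6)),
    context = c("ACG", "TCG", "ACA", "TCT", rep("ATA", 6)),
    stringsAsFactors = FALSE)
  sp <- spectrumProfile(muts)
  expect_equal(sp$fr_C.T, 0.4)
  expect_equal(sp$fr_T.A, 0.6)
  expect_equal(sp$ct_at_cpg_fraction, 0.2)

  one <- spectrumProfile(data.frame(sample_id = "S1", substitution = "T>A",
                                    context = "ATA"))
  expect_equal(one$fr_T.A, 1)
  expect_equal(sum(one[paste0("fr_", c("C.A", "C.G", "C.T", "T.C",
                                       "T.G"))]), 0)

  none <- spectrumProfile(muts, samples = c("S1", "S2"))
  expect_equal(none$n_mutations[none$sample_id == "S2"], 0)
  expect_true(is.na(none$fr_C.T[none$sample_id == "S2"]))
})

test_that("spectrum invariants hold across a simulated cohort", {
  co <- smallCohort(seed = 6, n = 25)
  sp <- spectrumProfile(mutations(co))
  frCols <- grep("^fr_", colnames(sp))
  expect_equal(rowSums(sp[, frCols]), rep(1, nrow(sp)), tolerance = 1e-9)
  expect_true(all(sp$ct_at_cpg_fraction <= sp$fr_C.T + 1e-12))
})

test_that("odds ratio and Wald CI follow the closed form", {
  or <- oddsRatio(contingency2x2(4, 2, 13, 47))
  expect_equal(or$or, 4 * 47 / (2 * 13), tolerance = 1e-12)
  expect_equal(or$ci_low, 1.19, tolerance = 0.01)
  expect_equal(or$ci_high, 44.0, tolerance = 0.01)
  expect_false(or$haldane)
  expect_equal(oddsRatio(contingency2x2(1, 1, 1, 1))$or, 1.0)
  expect_equal(oddsRatio(contingency2x2(2, 1, 1, 2))$or, 4.0)
})

test_that("zero cells trigger Haldane correction or an undefined error", {
  or <- oddsRatio(contingency2x2(0, 5, 5, 5))
  expect_true(or$haldane)
  expect_equal(or$or, (0.5 * 5.5) / (5.5 * 5.5))
  expect_error(oddsRatio(contingency2x2(0, 5, 5, 0)), "undefined")
  expect_error(oddsRatio(contingency2x2(5, 0, 0, 5)), "undefined")
  expect_error(contingency2x2(-1, 1, 1, 1), "non-negative")
})

test_that("odds ratio symmetry: table transposition and row swap", {
  or <- function(a, b, c, d) oddsRatio(contingency2x2(a, b, c, d))$or
  expect_equal(or(4, 2, 13, 47), or(47, 13, 2, 4))       # row+col swap
  expect_equal(or(13, 47, 4, 2), 1 / or(4, 2, 13, 47))   # row swap
})

test_that("Pearson chi-square reproduces hand-computed statistics", {
  cs <- chiSquare2x2(contingency2x2(17, 51, 5, 60))
  expect_equal(cs$statistic, 7.21, tolerance = 0.001)
  expect_lt(cs$p, 0.01)
  expect_equal(chiSquare2x2(contingency2x2(10, 20, 5, 10))$statistic, 0)
  expect_equal(chiSquare2x2(contingency2x2(10, 0, 0, 10))$statistic, 20)
  expect_error(chiSquare2x2(contingency2x2(0, 0, 5, 5)), "margin")
  # continuity-corrected variant is available and smaller
  expect_lt(chiSquare2x2(contingency2x2(17, 51, 5, 60),
                         correct = TRUE)$statistic, 7.21)
})

test_that("cryptorchidism table presets reconstruct the published counts", {
  tabS <- cryptorchidismTable("sample")
  expect_equal(unlist(tabS[c("a", "b", "c", "d")]),
               c(a = 4L, b = 2L, c = 13L, d = 47L))
  tabP <- cryptorchidismTable("patient")
  expect_equal(tabP$d, 49L)
})

test_that("the dual-mutation table can be rebuilt from cohort metadata", {
  meta <- data.frame(
    sample_id = sprintf("S%d", 1:8),
    histology = c(rep("seminoma", 6), "EC", "teratoma"),
    kit_status = c("mutant", "mutant", "wildtype", "wildtype", "mutant",
                   "unknown", "wildtype", "wildtype"),
    ras_status = c("mutant", "wildtype", "mutant", "wildtype", "mutant",
                   "mutant", "wildtype", "wildtype"),
    cryptorchidism = c("yes", "no", "no", "no", "no", "yes", "no", "no"),
    stringsAsFactors = FALSE)
  tab <- dualMutationCryptTable(meta)
  expect_equal(unlist(tab[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 0L, d = 3L))
})

test_that("immune signature scores are medians of centered members", {
  expr <- rbind(g1 = c(1, 2, 3, 10), g2 = c(5, 5, 5, 5),
                g3 = c(0, 0, 4, 4))
  colnames(expr) <- sprintf("s%d", 1:4)
  sc <- immuneSignatureScores(expr, list(solo = "g1", flat = "g2"))
  expect_equal(sc[, "solo"], expr["g1", ] - median(expr["g1", ]))
  expect_equal(unname(sc[, "flat"]), rep(0, 4))
  expect_warning(
    sc2 <- immuneSignatureScores(expr, list(ok = "g1", gone = "zz")),
    "skipped")
  expect_equal(colnames(sc2), "ok")
})

test_that("simulated immune signatures track the lymphocyte fraction", {
  co <- defaultCohort()
  tr <- cohortTruth(co)
  sc <- immuneSignatureScores(exprMatrix(co), tr$immuneSignatures)
  f <- tr$samples$true_lymph_fraction
  for (j in seq_len(ncol(sc)))
    expect_gte(cor(sc[, j], f), 0.9)
})

test_that("group comparisons use exact and approximate Mann-Whitney", {
  same <- groupCompare(c(1, 2, 3, 1, 2, 3),
                       rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  sep <- groupCompare(c(1:5, 11:15), rep(c("a", "b"), each = 5))
  expect_equal(sep$p, 2 / 252, tolerance = 1e-12)
  tt <- groupCompare(c(rnorm(10), rnorm(10, 5)), rep(c("a", "b"), each = 10),
                     test = "t_test")
  expect_lt(tt$p, 1e-4)
  expect_error(groupCompare(1:4, rep("a", 4)), "two groups")
})

test_that("seminoma/NSGCT ploidy separation is detected by rank-sum", {
  co <- defaultCohort()
  meta <- sampleMeta(co)
  cls <- ifelse(meta$histology == "seminoma", "seminoma", "NSGCT")
  res <- groupCompare(meta$ploidy, cls, "mann_whitney")
  expect_lt(res$p, 1e-4)
})

test_that("CpG-transition depletion in KIT-mutant seminoma is detectable", {
  # cohort-scale replicates: the spectrum shift must reject at alpha=0.01
  rejections <- 0L
  nRep <- 40L
  for (r in seq_len(nRep)) {
    co <- generateCohort(simConfig(n_samples = 120, n_probes = 700,
                                   rng_seed = 3000 + r))
    meta <- sampleMeta(co)
    sp <- spectrumProfile(mutations(co), samples = meta$sample_id)
    kitMutSem <- meta$histology == "seminoma" & meta$kit_status == "mutant"
    p <- groupCompare(sp$ct_at_cpg_fraction,
                      ifelse(kitMutSem, "km", "other"))$p
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_gte(rejections / nRep, 0.9)
})

test_that("BH helper matches p.adjust", {
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_equal(bhAdjust(p), p.adjust(p, "BH"))
})
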