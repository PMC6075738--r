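allArms <- function(major, minor, sample = "S1") {
  arms <- names(TGCTools:::.ARM_LENGTHS_MB)
  data.frame(sample_id = sample, arm = arms, major_cn = major,
             minor_cn = minor, stringsAsFactors = FALSE)
}

test_that("WGD count follows the major-allele-fraction rule", {
  w <- inferWGD(allArms(2L, 1L))
  expect_equal(w$wgd_count, 1L)
  expect_equal(w$ploidy, 3.0)
  w <- inferWGD(allArms(1L, 1L))
  expect_equal(w$wgd_count, 0L)
  expect_equal(w$ploidy, 2.0)
  w <- inferWGD(allArms(4L, 2L))
  expect_equal(w$wgd_count, 2L)
  expect_equal(w$fraction_major_ge3, 1.0)
})

test_that("inferWGD requires a minimally covered genome", {
  few <- allArms(2L, 1L)[1:5, ]
  expect_error(inferWGD(few), "at least 10")
  expect_error(inferWGD(allArms(2L, 1L)[0, ]), "")
})

test_that("i(12p) detection needs both excess total and excess major copies", {
  s <- allArms(2L, 2L)
  s[s$arm == "12p", c("major_cn", "minor_cn")] <- c(4L, 2L)
  call <- detectI12p(s)
  expect_true(call$present)
  expect_equal(call$n_12p_copies, 6L)
  expect_equal(call$n_12q_copies, 4L)
  expect_false(call$loh_12q)

  call <- detectI12p(allArms(2L, 2L))
  expect_false(call$present)
  expect_equal(call$n_12p_copies, 4L)

  s <- allArms(2L, 2L)
  s[s$arm == "12p", c("major_cn", "minor_cn")] <- c(3L, 2L)
  s[s$arm == "12q", c("major_cn", "minor_cn")] <- c(3L, 0L)
  call <- detectI12p(s)
  expect_false(call$present)  # more total 12p but no major-haplotype excess
  expect_true(call$loh_12q)

  expect_error(detectI12p(allArms(2L, 2L)[-23, ]), "12p or 12q")
})

test_that("arm events are called relative to rounded ploidy", {
  segs <- data.frame(sample_id = "S1",
                     arm = c("1p", "1q", "2p"),
                     major_cn = c(1L, 2L, 4L), minor_cn = c(1L, 1L, 2L))
  ev <- callArmEvents(segs, ploidy = 3.1)
  expect_equal(ev$direction, c("loss", "neutral", "gain"))
  expect_equal(ev$delta_vs_ploidy, c(-1, 0, 3))
  expect_error(callArmEvents(segs, ploidy = -1), "positive")
})

test_that("timing score ranks a solitary universal event first", {
  # every carrier bears only this one event: freq 1, burden 1, score 0.5
  ev <- data.frame(sample_id = sprintf("S%d", 1:6), arm = "4p",
                   direction = "loss", total_cn = 2L, delta_vs_ploidy = -1)
  groups <- setNames(rep("g", 6), ev$sample_id)
  tab <- orderArmEvents(ev, groups)
  expect_equal(tab$timing_score, 0.5)
  expect_equal(tab$rank, 1L)
})

test_that("event ordering is invariant to sample order and duplication", {
  co <- smallCohort(seed = 21, n = 14)
  ev <- callArmEvents(segments(co))
  groups <- setNames(rep("all", nrow(sampleMeta(co))),
                     sampleMeta(co)$sample_id)
  tab <- orderArmEvents(ev, groups)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(orderArmEvents(shuffled, groups), tab)
  # duplicating the entire cohort changes counts but not freq/score/rank
  ev2 <- ev
  ev2$sample_id <- paste0(ev2$sample_id, "_dup")
  groups2 <- c(groups, setNames(rep("all", length(groups)),
                                paste0(names(groups), "_dup")))
  tab2 <- orderArmEvents(rbind(ev, ev2), groups2)
  expect_equal(tab2$freq, tab$freq)
  expect_equal(tab2$timing_score, tab$timing_score)
  expect_equal(tab2$rank, tab$rank)
})

test_that("small groups are skipped with a warning", {
  ev <- data.frame(sample_id = c("A", "B"), arm = "4p", direction = "loss",
                   total_cn = 2L, delta_vs_ploidy = -1)
  expect_warning(out <- orderArmEvents(ev, c(A = "g", B = "g")),
                 "fewer than")
  expect_equal(nrow(out), 0)
})

test_that("an early ubiquitous event outranks a late high-burden event", {
  # arm A lost in all samples at every aneuploidy level; arm B lost only in
  # high-burden genomes: A must rank earlier in nearly every replicate
  wins <- 0L
  set.seed(2024)
  for (rep in 1:100) {
    n <- 20
    burden <- sample(2:12, n, replace = TRUE)
    rows <- list()
    otherArms <- setdiff(names(TGCTools:::.ARM_LENGTHS_MB), c("4p", "15q"))
    for (i in seq_len(n)) {
      sid <- sprintf("S%02d", i)
      arms <- c("4p", if (burden[i] >= 8) "15q",
                sample(otherArms, max(0, burden[i] - 1 - (burden[i] >= 8))))
      rows[[i]] <- data.frame(sample_id = sid, arm = arms,
                              direction = "loss", total_cn = 2L,
                              delta_vs_ploidy = -1,
                              stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, rows)
    tab <- orderArmEvents(ev, setNames(rep("g", n),
                                       sprintf("S%02d", seq_len(n))))
    rkA <- tab$rank[tab$arm == "4p"]
    rkB <- tab$rank[tab$arm == "15q"]
    if (length(rkB) == 0 || rkA < rkB) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("copy-number calls agree with simulation truth", {
  for (co in list(defaultCohort(), smallCohort(seed = 33, n = 40))) {
    tr <- cohortTruth(co)$samples
    w <- inferWGD(segments(co))
    i <- detectI12p(segments(co))
    expect_equal(w$wgd_count[match(tr$sample_id, w$sample_id)],
                 tr$wgd_count)
    expect_equal(i$present[match(tr$sample_id, i$sample_id)],
                 tr$i12p_present)
    # i(12p)-negative genomes still hold at least 4 copies of 12p
    expect_true(all(i$n_12p_copies[!i$present] >= 4))
  }
})
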