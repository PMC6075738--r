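# Arm-level copy-number inference: WGD count, i(12p), 12q LOH, arm
# gains/losses relative to ploidy, and an early/late timing score for
# recurrent arm events.

.splitBySample <- function(segments) {
  segments <- .validateSegments(as.data.frame(segments))
  if (!nrow(segments)) .stopf("empty segment set")
  split(segments, segments$sample_id)
}

.armWeights <- function(arms) .ARM_LENGTHS_MB[arms]

#' Infer whole-genome doubling count and ploidy from allelic segments
#'
#' A sample is called once-doubled when the genome-length-weighted fraction
#' of arms with major allele copy number at least 2 exceeds 0.5, and
#' twice-doubled when the weighted fraction with major copy number at least
#' 3 also exceeds 0.5 (the standard major-allele-fraction convention).
#' Ploidy is the length-weighted mean total copy number over arms.
#'
#' @param segments data.frame of arm-level allelic segments
#'   (\code{sample_id, arm, major_cn, minor_cn}); one or more samples, at
#'   least 10 arms each.
#' @return data.frame with one row per sample: \code{sample_id, wgd_count,
#'   ploidy, fraction_major_ge2, fraction_major_ge3}.
#' @examples
#' segs <- data.frame(sample_id = "S1",
#'                    arm = c("1p","1q","2p","2q","3p","3q","4p","4q","5p","5q"),
#'                    major_cn = 2L, minor_cn = 1L)
#' inferWGD(segs)  # wgd_count 1, ploidy 3
#' @export
inferWGD <- function(segments) {
  bySample <- .splitBySample(segments)
  out <- lapply(bySample, function(s) {
    if (nrow(s) < 10)
      .stopf("inferWGD: sample '%s' has %d arms; at least 10 required",
             s$sample_id[1], nrow(s))
    w <- .armWeights(s$arm)
    f2 <- sum(w[s$major_cn >= 2]) / sum(w)
    f3 <- sum(w[s$major_cn >= 3]) / sum(w)
    wgd <- if (f2 > 0.5) 1L else 0L
    if (wgd == 1L && f3 > 0.5) wgd <- 2L
    data.frame(sample_id = s$sample_id[1], wgd_count = wgd,
               ploidy = sum(w * (s$major_cn + s$minor_cn)) / sum(w),
               fraction_major_ge2 = f2, fraction_major_ge3 = f3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect isochromosome 12p from allelic copy number
#'
#' i(12p) duplicates the short arm of chromosome 12 on one haplotype; it is
#' called present when 12p carries at least one more total copy AND at
#' least one more major-haplotype copy than 12q. 12q LOH is reported when
#' the 12q minor allele count is zero.
#'
#' @param segments arm-level allelic segment data.frame; every sample must
#'   include both 12p and 12q.
#' @return data.frame per sample: \code{sample_id, present, n_12p_copies,
#'   n_12q_copies, loh_12q}.
#' @examples
#' segs <- data.frame(sample_id = "S1", arm = c("12p", "12q"),
#'                    major_cn = c(4L, 2L), minor_cn = c(2L, 2L))
#' detectI12p(segs)  # present, 6 vs 4 copies
#' @export
detectI12p <- function(segments) {
  bySample <- .splitBySample(segments)
  out <- lapply(bySample, function(s) {
    p <- s[s$arm == "12p", ]; q <- s[s$arm == "12q", ]
    if (nrow(p) != 1 || nrow(q) != 1)
      .stopf("detectI12p: sample '%s' lacks a 12p or 12q segment",
             s$sample_id[1])
    tp <- p$major_cn + p$minor_cn; tq <- q$major_cn + q$minor_cn
    data.frame(sample_id = s$sample_id[1],
               present = (tp - tq >= 1) && (p$major_cn - q$major_cn >= 1),
               n_12p_copies = tp, n_12q_copies = tq,
               loh_12q = q$minor_cn == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call arm-level gains and losses relative to sample ploidy
#'
#' The per-arm total copy number is compared to the rounded sample ploidy:
#' a deviation of at least one copy below is a loss, at least one above a
#' gain, otherwise neutral.
#'
#' @param segments arm-level allelic segment data.frame.
#' @param ploidy sample ploidy: a single value, or a vector named by
#'   sample_id; when \code{NULL} it is computed with [inferWGD()].
#' @return data.frame: \code{sample_id, arm, direction, total_cn,
#'   delta_vs_ploidy}.
#' @export
callArmEvents <- function(segments, ploidy = NULL) {
  segments <- .validateSegments(as.data.frame(segments))
  if (is.null(ploidy)) {
    wg <- inferWGD(segments)
    ploidy <- stats::setNames(wg$ploidy, wg$sample_id)
  }
  if (is.null(names(ploidy))) {
    if (length(ploidy) != 1)
      .stopf("callArmEvents: unnamed ploidy must be a single value")
    ploidy <- stats::setNames(rep(ploidy, length(unique(segments$sample_id))),
                              unique(segments$sample_id))
  }
  if (any(ploidy <= 0)) .stopf("callArmEvents: ploidy must be positive")
  pl <- ploidy[segments$sample_id]
  if (anyNA(pl)) .stopf("callArmEvents: ploidy missing for some samples")
  total <- segments$major_cn + segments$minor_cn
  delta <- total - round(pl)
  direction <- ifelse(delta <= -1, "loss", ifelse(delta >= 1, "gain",
                                                  "neutral"))
  data.frame(sample_id = segments$sample_id, arm = segments$arm,
             direction = direction, total_cn = total,
             delta_vs_ploidy = as.numeric(delta), stringsAsFactors = FALSE)
}

#' Rank arm events as early or late within sample groups
#'
#' Concrete instantiation of the frequency-plus-aneuploidy heuristic for
#' ordering arm-level events: recurrent events found across samples with
#' little other aneuploidy are inferred early; events confined to
#' high-burden genomes are inferred late. For event e in group g,
#' \code{freq(e)} is the carrier fraction, \code{burden(e)} the median over
#' carriers of the carrier's total non-neutral arm count, and
#' \code{timing_score = freq / (1 + burden)}; events are ranked per group by
#' descending score (rank 1 = inferred earliest). Ties break by higher
#' frequency, then arm name. The statistic is isolated behind this one
#' function so an alternative ordering model can be swapped in.
#'
#' @param events arm-event data.frame from [callArmEvents()].
#' @param groups group label per sample: a vector named by sample_id.
#' @param minGroup minimum samples per group (smaller groups are skipped
#'   with a warning).
#' @return data.frame: \code{group, arm, direction, n_carriers, freq,
#'   median_burden, timing_score, rank}, ranked within group.
#' @export
orderArmEvents <- function(events, groups, minGroup = 5L) {
  events <- as.data.frame(events)
  if (is.null(names(groups)))
    .stopf("orderArmEvents: 'groups' must be named by sample_id")
  out <- list()
  samples <- unique(events$sample_id)
  burden <- vapply(split(events$direction != "neutral", events$sample_id),
                   sum, numeric(1))
  for (g in sort(unique(groups[samples]))) {
    gs <- samples[groups[samples] == g]
    if (length(gs) < minGroup) {
      warning(sprintf("group '%s' has fewer than %d samples; skipped",
                      g, minGroup))
      next
    }
    ev <- events[events$sample_id %in% gs & events$direction != "neutral", ]
    if (!nrow(ev)) next
    key <- paste(ev$arm, ev$direction)
    tab <- lapply(split(ev, key), function(e) {
      data.frame(group = g, arm = e$arm[1], direction = e$direction[1],
                 n_carriers = nrow(e), freq = nrow(e) / length(gs),
                 median_burden = stats::median(burden[e$sample_id]),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tab)
    tab$timing_score <- tab$freq / (1 + tab$median_burden)
    ord <- order(-tab$timing_score, -tab$freq, tab$arm, tab$direction)
    tab <- tab[ord, ]
    tab$rank <- seq_len(nrow(tab))
    out[[g]] <- tab
  }
  if (!length(out))
    return(data.frame(group = character(), arm = character(),
                      direction = character(), n_carriers = integer(),
                      freq = numeric(), median_burden = numeric(),
                      timing_score = numeric(), rank = integer()))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
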