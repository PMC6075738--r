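# Two-component methylation deconvolution. Bulk seminoma methylation is
# modeled as a mixture of an (almost) unmethylated tumor component and
# infiltrating lymphocytes; the lymphocyte fraction f is estimated from
# cell-type signature probes (LUMP-style ratio of means) and subtracted
# from every probe.

#' Estimate the infiltrating-lymphocyte fraction per sample
#'
#' Ratio-of-means estimator over the lymphocyte signature probes:
#' \code{f = clip(mean(beta at signature probes) /
#' mean(lymphocyte_ref_beta), 0, 1)}. The signature probes are methylated
#' in lymphocytes and unmethylated in tumor, so the observed mean scales
#' linearly with the lymphocyte content. Probes with missing beta are
#' skipped per sample.
#'
#' @param bs a \linkS4class{BetaSet}; at least 20 usable signature probes
#'   are required per sample.
#' @return data.frame: \code{sample_id, f, n_probes_used}.
#' @export
estimateLymphocyteFraction <- function(bs) {
  stopifnot(is(bs, "BetaSet"))
  rd <- probeInfo(bs)
  sig <- which(rd$lymphocyte_signature)
  if (length(sig) < 20)
    .stopf("estimation error: %d signature probes annotated; >= 20 required",
           length(sig))
  b <- betaValues(bs)[sig, , drop = FALSE]
  ref <- rd$lymphocyte_ref_beta[sig]
  out <- lapply(seq_len(ncol(b)), function(j) {
    use <- !is.na(b[, j])
    if (sum(use) < 20)
      .stopf("estimation error: sample '%s' has %d usable signature probes",
             colnames(b)[j], sum(use))
    f <- .clip01(mean(b[use, j]) / mean(ref[use]))
    data.frame(sample_id = colnames(b)[j], f = f,
               n_probes_used = sum(use), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correct beta values for lymphocyte contamination
#'
#' Exact inverse of the two-component mixture [mixBeta()] before clipping:
#' \code{clip((beta_obs - f * ref_beta) / (1 - f), 0, 1)}. Negative mass
#' before clipping diagnoses an overestimated f.
#'
#' @param beta_obs observed beta value(s) in [0, 1].
#' @param f lymphocyte fraction in [0, 1); \code{f = 1} leaves no tumor
#'   signal and is a domain error.
#' @param ref_beta lymphocyte reference beta value(s) in [0, 1].
#' @return corrected beta value(s), clipped to [0, 1].
#' @examples
#' correctBeta(0.5, 0.5, 1.0)  # 0
#' correctBeta(0.6, 0.4, 0.9)  # 0.4
#' @export
correctBeta <- function(beta_obs, f, ref_beta) {
  .assertScalarIn(beta_obs, 0, 1, "beta_obs")
  .assertScalarIn(ref_beta, 0, 1, "ref_beta")
  if (!is.numeric(f) || anyNA(f) || any(f < 0) || any(f >= 1))
    .stopf("'f' must lie in [0, 1): f = 1 leaves no tumor signal")
  .clip01((beta_obs - f * ref_beta) / (1 - f))
}

#' Correct every probe of a BetaSet
#'
#' Applies [correctBeta()] columnwise with the per-probe
#' \code{lymphocyte_ref_beta} from the annotation (CpH probes carry a
#' reference of 0: lymphocytes have no CpH methylation).
#'
#' @param bs a \linkS4class{BetaSet}.
#' @param f lymphocyte fractions: named vector by sample_id, or the
#'   data.frame from [estimateLymphocyteFraction()].
#' @return a \linkS4class{BetaSet} of corrected beta values.
#' @export
correctBetaSet <- function(bs, f) {
  stopifnot(is(bs, "BetaSet"))
  if (is.data.frame(f)) f <- stats::setNames(f$f, f$sample_id)
  f <- f[colnames(bs)]
  if (anyNA(f)) .stopf("lymphocyte fraction missing for some samples")
  ref <- probeInfo(bs)$lymphocyte_ref_beta
  ref[is.na(ref)] <- 0
  b <- betaValues(bs)
  corrected <- .clip01(sweep(b - outer(ref, f), 2, 1 - f, `/`))
  BetaSet(corrected, probeInfo(bs))
}

#' Summarize the density of beta values
#'
#' Kernel density on [0, 1] with boundary reflection (the sample is
#' augmented with its reflections at 0 and 1, the density evaluated inside
#' the unit interval and rescaled), Gaussian kernel with bandwidth 0.03 by
#' default. Modes are local maxima with topographic prominence at least
#' \code{prominence} of the maximum density, which suppresses noise
#' ripples.
#'
#' @param values beta values (missing values dropped); at least 500
#'   required.
#' @param bw kernel bandwidth on the beta scale.
#' @param prominence minimum relative prominence of a reported mode.
#' @param massThreshold threshold for the reported mass above (default
#'   0.3, the methylated-call boundary used throughout the package).
#' @return list: \code{peak_positions} (ascending), \code{n_modes},
#'   \code{mass_above} and \code{n}.
#' @export
densitySummary <- function(values, bw = 0.03, prominence = 0.05,
                           massThreshold = 0.3) {
  values <- values[!is.na(values)]
  if (length(values) < 500)
    .stopf("estimation error: %d values; >= 500 required for density",
           length(values))
  .assertScalarIn(values, 0, 1, "values")
  aug <- c(-values, values, 2 - values)
  d <- stats::density(aug, bw = bw, from = 0, to = 1, n = 512)
  y <- 3 * d$y  # reflection triples the mass; renormalize to [0,1]
  x <- d$x
  npt <- length(y)
  # local maxima including the boundaries
  isMax <- c(y[1] > y[2],
             y[2:(npt - 1)] >= y[1:(npt - 2)] & y[2:(npt - 1)] > y[3:npt],
             y[npt] > y[npt - 1])
  cand <- which(isMax)
  # topographic prominence: height minus the highest saddle separating the
  # peak from any higher ground
  prom <- vapply(cand, function(i) {
    h <- y[i]
    saddleL <- -Inf
    left <- which(y[seq_len(i - 1)] > h)
    saddleL <- if (length(left)) min(y[max(left):i]) else min(y[1:i])
    right <- which(y[(i + 1):npt] > h)
    saddleR <- if (length(right)) min(y[i:(i + min(right))]) else
      min(y[i:npt])
    if (!length(left) && !length(right)) return(h)  # global max
    h - max(saddleL[length(left) > 0], saddleR[length(right) > 0],
            -Inf, na.rm = TRUE)
  }, numeric(1))
  keep <- cand[prom >= prominence * max(y)]
  peaks <- sort(x[keep])
  list(peak_positions = peaks, n_modes = length(peaks),
       mass_above = mean(values > massThreshold), n = length(values))
}

#' Fraction of probes recurrently methylated after correction
#'
#' A probe counts as recurrently methylated when its corrected beta is at
#' least \code{betaThreshold} in at least a \code{recurrence} fraction of
#' the samples. Applied to corrected seminoma matrices this measures the
#' residual methylation left after removing the lymphocyte contribution.
#'
#' @param correctedBeta corrected beta matrix (probes x samples) or a
#'   corrected \linkS4class{BetaSet}; at least 2 samples.
#' @param betaThreshold methylated-call threshold (default 0.3).
#' @param recurrence minimum fraction of samples (default 0.10).
#' @return fraction of probes recurrently methylated.
#' @export
residualMethylationFraction <- function(correctedBeta, betaThreshold = 0.3,
                                        recurrence = 0.10) {
  if (is(correctedBeta, "BetaSet")) correctedBeta <- betaValues(correctedBeta)
  if (ncol(correctedBeta) < 2)
    .stopf("at least 2 samples required for a recurrence fraction")
  frac <- rowMeans(correctedBeta >= betaThreshold, na.rm = TRUE)
  mean(frac >= recurrence)
}

#' Per-sample mean CpH methylation after lymphocyte correction
#'
#' Lymphocytes carry no CpH methylation, so the CpH reference is 0 and the
#' correction reduces to \code{beta_obs / (1 - f)}. The mean corrected CpH
#' beta tracks the embryonal-carcinoma content of a tumor (CpH methylation
#' is an embryonic-stem-cell hallmark re-established in EC).
#'
#' @param bs a \linkS4class{BetaSet} with at least 50 CpH probes.
#' @param f lymphocyte fractions (named vector or the data.frame from
#'   [estimateLymphocyteFraction()]).
#' @return data.frame: \code{sample_id, cph_score, n_probes}.
#' @export
cphScore <- function(bs, f) {
  stopifnot(is(bs, "BetaSet"))
  if (is.data.frame(f)) f <- stats::setNames(f$f, f$sample_id)
  rd <- probeInfo(bs)
  cph <- which(rd$context == "CpH")
  if (length(cph) < 50)
    .stopf("estimation error: %d CpH probes; >= 50 required", length(cph))
  f <- f[colnames(bs)]
  if (anyNA(f) || any(f >= 1))
    .stopf("valid lymphocyte fraction (< 1) required for every sample")
  b <- betaValues(bs)[cph, , drop = FALSE]
  score <- vapply(seq_len(ncol(b)), function(j) {
    mean(.clip01(b[, j] / (1 - f[j])), na.rm = TRUE)
  }, numeric(1))
  data.frame(sample_id = colnames(b), cph_score = score,
             n_probes = length(cph), stringsAsFactors = FALSE)
}

#' Survey imprinted DMR methylation states
#'
#' Imprinted differentially methylated regions carry parent-of-origin
#' methylation near 0.5 in soma; germ cell tumors largely erase it. Per
#' (sample, DMR) the mean corrected beta is classified: \code{erased}
#' below 0.15, \code{biparental} in [0.35, 0.65], \code{methylated} above
#' 0.65; values in between are assigned the nearest state and flagged.
#'
#' @param bs a \linkS4class{BetaSet} with at least one annotated imprinted
#'   DMR.
#' @param f lymphocyte fractions (named vector or data.frame).
#' @param correct correct for lymphocyte contamination first (default
#'   TRUE; lymphocytes are biparentally imprinted, reference 0.5).
#' @return data.frame: \code{sample_id, dmr, mean_beta, state, flagged}.
#' @export
imprintingSurvey <- function(bs, f, correct = TRUE) {
  stopifnot(is(bs, "BetaSet"))
  rd <- probeInfo(bs)
  if (!any(!is.na(rd$imprinted_dmr)))
    .stopf("no imprinted DMR annotated")
  use <- if (correct) correctBetaSet(bs, f) else bs
  b <- betaValues(use)
  out <- list()
  for (d in unique(stats::na.omit(rd$imprinted_dmr))) {
    rows <- which(rd$imprinted_dmr == d)
    mb <- colMeans(b[rows, , drop = FALSE], na.rm = TRUE)
    state <- ifelse(mb < 0.15, "erased",
                    ifelse(mb <= 0.65 & mb >= 0.35, "biparental",
                           ifelse(mb > 0.65, "methylated",
                                  ifelse(mb < 0.25, "erased", "biparental"))))
    flagged <- mb >= 0.15 & mb < 0.35
    out[[d]] <- data.frame(sample_id = names(mb), dmr = d, mean_beta = mb,
                           state = state, flagged = flagged,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call promoter epigenetic silencing against expression
#'
#' A gene is silenced in a sample when its mean corrected promoter beta is
#' at least \code{betaThreshold} AND its expression is at or below the
#' \code{exprQuantile} quantile of the unmethylated reference samples
#' (promoter beta below \code{refBetaMax}) for that gene. Genes with no
#' unmethylated reference samples are reported as \code{NA} (unknown).
#'
#' @param correctedBs corrected \linkS4class{BetaSet} (see
#'   [correctBetaSet()]).
#' @param expr log2 expression matrix, genes x samples.
#' @param genes genes to call; default every gene with annotated promoter
#'   probes.
#' @param betaThreshold methylated-promoter threshold (default 0.3).
#' @param refBetaMax unmethylated-reference threshold (default 0.1).
#' @param exprQuantile expression quantile of the reference samples
#'   (default 0.25).
#' @return data.frame: \code{sample_id, gene, promoter_beta_corrected,
#'   expression_log2, silenced} (logical, \code{NA} = unknown).
#' @export
callEpigeneticSilencing <- function(correctedBs, expr, genes = NULL,
                                    betaThreshold = 0.3, refBetaMax = 0.1,
                                    exprQuantile = 0.25) {
  stopifnot(is(correctedBs, "BetaSet"))
  rd <- probeInfo(correctedBs)
  genes <- genes %||% unique(stats::na.omit(rd$promoter_of_gene))
  if (!length(genes)) .stopf("no promoter-annotated genes to call")
  b <- betaValues(correctedBs)
  sharedSamples <- intersect(colnames(b), colnames(expr))
  if (!length(sharedSamples))
    .stopf("no samples shared between beta and expression")
  out <- list()
  for (g in genes) {
    rows <- which(rd$promoter_of_gene == g)
    if (!length(rows))
      .stopf("gene '%s' has no annotated promoter probes", g)
    if (!g %in% rownames(expr))
      .stopf("gene '%s' absent from expression matrix", g)
    pb <- colMeans(b[rows, sharedSamples, drop = FALSE], na.rm = TRUE)
    ex <- expr[g, sharedSamples]
    refSamples <- names(pb)[pb < refBetaMax]
    if (length(refSamples)) {
      cut <- stats::quantile(ex[refSamples], exprQuantile, names = FALSE)
      silencedFlag <- pb >= betaThreshold & ex <= cut
    } else {
      silencedFlag <- rep(NA, length(pb))
    }
    out[[g]] <- data.frame(sample_id = sharedSamples, gene = g,
                           promoter_beta_corrected = as.numeric(pb),
                           expression_log2 = as.numeric(ex),
                           silenced = silencedFlag,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
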