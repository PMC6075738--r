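# Mutation multiplicity and clonal timing. The multiplicity s_q is the
# inferred number of mutated allele copies per tumor cell, computed from the
# tumor variant allele fraction (TVAF), the local total copy number and the
# tumor purity. Rounded multiplicities time mutations relative to
# whole-genome doubling (a mutation present on >= 2 copies predates the
# doubling that duplicated it) and, on 12p, relative to i(12p) formation.

#' Mutation multiplicity from TVAF, copy number and purity
#'
#' \deqn{s_q = TVAF \cdot (CN \cdot purity + 2 (1 - purity)) / purity}
#'
#' @param tvaf tumor variant allele fraction in [0, 1].
#' @param total_cn local total (major + minor) integer copy number, >= 1.
#' @param purity tumor purity in (0, 1].
#' @return s_q (vectorized).
#' @examples
#' computeMultiplicity(0.5, 2, 1.0)   # 1
#' computeMultiplicity(0.25, 4, 0.5)  # 1.5
#' @export
computeMultiplicity <- function(tvaf, total_cn, purity) {
  .assertScalarIn(tvaf, 0, 1, "tvaf")
  if (!is.numeric(purity) || anyNA(purity) || any(purity <= 0 | purity > 1))
    .stopf("'purity' must lie in (0, 1]")
  if (!is.numeric(total_cn) || anyNA(total_cn) || any(total_cn < 1))
    .stopf("'total_cn' must be a positive copy number")
  tvaf * (total_cn * purity + 2 * (1 - purity)) / purity
}

#' Expected TVAF of a clonal mutation at multiplicity m
#'
#' Inverse of [computeMultiplicity()]:
#' \code{m * purity / (CN * purity + 2 (1 - purity))}. Used by the
#' simulator and as the oracle in round-trip tests.
#'
#' @param m mutated allele copies per tumor cell (\code{m <= total_cn}).
#' @param total_cn local total integer copy number.
#' @param purity tumor purity in (0, 1].
#' @return expected TVAF (vectorized).
#' @examples
#' expectedTvaf(1, 2, 1.0)  # 0.5
#' expectedTvaf(2, 4, 0.5)  # 1/3
#' @export
expectedTvaf <- function(m, total_cn, purity) {
  if (!is.numeric(purity) || anyNA(purity) || any(purity <= 0 | purity > 1))
    .stopf("'purity' must lie in (0, 1]")
  if (!is.numeric(total_cn) || anyNA(total_cn) || any(total_cn < 1))
    .stopf("'total_cn' must be a positive copy number")
  if (any(m < 0) || any(m > total_cn))
    .stopf("'m' must satisfy 0 <= m <= total_cn")
  m * purity / (total_cn * purity + 2 * (1 - purity))
}

#' Classify a mutation's timing relative to whole-genome doubling
#'
#' The multiplicity is rounded to the nearest integer m*; values further
#' than \code{tol} from an integer abstain as \code{"ambiguous"}. In a
#' doubled genome, m* >= 2 (and consistent with the major allele count)
#' implies the mutation predates the doubling; m* = 1 implies it arose
#' after. Samples without WGD return \code{"na"}.
#'
#' @param s_q multiplicity from [computeMultiplicity()].
#' @param major_cn major allele copy number at the locus (used as the upper
#'   bound for a consistent multiplicity; \code{NA} skips the bound).
#' @param minor_cn minor allele copy number (currently unused by the rule;
#'   kept for interface completeness).
#' @param wgd_count number of whole-genome doublings (0, 1 or 2).
#' @param tol rounding tolerance for calling an integer multiplicity
#'   (default 0.35).
#' @return character vector over \code{before_wgd, after_wgd, ambiguous,
#'   na}.
#' @examples
#' classifyVsWGD(2.05, 2, 2, 1)  # before_wgd
#' classifyVsWGD(1.0,  2, 2, 1)  # after_wgd
#' classifyVsWGD(1.6,  2, 2, 1)  # ambiguous
#' @export
classifyVsWGD <- function(s_q, major_cn, minor_cn = NA_integer_,
                          wgd_count, tol = 0.35) {
  if (any(wgd_count < 0, na.rm = TRUE))
    .stopf("'wgd_count' must be non-negative")
  nn <- max(length(s_q), length(major_cn), length(wgd_count))
  s_q <- rep_len(s_q, nn); major_cn <- rep_len(major_cn, nn)
  wgd_count <- rep_len(wgd_count, nn)
  m <- round(s_q)
  out <- rep("ambiguous", nn)
  out[abs(s_q - m) <= tol & m == 1] <- "after_wgd"
  before <- abs(s_q - m) <= tol & m >= 2 &
    (is.na(major_cn) | m <= major_cn)
  out[before] <- "before_wgd"
  out[wgd_count == 0] <- "na"
  out[is.na(s_q)] <- "na"
  out
}

#' Classify a 12p mutation's timing relative to i(12p) formation
#'
#' Only meaningful for mutations on 12p in samples carrying i(12p): the
#' isochromosome duplicates the arm, so a mutation already present on the
#' duplicated haplotype is amplified to multiplicity >= 2, while one
#' arising afterwards stays at multiplicity 1 on either allele.
#'
#' @param s_q multiplicity.
#' @param i12p_present logical; i(12p) call for the sample (see
#'   [detectI12p()]).
#' @param arm the mutation's arm; must be \code{"12p"}.
#' @param tol rounding tolerance (non-integer multiplicities return
#'   \code{"na"}).
#' @return character vector over \code{before_or_during, after, na}.
#' @examples
#' classifyVsI12p(1.02, TRUE)  # after
#' classifyVsI12p(3.9, TRUE)   # before_or_during
#' @export
classifyVsI12p <- function(s_q, i12p_present, arm = "12p", tol = 0.35) {
  if (any(arm != "12p"))
    .stopf("classifyVsI12p applies only to mutations on 12p")
  nn <- max(length(s_q), length(i12p_present))
  s_q <- rep_len(s_q, nn); i12p_present <- rep_len(i12p_present, nn)
  m <- round(s_q)
  out <- rep("na", nn)
  ok <- i12p_present & !is.na(s_q) & abs(s_q - m) <= tol
  out[ok & m <= 1] <- "after"
  out[ok & m >= 2] <- "before_or_during"
  out
}

#' Assess clonality from cancer cell fraction and DNA/RNA VAF concordance
#'
#' The cancer cell fraction (CCF) is \code{s_q / max(1, round(s_q))} capped
#' at 1. A mutation is \code{clonal} when CCF >= \code{ccfThreshold} and
#' any available RNA VAF agrees with the DNA VAF within \code{rnaTol};
#' \code{subclonal} when the CCF is below threshold and the binomial
#' confidence interval of the VAF (Clopper-Pearson at the observed depth)
#' excludes the threshold; \code{unknown} otherwise (e.g. underpowered
#' depth).
#'
#' @param tvaf_dna DNA variant allele fraction.
#' @param rna_vaf RNA variant allele fraction or \code{NA}.
#' @param depth total read depth (alt + ref), > 0.
#' @param total_cn,purity passed to [computeMultiplicity()].
#' @param ccfThreshold clonality threshold on CCF (default 0.8).
#' @param rnaTol maximum |RNA - DNA| VAF difference for clonal support.
#' @return character vector over \code{clonal, subclonal, unknown}.
#' @export
assessClonality <- function(tvaf_dna, rna_vaf, depth, total_cn, purity,
                            ccfThreshold = 0.8, rnaTol = 0.2) {
  nn <- max(length(tvaf_dna), length(depth), length(total_cn),
            length(purity))
  tvaf_dna <- rep_len(tvaf_dna, nn); rna_vaf <- rep_len(rna_vaf, nn)
  depth <- rep_len(depth, nn); total_cn <- rep_len(total_cn, nn)
  purity <- rep_len(purity, nn)
  if (any(depth <= 0)) .stopf("'depth' must be positive")
  out <- character(nn)
  for (i in seq_len(nn)) {
    sq <- computeMultiplicity(tvaf_dna[i], total_cn[i], purity[i])
    mstar <- max(1, round(sq))
    ccf <- min(sq / mstar, 1)
    rnaOk <- is.na(rna_vaf[i]) || abs(rna_vaf[i] - tvaf_dna[i]) <= rnaTol
    if (ccf >= ccfThreshold && rnaOk) {
      out[i] <- "clonal"
    } else if (ccf < ccfThreshold) {
      alt <- round(tvaf_dna[i] * depth[i])
      ci <- stats::binom.test(alt, depth[i])$conf.int
      sqHi <- computeMultiplicity(ci[2], total_cn[i], purity[i])
      ccfHi <- min(sqHi / mstar, 1)
      out[i] <- if (ccfHi < ccfThreshold) "subclonal" else "unknown"
    } else {
      out[i] <- "unknown"
    }
  }
  out
}

#' Time all mutations of a cohort
#'
#' Joins mutations with the sample's arm-level copy number and purity, then
#' computes s_q, the timing classes relative to WGD and (for 12p mutations
#' in i(12p) carriers) relative to i(12p) formation, and the clonality
#' flag. Samples with purity below \code{minPurity} (or missing purity) are
#' excluded from inference and reported with \code{s_q = NA} and classes
#' \code{"na"}/\code{"unknown"}, mirroring the exclusion of low-purity
#' tumors from copy-number-based inference.
#'
#' @param mutations mutation data.frame ([readMutations()] format).
#' @param segs arm-level allelic segment data.frame.
#' @param meta sample metadata with \code{sample_id} and \code{purity}.
#' @param minPurity minimum purity for timing inference (default 0.3).
#' @param tol rounding tolerance for integer multiplicities.
#' @return data.frame of multiplicity calls: \code{sample_id, gene, arm,
#'   s_q, nearest_integer_m, timing_vs_wgd, timing_vs_i12p, clonal}.
#' @export
timeMutations <- function(mutations, segs, meta, minPurity = 0.3,
                          tol = 0.35) {
  mutations <- .validateMutations(as.data.frame(mutations))
  segs <- .validateSegments(as.data.frame(segs))
  meta <- as.data.frame(meta)
  wgdCalls <- inferWGD(segs)
  i12pCalls <- detectI12p(segs)
  segKey <- paste(segs$sample_id, segs$arm)
  idx <- match(paste(mutations$sample_id, mutations$arm), segKey)
  if (anyNA(idx))
    .stopf("timeMutations: no segment for mutation %d (%s %s)",
           which(is.na(idx))[1], mutations$sample_id[which(is.na(idx))[1]],
           mutations$arm[which(is.na(idx))[1]])
  totalCN <- segs$major_cn[idx] + segs$minor_cn[idx]
  majorCN <- segs$major_cn[idx]
  purity <- meta$purity[match(mutations$sample_id, meta$sample_id)]
  wgd <- wgdCalls$wgd_count[match(mutations$sample_id, wgdCalls$sample_id)]
  i12p <- i12pCalls$present[match(mutations$sample_id,
                                  i12pCalls$sample_id)]
  usable <- !is.na(purity) & purity >= minPurity
  sq <- rep(NA_real_, nrow(mutations))
  sq[usable] <- computeMultiplicity(mutations$tvaf[usable],
                                    pmax(1, totalCN[usable]),
                                    purity[usable])
  vsWgd <- rep("na", nrow(mutations))
  vsWgd[usable] <- classifyVsWGD(sq[usable], majorCN[usable],
                                 wgd_count = wgd[usable], tol = tol)
  vsI12p <- rep("na", nrow(mutations))
  on12p <- usable & mutations$arm == "12p"
  if (any(on12p))
    vsI12p[on12p] <- classifyVsI12p(sq[on12p], i12p[on12p], tol = tol)
  clonal <- rep("unknown", nrow(mutations))
  depth <- mutations$alt_count + mutations$ref_count
  ok <- usable & depth > 0
  if (any(ok))
    clonal[ok] <- assessClonality(mutations$tvaf[ok], mutations$rna_vaf[ok],
                                  depth[ok], pmax(1, totalCN[ok]),
                                  purity[ok])
  data.frame(sample_id = mutations$sample_id, gene = mutations$gene,
             arm = mutations$arm, s_q = sq,
             nearest_integer_m = as.integer(round(sq)),
             timing_vs_wgd = vsWgd, timing_vs_i12p = vsI12p,
             clonal = clonal, stringsAsFactors = FALSE)
}
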