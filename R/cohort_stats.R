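# Cohort-level statistics: mutation spectrum fractions, 2x2 association
# measures, immune signature scores, and two-group comparisons.

#' Per-sample mutation spectrum profile
#'
#' Fractions of the six pyrimidine-centred substitution classes, plus the
#' fraction of all mutations that are C>T transitions at CpG dinucleotides
#' (central C with a 3' G in the trinucleotide context) -- the
#' 5-methylcytosine deamination channel (COSMIC signature 1).
#'
#' @param muts mutation data.frame with \code{sample_id, substitution,
#'   context}.
#' @param samples sample ids to profile; defaults to the samples present in
#'   \code{muts}. Samples with zero mutations get count 0 and \code{NA}
#'   fractions.
#' @return data.frame: \code{sample_id, n_mutations}, one fraction column
#'   per substitution class (\code{fr_C.A} ... \code{fr_T.G}) and
#'   \code{ct_at_cpg_fraction}.
#' @export
spectrumProfile <- function(muts, samples = NULL) {
  muts <- as.data.frame(muts)
  samples <- samples %||% unique(muts$sample_id)
  frNames <- paste0("fr_", sub(">", ".", .SUBSTITUTIONS))
  bySample <- split(muts, factor(muts$sample_id, levels = samples))
  out <- lapply(samples, function(sid) {
    m <- bySample[[sid]]
    n <- nrow(m)
    row <- data.frame(sample_id = sid, n_mutations = n,
                      stringsAsFactors = FALSE)
    if (n == 0) {
      row[frNames] <- NA_real_
      row$ct_at_cpg_fraction <- NA_real_
    } else {
      counts <- table(factor(m$substitution, levels = .SUBSTITUTIONS))
      row[frNames] <- as.numeric(counts) / n
      row$ct_at_cpg_fraction <-
        mean(m$substitution == "C>T" & substr(m$context, 3, 3) == "G")
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' 2x2 contingency table constructor
#'
#' Layout: rows = exposure (exposed first), columns = outcome (positive
#' first), so \code{a} = exposed & positive, \code{b} = exposed & negative,
#' \code{c} = unexposed & positive, \code{d} = unexposed & negative.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return a named list of class \code{ContingencyTable2x2}.
#' @export
contingency2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells)))
    .stopf("cells must be non-negative integers")
  if (sum(cells) == 0) .stopf("table total must be positive")
  cells <- stats::setNames(as.integer(round(cells)), names(cells))
  structure(as.list(cells), class = "ContingencyTable2x2")
}

#' Sample odds ratio with Wald confidence interval
#'
#' \code{OR = ad / bc}; 95 percent Wald CI
#' \code{exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))}. If any single
#' cell is zero the Haldane-Anscombe 0.5 correction is added to every cell
#' (flagged in the output); two zero cells in a cross pattern leave the OR
#' undefined and raise an error.
#'
#' @param table a \code{ContingencyTable2x2} from [contingency2x2()].
#' @param conf confidence level (default 0.95).
#' @return list: \code{or, ci_low, ci_high, haldane}.
#' @examples
#' oddsRatio(contingency2x2(4, 2, 13, 47))  # about 7.23 [1.19, 44.0]
#' @export
oddsRatio <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "ContingencyTable2x2"))
  x <- unlist(table[c("a", "b", "c", "d")])
  if ((x["a"] == 0 && x["d"] == 0) || (x["b"] == 0 && x["c"] == 0))
    .stopf("odds ratio undefined: two zero cells in a cross pattern")
  haldane <- any(x == 0)
  if (haldane) x <- x + 0.5
  or <- (x["a"] * x["d"]) / (x["b"] * x["c"])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(sum(1 / x))
  list(or = unname(or), ci_low = unname(exp(log(or) - z * se)),
       ci_high = unname(exp(log(or) + z * se)), haldane = haldane)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected by default; Yates continuity correction available via
#' \code{correct = TRUE}. Zero margins raise an error.
#'
#' @param table a \code{ContingencyTable2x2}.
#' @param correct apply continuity correction.
#' @return list: \code{statistic, p}.
#' @examples
#' chiSquare2x2(contingency2x2(17, 51, 5, 60))  # statistic about 7.21
#' @export
chiSquare2x2 <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "ContingencyTable2x2"))
  m <- matrix(unlist(table[c("a", "b", "c", "d")]), 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    .stopf("chi-square undefined: zero margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Cryptorchidism-association table for dual KIT+RAS mutant seminoma
#'
#' Reconstructs the 2x2 table relating dual KIT and KRAS/NRAS mutation
#' (exposure) to a history of cryptorchidism (outcome) among the seminomas
#' of the TCGA TGCT cohort from the published counts: 6 dual-mutant
#' seminomas of which 4 cryptorchid, and 17 cryptorchid seminomas in
#' total. Two documented presets resolve the denominator for the
#' non-dual-mutant stratum:
#' \describe{
#'   \item{"sample"}{72 seminoma samples minus the 6 with missing
#'     cryptorchidism records: 60 non-dual samples, table (4, 2, 13, 47).}
#'   \item{"patient"}{the patient-level count of 68 seminomas with known
#'     cryptorchidism status: 62 non-dual, table (4, 2, 13, 49).}
#' }
#'
#' @param preset \code{"sample"} (default) or \code{"patient"}.
#' @return a \code{ContingencyTable2x2}.
#' @export
cryptorchidismTable <- function(preset = c("sample", "patient")) {
  preset <- match.arg(preset)
  nKnown <- switch(preset, sample = 66L, patient = 68L)
  a <- 4L; b <- 2L                 # dual mutants: 4 cryptorchid of 6
  c <- 17L - a                     # remaining cryptorchid seminomas
  d <- (nKnown - 6L) - c
  contingency2x2(a, b, c, d)
}

#' Build a 2x2 exposure/outcome table from sample metadata
#'
#' Counts samples by dual KIT+RAS mutation (exposure) against
#' cryptorchidism (outcome), dropping unknowns, optionally restricted to a
#' histology.
#'
#' @param meta sample metadata data.frame.
#' @param histology restrict to one histology (default \code{"seminoma"});
#'   \code{NULL} for all.
#' @return a \code{ContingencyTable2x2}.
#' @export
dualMutationCryptTable <- function(meta, histology = "seminoma") {
  meta <- as.data.frame(meta)
  if (!is.null(histology)) meta <- meta[meta$histology %in% histology, ]
  meta <- meta[meta$cryptorchidism != "unknown" &
                 meta$kit_status != "unknown" &
                 meta$ras_status != "unknown", ]
  dual <- meta$kit_status == "mutant" & meta$ras_status == "mutant"
  crypt <- meta$cryptorchidism == "yes"
  contingency2x2(sum(dual & crypt), sum(dual & !crypt),
                 sum(!dual & crypt), sum(!dual & !crypt))
}

#' Immune signature scores from expression
#'
#' Every gene is median-centered across the cohort first; a signature
#' score is then the median of its member genes per sample. Signatures
#' with no gene present in the matrix are skipped with a warning.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param geneSets named list of character vectors of gene names.
#' @return matrix, samples x signatures.
#' @export
immuneSignatureScores <- function(expr, geneSets) {
  if (!length(geneSets)) .stopf("no gene sets supplied")
  centered <- sweep(expr, 1, apply(expr, 1, stats::median))
  cols <- list()
  for (nm in names(geneSets)) {
    genes <- intersect(geneSets[[nm]], rownames(expr))
    if (!length(genes)) {
      warning(sprintf("signature '%s' has no genes in the matrix; skipped",
                      nm))
      next
    }
    cols[[nm]] <- apply(centered[genes, , drop = FALSE], 2, stats::median)
  }
  if (!length(cols)) .stopf("no signature could be scored")
  do.call(cbind, cols)
}

#' Two-group comparison (Mann-Whitney or t test)
#'
#' Two-sided. The Mann-Whitney test is exact when both groups have at most
#' 20 observations and there are no ties, otherwise the normal
#' approximation with tie correction is used.
#'
#' @param values numeric vector.
#' @param labels two-level grouping vector aligned with \code{values}.
#' @param test \code{"mann_whitney"} (default) or \code{"t_test"}.
#' @return list: \code{statistic, p}.
#' @export
groupCompare <- function(values, labels, test = c("mann_whitney",
                                                  "t_test")) {
  test <- match.arg(test)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  lv <- unique(labels)
  if (length(lv) != 2) .stopf("exactly two groups required")
  x <- values[labels == lv[1]]; y <- values[labels == lv[2]]
  if (!length(x) || !length(y)) .stopf("one group is empty")
  if (test == "t_test") {
    res <- stats::t.test(x, y)
    return(list(statistic = unname(res$statistic),
                p = unname(res$p.value)))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 20 && !ties
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = FALSE))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Benjamini-Hochberg adjustment helper
#'
#' Thin wrapper around \code{stats::p.adjust(p, "BH")} for batch use; the
#' targeted single comparisons in this package are reported unadjusted.
#'
#' @param p numeric vector of p values.
#' @return BH-adjusted p values.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")
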