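# Concordance between two asynchronous primary tumors of one patient:
# somatic mutation overlap plus per-platform correlation of molecular
# profiles, computed on the features shared by both tumors.

#' Pairwise concordance of two primary tumors
#'
#' Mutation identity is keyed at (gene, substitution, trinucleotide
#' context) granularity -- the arm-level model carries no base-pair
#' positions, so two events in the same gene with the same change are
#' treated as shared. For each supplied platform matrix the correlation is
#' computed over the features present for both tumors; a platform missing
#' one of the tumors is skipped with a warning.
#'
#' @param mutations_t1,mutations_t2 mutation data.frames of the first and
#'   second primary.
#' @param platforms named list of feature x sample matrices (e.g. beta
#'   values, miRNA, mRNA, protein).
#' @param t1,t2 sample ids of the two tumors in the platform matrices.
#' @param patient_id optional patient identifier carried into the output.
#' @param method correlation method, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return list: \code{patient_id, shared_mutations, mutations_t1_only,
#'   mutations_t2_only, correlations} (named numeric vector per platform).
#' @export
pairConcordance <- function(mutations_t1, mutations_t2, platforms = list(),
                            t1 = NULL, t2 = NULL, patient_id = NA_character_,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  key <- function(m) {
    m <- as.data.frame(m)
    if (!nrow(m)) return(character())
    unique(paste(m$gene, m$substitution, m$context))
  }
  k1 <- key(mutations_t1); k2 <- key(mutations_t2)
  shared <- length(intersect(k1, k2))
  correlations <- numeric(0)
  for (nm in names(platforms)) {
    mat <- platforms[[nm]]
    if (is.null(t1) || is.null(t2) ||
        !all(c(t1, t2) %in% colnames(mat))) {
      warning(sprintf("platform '%s' lacks one of the tumors; skipped", nm))
      next
    }
    x <- mat[, t1]; y <- mat[, t2]
    use <- is.finite(x) & is.finite(y)
    if (sum(use) < 3) {
      warning(sprintf("platform '%s' has < 3 shared features; skipped", nm))
      next
    }
    correlations[nm] <- stats::cor(x[use], y[use], method = method)
  }
  list(patient_id = patient_id, shared_mutations = shared,
       mutations_t1_only = length(setdiff(k1, k2)),
       mutations_t2_only = length(setdiff(k2, k1)),
       correlations = correlations)
}
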