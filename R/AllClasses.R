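#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

#' BetaSet: methylation beta values with probe annotation
#'
#' An S4 container for a probes-by-samples matrix of methylation fractions
#' (beta values, in \code{[0,1]}, \code{NA} allowed) together with the probe
#' annotation every deconvolution step needs. It extends
#' \linkS4class{SummarizedExperiment}: the single assay is named
#' \code{"beta"} and the annotation lives in \code{rowData}.
#'
#' Required \code{rowData} columns:
#' \describe{
#'   \item{context}{\code{"CpG"} or \code{"CpH"} (non-CpG cytosine).}
#'   \item{region}{chromatin-state label: \code{"active_promoter"},
#'     \code{"poised_promoter"}, \code{"heterochromatin"} or \code{"other"}.}
#'   \item{imprinted_dmr}{name of the imprinted DMR the probe belongs to, or
#'     \code{NA}.}
#'   \item{lymphocyte_signature}{logical; \code{TRUE} for probes of the
#'     lymphocyte methylation signature used to estimate infiltration.}
#'   \item{lymphocyte_ref_beta}{beta value of the probe in the lymphocyte
#'     reference; must be non-missing wherever
#'     \code{lymphocyte_signature} is \code{TRUE}.}
#'   \item{promoter_of_gene}{gene whose promoter the probe interrogates, or
#'     \code{NA}.}
#' }
#'
#' @seealso [estimateLymphocyteFraction()], [correctBetaSet()], [cphScore()]
#' @aliases BetaSet-class
#' @exportClass BetaSet
setClass("BetaSet", contains = "SummarizedExperiment")

.BETASET_COLS <- c("context", "region", "imprinted_dmr",
                   "lymphocyte_signature", "lymphocyte_ref_beta",
                   "promoter_of_gene")

setValidity("BetaSet", function(object) {
  msg <- character()
  if (!"beta" %in% assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    bad <- b[!is.na(b)]
    if (length(bad) && (min(bad) < 0 || max(bad) > 1))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  rd <- rowData(object)
  missing <- setdiff(.BETASET_COLS, colnames(rd))
  if (length(missing))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(missing, collapse = ", ")))
  else {
    if (!all(rd$context %in% .PROBE_CONTEXTS))
      msg <- c(msg, "context must be 'CpG' or 'CpH'")
    if (!all(rd$region %in% .PROBE_REGIONS))
      msg <- c(msg, "region has values outside the chromatin-state enum")
    sig <- rd$lymphocyte_signature
    if (!is.logical(sig))
      msg <- c(msg, "lymphocyte_signature must be logical")
    else if (any(sig & !is.finite(rd$lymphocyte_ref_beta)))
      msg <- c(msg, "signature probes require lymphocyte_ref_beta")
    ref <- rd$lymphocyte_ref_beta
    ref <- ref[!is.na(ref)]
    if (length(ref) && (min(ref) < 0 || max(ref) > 1))
      msg <- c(msg, "lymphocyte_ref_beta must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BetaSet
#'
#' @param beta numeric matrix of beta values (probes x samples) with probe
#'   ids as rownames and sample ids as colnames.
#' @param probes data.frame of probe annotation with a \code{probe_id}
#'   column (or rownames) matching \code{rownames(beta)} and the columns
#'   documented in \linkS4class{BetaSet}.
#' @return A \linkS4class{BetaSet}.
#' @examples
#' b <- matrix(c(0, 0.5, 1, 0.2), nrow = 2,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' pr <- data.frame(probe_id = c("p1", "p2"), context = "CpG",
#'                  region = "other", imprinted_dmr = NA,
#'                  lymphocyte_signature = c(TRUE, FALSE),
#'                  lymphocyte_ref_beta = c(0.9, NA),
#'                  promoter_of_gene = NA)
#' bs <- BetaSet(b, pr)
#' @export
BetaSet <- function(beta, probes) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    .stopf("'beta' needs probe rownames and sample colnames")
  probes <- as.data.frame(probes)
  if ("probe_id" %in% colnames(probes)) rownames(probes) <- probes$probe_id
  missing <- setdiff(rownames(beta), rownames(probes))
  if (length(missing))
    .stopf("probe annotation missing for %d probe(s), e.g. '%s'",
           length(missing), missing[1])
  probes <- probes[rownames(beta), .BETASET_COLS, drop = FALSE]
  new("BetaSet",
      SummarizedExperiment(assays = list(beta = beta),
                           rowData = DataFrame(probes)))
}

#' Extract the beta-value matrix of a BetaSet
#' @param object a \linkS4class{BetaSet}.
#' @return numeric matrix, probes x samples.
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname betaValues
#' @export
setMethod("betaValues", "BetaSet", function(object) assay(object, "beta"))

#' Extract probe annotation of a BetaSet as a data.frame
#' @param object a \linkS4class{BetaSet}.
#' @return data.frame with one row per probe (probe_id column included).
#' @export
setGeneric("probeInfo", function(object) standardGeneric("probeInfo"))

#' @rdname probeInfo
#' @export
setMethod("probeInfo", "BetaSet", function(object) {
  df <- as.data.frame(rowData(object))
  cbind(probe_id = rownames(df), df, row.names = NULL,
        stringsAsFactors = FALSE)
})

#' TGCTCohort: one cohort, all platforms, plus simulation truth
#'
#' The container returned by [generateCohort()] and consumed by the
#' pipeline. Slots:
#' \describe{
#'   \item{sampleMeta}{per-sample clinical table (histology, component
#'     fractions, KIT/RAS status, cryptorchidism, purity, ploidy).}
#'   \item{segments}{arm-level allelic integer copy-number table
#'     (\code{sample_id, arm, major_cn, minor_cn}).}
#'   \item{mutations}{somatic mutation table with read counts, TVAF,
#'     trinucleotide context and substitution class.}
#'   \item{beta}{a \linkS4class{BetaSet} of observed beta values.}
#'   \item{expression}{log2 expression matrix, genes x samples.}
#'   \item{truth}{list of simulation ground truth (empty for real data):
#'     per-sample truth table, per-mutation truth, the tumor-intrinsic beta
#'     matrix before lymphocyte mixing, and the planted silencing matrix.}
#' }
#' @aliases TGCTCohort-class
#' @exportClass TGCTCohort
setClass("TGCTCohort",
         representation(sampleMeta = "data.frame",
                        segments = "data.frame",
                        mutations = "data.frame",
                        beta = "BetaSet",
                        expression = "matrix",
                        truth = "list"))

setValidity("TGCTCohort", function(object) {
  msg <- character()
  ids <- object@sampleMeta$sample_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "sampleMeta needs unique sample_id")
  for (slotname in c("segments", "mutations")) {
    tab <- slot(object, slotname)
    if (nrow(tab) && !all(tab$sample_id %in% ids))
      msg <- c(msg, sprintf("%s refers to samples absent from sampleMeta",
                            slotname))
  }
  if (ncol(object@beta) && !all(colnames(object@beta) %in% ids))
    msg <- c(msg, "beta has samples absent from sampleMeta")
  if (length(msg)) msg else TRUE
})

#' @describeIn TGCTCohort-class compact summary
#' @param object a \code{TGCTCohort}.
#' @export
setMethod("show", "TGCTCohort", function(object) {
  m <- object@sampleMeta
  cat(sprintf("TGCTCohort: %d samples (%s)\n", nrow(m),
              paste(sprintf("%s=%d", names(table(m$histology)),
                            as.integer(table(m$histology))),
                    collapse = ", ")))
  cat(sprintf("  segments: %d rows; mutations: %d; beta: %d probes; expression: %d genes\n",
              nrow(object@segments), nrow(object@mutations),
              nrow(object@beta), nrow(object@expression)))
  cat(sprintf("  simulation truth: %s\n",
              if (length(object@truth)) "present" else "absent"))
})

#' Accessors for TGCTCohort slots
#'
#' @param object a \linkS4class{TGCTCohort}.
#' @return the corresponding table, matrix or \linkS4class{BetaSet}.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))
#' @rdname cohort-accessors
#' @export
setMethod("sampleMeta", "TGCTCohort", function(object) object@sampleMeta)

#' @rdname cohort-accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname cohort-accessors
#' @export
setMethod("segments", "TGCTCohort", function(object) object@segments)

#' @rdname cohort-accessors
#' @export
setGeneric("mutations", function(object) standardGeneric("mutations"))
#' @rdname cohort-accessors
#' @export
setMethod("mutations", "TGCTCohort", function(object) object@mutations)

#' @rdname cohort-accessors
#' @export
setGeneric("betaSet", function(object) standardGeneric("betaSet"))
#' @rdname cohort-accessors
#' @export
setMethod("betaSet", "TGCTCohort", function(object) object@beta)

#' @rdname cohort-accessors
#' @export
setGeneric("exprMatrix", function(object) standardGeneric("exprMatrix"))
#' @rdname cohort-accessors
#' @export
setMethod("exprMatrix", "TGCTCohort", function(object) object@expression)

#' @rdname cohort-accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @rdname cohort-accessors
#' @export
setMethod("cohortTruth", "TGCTCohort", function(object) object@truth)
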