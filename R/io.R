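# Tabular IO. Everything is UTF-8 TSV with one header row, NA serialized as
# "NA", decimal point only (locale-independent). Doubles are written with 17
# significant digits so writer/reader pairs are bit-exact round trips.

.fmtNum <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out
}

.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) out[[j]] <- .fmtNum(col)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.readTsv <- function(path, required, what) {
  if (!file.exists(path)) .stopf("%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = "\t", quote = "", na.strings = "NA",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    .stopf("%s file %s lacks required column(s): %s", what, path,
           paste(missing, collapse = ", "))
  df
}

.checkNonNegInt <- function(df, cols, what) {
  for (cc in cols) {
    v <- df[[cc]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      .stopf("%s: column '%s' must be a non-negative integer (row %d)",
             what, cc, bad[1])
    df[[cc]] <- as.integer(round(v))
  }
  df
}

.checkArm <- function(arm, what) {
  bad <- which(!arm %in% .ARMS)
  if (length(bad))
    .stopf("%s: unknown chromosome arm '%s' (row %d)", what,
           arm[bad[1]], bad[1])
  invisible(arm)
}

.MUTATION_COLS <- c("sample_id", "gene", "arm", "alt_count", "ref_count",
                    "tvaf", "context", "substitution", "rna_vaf")

.validateMutations <- function(df, what = "mutations") {
  df <- .checkNonNegInt(df, c("alt_count", "ref_count"), what)
  .checkArm(df$arm, what)
  if (!"tvaf" %in% colnames(df)) df$tvaf <- NA_real_
  if (!"rna_vaf" %in% colnames(df)) df$rna_vaf <- NA_real_
  df$tvaf <- as.double(df$tvaf)
  df$rna_vaf <- as.double(df$rna_vaf)
  depth <- df$alt_count + df$ref_count
  computed <- ifelse(depth > 0, df$alt_count / depth, 0)
  df$tvaf <- ifelse(is.na(df$tvaf), computed, as.numeric(df$tvaf))
  bad <- which(depth > 0 & abs(df$tvaf - computed) > 1e-9)
  if (length(bad))
    .stopf("%s: tvaf inconsistent with read counts (row %d)", what, bad[1])
  bad <- which(!is.na(df$tvaf) & (df$tvaf < 0 | df$tvaf > 1))
  if (length(bad)) .stopf("%s: tvaf outside [0,1] (row %d)", what, bad[1])
  bad <- which(!grepl("^[ACGT]{3}$", df$context))
  if (length(bad))
    .stopf("%s: context must be a 3-mer over ACGT (row %d)", what, bad[1])
  bad <- which(!df$substitution %in% .SUBSTITUTIONS)
  if (length(bad))
    .stopf("%s: substitution '%s' not one of the 6 pyrimidine classes (row %d)",
           what, df$substitution[bad[1]], bad[1])
  df <- df[, .MUTATION_COLS]
  rownames(df) <- NULL
  df
}

#' Read / write somatic mutation tables
#'
#' MAF-subset tab-separated dialect: columns \code{sample_id, gene, arm,
#' alt_count, ref_count, tvaf, context, substitution, rna_vaf}. When
#' \code{tvaf} is absent it is computed as \code{alt/(alt+ref)} (0 at zero
#' depth); when present it must agree with the counts to 1e-9.
#' \code{context} is the reference trinucleotide around the variant,
#' \code{substitution} one of the six pyrimidine-centred classes.
#'
#' @param path path to a TSV file.
#' @return \code{readMutations}: a validated data.frame of somatic mutations.
#' @export
readMutations <- function(path) {
  df <- .readTsv(path, setdiff(.MUTATION_COLS, c("tvaf", "rna_vaf")),
                 "mutations")
  .validateMutations(df)
}

#' @rdname readMutations
#' @param mutations a mutation data.frame as returned by [readMutations()]
#'   or [mutations()].
#' @return \code{writeMutations}: the path, invisibly.
#' @export
writeMutations <- function(mutations, path) {
  .writeTsv(.validateMutations(as.data.frame(mutations)), path)
}

.SEGMENT_COLS <- c("sample_id", "arm", "major_cn", "minor_cn")

.validateSegments <- function(df, what = "segments") {
  df <- .checkNonNegInt(df, c("major_cn", "minor_cn"), what)
  .checkArm(df$arm, what)
  bad <- which(df$major_cn < df$minor_cn)
  if (length(bad))
    .stopf("%s: major_cn < minor_cn (row %d)", what, bad[1])
  key <- paste(df$sample_id, df$arm)
  if (anyDuplicated(key))
    .stopf("%s: duplicated (sample, arm) pair '%s'", what,
           key[anyDuplicated(key)])
  df <- df[order(df$sample_id, match(df$arm, .ARMS)), .SEGMENT_COLS]
  rownames(df) <- NULL
  df
}

#' Read / write arm-level allelic copy-number segments
#'
#' SEG-like TSV extended with allelic integer copy number: columns
#' \code{sample_id, arm, major_cn, minor_cn} with
#' \code{major_cn >= minor_cn >= 0}, one row per (sample, arm). Rows are
#' returned grouped by sample in genomic arm order.
#'
#' @param path path to a TSV file.
#' @return \code{readSegments}: a validated data.frame of segments.
#' @export
readSegments <- function(path) {
  .validateSegments(.readTsv(path, .SEGMENT_COLS, "segments"))
}

#' @rdname readSegments
#' @param segments a segment data.frame.
#' @return \code{writeSegments}: the path, invisibly.
#' @export
writeSegments <- function(segments, path) {
  .writeTsv(.validateSegments(as.data.frame(segments)), path)
}

.META_COLS <- c("sample_id", "histology", "frac_seminoma", "frac_EC",
                "frac_teratoma", "frac_yolk_sac", "kit_status", "ras_status",
                "cryptorchidism", "purity", "ploidy")

.validateSampleMeta <- function(df, what = "sample metadata") {
  if (anyDuplicated(df$sample_id)) .stopf("%s: duplicated sample_id", what)
  for (cc in c(paste0("frac_", .COMPONENTS), "purity", "ploidy"))
    if (cc %in% colnames(df)) df[[cc]] <- as.double(df[[cc]])
  bad <- which(!df$histology %in% .HISTOLOGIES)
  if (length(bad))
    .stopf("%s: unknown histology '%s' (row %d)", what,
           df$histology[bad[1]], bad[1])
  fr <- as.matrix(df[, paste0("frac_", .COMPONENTS)])
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    .stopf("%s: component fractions must lie in [0,1]", what)
  bad <- which(abs(rowSums(fr) - 1) > 1e-6)
  if (length(bad))
    .stopf("%s: component fractions must sum to 1 (row %d)", what, bad[1])
  for (cc in c("kit_status", "ras_status")) {
    if (!all(df[[cc]] %in% .TRISTATE))
      .stopf("%s: %s must be mutant/wildtype/unknown", what, cc)
  }
  if (!all(df$cryptorchidism %in% .YESNO))
    .stopf("%s: cryptorchidism must be yes/no/unknown", what)
  p <- df$purity
  bad <- which(!is.na(p) & (p <= 0 | p > 1))
  if (length(bad)) .stopf("%s: purity outside (0,1] (row %d)", what, bad[1])
  bad <- which(!is.na(df$ploidy) & df$ploidy <= 0)
  if (length(bad)) .stopf("%s: ploidy must be positive (row %d)", what, bad[1])
  df <- df[, .META_COLS]
  rownames(df) <- NULL
  df
}

#' Read / write per-sample clinical metadata
#'
#' Columns: \code{sample_id, histology, frac_seminoma, frac_EC,
#' frac_teratoma, frac_yolk_sac, kit_status, ras_status, cryptorchidism,
#' purity, ploidy}. Component fractions are the pathologist-style tumor
#' composition and must sum to 1; purity (when present) lies in (0,1].
#'
#' @param path path to a TSV file.
#' @return \code{readSampleMeta}: a validated data.frame.
#' @export
readSampleMeta <- function(path) {
  .validateSampleMeta(.readTsv(path, .META_COLS, "sample metadata"))
}

#' @rdname readSampleMeta
#' @param meta a sample-metadata data.frame.
#' @return \code{writeSampleMeta}: the path, invisibly.
#' @export
writeSampleMeta <- function(meta, path) {
  .writeTsv(.validateSampleMeta(as.data.frame(meta)), path)
}

#' Read / write feature-by-sample matrices (beta values, expression)
#'
#' Plain TSV with the feature identifier in the first column
#' (\code{feature_id}) and one column per sample.
#'
#' @param path path to a TSV file.
#' @return \code{readMatrix}: a numeric matrix with feature rownames.
#' @export
readMatrix <- function(path) {
  df <- .readTsv(path, "feature_id", "matrix")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- df$feature_id
  m
}

#' @rdname readMatrix
#' @param mat numeric matrix with rownames and colnames.
#' @return \code{writeMatrix}: the path, invisibly.
#' @export
writeMatrix <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  .writeTsv(df, path)
}

.PROBE_COLS <- c("probe_id", "context", "region", "imprinted_dmr",
                 "lymphocyte_signature", "lymphocyte_ref_beta",
                 "promoter_of_gene")

.validateProbes <- function(df, what = "probe annotation") {
  if (anyDuplicated(df$probe_id)) .stopf("%s: duplicated probe_id", what)
  if (!all(df$context %in% .PROBE_CONTEXTS))
    .stopf("%s: context must be CpG or CpH", what)
  if (!all(df$region %in% .PROBE_REGIONS))
    .stopf("%s: region outside chromatin-state enum", what)
  df$lymphocyte_signature <- as.logical(df$lymphocyte_signature)
  if (anyNA(df$lymphocyte_signature))
    .stopf("%s: lymphocyte_signature must be TRUE/FALSE", what)
  if (any(df$lymphocyte_signature & !is.finite(df$lymphocyte_ref_beta)))
    .stopf("%s: signature probes need lymphocyte_ref_beta", what)
  df[, .PROBE_COLS]
}

#' Read / write probe annotation tables
#'
#' Columns as documented in \linkS4class{BetaSet}.
#'
#' @param path path to a TSV file.
#' @return \code{readProbeAnnotation}: a validated data.frame.
#' @export
readProbeAnnotation <- function(path) {
  .validateProbes(.readTsv(path, .PROBE_COLS, "probe annotation"))
}

#' @rdname readProbeAnnotation
#' @param probes a probe-annotation data.frame.
#' @return \code{writeProbeAnnotation}: the path, invisibly.
#' @export
writeProbeAnnotation <- function(probes, path) {
  .writeTsv(.validateProbes(as.data.frame(probes)), path)
}

#' Assemble a BetaSet from beta-matrix and probe-annotation files
#'
#' @param betaPath TSV of beta values (see [readMatrix()]).
#' @param probePath TSV of probe annotation (see [readProbeAnnotation()]).
#' @return a \linkS4class{BetaSet}.
#' @export
readBetaSet <- function(betaPath, probePath) {
  BetaSet(readMatrix(betaPath), readProbeAnnotation(probePath))
}
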