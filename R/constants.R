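# Chromosome-arm model shared across modules. All copy-number reasoning in
# this package is arm-granular: the five acrocentric short arms carry no
# meaningful euchromatin and are excluded, leaving 41 arms.

# Approximate arm lengths in Mb (hg38), used as genome-length weights for
# WGD fraction and ploidy computations.
.ARM_LENGTHS_MB <- c(
  "1p" = 123, "1q" = 125, "2p" = 93, "2q" = 149, "3p" = 91, "3q" = 108,
  "4p" = 50, "4q" = 140, "5p" = 48, "5q" = 133, "6p" = 61, "6q" = 110,
  "7p" = 60, "7q" = 99, "8p" = 45, "8q" = 100, "9p" = 43, "9q" = 95,
  "10p" = 40, "10q" = 94, "11p" = 53, "11q" = 82, "12p" = 36, "12q" = 97,
  "13q" = 98, "14q" = 91, "15q" = 85, "16p" = 36, "16q" = 54,
  "17p" = 25, "17q" = 58, "18p" = 19, "18q" = 62, "19p" = 26, "19q" = 33,
  "20p" = 28, "20q" = 36, "21q" = 34, "22q" = 37, "Xp" = 61, "Xq" = 95
)

.ARMS <- names(.ARM_LENGTHS_MB)

.HISTOLOGIES <- c("seminoma", "EC", "teratoma", "yolk_sac", "mixed")
.COMPONENTS <- c("seminoma", "EC", "teratoma", "yolk_sac")
.TRISTATE <- c("mutant", "wildtype", "unknown")
.YESNO <- c("yes", "no", "unknown")

# Pyrimidine-centred substitution classes (standard mutation-spectrum basis).
.SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.PROBE_CONTEXTS <- c("CpG", "CpH")
.PROBE_REGIONS <- c("active_promoter", "poised_promoter", "heterochromatin",
                    "other")

# Arms after whole-genome doubling that preferentially lose copies, by
# histology class (recurrent subtype-specific losses in TGCT cohorts).
.NSGCT_LOSS_ARMS <- c("19q", "15q", "22q", "19p", "10q", "8p", "2q", "8q")
.SEMINOMA_LOSS_ARMS <- c("11q")

# Tumor suppressors recurrently silenced by promoter hypermethylation in
# non-seminomatous TGCT, with per-histology silencing probabilities used by
# the simulator (fractions observed in the non-seminoma histology classes;
# seminoma never silences these).
.SILENCING_GENES <- c("BRCA1", "RAD51C", "MGMT", "DNAJC15", "RASSF1A")
.SILENCING_RATES <- rbind(
  BRCA1    = c(seminoma = 0, EC = 0.07, teratoma = 0.31, yolk_sac = 0.54),
  RAD51C   = c(seminoma = 0, EC = 0.11, teratoma = 0.31, yolk_sac = 0.31),
  MGMT     = c(seminoma = 0, EC = 0.11, teratoma = 0.56, yolk_sac = 0.38),
  DNAJC15  = c(seminoma = 0, EC = 0.00, teratoma = 0.50, yolk_sac = 0.31),
  RASSF1A  = c(seminoma = 0, EC = 0.10, teratoma = 0.35, yolk_sac = 0.35)
)

`%||%` <- function(a, b) if (is.null(a)) b else a

.clip01 <- function(x) pmax(pmin(x, 1), 0)  # first-arg order keeps dimnames

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertScalarIn <- function(x, lo, hi, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi))
    .stopf("'%s' must be in [%g, %g]", name, lo, hi)
  invisible(x)
}
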