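# Synthetic TGCT cohort generator. Emulates the statistical structure the
# downstream inference assumes -- hyper-triploid genomes from 1-2 WGD events,
# histology-specific arm losses, i(12p) in all NSGCTs and most seminomas,
# lymphocyte contamination anti-correlated with purity, histology-specific
# methylomes (seminoma unmethylated, EC CpH-methylated, other NSGCT
# soma-like), and mutation read counts binomial around the multiplicity
# model -- with full ground truth recorded for recovery tests.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [generateCohort()]. Defaults
#' encode the cohort archetypes of the TCGA TGCT study population: histology
#' mix 72:27:16:13:9 (seminoma : EC : teratoma : yolk sac : mixed), KIT
#' mutation in 25/72 seminomas, i(12p) in 80 percent of seminomas and all
#' NSGCTs, a second WGD in 10/131 samples, seminoma purity Uniform(0.2, 0.8)
#' versus NSGCT Uniform(0.4, 0.95), and lymphocyte fraction
#' \code{(1 - purity) + Normal(0, lymph_noise_sd)} clipped to [0, 1].
#'
#' @param n_samples number of tumors to simulate.
#' @param histology_mix named probabilities over
#'   \code{seminoma, EC, teratoma, yolk_sac, mixed}; must sum to 1.
#' @param seminoma_kit_mut_rate probability a seminoma carries a KIT
#'   mutation.
#' @param p_i12p_seminoma probability a seminoma carries i(12p); NSGCTs
#'   always do.
#' @param p_second_wgd probability of a second whole-genome doubling.
#' @param purity_range_seminoma,purity_range_nsgct uniform purity ranges.
#' @param lymph_noise_sd sd of the noise on the lymphocyte fraction around
#'   \code{1 - purity}.
#' @param n_probes total methylation probes (must be at least 600).
#' @param cph_fraction fraction of probes in CpH (non-CpG) context.
#' @param n_signature_probes lymphocyte-signature probes.
#' @param n_imprinted_dmrs,probes_per_dmr imprinted-DMR layout.
#' @param residual_fraction fraction of probes forming the shared residual
#'   methylated set of KIT-wild-type seminomas (the study reports recurrent
#'   seminoma methylation at under 1 percent of sites; 0.5 percent is the
#'   default archetype).
#' @param mean_depth mean sequencing depth for mutation read counts.
#' @param mean_mutations mean somatic mutation count per sample (roughly
#'   0.5/Mb over a 30 Mb exome).
#' @param rng_seed integer seed; the whole cohort is drawn from one RNG
#'   stream seeded here, so identical configs give identical cohorts.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_samples = 120,
                      histology_mix = c(seminoma = 72, EC = 27,
                                        teratoma = 16, yolk_sac = 13,
                                        mixed = 9) / 137,
                      seminoma_kit_mut_rate = 25 / 72,
                      p_i12p_seminoma = 0.8,
                      p_second_wgd = 10 / 131,
                      purity_range_seminoma = c(0.2, 0.8),
                      purity_range_nsgct = c(0.4, 0.95),
                      lymph_noise_sd = 0.03,
                      n_probes = 5000,
                      cph_fraction = 0.2,
                      n_signature_probes = 200,
                      n_imprinted_dmrs = 10,
                      probes_per_dmr = 5,
                      residual_fraction = 0.005,
                      mean_depth = 120,
                      mean_mutations = 15,
                      rng_seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              histology_mix = histology_mix,
              seminoma_kit_mut_rate = seminoma_kit_mut_rate,
              p_i12p_seminoma = p_i12p_seminoma,
              p_second_wgd = p_second_wgd,
              purity_range_seminoma = purity_range_seminoma,
              purity_range_nsgct = purity_range_nsgct,
              lymph_noise_sd = lymph_noise_sd,
              n_probes = as.integer(n_probes),
              cph_fraction = cph_fraction,
              n_signature_probes = as.integer(n_signature_probes),
              n_imprinted_dmrs = as.integer(n_imprinted_dmrs),
              probes_per_dmr = as.integer(probes_per_dmr),
              residual_fraction = residual_fraction,
              mean_depth = mean_depth,
              mean_mutations = mean_mutations,
              rng_seed = as.integer(rng_seed))
  if (cfg$n_samples < 1) .stopf("config error: n_samples must be positive")
  if (!setequal(names(cfg$histology_mix), .HISTOLOGIES))
    .stopf("config error: histology_mix must name %s",
           paste(.HISTOLOGIES, collapse = ", "))
  cfg$histology_mix <- cfg$histology_mix[.HISTOLOGIES]
  .assertScalarIn(cfg$histology_mix, 0, 1, "histology_mix")
  if (abs(sum(cfg$histology_mix) - 1) > 1e-6)
    .stopf("config error: histology_mix must sum to 1")
  for (p in c("seminoma_kit_mut_rate", "p_i12p_seminoma", "p_second_wgd",
              "cph_fraction", "residual_fraction"))
    .assertScalarIn(cfg[[p]], 0, 1, p)
  for (p in c("purity_range_seminoma", "purity_range_nsgct")) {
    r <- cfg[[p]]
    if (length(r) != 2 || r[1] <= 0 || r[2] > 1 || r[1] > r[2])
      .stopf("config error: %s must be an increasing range within (0,1]", p)
  }
  if (cfg$lymph_noise_sd < 0) .stopf("config error: lymph_noise_sd < 0")
  nFixed <- cfg$n_signature_probes +
    cfg$n_imprinted_dmrs * cfg$probes_per_dmr +
    length(.SILENCING_GENES) * 5
  if (cfg$n_probes < nFixed + ceiling(cfg$n_probes * cfg$cph_fraction) + 100)
    .stopf("config error: n_probes too small for the probe layout")
  if (cfg$mean_depth < 1 || cfg$mean_mutations < 0)
    .stopf("config error: depth/mutation means out of range")
  structure(cfg, class = "SimConfig")
}

#' Two-component beta-value mixture
#'
#' Forward model of bulk methylation in an infiltrated tumor: the observed
#' beta value is \code{f * ref_beta + (1 - f) * tumor_beta}, where \code{f}
#' is the lymphocyte fraction. Exact inverse of [correctBeta()] (before
#' clipping).
#'
#' @param tumor_beta,f,ref_beta numerics in [0, 1] (vectorized, recycled).
#' @return the mixed beta value(s).
#' @examples
#' mixBeta(0, 0.5, 1)      # 0.5
#' mixBeta(0.4, 0.25, 0.8) # 0.5
#' @export
mixBeta <- function(tumor_beta, f, ref_beta) {
  .assertScalarIn(tumor_beta, 0, 1, "tumor_beta")
  .assertScalarIn(f, 0, 1, "f")
  .assertScalarIn(ref_beta, 0, 1, "ref_beta")
  f * ref_beta + (1 - f) * tumor_beta
}

# --- internal pieces ---------------------------------------------------

.runif2 <- function(n, r) stats::runif(n, r[1], r[2])

# Draw per-sample allelic copy number for all arms, the i(12p) status and
# the WGD count; returns list(segments major/minor vectors, truth fields).
.simGenome <- function(histology, isSeminoma, p_i12p, p_second_wgd) {
  arms <- .ARMS
  major <- stats::setNames(rep(2L, length(arms)), arms)   # after first WGD
  minor <- stats::setNames(rep(2L, length(arms)), arms)
  lossArms <- setdiff(arms, c("12p", "12q"))
  # first loss (one minor copy), then for NSGCT sometimes a second
  l1 <- stats::rbinom(length(lossArms), 1, 0.85) == 1
  if (isSeminoma) {
    l2p <- ifelse(lossArms %in% .SEMINOMA_LOSS_ARMS, 0.70, 0.05)
  } else {
    l2p <- ifelse(lossArms %in% .NSGCT_LOSS_ARMS, 0.70, 0.25)
  }
  l2 <- l1 & (stats::rbinom(length(lossArms), 1, l2p) == 1)
  minor[lossArms][l1] <- 1L
  minor[lossArms][l2] <- 0L
  i12p <- if (isSeminoma) stats::runif(1) < p_i12p else TRUE
  k <- 0L
  if (i12p) {
    k <- sample(1:3, 1, prob = c(0.4, 0.4, 0.2))
    major["12p"] <- major["12p"] + k
  }
  wgd <- 1L + as.integer(stats::runif(1) < p_second_wgd)
  if (wgd == 2L) { major <- 2L * major; minor <- 2L * minor }
  list(major = major, minor = minor, i12p = i12p, k = k, wgd = wgd,
       lost = lossArms[l1])
}

.drawContext <- function(substitution, cpgShare) {
  n <- length(substitution)
  five <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  central <- substr(substitution, 1, 1)
  three <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  isCT <- substitution == "C>T"
  atCpg <- isCT & stats::runif(n) < cpgShare
  three[isCT & !atCpg] <- sample(c("A", "C", "T"), sum(isCT & !atCpg),
                                 replace = TRUE)
  three[atCpg] <- "G"
  paste0(five, central, three)
}

# Per-sample tumor-intrinsic beta archetype for one pure component.
.archetypeBeta <- function(component, kitMutant, layout, silencedGenes) {
  P <- layout$n_probes
  beta <- stats::runif(P, 0, 0.02)      # unmethylated floor everywhere
  bg <- layout$background
  if (component == "seminoma") {
    if (!kitMutant)
      beta[layout$residual] <- stats::runif(length(layout$residual), 0.6, 0.9)
  } else if (component == "EC") {
    on <- bg[layout$escMeth[bg]]
    beta[on] <- stats::runif(length(on), 0.8, 0.92)
    beta[layout$poised] <- stats::runif(length(layout$poised), 0.08, 0.2)
    beta[layout$cph] <- .clip01(stats::rnorm(length(layout$cph), 0.25, 0.03))
  } else {  # teratoma / yolk sac: soma-like
    on <- bg[layout$somaMeth[bg]]
    beta[on] <- stats::runif(length(on), 0.8, 0.92)
    gain <- stats::runif(length(layout$poised)) < 0.45
    beta[layout$poised][gain] <- stats::runif(sum(gain), 0.55, 0.75)
    if (stats::runif(1) < 0.6) {
      gp <- layout$dmrProbes[["GNAS"]]
      beta[gp] <- stats::runif(length(gp), 0.7, 0.85)
    }
  }
  if (component != "seminoma" && length(silencedGenes)) {
    for (g in silencedGenes) {
      pp <- layout$promoterProbes[[g]]
      beta[pp] <- stats::runif(length(pp), 0.6, 0.8)
    }
  }
  beta
}

.probeLayout <- function(cfg) {
  P <- cfg$n_probes
  ids <- sprintf("P%05d", seq_len(P))
  nCph <- round(P * cfg$cph_fraction)
  idx <- seq_len(P)
  sig <- idx[seq_len(cfg$n_signature_probes)]
  at <- max(sig)
  cph <- idx[at + seq_len(nCph)]; at <- max(cph)
  dmrNames <- c("GNAS", sprintf("DMR%02d", seq_len(cfg$n_imprinted_dmrs - 1)))
  dmrProbes <- list()
  for (d in dmrNames) {
    dmrProbes[[d]] <- idx[at + seq_len(cfg$probes_per_dmr)]
    at <- max(dmrProbes[[d]])
  }
  promoterProbes <- list()
  for (g in .SILENCING_GENES) {
    promoterProbes[[g]] <- idx[at + seq_len(5)]
    at <- max(promoterProbes[[g]])
  }
  background <- idx[(at + 1):P]
  nBg <- length(background)
  regionBg <- sample(c("poised_promoter", "heterochromatin", "other"), nBg,
                     replace = TRUE, prob = c(0.08, 0.30, 0.62))
  poised <- background[regionBg == "poised_promoter"]
  hetero <- background[regionBg == "heterochromatin"]
  other <- background[regionBg == "other"]

  somaMeth <- logical(P)
  somaMeth[hetero] <- TRUE
  somaMeth[other] <- stats::runif(length(other)) < 0.5
  escMeth <- logical(P)
  escMeth[hetero] <- TRUE
  escMeth[other] <- stats::runif(length(other)) < 0.5

  refBeta <- numeric(P)
  refBeta[sig] <- stats::runif(length(sig), 0.85, 1.0)
  refBeta[cph] <- 0
  for (d in dmrNames) refBeta[dmrProbes[[d]]] <- 0.5
  for (g in .SILENCING_GENES)
    refBeta[promoterProbes[[g]]] <- stats::runif(5, 0.02, 0.08)
  refBeta[poised] <- stats::runif(length(poised), 0.01, 0.08)
  refBeta[background[somaMeth[background]]] <-
    stats::runif(sum(somaMeth[background]), 0.8, 0.95)
  bgUn <- setdiff(background[!somaMeth[background]], poised)
  refBeta[bgUn] <- stats::runif(length(bgUn), 0.01, 0.06)

  region <- rep("other", P)
  region[background] <- regionBg
  for (g in .SILENCING_GENES) region[promoterProbes[[g]]] <- "active_promoter"

  context <- rep("CpG", P)
  context[cph] <- "CpH"

  dmrCol <- rep(NA_character_, P)
  for (d in dmrNames) dmrCol[dmrProbes[[d]]] <- d
  promCol <- rep(NA_character_, P)
  for (g in .SILENCING_GENES) promCol[promoterProbes[[g]]] <- g

  residual <- sample(other, max(1L, round(cfg$residual_fraction * P)))

  probes <- data.frame(probe_id = ids, context = context, region = region,
                       imprinted_dmr = dmrCol,
                       lymphocyte_signature = idx %in% sig,
                       lymphocyte_ref_beta = refBeta,
                       promoter_of_gene = promCol,
                       stringsAsFactors = FALSE)
  list(n_probes = P, ids = ids, probes = probes, signature = sig, cph = cph,
       dmrProbes = dmrProbes, promoterProbes = promoterProbes,
       background = background, poised = poised, somaMeth = somaMeth,
       escMeth = escMeth, residual = residual, refBeta = refBeta)
}

#' Generate a synthetic TGCT cohort with recorded ground truth
#'
#' Draws a full multi-platform cohort under the configuration from
#' [simConfig()]: clinical metadata, arm-level allelic copy number (every
#' sample doubled at least once; i(12p) simulated as extra copies of the
#' major 12p haplotype; samples lacking i(12p) retain at least 4 copies of
#' 12p), somatic mutations with binomially sampled read counts around the
#' expected TVAF \code{m * purity / (CN * purity + 2(1 - purity))}, observed
#' beta values mixed exactly as \code{f * lymphocyte_ref +
#' (1 - f) * tumor_beta}, and a log2 expression matrix (KIT and
#' cancer-testis antigens high in seminoma, immune signature genes scaling
#' with the lymphocyte fraction, silenced tumor suppressors down).
#'
#' KIT mutations occur only in seminomas and are predominantly pre-WGD
#' (multiplicity 2 per doubling); KRAS/NRAS mutations are post-WGD, with
#' KRAS (on 12p) either before/during i(12p) formation (amplified
#' multiplicity) or after it (multiplicity 1). The per-sample and
#' per-mutation truth, the tumor-intrinsic beta matrix before mixing, and
#' the planted silencing flags are returned in the \code{truth} slot.
#'
#' @param config a \code{SimConfig} from [simConfig()].
#' @return a \linkS4class{TGCTCohort}.
#' @examples
#' cohort <- generateCohort(simConfig(n_samples = 8, n_probes = 700,
#'                                    rng_seed = 11))
#' cohort
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "SimConfig"))
    config <- do.call(simConfig, as.list(config))
  cfg <- config
  set.seed(cfg$rng_seed)
  n <- cfg$n_samples
  ids <- sprintf("SIM%04d", seq_len(n))

  histology <- sample(.HISTOLOGIES, n, replace = TRUE,
                      prob = cfg$histology_mix)
  isSem <- histology == "seminoma"

  # component fractions (pathology-style composition)
  frac <- matrix(0, n, length(.COMPONENTS),
                 dimnames = list(ids, .COMPONENTS))
  for (i in seq_len(n)) {
    if (histology[i] == "mixed") {
      comps <- sample(.COMPONENTS, sample(2:3, 1))
      w <- stats::runif(length(comps), 0.2, 1)
      frac[i, comps] <- w / sum(w)
    } else {
      frac[i, histology[i]] <- 1
    }
  }

  kit <- ifelse(isSem & stats::runif(n) < cfg$seminoma_kit_mut_rate,
                "mutant", "wildtype")
  # RAS mutation propensity in seminoma (KIT-mutant seminomas have fewer
  # KRAS mutations); NSGCT essentially never
  pKras <- ifelse(isSem, ifelse(kit == "mutant", 0.16, 0.30), 0)
  pNras <- ifelse(isSem, 0.06, 0)
  hasKras <- stats::runif(n) < pKras
  hasNras <- stats::runif(n) < pNras
  ras <- ifelse(hasKras | hasNras, "mutant", "wildtype")

  # cryptorchidism enriched in dual KIT+RAS mutant seminoma
  dual <- kit == "mutant" & ras == "mutant"
  pCrypt <- ifelse(isSem, ifelse(dual, 0.65, 0.22), 0.08)
  crypt <- ifelse(stats::runif(n) < pCrypt, "yes", "no")

  purity <- ifelse(isSem, .runif2(n, cfg$purity_range_seminoma),
                   .runif2(n, cfg$purity_range_nsgct))
  lymph <- .clip01((1 - purity) + stats::rnorm(n, 0, cfg$lymph_noise_sd))

  # --- genomes ---------------------------------------------------------
  segList <- vector("list", n)
  wgd <- integer(n); i12p <- logical(n); i12k <- integer(n)
  ploidy <- numeric(n)
  w <- .ARM_LENGTHS_MB[.ARMS]
  lostArms <- vector("list", n)
  for (i in seq_len(n)) {
    g <- .simGenome(histology[i], isSem[i], cfg$p_i12p_seminoma,
                    cfg$p_second_wgd)
    segList[[i]] <- data.frame(sample_id = ids[i], arm = .ARMS,
                               major_cn = as.integer(g$major),
                               minor_cn = as.integer(g$minor),
                               stringsAsFactors = FALSE)
    wgd[i] <- g$wgd; i12p[i] <- g$i12p; i12k[i] <- g$k
    lostArms[[i]] <- g$lost
    ploidy[i] <- sum(w * (g$major + g$minor)) / sum(w)
  }
  segs <- do.call(rbind, segList)
  rownames(segs) <- NULL

  # --- mutations -------------------------------------------------------
  mutRows <- list(); truthRows <- list()
  geneCtr <- 0L
  for (i in seq_len(n)) {
    cpgShare <- if (kit[i] == "mutant" && isSem[i]) 0.25 else 0.5
    gene <- character(); arm <- character(); mm <- integer()
    isDriver <- logical()
    if (kit[i] == "mutant") {
      gene <- c(gene, "KIT"); arm <- c(arm, "4q")
      mm <- c(mm, if (stats::runif(1) < 0.7) 2L^wgd[i] else 1L)
      isDriver <- c(isDriver, TRUE)
    }
    if (hasKras[i]) {
      m <- 1L
      if (i12p[i] && stats::runif(1) < 0.4)
        m <- 1L + i12k[i] * (2L^(wgd[i] - 1L))
      gene <- c(gene, "KRAS"); arm <- c(arm, "12p"); mm <- c(mm, m)
      isDriver <- c(isDriver, TRUE)
    }
    if (hasNras[i]) {
      gene <- c(gene, "NRAS"); arm <- c(arm, "1p"); mm <- c(mm, 1L)
      isDriver <- c(isDriver, TRUE)
    }
    nPass <- stats::rpois(1, cfg$mean_mutations)
    if (nPass > 0) {
      pArm <- sample(.ARMS, nPass, replace = TRUE, prob = w)
      pMajor <- segList[[i]]$major_cn[match(pArm, segList[[i]]$arm)]
      pM <- ifelse(stats::runif(nPass) < 0.25, pmin(2L, pMajor), 1L)
      gene <- c(gene, sprintf("GENE%05d", geneCtr + seq_len(nPass)))
      geneCtr <- geneCtr + nPass
      arm <- c(arm, pArm); mm <- c(mm, as.integer(pM))
      isDriver <- c(isDriver, rep(FALSE, nPass))
    }
    if (!length(gene)) next
    sidx <- match(arm, segList[[i]]$arm)
    cn <- segList[[i]]$major_cn[sidx] + segList[[i]]$minor_cn[sidx]
    evaf <- mm * purity[i] / (cn * purity[i] + 2 * (1 - purity[i]))
    depth <- pmax(20L, stats::rpois(length(gene), cfg$mean_depth))
    alt <- stats::rbinom(length(gene), depth, evaf)
    sub <- sample(.SUBSTITUTIONS, length(gene), replace = TRUE,
                  prob = c(0.10, 0.10, 0.40, 0.10, 0.20, 0.10))
    rna <- rep(NA_real_, length(gene))
    rna[isDriver] <- .clip01(alt[isDriver] / depth[isDriver] +
                               stats::rnorm(sum(isDriver), 0, 0.03))
    mutRows[[i]] <- data.frame(
      sample_id = ids[i], gene = gene, arm = arm, alt_count = alt,
      ref_count = depth - alt, tvaf = alt / depth,
      context = .drawContext(sub, cpgShare), substitution = sub,
      rna_vaf = rna, stringsAsFactors = FALSE)
    truthRows[[i]] <- data.frame(
      sample_id = ids[i], gene = gene, arm = arm, true_m = mm,
      total_cn = cn, major_cn = segList[[i]]$major_cn[sidx],
      expected_tvaf = evaf, stringsAsFactors = FALSE)
  }
  muts <- do.call(rbind, mutRows)
  mutTruth <- do.call(rbind, truthRows)
  rownames(muts) <- rownames(mutTruth) <- NULL
  # noise-free timing labels from the true multiplicity
  mutTruth$timing_vs_wgd <- classifyVsWGD(mutTruth$true_m, mutTruth$major_cn,
                                          NA_integer_,
                                          wgd[match(mutTruth$sample_id, ids)])
  mutTruth$timing_vs_i12p <- ifelse(
    mutTruth$arm == "12p" & i12p[match(mutTruth$sample_id, ids)],
    ifelse(mutTruth$true_m >= 2, "before_or_during", "after"), "na")

  # --- methylation -----------------------------------------------------
  layout <- .probeLayout(cfg)
  P <- cfg$n_probes
  tumorBeta <- matrix(0, P, n, dimnames = list(layout$ids, ids))
  silenced <- matrix(FALSE, length(.SILENCING_GENES), n,
                     dimnames = list(.SILENCING_GENES, ids))
  for (i in seq_len(n)) {
    comps <- .COMPONENTS[frac[i, ] > 0]
    rate <- as.numeric(.SILENCING_RATES[.SILENCING_GENES, , drop = FALSE] %*%
                         frac[i, colnames(.SILENCING_RATES)])
    silenced[, i] <- stats::runif(length(.SILENCING_GENES)) < rate
    sg <- .SILENCING_GENES[silenced[, i]]
    acc <- numeric(P)
    for (comp in comps) {
      arch <- .archetypeBeta(comp, kit[i] == "mutant", layout, sg)
      acc <- acc + frac[i, comp] * arch
    }
    tumorBeta[, i] <- acc
  }
  obsBeta <- sweep(tumorBeta, 2, 1 - lymph, `*`) +
    outer(layout$refBeta, lymph)
  bs <- BetaSet(obsBeta, layout$probes)

  # --- expression ------------------------------------------------------
  nsgctFrac <- 1 - frac[, "seminoma"]
  silencedFrac <- sweep(silenced * 1, 2, nsgctFrac, `*`)
  immGenes <- sprintf("IMM_SIG%d_%02d", rep(1:3, each = 10), rep(1:10, 3))
  ctaGenes <- sprintf("CTA_%02d", 1:20)
  hkGenes <- sprintf("HK_%02d", 1:50)
  genes <- c("KIT", "KRAS", "NRAS", .SILENCING_GENES, immGenes, ctaGenes,
             hkGenes)
  expr <- matrix(0, length(genes), n, dimnames = list(genes, ids))
  expr["KIT", ] <- 6 + 5 * frac[, "seminoma"] + 1.5 * (kit == "mutant") +
    stats::rnorm(n, 0, 0.5)
  expr["KRAS", ] <- 8 - 1 * (kit == "mutant") + stats::rnorm(n, 0, 0.5)
  expr["NRAS", ] <- 8 + stats::rnorm(n, 0, 0.5)
  for (g in .SILENCING_GENES)
    expr[g, ] <- 9 - 5 * silencedFrac[g, ] + stats::rnorm(n, 0, 0.4)
  for (g in immGenes) expr[g, ] <- 6 + 5 * lymph + stats::rnorm(n, 0, 0.3)
  for (g in ctaGenes)
    expr[g, ] <- 6 + 4 * frac[, "seminoma"] + stats::rnorm(n, 0, 0.5)
  hkBase <- stats::rnorm(length(hkGenes), 8, 1)
  for (j in seq_along(hkGenes))
    expr[hkGenes[j], ] <- hkBase[j] + stats::rnorm(n, 0, 0.3)

  meta <- data.frame(sample_id = ids, histology = histology,
                     frac_seminoma = unname(frac[, "seminoma"]),
                     frac_EC = unname(frac[, "EC"]),
                     frac_teratoma = unname(frac[, "teratoma"]),
                     frac_yolk_sac = unname(frac[, "yolk_sac"]),
                     kit_status = kit, ras_status = ras,
                     cryptorchidism = crypt, purity = purity,
                     ploidy = ploidy, stringsAsFactors = FALSE,
                     row.names = NULL)

  truth <- list(
    samples = data.frame(sample_id = ids, true_purity = purity,
                         true_lymph_fraction = lymph, wgd_count = wgd,
                         i12p_present = i12p, i12p_extra_copies = i12k,
                         ec_fraction = frac[, "EC"],
                         ploidy = ploidy, stringsAsFactors = FALSE),
    mutations = mutTruth,
    tumorBeta = tumorBeta,
    lymphocyteRef = stats::setNames(layout$refBeta, layout$ids),
    silenced = silenced,
    lostArms = stats::setNames(lostArms, ids),
    immuneSignatures = split(immGenes, rep(paste0("SIG", 1:3), each = 10))
  )
  new("TGCTCohort", sampleMeta = meta, segments = segs, mutations = muts,
      beta = bs, expression = expr, truth = truth)
}

#' Write all cohort tables to a directory
#'
#' Serializes a \linkS4class{TGCTCohort} as the TSV bundle the readers in
#' this package consume (sample_meta, segments, mutations, beta matrix,
#' probe annotation, expression), plus the simulation truth as JSON when
#' present.
#'
#' @param cohort a \linkS4class{TGCTCohort}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSampleMeta(sampleMeta(cohort), file.path(dir, "sample_meta.tsv"))
  writeSegments(segments(cohort), file.path(dir, "segments.tsv"))
  writeMutations(mutations(cohort), file.path(dir, "mutations.tsv"))
  writeMatrix(betaValues(betaSet(cohort)), file.path(dir, "beta.tsv"))
  writeProbeAnnotation(probeInfo(betaSet(cohort)),
                       file.path(dir, "probes.tsv"))
  writeMatrix(exprMatrix(cohort), file.path(dir, "expression.tsv"))
  tr <- cohortTruth(cohort)
  if (length(tr)) {
    tr$lostArms <- lapply(tr$lostArms, as.list)
    jsonlite::write_json(
      list(samples = tr$samples, mutations = tr$mutations,
           silenced = as.data.frame(tr$silenced)),
      file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}
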