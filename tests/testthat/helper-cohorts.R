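# Shared simulated fixtures, generated once per test run and cached.

.cohortCache <- new.env(parent = emptyenv())

# Study-scale cohort under the default archetype parameters.
defaultCohort <- function() {
  if (is.null(.cohortCache$default))
    .cohortCache$default <- generateCohort(simConfig(rng_seed = 101))
  .cohortCache$default
}

# Small, fast cohort for structural tests (probe layout minimized).
smallCohort <- function(seed = 7, n = 12) {
  key <- sprintf("small_%d_%d", seed, n)
  if (is.null(.cohortCache[[key]]))
    .cohortCache[[key]] <- generateCohort(
      simConfig(n_samples = n, n_probes = 700, rng_seed = seed))
  .cohortCache[[key]]
}

# Minimal valid probe-annotation rows for hand-built BetaSets.
makeProbes <- function(probe_id, context = "CpG", region = "other",
                       imprinted_dmr = NA_character_,
                       lymphocyte_signature = FALSE,
                       lymphocyte_ref_beta = NA_real_,
                       promoter_of_gene = NA_character_) {
  data.frame(probe_id = probe_id, context = context, region = region,
             imprinted_dmr = imprinted_dmr,
             lymphocyte_signature = lymphocyte_signature,
             lymphocyte_ref_beta = lymphocyte_ref_beta,
             promoter_of_gene = promoter_of_gene,
             stringsAsFactors = FALSE)
}
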