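---
title: "Inference methods for testicular germ cell tumor genomics"
author: "TGCTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference methods for testicular germ cell tumor genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

TGCTools implements the bespoke inference layer used in integrated molecular
studies of testicular germ cell tumors (TGCTs): timing somatic mutations
relative to whole-genome doubling (WGD) and isochromosome 12p formation,
calling arm-level allelic copy-number events, deconvolving the
lymphocyte/tumor methylation mixture that dominates seminoma methylomes,
scoring non-CpG (CpH) methylation, calling promoter epigenetic silencing,
and the cohort statistics behind the KIT-mutant seminoma subtype. Purity and
ploidy estimation from raw data (the ABSOLUTE problem), focal-event
discovery, significance analysis of mutated genes and unsupervised
clustering are deliberately out of scope: purity, allelic integer copy
number and beta values are *inputs*.

Because the real cohort is controlled-access, the package ships a
first-class synthetic cohort generator whose defaults encode the published
cohort archetypes, with full ground truth recorded. Every analysis stage is
validated against that truth.

# The multiplicity model

For a clonal somatic mutation observed at tumor variant allele fraction
(TVAF) in a tumor of purity $\alpha$ with local total copy number $CN$, the
expected fraction of reads carrying the variant is
$m\alpha / (CN\,\alpha + 2(1-\alpha))$, where $m$ is the number of mutated
copies per tumor cell. Inverting gives the **mutation multiplicity**

$$ s_q = \mathrm{TVAF}\cdot\frac{CN\,\alpha + 2(1-\alpha)}{\alpha}. $$

`computeMultiplicity()` evaluates this exactly; `expectedTvaf()` is its
inverse and doubles as the simulation oracle (the round trip is exact to
machine precision, asserted at 1e-12 in the tests).

**Timing relative to WGD.** A genome doubling duplicates every allele, so a
mutation already present on the duplicated haplotype surfaces at $m \ge 2$,
while a mutation acquired afterwards stays at $m = 1$. `classifyVsWGD()`
rounds $s_q$ to the nearest integer $m^\*$ and calls `before_wgd` when
$m^\* \ge 2$ (and $m^\*$ does not exceed the major allele count) or
`after_wgd` when $m^\* = 1$. Multiplicities further than a tolerance (0.35
by default) from any integer **abstain** as `ambiguous`. The tolerance is a
design choice: at a mean sequencing depth of 120 the binomial noise on TVAF
propagates to a standard deviation of roughly 0.15-0.25 on $s_q$ at typical
purities, so a 0.35 band leaves wrong *confident* calls (an error of more
than 0.65) rare while abstaining on the noisy middle. We treat abstention
as the analysis's analogue of the "unable to infer the order of events"
samples of real cohorts: accuracy is therefore reported over confident
calls, with the abstention rate alongside (about 5-7% at depth 120 on the
default cohort). Timing inference additionally skips samples with purity
below 0.3 (configurable `minPurity`), mirroring the exclusion of low-purity
tumors from copy-number-based inference in practice.

**Timing relative to i(12p).** The isochromosome duplicates 12p on one
haplotype, so for 12p mutations in i(12p) carriers, $m^\* \ge 2$ implies the
mutation existed before or during isochromosome formation and $m^\* = 1$
implies it arose after, on either allele (`classifyVsI12p()`; KRAS sits on
12p, which is what makes this readout interesting).

**Clonality.** The cancer cell fraction is $s_q / \max(1, m^\*)$ capped at
1. A mutation is `clonal` at CCF $\ge 0.8$ with DNA/RNA VAF concordance
(within 0.2 when RNA is available), `subclonal` when the Clopper-Pearson
interval of the VAF at the observed depth keeps the CCF below 0.8, and
`unknown` otherwise — low depth cannot force a subclonal call.

# Arm-level copy-number calls

All copy-number reasoning is arm-granular over 41 arms (acrocentric short
arms excluded); fractions and ploidy are weighted by approximate hg38 arm
lengths.

* **WGD count** (`inferWGD()`): once-doubled when the length-weighted
  fraction of arms with major allele count $\ge 2$ exceeds 0.5, upgraded to
  twice-doubled when the fraction with major count $\ge 3$ also exceeds
  0.5. This is the standard major-allele-fraction convention; the
  thresholds are conventions, not fitted values.
* **i(12p)** (`detectI12p()`): present when 12p has at least one more total
  copy *and* one more major-haplotype copy than 12q. Requiring the major
  excess distinguishes an isochromosome from balanced whole-chromosome
  gains. 12q LOH is reported when the 12q minor count is zero.
* **Arm events** (`callArmEvents()`): total copy number compared to the
  rounded ploidy; $\pm 1$ copy calls gain/loss.
* **Event ordering** (`orderArmEvents()`): for each recurrent event in a
  group, `timing_score = freq / (1 + median carrier burden)` where burden
  is the carrier's count of non-neutral arms. An event found in most
  samples including low-aneuploidy genomes scores high (inferred early); an
  event confined to heavily rearranged genomes scores low (inferred late).
  The exact statistic used in the original study is not published; this
  concrete instantiation of the frequency-plus-aneuploidy idea is isolated
  behind one function so it can be replaced, and only *rank* behaviour is
  treated as contractual (tested by simulation: a planted early event
  outranks a planted late one in more than 95% of replicates). Ties break
  by higher frequency, then arm name — determinism over elegance.

# Methylation deconvolution

Seminomas are heavily infiltrated by lymphocytes, and nearly all of their
bulk methylation signal is lymphocytic. We model each probe as a
two-component mixture

$$ \beta_{obs} = f\,\beta_{lymph} + (1-f)\,\beta_{tumor}, $$

with a single per-sample lymphocyte fraction $f$.

* **Estimation** (`estimateLymphocyteFraction()`): LUMP-style ratio of
  means over signature probes that are methylated in lymphocytes and
  unmethylated in tumor: $f = \text{mean}(\beta_{obs}) /
  \text{mean}(\beta_{ref})$, clipped to $[0,1]$. At least 20 usable probes
  are required. The estimator is deliberately simple and isolated behind
  one function; reference-based multi-cell-type deconvolution is a
  non-goal.
* **Correction** (`correctBeta()`): the exact mixture inverse
  $(\beta_{obs} - f\beta_{ref})/(1-f)$, clipped to $[0,1]$. Negative mass
  before clipping diagnoses an overestimated $f$. Numerically the
  inversion is exact to 1e-12 for $f \le 0.99$; as $f \to 1$ the division
  amplifies machine epsilon without bound (and $f = 1$ is a domain error —
  no tumor signal remains), so tests assert an absolute bound up to 0.99
  and a relative bound beyond.
* **Density summaries** (`densitySummary()`): Gaussian KDE with bandwidth
  0.03 on the beta scale, boundary-corrected by reflecting the sample at 0
  and 1 (betas pile up at both boundaries and an uncorrected KDE leaks
  mass outside the unit interval). Modes are local maxima with topographic
  prominence of at least 5% of the peak density — plain local maxima would
  count noise ripples.
* **Residual methylation** (`residualMethylationFraction()`): a probe is
  recurrently methylated when corrected beta $\ge 0.3$ in $\ge 10\%$ of
  samples. Thresholds are arguments with these defaults; the source
  studies state outcomes ("under 1% of sites"), not cutoffs.
* **CpH score** (`cphScore()`): mean corrected beta over CpH probes, with
  lymphocyte CpH reference fixed at 0 (somatic cells have essentially no
  CpH methylation). CpH methylation is an embryonic-stem-cell hallmark
  re-established in embryonal carcinoma; across a cohort the score tracks
  the EC component fraction.
* **Imprinting** (`imprintingSurvey()`): mean corrected beta per imprinted
  DMR, banded as erased (< 0.15), biparental ([0.35, 0.65], the somatic
  parent-of-origin pattern), methylated (> 0.65); the gap is assigned the
  nearest state and flagged rather than silently binned.
* **Silencing** (`callEpigeneticSilencing()`): methylated promoter
  (corrected beta $\ge 0.3$) *and* expression at or below the 25th
  percentile of the gene's unmethylated reference samples (promoter beta
  < 0.1). Genes with no unmethylated reference cannot anchor the
  expression contrast and return unknown.

# Cohort statistics

Spectrum profiles report the six pyrimidine-centred substitution fractions
and the fraction of all mutations that are C>T at CpG (the
5-methylcytosine-deamination channel; globally demethylated genomes starve
it, which is why KIT-mutant seminomas are depleted). The odds ratio is the
sample $ad/bc$ with a Wald CI and Haldane 0.5 correction only when a cell
is zero; the chi-square is uncorrected Pearson by default (the corrected
variant is a flag). Mann-Whitney tests are exact up to group size 20
without ties and tie-corrected normal approximations otherwise. The
dual-mutation-by-cryptorchidism table can be rebuilt from any cohort's
metadata (`dualMutationCryptTable()`); for the published counts two
documented denominator presets exist (`cryptorchidismTable()`), because the
printed numbers leave the non-dual denominator ambiguous between a
sample-level (66 known) and patient-level (68 known) reading — they yield
odds ratios of 7.23 and 7.54 respectively. No multiple-testing machinery is
applied by default; the in-scope claims are single targeted comparisons
(`bhAdjust()` is provided for batch use).

# The synthetic cohort generator

`generateCohort()` draws, per sample: histology from the 72:27:16:13:9
cohort mix; purity Uniform(0.2, 0.8) for seminoma versus Uniform(0.4, 0.95)
for NSGCT; lymphocyte fraction $(1-\text{purity}) + N(0, 0.03)$ clipped to
$[0,1]$; one guaranteed WGD with a second at probability 10/131; post-WGD
arm losses at histology-specific rates (11q in seminoma; 19q, 15, 22, 19p,
10q, 8p, 2q, 8q in NSGCT) tuned so ploidy medians land near 3.1 (seminoma)
versus 2.8 (NSGCT); i(12p) in every NSGCT and 80% of seminomas, simulated
as 1-3 extra copies of the major 12p haplotype with 12q untouched — so
i(12p)-negative genomes retain the 4 post-WGD copies of 12p. KIT mutations
(seminoma only, rate 25/72) are pre-WGD with probability 0.7; KRAS/NRAS
are post-WGD, with KRAS on 12p placed before/during i(12p) formation with
probability 0.4 (multiplicity amplified by the isochromosome) and after it
otherwise. Read counts are binomial around the expected TVAF at
Poisson(120) depth. The C>T share of the spectrum is 0.40 with a CpG
context share of 0.5, halved to 0.25 in KIT-mutant seminoma to emulate the
signature-1 depletion.

Methylomes are built from per-component archetypes (KIT-mutant seminoma
fully unmethylated; KIT-wild-type seminoma with a shared residual set of
0.5% of probes — the "under 1% of sites" statement quantifies recurrence,
not the set size, so the set size is a free parameter fixed once at 0.5%;
EC with ESC-like CpG bimodality plus CpH means of 0.25 scaled by the EC
fraction; teratoma/yolk sac soma-like with poised-promoter gains and
planted tumor-suppressor silencing at the histology-specific rates), then
mixed *exactly* with the lymphocyte reference at fraction $f$ — the
emitted matrix reproduces the mixture to the last bit, which is what makes
the deconvolution recovery tests sharp. Expression encodes KIT and
cancer-testis antigens high in seminoma, immune signature genes linear in
$f$, and silenced suppressors down.

One RNG stream is seeded from the config, so identical configs give
identical cohorts; the generator controls sample order internally, which
is why no per-sample substream machinery is needed.

**What the simulation does not emulate** — and hence what passing tests do
not show about real data: array measurement noise and batch effects on
beta values (the mixture is exact), sub-arm copy-number structure, focal
amplifications, subclonal mutations and copy-number heterogeneity,
trinucleotide-complete mutational signatures, and real lymphocyte
signature probe sets. Recovery results on this cohort validate the
*inference logic*, not robustness to array noise.

# Problem sizes and reproducibility

The shipped tests and the acceptance script use the default study-scale
cohort (120 samples, 5000 probes, about 1800 mutations, mean depth 120),
smaller 700-probe cohorts for structural checks, 1000-triple round-trip
properties, and 40-100 seeded replicates for rejection-rate and
rank-ordering properties — sizes chosen to give stable statistics at
interactive runtimes. `fullRun()` executes the entire pipeline from a YAML
or programmatic config and writes byte-identical TSV/JSON output for a
fixed seed, with every threshold echoed into the report's provenance
block.

# Known limitations

Arm-granular copy number means mutation multiplicity uses the arm's total
copy number, which is wrong inside focal events; the i(12p) rule cannot
see isochromosomes balanced by 12q gains; the WGD thresholds misclassify
extreme near-tetraploid-with-massive-loss genomes; the two-component
mixture cannot separate multiple immune cell types; and the timing-score
ordering is a heuristic whose scores have no calibrated scale — only ranks
are meaningful.
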