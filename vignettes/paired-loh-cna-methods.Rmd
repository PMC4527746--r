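---
title: "Methods: paired LOH/CNA calling and the survival screen"
author: "lohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired LOH/CNA calling and the survival screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohscan)
```

# Overview

`lohscan` analyzes paired tumor/blood SNP-array data from cancer cohorts
(the package's defaults emulate an HPV-negative oral squamous cell
carcinoma study design: 75 patients, cause-specific follow-up, paired
genotype calls and copy-number signal per probe). The pipeline has five
stages:

1. **LOH calling** from paired genotype calls,
2. **copy-number segmentation** of the paired signal and **empirically
   FDR-controlled gain/loss calling**,
3. **joint LOH-by-CNA classification** (copy-neutral LOH, high-level
   amplification),
4. **landscape summaries** (consensus frequencies, per-sample burden,
   chromosome-arm large-region events),
5. **association analyses**: hierarchical clustering with Fisher-exact
   covariate tests and log-rank mortality comparison, and a genome-wide
   per-probe Cox proportional-hazards screen with a CNA-by-LOH
   interaction.

A synthetic-cohort generator with recorded ground truth backs the test
suite; every stage is validated against either exact hand-computable cases
or an independent oracle.

# LOH calling

A probe is *informative* in a patient when the blood (germline) call is
heterozygous and both calls are present. The call rule is purely
definitional: blood `AB` with tumor homozygous is LOH; blood `AB` with
tumor `AB` is retained heterozygosity; anything else (homozygous germline,
or a no-call in either tissue) is non-informative — a germline-homozygous
locus cannot lose heterozygosity observably, and a no-call carries no
evidence either way. Probes non-informative in *every* sample are excluded
before downstream analysis; this is the coherent reading of excluding
SNPs that cannot evidence LOH in any patient (an alternative literal
reading — excluding SNPs homozygous in all *tumors* — would also discard
probes with universal LOH, and is deliberately not implemented).

Per-probe LOH frequency divides by the informative samples at that probe
by default; a probe with no informative samples yields a missing value,
not zero. An `"all"`-samples denominator is provided because consensus
figures in the literature are often computed both ways.

# Copy-number segmentation

Allele-specific likelihood smoothing of raw intensities is out of scope;
the package consumes an already-estimated per-probe copy-number signal and
replaces model-based smoothing with **recursive binary segmentation** on
the paired difference `d = tumor − blood`. At each step the candidate
split maximizes the pooled-variance two-sample t-statistic between the
flanks; it is accepted iff `|t| > 4.0` and both children have at least 10
probes. Ties go to the left-most split, so segmentation is deterministic.
The downstream calling rules only consume per-probe *segmented* values, so
any reasonable segmenter can stand here; the defaults (`t_threshold = 4`,
`min_seg_len = 10`) are conservative enough that a diploid chromosome is
rarely split while a 10-probe single-copy event is still detectable at the
package's default noise level.

Both tissues pass through the identical procedure: the tumor against its
matched blood, and the blood against the constant diploid reference 2.
That symmetry is what makes the blood usable as a null.

Numerical notes: residual sums of squares are clamped at zero against
floating-point cancellation; a zero pooled variance with unequal flank
means is treated as an infinite t (noise-free step functions split
exactly); a chromosome shorter than `min_seg_len` yields a single segment
with a warning.

# Empirical FDR calling of gains and losses

The blood genome of a cancer patient is assumed free of *somatic* copy
number change, so any blood probe whose segmented deviation from 2 exceeds
a magnitude cutoff is a false discovery of the calling rule. For each
subject and cutoff `c`:

- blood count = number of probes with |segmented blood − 2| ≥ c,
- tumor count = number of probes with |segmented tumor − blood| ≥ c,
- subject FDR = blood count / tumor count (defined as 0 when the tumor
  count is 0 — no discoveries, hence no false discoveries — and capped at
  1 for reporting).

The pipeline selects the **smallest** cutoff on a grid (default 0.05 to
2.0 by 0.05 on the CN scale) whose **cross-subject mean** FDR is at or
below the 10% target. One global cutoff is the default because an
average-level target is a statement about the cohort; a per-subject mode
is available since the per-subject FDRs at a shared cutoff legitimately
vary (typically a 0–12%-style range). Final calls: `GAIN` at delta ≥
cutoff, `LOSS` at delta ≤ −cutoff; high-level amplification is flagged at
delta ≥ 5 (tumor-minus-blood copies).

Joint classification crosses the LOH status with the CNA class into seven
total classes; LOH with neutral copy number is copy-neutral LOH (one
allele lost, the other duplicated), and non-informative LOH dominates the
joint label.

# Landscape statistics

Consensus fractions per probe feed two strict tiers: *frequent* (> 20% of
samples) and *extremely frequent* (> 80%); a *large-region* arm event
requires LOH/gain/loss at strictly more than 50% of the arm's probes in a
sample. All three thresholds are strict inequalities, matching the ">"
convention used throughout this literature. Arm membership comes from the
annotation file only; the package has no internal centromere table, which
keeps it platform-agnostic. LOH denominators follow the LOH module's
default (informative samples); gain/loss use all samples.

# The survival screen

For each probe with LOH in at least 5 patients (strictly fewer are
excluded before testing), three Cox proportional-hazards models are fit
with Efron tie handling: covariates only (sex, age, smoking), covariates
plus CNA and LOH main effects, and the full model adding the
multiplicative CNA-by-LOH interaction. Two nested likelihood-ratio tests
are reported per probe: the joint 3-df test of all genomic terms (full vs
covariates-only) and the 1-df interaction test (full vs main effects).

Coding choices: CNA enters as a ternary code (gain +1, neutral 0, loss
−1), which preserves the sign semantics of "direction of CNA
association" tables; a continuous segmented-delta mode is provided.
Non-informative LOH codes to 0 (no evidence of LOH) so that the risk set
does not change probe by probe. Age is continuous; smoking has three
levels with never-smokers as reference. Deaths from other causes are
censored at the death time (cause-specific hazards).

The CNA effect sign is reported per LOH stratum — `beta_CNA` without LOH
and `beta_CNA + beta_interaction` with LOH — so opposite-sign interactions
(gain deleterious only on an LOH background) are directly visible. Fits
with suspected monotone likelihood (coefficients or standard errors beyond
|beta| > 12 or se > 100 on the log-hazard scale) are reported with
*undetermined* signs rather than dropped.

Multiplicity: the Bonferroni flag uses 0.05 divided by the number of
probes actually tested; Storey q-values (pi0 estimated at lambda = 0.5,
capped at 1) are computed separately for the joint and interaction p-value
families, since pooling families with different null behavior would bias
pi0.

Small-sample behavior: partial-likelihood LRTs rely on a chi-square
approximation. At desk scale (tens of events against an 8-parameter full
model) the 1-df interaction test is mildly anti-conservative; the
calibration check in the test suite therefore runs at 300 patients per
cohort — 2,000 independent probe-tests — where the approximation holds,
and the package makes no claim that nominal level is exact at 75 patients
with ~24 events. Screens at that scale should be read through the
Bonferroni/q-value lens, as the published analyses of this design do.

# Clustering and association

Samples are clustered hierarchically with complete linkage and cut into
exactly two groups (every analysis this design supports compares two
groups). LOH features are binary indicators with Jaccard distance — two
samples are close when they share LOH loci, and co-absence is
uninformative; CNA features are segmented deltas with Euclidean distance,
which respects magnitude. Neither choice is canonical; both are exposed as
configuration. All-identical samples yield a flagged single-cluster
result instead of an arbitrary split.

Cluster-covariate association uses the exact conditional Fisher test
(full enumeration for small tables; a seeded Monte-Carlo mode covers
tables too large to enumerate). Mortality comparison censors competing
deaths and reports cumulative incidence as 1 − Kaplan–Meier per cluster
with a two-group log-rank test; a true competing-risks (Aalen–Johansen)
estimator is deliberately out of scope — with competing deaths censored,
1 − KM mildly overstates absolute incidence but leaves the log-rank test
of the cause-specific hazard untouched, which is the inferential quantity
here. A Cox variant (`cluster_covariate_cox`) tests the cluster term by
LRT with configurable adjusters (e.g. adding stage).

# The synthetic cohort generator

The generator is first-class, tested code; it defines the conditions under
which every downstream claim is validated.

* **Scale and layout**: 75 samples and 5,000 probes over four synthetic
  autosomes with p/q arms, mirroring the study scale at desk size.
* **Genotypes**: per-probe i.i.d. calls, heterozygous at rate 0.30 (a
  typical genome-wide SNP-array het rate), no-calls at 0.002. Linkage
  disequilibrium is deliberately not modeled: no downstream operation
  consumes haplotype structure. The no-call rate is a package addition so
  the non-informative path is exercisable end to end.
* **Aberrations**: implanted segment templates covering all six classes
  (LOH with loss/neutral/gain, pure gain, pure loss, high-level
  amplification at CN 7). The default landscape includes a focal 85-probe
  amplicon carried by 20% of samples and several arm-scale events with
  carrier fractions 0.2–0.45, echoing the mix of focal amplification and
  arm-level events seen in these tumors. Ground-truth LOH is recorded at
  blood-heterozygous loci only — LOH is only an observable event where the
  germline is heterozygous, and the conservation identity (LOH count =
  carriers × blood-het probes per segment) holds by construction.
  Overlapping templates are contradictory iff they imply different copy
  numbers in the same sample; LOH flags combine by union.
* **Signal**: Gaussian noise (sd 0.35 on the CN scale) on both tissues,
  the simplest family that exercises the segmentation and FDR machinery;
  an optional purity parameter shrinks the tumor signal toward 2 (no
  study value exists to default to, so the default is 1).
* **Genotype error**: zygosity flips at rate 0.01 applied to tumor calls
  after implantation, so the false-LOH rate at informative probes equals
  the error rate — a property the tests verify by simulation.
* **Survival**: exponential cause-specific baseline (0.004/month) scaled
  by `exp(lp)`, where `lp` adds configured genomic effects at designated
  probes (using the true ternary CNA code and the true LOH indicator) to
  covariate effects; competing other-cause death (0.005/month) and
  uniform administrative censoring on 33–111 months. These rates were
  chosen so a default cohort experiences roughly 24 tumor-specific and 16
  other deaths among 75 patients — the event mix of the emulated design.

What the generator does **not** emulate: raw allele intensities and
genotype-caller behavior, LD, GC/wave artifacts in the CN signal,
subclonal mosaicism, and platform-specific probe quality. Passing tests
therefore demonstrate the correctness of the calling rules, the FDR
machinery, and the inference code under the stated noise model — not
robustness to array artifacts, which an analysis of real arrays must
assess upstream.

# Reproducibility and problem sizes

Every random draw flows from one integer seed per configuration (fixed
per-stage offsets give each generator stage its own substream), so each
artifact is a pure function of its configuration. The validation suite
uses: 20 cohorts of 75 × 5,000 for the FDR-control check; 20 cohorts of
300 patients × 100 i.i.d. probes (2,000 tests) for type-I calibration; 50
replicates of 300 patients for interaction sign recovery; exact
hand-worked examples (6-patient log-rank risk table, 4-sample complete
linkage, 2×2 hypergeometric enumeration, 8-patient partial likelihood)
for the oracle checks.

# Known limitations

* Call-based LOH (no B-allele-fraction modeling): copy-neutral LOH is
  detected only at germline-heterozygous probes, so per-probe LOH
  covariates in the screen are sparse in patients homozygous at that
  probe.
* Sex chromosomes are not handled; the diploid blood reference is 2
  everywhere (autosomes only).
* The segmenter is a change-point method on the total CN difference; it
  does not estimate parental/allele-specific copy number.
* The two-group log-rank comparison uses 1 − KM for display; absolute
  cumulative incidence under competing risks is modestly overstated.
* With tens of events, likelihood-ratio p-values near the Bonferroni
  threshold should be treated as ranking devices rather than calibrated
  tail probabilities.
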