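# lohscan

Paired tumor–blood SNP-array analysis of loss of heterozygosity (LOH) and
DNA copy number aberration (CNA), with genomic landscape statistics and a
genome-wide survival screen.

`lohscan` is for cancer-genomics analysts working with paired
tumor/germline genotyping arrays — the setting of HPV-negative oral
squamous cell carcinoma cohorts, where tumor cells are compared against
the patient's own blood DNA to separate somatic events from germline
variation. The package consumes post-genotyping data (genotype-call
matrices and per-probe copy-number signal for both tissues, a probe
annotation, and a clinical table with cause-specific follow-up) and
produces per-probe, per-patient calls, cohort-level summaries, and
survival associations.

## What it computes

**LOH calling.** At a probe where the blood call is heterozygous, a
homozygous tumor call is LOH; a heterozygous tumor call is retained; a
homozygous blood call or a no-call in either tissue is non-informative.
Probes non-informative in every patient are excluded.

**Empirically FDR-controlled CNA calling.** The paired signal difference
*d* = tumor − blood is segmented per chromosome by recursive binary
segmentation (splits accepted at |t| > 4 with ≥ 10 probes per child); the
blood is segmented identically against its diploid reference. Treating
blood as free of somatic change, the false discovery rate of a magnitude
cutoff *c* is estimated per subject as

    FDR(c) = #{probes: |bloodSeg − 2| ≥ c} / #{probes: |tumorSeg − 2| ≥ c}

and the final gain/loss cutoff is the smallest grid value whose
cross-subject mean FDR is ≤ 10%. Calls: GAIN at Δ ≥ *c*, LOSS at Δ ≤ −*c*,
high-level amplification at Δ ≥ 5. Crossing LOH with CNA yields the seven
joint classes, including copy-neutral LOH.

**Landscape statistics.** Consensus per-probe frequencies with *frequent*
(> 20% of samples) and *extremely frequent* (> 80%) tiers; per-sample
aberration burden; chromosome-arm *large-region* events (> 50% of arm
probes); annotated top-*k* tables.

**Survival screen.** For every probe with LOH in ≥ 5 patients, Cox
proportional-hazards models of cause-specific death adjusted for sex, age
and smoking:

    h(t | x) = h0(t) · exp(β_CNA·CNA + β_LOH·LOH + β_int·CNA·LOH + γ'z)

with CNA coded −1/0/+1, and two nested likelihood-ratio tests per probe:
the joint 3-df test of (CNA, LOH, CNA:LOH) and the 1-df interaction test.
The CNA effect sign is reported per LOH stratum (β_CNA without LOH,
β_CNA + β_int with LOH), with Bonferroni flags and Storey q-values.

**Clustering and association.** Complete-linkage hierarchical clustering
of samples (Jaccard distance on binary LOH, Euclidean on segmented CNA)
into two groups; Fisher exact tests against categorical covariates;
cumulative incidence (1 − Kaplan–Meier) with a log-rank test, and a Cox
LRT for the cluster term with configurable adjusters.

**Synthetic cohorts.** A generator with recorded ground truth implants
LOH/CNA segments of all six classes into paired genotype + signal
matrices and simulates proportional-hazards survival tied to designated
probes — the basis of the validation suite.

## Worked example

Simulate a 75-patient cohort with the default aberration landscape plus a
region where copy-number gain and LOH vary independently, and a planted
opposite-sign interaction at probe `P04140` (gain lowers the hazard
without LOH, β_CNA = −1.2, and raises it with LOH, β_CNA + β_int = +1.2):

```r
library(lohscan)

extra <- list(
  aberration("chr4", 100L, 180L, "LOH_gain",    carriers = 1:20),
  aberration("chr4", 100L, 180L, "gain_only",   carriers = 21:40),
  aberration("chr4", 100L, 180L, "LOH_neutral", carriers = 41:60))
sp  <- survival_spec(effect_probes = 4140L, beta_cna = -1.2,
                     beta_loh = 0.4, beta_interaction = 2.4)
cfg <- cohort_config(aberration_spec = c(default_aberrations(), extra),
                     survival_spec = sp, seed = 1L)
cohort <- simulate_cohort(cfg)

seg <- segment_cohort(cohort$tumor_signal, cohort$blood_signal, cohort$annotation)
sel <- select_cutoff(estimate_fdr_curve(seg$tumor_delta, seg$blood_delta),
                     target = 0.10)
callset <- build_callset(call_loh(cohort$blood_genotype, cohort$tumor_genotype),
                         call_cna(seg$tumor_delta, sel$cutoff))
scr <- screen(callset, cohort$clinical)
```

The cutoff selection and joint classification print:

```
chosen cutoff: 0.05   mean estimated FDR: 0.0133
   CN_GAIN_LOH    CN_LOSS_LOH CN_NEUTRAL_LOH
          1644           5763           3819
```

i.e. at the chosen magnitude cutoff the blood-null procedure estimates
1.3% of tumor calls to be false (well under the 10% target), and LOH
events split into gain-LOH, loss-LOH and copy-neutral-LOH as implanted.
Per-sample burden (mean ± sd): LOH 10.0 ± 6.3%, CNA 13.2 ± 8.1% of
probes. The screen tests 813 probes (those with LOH in ≥ 5 patients); the
effect probe's row recovers the planted pattern:

```
 probe_id beta_cna beta_interaction   p_all p_interaction sign_no_loh sign_loh
   P04140     -1.3             2.59 0.00212       0.00802           -        +
```

— the fitted log hazard ratios are within one standard error of the
implanted −1.2 / +2.4, and the per-stratum direction of the CNA effect
(protective without LOH, deleterious with LOH) is recovered; at this
cohort size the probe ranks 5th of 813 by interaction p-value, which is
the realistic power of a 75-patient screen.

The whole chain — including landscape tables, clustering and the written
output directory with a manifest — also runs as one call:

```r
res <- run_pipeline(list(cohort = cfg, seed = 1L, outdir = "run1"))
```

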