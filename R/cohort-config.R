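#' Implanted aberration template
#'
#' Describes one aberrant segment to implant into the tumor genomes of a
#' synthetic cohort. Coordinates are 1-based probe indices *within* the
#' chromosome. Carriers may be given either as a fraction of the cohort
#' (sampled without replacement) or as explicit sample indices.
#'
#' The six types realize every LOH-by-copy-number combination the joint
#' classifier distinguishes: `LOH_loss` (LOH with one copy lost, tumor CN 1),
#' `LOH_neutral` (copy-neutral LOH, CN 2), `LOH_gain` (LOH with gain, CN 3),
#' `gain_only` (CN 3, heterozygosity retained), `loss_only` (CN 1),
#' and `high_amp` (high-level amplification, tumor minus blood CN >= 5,
#' implanted as CN 7).
#'
#' @param chrom Chromosome label, must appear in the cohort's layout.
#' @param start,end First and last probe index covered (within-chromosome,
#'   inclusive).
#' @param type One of `"LOH_loss"`, `"LOH_neutral"`, `"LOH_gain"`,
#'   `"gain_only"`, `"loss_only"`, `"high_amp"`.
#' @param carrier_fraction Fraction of samples carrying the segment, in
#'   (0, 1]. Ignored when `carriers` is given.
#' @param carriers Optional integer vector of carrier sample indices.
#' @param defines_cluster Logical; carriers of cluster-defining segments make
#'   up ground-truth cluster 2 (used for planted-partition scenarios).
#' @return A list of class `"lohscan_aberration"`.
#' @export
aberration <- function(chrom, start, end, type,
                       carrier_fraction = NULL, carriers = NULL,
                       defines_cluster = FALSE) {
  types <- c("LOH_loss", "LOH_neutral", "LOH_gain",
             "gain_only", "loss_only", "high_amp")
  if (!is.character(chrom) || length(chrom) != 1L)
    .config_err("aberration 'chrom' must be a single chromosome label")
  start <- .check_count(start, "aberration start")
  end <- .check_count(end, "aberration end")
  if (end < start)
    .config_err("aberration on %s has end (%d) < start (%d)", chrom, end, start)
  if (!type %in% types)
    .config_err("aberration 'type' must be one of: %s",
                paste(types, collapse = ", "))
  if (is.null(carriers)) {
    if (is.null(carrier_fraction))
      .config_err("aberration needs 'carrier_fraction' or explicit 'carriers'")
    .check_number(carrier_fraction, "carrier_fraction", 0, 1, lo_open = TRUE)
  } else {
    carriers <- vapply(carriers, .check_count, integer(1),
                       name = "aberration carriers")
  }
  structure(list(chrom = chrom, start = start, end = end, type = type,
                 carrier_fraction = carrier_fraction, carriers = carriers,
                 defines_cluster = isTRUE(defines_cluster)),
            class = "lohscan_aberration")
}

# tumor copy number and LOH status implied by each template type
.aberration_effect <- function(type) {
  switch(type,
         LOH_loss    = list(cn = 1L, loh = TRUE),
         LOH_neutral = list(cn = 2L, loh = TRUE),
         LOH_gain    = list(cn = 3L, loh = TRUE),
         gain_only   = list(cn = 3L, loh = FALSE),
         loss_only   = list(cn = 1L, loh = FALSE),
         high_amp    = list(cn = 7L, loh = FALSE),
         .config_err("unknown aberration type '%s'", type))
}

#' Default chromosome layout for synthetic cohorts
#'
#' Four synthetic autosomes with p and q arms, 5,000 probes in total: a
#' desk-scale stand-in for a genome-wide array.
#'
#' @return Data frame with columns `chrom`, `arm`, `n_probes`.
#' @export
default_chrom_layout <- function() {
  data.frame(
    chrom = rep(c("chr1", "chr2", "chr3", "chr4"), each = 2L),
    arm = rep(c("p", "q"), 4L),
    n_probes = c(700L, 800L, 600L, 700L, 550L, 650L, 450L, 550L),
    stringsAsFactors = FALSE
  )
}

#' Default implanted aberrations
#'
#' A landscape emulating the broad features of HPV-negative oral tumors:
#' a large LOH-with-loss region (the 3p/8p pattern), an arm-scale gain
#' (3q/8q), a copy-neutral LOH block (9p-like), a plain loss, an LOH-with-gain
#' region, a focal 85-probe high-level amplicon carried by ~20% of samples
#' (the 11q13 pattern), and a distal-arm LOH-with-loss region (4q-like).
#'
#' @return List of [aberration()] templates.
#' @export
default_aberrations <- function() {
  list(
    aberration("chr1", 150L, 550L, "LOH_loss",    carrier_fraction = 0.45),
    aberration("chr1", 850L, 1150L, "gain_only",  carrier_fraction = 0.40),
    aberration("chr2", 80L,  380L, "LOH_neutral", carrier_fraction = 0.35),
    aberration("chr2", 750L, 1000L, "loss_only",  carrier_fraction = 0.30),
    aberration("chr3", 120L, 320L, "LOH_gain",    carrier_fraction = 0.25),
    aberration("chr3", 700L, 784L, "high_amp",    carrier_fraction = 0.20),
    aberration("chr4", 500L, 900L, "LOH_loss",    carrier_fraction = 0.20)
  )
}

#' Survival model specification for the synthetic cohort
#'
#' Cause-specific survival is generated from an exponential baseline hazard
#' for tumor-specific death scaled by `exp(linear predictor)`. The linear
#' predictor combines, at each designated effect probe, `beta_cna * code +
#' beta_loh * LOH + beta_interaction * code * LOH` (where `code` is the
#' ternary true CNA code -1/0/+1 and `LOH` the true indicator), plus
#' covariate effects for sex, age (per year, centered at 60) and smoking
#' (never as reference). Deaths from other causes arrive independently at
#' `other_death_rate`; administrative censoring times are uniform on
#' `[censor_min, censor_max]` months.
#'
#' Default rates are calibrated so a 75-patient cohort experiences roughly
#' 24 tumor-specific and 16 other deaths over a 33-111 month follow-up
#' window, the event mix of the study design this generator emulates.
#'
#' @param baseline_rate Baseline tumor-death hazard per month (>= 0).
#' @param other_death_rate Competing (non-tumor) death hazard per month.
#' @param censor_min,censor_max Administrative censoring window in months;
#'   `Inf` disables censoring.
#' @param effect_probes Integer vector of global probe indices whose true
#'   aberration status enters the hazard.
#' @param beta_cna,beta_loh,beta_interaction Log-hazard-ratio coefficients
#'   at the effect probes.
#' @param beta_sex,beta_age,beta_smoke_former,beta_smoke_current Covariate
#'   coefficients.
#' @return List of class `"lohscan_survival_spec"`.
#' @export
survival_spec <- function(baseline_rate = 0.004,
                          other_death_rate = 0.005,
                          censor_min = 33, censor_max = 111,
                          effect_probes = integer(0),
                          beta_cna = 0, beta_loh = 0, beta_interaction = 0,
                          beta_sex = 0.2, beta_age = 0.02,
                          beta_smoke_former = 0.3, beta_smoke_current = 0.6) {
  .check_number(baseline_rate, "baseline_rate", 0, Inf)
  .check_number(other_death_rate, "other_death_rate", 0, Inf)
  if (!is.infinite(censor_min)) .check_number(censor_min, "censor_min", 0, Inf)
  if (!is.infinite(censor_max)) .check_number(censor_max, "censor_max", 0, Inf)
  if (censor_max < censor_min)
    .config_err("censor_max < censor_min")
  effect_probes <- as.integer(effect_probes)
  for (nm in c("beta_cna", "beta_loh", "beta_interaction", "beta_sex",
               "beta_age", "beta_smoke_former", "beta_smoke_current"))
    .check_number(get(nm), nm)
  structure(list(baseline_rate = baseline_rate,
                 other_death_rate = other_death_rate,
                 censor_min = censor_min, censor_max = censor_max,
                 effect_probes = effect_probes,
                 beta_cna = beta_cna, beta_loh = beta_loh,
                 beta_interaction = beta_interaction,
                 beta_sex = beta_sex, beta_age = beta_age,
                 beta_smoke_former = beta_smoke_former,
                 beta_smoke_current = beta_smoke_current),
            class = "lohscan_survival_spec")
}

#' Synthetic cohort configuration
#'
#' Bundles and validates every parameter of the paired-cohort generator.
#' The defaults mirror the scale of the study design the package emulates:
#' 75 patients, 5,000 probes over four synthetic autosomes with p/q arms,
#' a 30% germline heterozygosity rate, 1% genotype error, and a Gaussian
#' copy-number noise standard deviation of 0.35 on the CN scale.
#'
#' @param n_samples Number of patients.
#' @param chrom_layout Data frame (`chrom`, `arm`, `n_probes`) as from
#'   [default_chrom_layout()]. `n_probes` is derived from it.
#' @param het_rate Probability in (0, 1) that a germline call is
#'   heterozygous. A value of exactly 0 is accepted for boundary scenarios.
#' @param genotype_error_rate Probability in \[0, 0.2) that a tumor call has
#'   its zygosity flipped after implantation (AB to a random homozygote,
#'   homozygote to AB).
#' @param nc_rate Probability of a no-call (NC) per genotype, in \[0, 0.1).
#' @param cn_noise_sd Standard deviation of per-probe Gaussian noise added
#'   to both tissues' copy-number signal.
#' @param purity Tumor purity in (0, 1\]; the tumor signal is shrunk toward
#'   the diploid level 2 by `2 + purity * (CN - 2)`.
#' @param aberration_spec List of [aberration()] templates.
#' @param survival_spec A [survival_spec()].
#' @param seed Integer master seed; all generator randomness derives from it.
#' @return List of class `"lohscan_cohort_config"`.
#' @export
cohort_config <- function(n_samples = 75L,
                          chrom_layout = default_chrom_layout(),
                          het_rate = 0.3,
                          genotype_error_rate = 0.01,
                          nc_rate = 0.002,
                          cn_noise_sd = 0.35,
                          purity = 1.0,
                          aberration_spec = default_aberrations(),
                          survival_spec = lohscan::survival_spec(),
                          seed = 1L) {
  n_samples <- .check_count(n_samples, "n_samples")
  if (!is.data.frame(chrom_layout) ||
      !all(c("chrom", "arm", "n_probes") %in% names(chrom_layout)))
    .config_err("'chrom_layout' must have columns chrom, arm, n_probes")
  chrom_layout$n_probes <- vapply(chrom_layout$n_probes, .check_count,
                                  integer(1), name = "chrom_layout$n_probes")
  .check_number(het_rate, "het_rate", 0, 1, hi_open = TRUE)
  .check_number(genotype_error_rate, "genotype_error_rate", 0, 0.2,
                hi_open = TRUE)
  .check_number(nc_rate, "nc_rate", 0, 0.1, hi_open = TRUE)
  if (het_rate + nc_rate >= 1)
    .config_err("'het_rate' + 'nc_rate' must be < 1")
  .check_number(cn_noise_sd, "cn_noise_sd", 0, Inf)
  .check_number(purity, "purity", 0, 1, lo_open = TRUE)
  if (!inherits(survival_spec, "lohscan_survival_spec"))
    .config_err("'survival_spec' must be built with survival_spec()")
  seed <- .check_seed(seed)

  chrom_sizes <- tapply(chrom_layout$n_probes, chrom_layout$chrom, sum)
  if (!is.list(aberration_spec))
    .config_err("'aberration_spec' must be a list of aberration() templates")
  for (ab in aberration_spec) {
    if (!inherits(ab, "lohscan_aberration"))
      .config_err("'aberration_spec' entries must be built with aberration()")
    if (!ab$chrom %in% names(chrom_sizes))
      .config_err("aberration chromosome '%s' not in chrom_layout", ab$chrom)
    if (ab$end > chrom_sizes[[ab$chrom]])
      .config_err("aberration on %s ends at probe %d but the chromosome has %d probes",
                  ab$chrom, ab$end, chrom_sizes[[ab$chrom]])
    if (!is.null(ab$carriers) && any(ab$carriers > n_samples))
      .config_err("aberration carriers exceed n_samples on %s", ab$chrom)
  }

  structure(list(n_samples = n_samples,
                 n_probes = sum(chrom_layout$n_probes),
                 chrom_layout = chrom_layout,
                 het_rate = het_rate,
                 genotype_error_rate = genotype_error_rate,
                 nc_rate = nc_rate,
                 cn_noise_sd = cn_noise_sd,
                 purity = purity,
                 aberration_spec = aberration_spec,
                 survival_spec = survival_spec,
                 seed = seed),
            class = "lohscan_cohort_config")
}

#' Probe annotation implied by a cohort configuration
#'
#' Builds the BED-like annotation table: probe identifier, chromosome, arm,
#' 1-based nucleotide position (probes every 20 kb), a synthetic cytoband
#' (`<chrom><arm>.<block>` in blocks of 100 probes) and a synthetic gene
#' symbol (one gene per block of 25 probes).
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `probe_id`, `chrom`, `arm`, `position`,
#'   `cytoband`, `gene`, one row per probe in genome order.
#' @export
build_annotation <- function(config) {
  stopifnot(inherits(config, "lohscan_cohort_config"))
  lay <- config$chrom_layout
  chrom <- rep(lay$chrom, lay$n_probes)
  arm <- rep(lay$arm, lay$n_probes)
  idx_in_chrom <- integer(0)
  for (ch in unique(lay$chrom)) {
    n <- sum(lay$n_probes[lay$chrom == ch])
    idx_in_chrom <- c(idx_in_chrom, seq_len(n))
  }
  n_tot <- config$n_probes
  probe_id <- sprintf("P%05d", seq_len(n_tot))
  data.frame(
    probe_id = probe_id,
    chrom = chrom,
    arm = arm,
    position = idx_in_chrom * 20000L,
    cytoband = paste0(chrom, arm, ".", (idx_in_chrom - 1L) %/% 100L + 1L),
    gene = paste0("G", sub("^chr", "", chrom), "_",
                  (idx_in_chrom - 1L) %/% 25L + 1L),
    stringsAsFactors = FALSE
  )
}
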