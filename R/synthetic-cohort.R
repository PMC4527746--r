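# Synthetic paired-cohort generator. Every random draw flows from the
# config seed through fixed per-stage offsets, so each stage is a pure
# function of the configuration.

.SEED_GERMLINE <- 0L
.SEED_IMPLANT <- 1L
.SEED_CLINICAL <- 2L

#' Generate germline (blood) genotype calls
#'
#' Each call is drawn independently: heterozygous (`AB`) with probability
#' `het_rate`, no-call (`NC`) with probability `nc_rate`, otherwise a
#' homozygote (`AA`/`BB` equiprobable).
#'
#' @param config A [cohort_config()].
#' @return Character matrix (probes x samples) with entries in
#'   `AA`, `AB`, `BB`, `NC`; dimnames are probe and sample identifiers.
#' @export
generate_germline <- function(config) {
  stopifnot(inherits(config, "lohscan_cohort_config"))
  n_p <- config$n_probes
  n_s <- config$n_samples
  p_het <- config$het_rate
  p_nc <- config$nc_rate
  p_hom <- (1 - p_het - p_nc) / 2
  calls <- .with_seed(config$seed + .SEED_GERMLINE, {
    sample(c("AA", "AB", "BB", "NC"), n_p * n_s, replace = TRUE,
           prob = c(p_hom, p_het, p_hom, p_nc))
  })
  matrix(calls, nrow = n_p, ncol = n_s,
         dimnames = list(sprintf("P%05d", seq_len(n_p)),
                         sprintf("S%03d", seq_len(n_s))))
}

# Resolve each aberration template to global probe indices and carrier set.
.resolve_aberrations <- function(config) {
  lay <- config$chrom_layout
  chrom_offset <- c(0L, cumsum(tapply(lay$n_probes, factor(lay$chrom, levels = unique(lay$chrom)), sum)))
  names(chrom_offset) <- c(unique(lay$chrom), "END")
  lapply(config$aberration_spec, function(ab) {
    off <- chrom_offset[[ab$chrom]]
    probes <- (off + ab$start):(off + ab$end)
    carriers <- ab$carriers
    if (is.null(carriers)) {
      k <- max(1L, round(ab$carrier_fraction * config$n_samples))
      carriers <- sort(sample.int(config$n_samples, k))
    }
    eff <- .aberration_effect(ab$type)
    list(chrom = ab$chrom, type = ab$type, probes = probes,
         carriers = carriers, cn = eff$cn, loh = eff$loh,
         defines_cluster = ab$defines_cluster)
  })
}

#' Implant aberrations into a synthetic cohort
#'
#' Applies every configured aberration template to its carrier samples:
#' at LOH probes the tumor genotype at blood-heterozygous loci is set to a
#' random homozygote; the true tumor copy number is set per template type
#' (blood stays diploid). Genotype errors (zygosity flips at
#' `genotype_error_rate`) are injected into the tumor calls *after*
#' implantation. Copy-number signal is the true copy number (shrunk toward 2
#' by `purity` for the tumor) plus Gaussian noise with sd `cn_noise_sd`.
#'
#' Two templates overlapping in both probes and carriers are contradictory
#' when they imply different tumor copy numbers (an error); overlapping
#' templates with equal copy number merge, with LOH flags combined by union.
#'
#' @param germline Blood genotype matrix from [generate_germline()] under the
#'   same config.
#' @param config The [cohort_config()].
#' @return List with elements `tumor_genotype` (character matrix),
#'   `blood_signal`, `tumor_signal` (numeric matrices, CN scale), and
#'   `truth`, a ground-truth record with `true_loh` (logical matrix of
#'   realized LOH events -- recorded at blood-heterozygous loci, where LOH
#'   is observable, before error injection), `true_cn` (integer matrix), `segments` (resolved
#'   templates with carrier sets), and `true_cluster` (per-sample labels
#'   1/2 when any template defines a cluster, else `NULL`).
#' @export
implant_aberrations <- function(germline, config) {
  stopifnot(inherits(config, "lohscan_cohort_config"))
  n_p <- config$n_probes
  n_s <- config$n_samples
  if (!is.matrix(germline) || nrow(germline) != n_p || ncol(germline) != n_s)
    .config_err("'germline' dimensions do not match the configuration")

  .with_seed(config$seed + .SEED_IMPLANT, {
    abs_resolved <- .resolve_aberrations(config)

    true_cn <- matrix(2L, n_p, n_s, dimnames = dimnames(germline))
    true_loh <- matrix(FALSE, n_p, n_s, dimnames = dimnames(germline))
    claimed <- matrix(0L, n_p, n_s)  # implied CN of first claiming template

    for (ab in abs_resolved) {
      sub_claim <- claimed[ab$probes, ab$carriers, drop = FALSE]
      clash <- sub_claim != 0L & sub_claim != ab$cn
      if (any(clash))
        .err("lohscan_generation_error",
             "contradictory overlapping aberrations (%s, CN %d) touch %d probe/sample cells already implanted with a different copy number",
             ab$type, ab$cn, sum(clash))
      claimed[ab$probes, ab$carriers] <- ab$cn
      true_cn[ab$probes, ab$carriers] <- ab$cn
      if (ab$loh) {
        # LOH is only realizable where the germline is heterozygous; the
        # ground-truth indicator records the observable event
        sub <- germline[ab$probes, ab$carriers, drop = FALSE] == "AB"
        true_loh[ab$probes, ab$carriers][sub] <- TRUE
      }
    }

    tumor <- germline
    flip <- true_loh
    n_flip <- sum(flip)
    if (n_flip > 0)
      tumor[flip] <- sample(c("AA", "BB"), n_flip, replace = TRUE)

    e <- config$genotype_error_rate
    if (e > 0) {
      hit <- matrix(stats::runif(n_p * n_s) < e, n_p, n_s) & tumor != "NC"
      het_hit <- hit & tumor == "AB"
      hom_hit <- hit & (tumor == "AA" | tumor == "BB")
      if (any(het_hit))
        tumor[het_hit] <- sample(c("AA", "BB"), sum(het_hit), replace = TRUE)
      tumor[hom_hit] <- "AB"
    }

    sd <- config$cn_noise_sd
    noise_b <- if (sd > 0) matrix(stats::rnorm(n_p * n_s, sd = sd), n_p, n_s) else 0
    noise_t <- if (sd > 0) matrix(stats::rnorm(n_p * n_s, sd = sd), n_p, n_s) else 0
    blood_signal <- matrix(2, n_p, n_s, dimnames = dimnames(germline)) + noise_b
    tumor_signal <- 2 + config$purity * (true_cn - 2) + noise_t
    dimnames(tumor_signal) <- dimnames(germline)

    true_cluster <- NULL
    cluster_abs <- Filter(function(a) a$defines_cluster, abs_resolved)
    if (length(cluster_abs)) {
      true_cluster <- rep(1L, n_s)
      for (ab in cluster_abs) true_cluster[ab$carriers] <- 2L
      names(true_cluster) <- colnames(germline)
    }

    list(tumor_genotype = tumor,
         blood_signal = blood_signal,
         tumor_signal = tumor_signal,
         truth = structure(list(true_loh = true_loh,
                                true_cn = true_cn,
                                segments = abs_resolved,
                                true_cluster = true_cluster),
                           class = "lohscan_truth"))
  })
}

#' Generate clinical covariates and cause-specific survival
#'
#' Covariates emulate an HPV-negative oral-cancer cohort: mostly male,
#' age ~ N(60, 10) truncated to 30-90, smoking mostly current/former,
#' majority alcohol users and late-stage tumors. Tumor-specific death times
#' are exponential with hazard `baseline_rate * exp(lp)`, where the linear
#' predictor `lp` adds the configured genomic effects at the effect probes
#' (using the *true* ternary CNA code and LOH indicator) to the covariate
#' effects. Independent other-cause death and uniform administrative
#' censoring compete; the earliest determines the outcome.
#'
#' @param config The [cohort_config()].
#' @param truth Ground truth from [implant_aberrations()].
#' @return Data frame with one row per patient: `sample_id`, `sex`, `age`,
#'   `smoking`, `alcohol`, `stage`, `site`, `nodal`, `time_months`,
#'   `vital_status` (one of `OSCC_death`, `other_death`, `censored`), plus
#'   an attribute `true_lp` holding the linear predictor used.
#' @export
generate_clinical <- function(config, truth) {
  stopifnot(inherits(config, "lohscan_cohort_config"),
            inherits(truth, "lohscan_truth"))
  sp <- config$survival_spec
  n <- config$n_samples

  .with_seed(config$seed + .SEED_CLINICAL, {
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.79, 0.21))
    age <- pmin(pmax(stats::rnorm(n, 60, 10), 30), 90)
    smoking <- sample(c("current", "former", "never"), n, replace = TRUE,
                      prob = c(0.48, 0.33, 0.19))
    alcohol <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.8, 0.2))
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                    prob = c(0.20, 0.21, 0.26, 0.33))
    site <- sample(c("oral_cavity", "oropharynx"), n, replace = TRUE,
                   prob = c(0.6, 0.4))
    nodal <- sample(c("positive", "negative"), n, replace = TRUE,
                    prob = c(0.467, 0.533))

    lp <- sp$beta_sex * (sex == "male") +
      sp$beta_age * (age - 60) +
      sp$beta_smoke_former * (smoking == "former") +
      sp$beta_smoke_current * (smoking == "current")
    for (p in sp$effect_probes) {
      code <- pmin(pmax(truth$true_cn[p, ] - 2L, -1L), 1L)
      loh <- as.numeric(truth$true_loh[p, ])
      lp <- lp + sp$beta_cna * code + sp$beta_loh * loh +
        sp$beta_interaction * code * loh
    }

    rate_oscc <- sp$baseline_rate * exp(lp)
    t_oscc <- ifelse(rate_oscc > 0, stats::rexp(n, pmax(rate_oscc, 1e-300)), Inf)
    t_other <- if (sp$other_death_rate > 0)
      stats::rexp(n, sp$other_death_rate) else rep(Inf, n)
    t_cens <- if (is.infinite(sp$censor_min) || is.infinite(sp$censor_max))
      rep(Inf, n) else stats::runif(n, sp$censor_min, sp$censor_max)

    time <- pmin(t_oscc, t_other, t_cens)
    status <- ifelse(time == t_oscc, "OSCC_death",
                     ifelse(time == t_other, "other_death", "censored"))
    if (any(is.infinite(time)))
      .config_err("survival generation produced infinite follow-up; enable censoring or a positive hazard")

    clin <- data.frame(sample_id = colnames(truth$true_cn) %||%
                         sprintf("S%03d", seq_len(n)),
                       sex = sex, age = age, smoking = smoking,
                       alcohol = alcohol, stage = stage, site = site,
                       nodal = nodal,
                       time_months = time, vital_status = status,
                       stringsAsFactors = FALSE)
    attr(clin, "true_lp") <- lp
    clin
  })
}

#' Simulate a complete paired cohort
#'
#' Runs [generate_germline()], [implant_aberrations()] and
#' [generate_clinical()] in sequence and bundles their outputs with the
#' probe annotation.
#'
#' @param config A [cohort_config()].
#' @return List of class `"lohscan_cohort"` with elements `config`,
#'   `annotation`, `blood_genotype`, `tumor_genotype`, `blood_signal`,
#'   `tumor_signal`, `clinical`, `truth`.
#' @export
simulate_cohort <- function(config) {
  germline <- generate_germline(config)
  imp <- implant_aberrations(germline, config)
  truth <- imp$truth
  clinical <- generate_clinical(config, truth)
  truth$true_lp <- attr(clinical, "true_lp")
  structure(list(config = config,
                 annotation = build_annotation(config),
                 blood_genotype = germline,
                 tumor_genotype = imp$tumor_genotype,
                 blood_signal = imp$blood_signal,
                 tumor_signal = imp$tumor_signal,
                 clinical = clinical,
                 truth = truth),
            class = "lohscan_cohort")
}
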