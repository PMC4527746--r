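# Genome-wide Cox proportional-hazards screen: per-probe models relating
# cause-specific mortality to the probe's CNA code, LOH indicator and their
# interaction, adjusted for sex, age and smoking; nested likelihood-ratio
# tests with Bonferroni and Storey q-value control.

.COVARIATES <- c("sex_male", "age", "smoke_former", "smoke_current")

#' Encode the per-probe Cox design
#'
#' CNA classes code to a ternary covariate (`GAIN` +1, `NEUTRAL` 0, `LOSS`
#' -1; a continuous mode uses the segmented delta instead); LOH codes to a
#' 0/1 indicator with non-informative status as 0 (no evidence of LOH).
#' Smoking is one-hot with never-smokers as reference; age enters
#' continuously. Deaths from other causes are censored at the death time;
#' the event indicator marks tumor-specific death only.
#'
#' @param callset A [build_callset()] result.
#' @param clinical Clinical table as from [generate_clinical()].
#' @param probe Probe identifier (row name of the call matrices).
#' @param cna_coding `"ternary"` (default) or `"delta"`.
#' @return Data frame, one row per patient: `time`, `event`, `cna`, `loh`,
#'   and the adjustment covariates.
#' @export
encode_design <- function(callset, clinical, probe,
                          cna_coding = c("ternary", "delta")) {
  cna_coding <- match.arg(cna_coding)
  stopifnot(inherits(callset, "lohscan_callset"))
  samples <- colnames(callset$loh)
  hit <- match(samples, clinical$sample_id)
  if (anyNA(hit))
    .err("lohscan_join_error",
         "samples missing from the clinical table: %s",
         paste(utils::head(samples[is.na(hit)], 5), collapse = ","))
  clin <- clinical[hit, ]
  if (!probe %in% rownames(callset$loh))
    .err("lohscan_input_error", "unknown probe '%s'", probe)
  cna <- if (cna_coding == "ternary") {
    unname(c(GAIN = 1, NEUTRAL = 0, LOSS = -1)[callset$cna_class[probe, ]])
  } else {
    unname(callset$delta[probe, ])
  }
  data.frame(
    time = clin$time_months,
    event = as.integer(clin$vital_status == "OSCC_death"),
    cna = cna,
    loh = as.integer(callset$loh[probe, ] == "L"),
    sex_male = as.integer(clin$sex == "male"),
    age = clin$age,
    smoke_former = as.integer(clin$smoking == "former"),
    smoke_current = as.integer(clin$smoking == "current"),
    row.names = NULL)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron tie handling for the requested
#' terms (columns of the design, plus `"cna:loh"` for the multiplicative
#' interaction). A constant included covariate raises a degenerate-design
#' error; a monotone-likelihood / non-converged fit is returned flagged
#' rather than raising.
#'
#' @param design A design frame from [encode_design()] (needs `time` and
#'   `event` plus the term columns).
#' @param terms Character vector of model terms.
#' @return List with `coef`, `vcov`, `loglik` (maximized log partial
#'   likelihood), `loglik_null`, `converged`, `monotone` (suspected
#'   infinite-coefficient flag), `n_events`, `terms`.
#' @export
fit_cox <- function(design, terms) {
  if (sum(design$event) < 1L)
    .err("lohscan_degenerate_design", "no events in the design")
  plain <- setdiff(terms, "cna:loh")
  for (tm in plain) {
    v <- design[[tm]]
    if (is.null(v))
      .err("lohscan_input_error", "term '%s' is not a design column", tm)
    if (length(unique(v)) < 2L)
      .err("lohscan_degenerate_design", "covariate '%s' is constant", tm)
  }
  if ("cna:loh" %in% terms && length(unique(design$cna * design$loh)) < 2L)
    .err("lohscan_degenerate_design", "interaction cna:loh is constant")
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = design, ties = "efron",
                                     control = survival::coxph.control(iter.max = 50))),
    error = function(e) .err("lohscan_fit_error", "coxph failed: %s",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  se <- sqrt(diag(vc))
  monotone <- any(!is.finite(cf)) || any(abs(cf) > 12) ||
    any(!is.finite(se)) || any(se > 100)
  list(coef = cf, vcov = vc,
       loglik = fit$loglik[length(fit$loglik)],
       loglik_null = fit$loglik[1L],
       converged = is.null(fit$info) && fit$iter < 50,
       monotone = monotone,
       n_events = sum(design$event),
       terms = terms)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' Statistic `2 * (logPL_full - logPL_nested)`, floored at zero, referred to
#' the upper tail of a chi-square with `df` degrees of freedom.
#'
#' @param full,nested Fits from [fit_cox()]; the nested model's terms must
#'   be a subset of the full model's.
#' @param df Degrees of freedom (difference in parameter count); derived
#'   from the term lists when omitted.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, nested, df = NULL) {
  if (!all(nested$terms %in% full$terms))
    .err("lohscan_usage_error",
         "models are not nested: nested terms must be a subset of full terms")
  if (is.null(df)) df <- length(full$terms) - length(nested$terms)
  df <- .check_count(df, "df", min = 0L)
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Genome-wide per-probe Cox screen
#'
#' For every probe with LOH in at least `min_loh_samples` patients
#' (strictly fewer are filtered out before testing), fits the
#' covariates-only, CNA+LOH, and full (CNA + LOH + CNA:LOH) models and
#' reports two likelihood-ratio p-values: `p_all` for the three genomic
#' terms jointly (3 df, full vs covariates-only) and `p_interaction` for
#' the interaction alone (1 df, full vs CNA+LOH). The CNA effect sign is
#' reported separately in the LOH-absent stratum (`beta_cna`) and the
#' LOH-present stratum (`beta_cna + beta_interaction`); fits with suspected
#' monotone likelihood are marked sign-undetermined. The Bonferroni flag
#' uses `0.05 / (number of probes tested)`; Storey q-values are computed
#' separately for the `p_all` and `p_interaction` families.
#'
#' Probes whose genomic covariates are constant (degenerate designs) are
#' skipped and listed in the `skipped` attribute.
#'
#' @param callset A [build_callset()] result.
#' @param clinical Clinical table.
#' @param min_loh_samples Minimum LOH-positive patients per probe
#'   (default 5).
#' @param cna_coding Passed to [encode_design()].
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05).
#' @return Data frame, one row per tested probe: coefficient estimates with
#'   95% CIs, `p_all`, `p_interaction`, stratum signs (`+`, `-`,
#'   `undetermined`), `bonferroni_significant`, `q_all`, `q_interaction`,
#'   `n_loh`. Attributes: `n_tested`, `bonferroni_cutoff`, `skipped`.
#' @export
screen <- function(callset, clinical, min_loh_samples = 5L,
                   cna_coding = c("ternary", "delta"), alpha = 0.05) {
  cna_coding <- match.arg(cna_coding)
  min_loh_samples <- .check_count(min_loh_samples, "min_loh_samples", min = 0L)
  stopifnot(inherits(callset, "lohscan_callset"))

  n_loh <- rowSums(callset$loh == "L")
  probes <- rownames(callset$loh)[n_loh >= min_loh_samples]
  if (length(probes) == 0L) {
    warning("no probes pass the LOH-count filter; empty screen")
    out <- data.frame()
    attr(out, "n_tested") <- 0L
    return(out)
  }

  design0 <- encode_design(callset, clinical, probes[1L], cna_coding)
  fit_cov <- fit_cox(design0, .COVARIATES)

  rows <- vector("list", length(probes))
  skipped <- character(0)
  genomic <- c("cna", "loh", "cna:loh")
  for (i in seq_along(probes)) {
    p <- probes[i]
    design <- encode_design(callset, clinical, p, cna_coding)
    res <- tryCatch({
      fit_main <- fit_cox(design, c("cna", "loh", .COVARIATES))
      fit_full <- fit_cox(design, c(genomic, .COVARIATES))
      p_all <- lrt(fit_full, fit_cov, df = 3L)$p_value
      p_int <- lrt(fit_full, fit_main, df = 1L)$p_value
      cf <- fit_full$coef
      vc <- fit_full$vcov
      b_cna <- cf[["cna"]]
      b_loh <- cf[["loh"]]
      b_int <- cf[["cna:loh"]]
      se_cna <- sqrt(vc["cna", "cna"])
      se_loh <- sqrt(vc["loh", "loh"])
      se_int <- sqrt(vc["cna:loh", "cna:loh"])
      b_strat <- b_cna + b_int
      und <- fit_full$monotone || !fit_full$converged
      sgn <- function(b) if (und || b == 0) "undetermined" else
        if (b > 0) "+" else "-"
      data.frame(probe_id = p,
                 beta_cna = b_cna,
                 ci_cna_lo = b_cna - 1.96 * se_cna,
                 ci_cna_hi = b_cna + 1.96 * se_cna,
                 beta_loh = b_loh,
                 ci_loh_lo = b_loh - 1.96 * se_loh,
                 ci_loh_hi = b_loh + 1.96 * se_loh,
                 beta_interaction = b_int,
                 ci_int_lo = b_int - 1.96 * se_int,
                 ci_int_hi = b_int + 1.96 * se_int,
                 p_all = p_all, p_interaction = p_int,
                 sign_no_loh = sgn(b_cna),
                 sign_loh = sgn(b_strat),
                 n_loh = n_loh[[p]],
                 stringsAsFactors = FALSE)
    }, lohscan_degenerate_design = function(e) {
      skipped[[length(skipped) + 1L]] <<- p
      NULL
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    warning("every candidate probe was degenerate; empty screen")
    out <- data.frame()
    attr(out, "n_tested") <- 0L
    return(out)
  }
  cutoff <- bonferroni_threshold(nrow(out), alpha)
  out$bonferroni_significant <- out$p_all < cutoff
  out$q_all <- qvalues(out$p_all)
  out$q_interaction <- qvalues(out$p_interaction)
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(out)
  attr(out, "bonferroni_cutoff") <- cutoff
  attr(out, "skipped") <- skipped
  out
}
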