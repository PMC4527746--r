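# Hierarchical clustering of samples on aberration matrices and association
# of the resulting two groups with covariates (Fisher exact) and with
# cause-specific mortality (cumulative incidence + log-rank; Cox LRT).

#' Cluster samples on LOH or CNA features
#'
#' LOH features are the binary LOH indicator per probe (1 = LOH, else 0,
#' including non-informative) with Jaccard distance; CNA features are the
#' segmented per-probe deltas with Euclidean distance. Complete-linkage
#' hierarchical clustering, cut into exactly two groups. When all samples
#' are identical in the feature space the result is a single cluster,
#' flagged degenerate.
#'
#' @param callset A [build_callset()] result.
#' @param features `"loh"` or `"cna"`.
#' @param probes Optional character vector restricting the feature space to
#'   a probe subset (e.g. one region or arm).
#' @return List of class `"lohscan_clusters"` with `labels` (named integer
#'   vector in 1/2), `hclust` (the dendrogram object, `NULL` if
#'   degenerate), `degenerate`, `features`, `n_probes`.
#' @export
cluster_samples <- function(callset, features = c("loh", "cna"),
                            probes = NULL) {
  features <- match.arg(features)
  stopifnot(inherits(callset, "lohscan_callset"))
  mat <- if (features == "loh") (callset$loh == "L") * 1 else callset$delta
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(mat))
    if (length(missing))
      .err("lohscan_input_error", "unknown probes in subset: %s",
           paste(utils::head(missing, 5), collapse = ","))
    mat <- mat[probes, , drop = FALSE]
  }
  if (nrow(mat) == 0L) .config_err("empty probe subset")
  if (ncol(mat) < 4L) .config_err("need at least 4 samples to cluster")

  x <- t(mat)  # samples in rows
  d <- if (features == "loh") stats::dist(x, method = "binary")
       else stats::dist(x, method = "euclidean")
  if (max(d) == 0) {
    labels <- stats::setNames(rep(1L, ncol(mat)), colnames(mat))
    return(structure(list(labels = labels, hclust = NULL, degenerate = TRUE,
                          features = features, n_probes = nrow(mat)),
                     class = "lohscan_clusters"))
  }
  hc <- stats::hclust(d, method = "complete")
  labels <- stats::cutree(hc, k = 2L)
  structure(list(labels = labels, hclust = hc, degenerate = FALSE,
                 features = features, n_probes = nrow(mat)),
            class = "lohscan_clusters")
}

#' Fisher exact association of cluster labels with a categorical covariate
#'
#' Exact conditional test on the 2 x k contingency table (the probability
#' of every table with the observed margins that is no more probable than
#' the observed one). Tables too large for exact enumeration fall back to
#' Monte-Carlo estimation with a seed.
#'
#' @param labels Cluster labels (from [cluster_samples()] or any vector).
#' @param covariate Categorical covariate, same length/order as `labels`.
#' @param monte_carlo Force Monte-Carlo estimation.
#' @param B Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo mode.
#' @return List with `p_value`, `table`, `method`.
#' @export
fisher_exact <- function(labels, covariate, monte_carlo = FALSE,
                         B = 1e5, seed = 1L) {
  if (inherits(labels, "lohscan_clusters")) labels <- labels$labels
  if (length(labels) != length(covariate))
    .err("lohscan_input_error", "labels and covariate lengths differ")
  tab <- table(labels, covariate)
  if (any(dim(tab) < 2L)) {
    warning("covariate or labels have a single level; no association to test")
    return(list(p_value = 1, table = tab, method = "degenerate"))
  }
  if (!monte_carlo) {
    ft <- tryCatch(stats::fisher.test(tab),
                   error = function(e) NULL)
    if (!is.null(ft))
      return(list(p_value = ft$p.value, table = tab, method = "exact"))
    .err("lohscan_usage_error",
         "table too large for exact enumeration; rerun with monte_carlo = TRUE")
  }
  ft <- .with_seed(seed,
                   stats::fisher.test(tab, simulate.p.value = TRUE, B = B))
  list(p_value = ft$p.value, table = tab, method = "monte_carlo")
}

#' Compare cause-specific mortality between two clusters
#'
#' Deaths from other causes are censored at their death time; the
#' cumulative incidence of tumor-specific death per cluster is reported as
#' 1 - Kaplan-Meier. The two-group log-rank statistic (observed minus
#' expected events, normalized by the hypergeometric variance summed over
#' event times) is referred to a 1-df chi-square.
#'
#' @param labels Cluster labels (1/2), named by sample or ordered as
#'   `clinical`.
#' @param clinical Clinical table with `sample_id`, `time_months`,
#'   `vital_status`.
#' @return List with `statistic`, `p_value`, `observed`, `expected` (per
#'   cluster), and `curves` (data frame: `cluster`, `time`, `cum_incidence`).
#' @export
compare_mortality <- function(labels, clinical) {
  if (inherits(labels, "lohscan_clusters")) labels <- labels$labels
  if (!is.null(names(labels))) {
    hit <- match(names(labels), clinical$sample_id)
    if (anyNA(hit))
      .err("lohscan_join_error", "cluster samples missing from clinical table")
    clinical <- clinical[hit, ]
  } else if (length(labels) != nrow(clinical)) {
    .err("lohscan_input_error", "labels and clinical table lengths differ")
  }
  grp <- factor(labels)
  if (nlevels(grp) != 2L)
    .err("lohscan_usage_error", "mortality comparison needs exactly 2 clusters")
  time <- clinical$time_months
  event <- as.integer(clinical$vital_status == "OSCC_death")

  fit_km <- survival::survfit(survival::Surv(time, event) ~ grp)
  strata_lab <- rep(sub("^grp=", "", names(fit_km$strata)),
                    fit_km$strata)
  curves <- data.frame(cluster = strata_lab, time = fit_km$time,
                       cum_incidence = 1 - fit_km$surv,
                       stringsAsFactors = FALSE)

  if (sum(event) == 0L) {
    warning("no tumor-specific deaths in either cluster; log-rank undefined")
    return(list(statistic = 0, p_value = 1,
                observed = c(0, 0), expected = c(0, 0), curves = curves))
  }
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd_fit$chisq),
       p_value = stats::pchisq(sd_fit$chisq, df = 1L, lower.tail = FALSE),
       observed = unname(sd_fit$obs), expected = unname(sd_fit$exp),
       curves = curves)
}

#' Cox LRT for a cluster effect on cause-specific mortality
#'
#' Fits a Cox model with the cluster indicator plus the requested
#' adjustment covariates and reports the likelihood-ratio p-value of the
#' cluster term against the adjusters-only model. Reuses [fit_cox()] and
#' [lrt()].
#'
#' @param labels Cluster labels (1/2).
#' @param clinical Clinical table.
#' @param adjusters Character vector of adjustment covariates among
#'   `"sex"`, `"age"`, `"smoking"`, `"stage"`.
#' @return List with `p_value`, `statistic`, `beta_cluster`.
#' @export
cluster_covariate_cox <- function(labels, clinical,
                                  adjusters = c("sex", "age", "smoking")) {
  if (inherits(labels, "lohscan_clusters")) labels <- labels$labels
  if (!is.null(names(labels))) {
    hit <- match(names(labels), clinical$sample_id)
    if (anyNA(hit))
      .err("lohscan_join_error", "cluster samples missing from clinical table")
    clinical <- clinical[hit, ]
  }
  bad <- setdiff(adjusters, c("sex", "age", "smoking", "stage"))
  if (length(bad))
    .err("lohscan_usage_error", "unknown adjusters: %s",
         paste(bad, collapse = ","))
  design <- data.frame(
    time = clinical$time_months,
    event = as.integer(clinical$vital_status == "OSCC_death"),
    cluster2 = as.integer(labels == sort(unique(labels))[2L]),
    sex_male = as.integer(clinical$sex == "male"),
    age = clinical$age,
    smoke_former = as.integer(clinical$smoking == "former"),
    smoke_current = as.integer(clinical$smoking == "current"),
    stage_late = as.integer(clinical$stage %in% c("III", "IV")))
  terms <- c("cluster2",
             if ("sex" %in% adjusters) "sex_male",
             if ("age" %in% adjusters) "age",
             if ("smoking" %in% adjusters) c("smoke_former", "smoke_current"),
             if ("stage" %in% adjusters) "stage_late")
  adj_terms <- setdiff(terms, "cluster2")
  # collinearity with an adjuster leaves the cluster term redundant
  for (tm in adj_terms)
    if (length(unique(design[[tm]])) > 1L &&
        all(design$cluster2 == design[[tm]]))
      .err("lohscan_degenerate_design",
           "cluster label duplicates adjuster '%s'", tm)
  fit_full <- fit_cox(design, terms)
  fit_null <- if (length(adj_terms)) fit_cox(design, adj_terms) else
    list(loglik = fit_full$loglik_null, terms = character(0))
  res <- lrt(fit_full, fit_null, df = 1L)
  list(p_value = res$p_value, statistic = res$statistic,
       beta_cluster = unname(fit_full$coef[["cluster2"]]))
}
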