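# Genomic landscape summaries: consensus frequencies with frequent/extreme
# tiers, chromosome-arm large-region events, per-sample burden, top-k tables.
# All tier thresholds are strict inequalities (> 20%, > 80%, > 50%).

#' Consensus per-probe event frequencies and tiers
#'
#' Cross-sample fraction of LOH, gain and loss per probe. The LOH
#' denominator defaults to the informative samples at that probe
#' ([loh_frequency()]); gain/loss fractions are over all samples. Tiers:
#' `FREQUENT` for a fraction strictly above 0.20, `EXTREME` strictly above
#' 0.80 (extreme events are also frequent).
#'
#' @param callset A [build_callset()] result.
#' @param loh_denominator Passed to [loh_frequency()].
#' @return Data frame, one row per probe: `probe_id`, `loh_frac`,
#'   `gain_frac`, `loss_frac`, and logical tier columns `loh_frequent`,
#'   `loh_extreme`, `gain_frequent`, `gain_extreme`, `loss_frequent`,
#'   `loss_extreme`.
#' @export
consensus_frequencies <- function(callset,
                                  loh_denominator = c("informative", "all")) {
  stopifnot(inherits(callset, "lohscan_callset"))
  loh_frac <- loh_frequency(callset$loh, loh_denominator)
  n <- ncol(callset$loh)
  gain_frac <- rowSums(callset$cna_class == "GAIN") / n
  loss_frac <- rowSums(callset$cna_class == "LOSS") / n
  tier <- function(f) list(frequent = !is.na(f) & f > 0.20,
                           extreme = !is.na(f) & f > 0.80)
  tl <- tier(loh_frac); tg <- tier(gain_frac); ts <- tier(loss_frac)
  data.frame(probe_id = rownames(callset$loh),
             loh_frac = loh_frac, gain_frac = gain_frac,
             loss_frac = loss_frac,
             loh_frequent = tl$frequent, loh_extreme = tl$extreme,
             gain_frequent = tg$frequent, gain_extreme = tg$extreme,
             loss_frequent = ts$frequent, loss_extreme = ts$extreme,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chromosome-arm event profiles and large-region flags
#'
#' Per sample and arm, the fraction of the arm's probes showing LOH, gain
#' and loss, with a large-region flag when the fraction is strictly above
#' 0.5. LOH fractions use the informative probes of the arm in that sample
#' as denominator; gain/loss use all arm probes. Also reports, per arm and
#' event type, the percentage of samples flagged.
#'
#' @param callset A [build_callset()] result.
#' @param annotation Annotation table assigning every probe to an arm
#'   (columns `probe_id`, `chrom`, `arm`).
#' @return List with `fractions` (long data frame: `sample`, `chrom`,
#'   `arm`, `event`, `fraction`, `large_region`) and `arm_percent` (data
#'   frame: `chrom`, `arm`, `event`, `percent_samples` flagged).
#' @export
arm_events <- function(callset, annotation) {
  stopifnot(inherits(callset, "lohscan_callset"))
  probes <- rownames(callset$loh)
  hit <- match(probes, annotation$probe_id)
  if (anyNA(hit))
    .err("lohscan_annotation_error",
         "probes missing from annotation: %s",
         paste(utils::head(probes[is.na(hit)], 5), collapse = ","))
  ann <- annotation[hit, ]
  if (anyNA(ann$arm) || any(!nzchar(ann$arm)))
    .err("lohscan_annotation_error", "probes with missing arm label")
  arm_key <- paste(ann$chrom, ann$arm, sep = ":")
  arms <- unique(arm_key)
  samples <- colnames(callset$loh)

  rows <- list()
  for (a in arms) {
    sel <- arm_key == a
    loh_a <- callset$loh[sel, , drop = FALSE]
    cna_a <- callset$cna_class[sel, , drop = FALSE]
    n_inf <- colSums(loh_a != "N")
    frac_loh <- ifelse(n_inf > 0, colSums(loh_a == "L") / n_inf, NA_real_)
    frac_gain <- colSums(cna_a == "GAIN") / sum(sel)
    frac_loss <- colSums(cna_a == "LOSS") / sum(sel)
    ca <- strsplit(a, ":")[[1L]]
    for (ev in c("LOH", "GAIN", "LOSS")) {
      f <- switch(ev, LOH = frac_loh, GAIN = frac_gain, LOSS = frac_loss)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = samples, chrom = ca[1L], arm = ca[2L], event = ev,
        fraction = unname(f),
        large_region = !is.na(f) & f > 0.5,
        stringsAsFactors = FALSE)
    }
  }
  fractions <- do.call(rbind, rows)
  arm_percent <- stats::aggregate(large_region ~ chrom + arm + event,
                                  data = fractions,
                                  FUN = function(z) 100 * mean(z))
  names(arm_percent)[names(arm_percent) == "large_region"] <- "percent_samples"
  list(fractions = fractions, arm_percent = arm_percent)
}

#' Per-sample aberration burden
#'
#' Percentage of probes per sample showing LOH (of that sample's
#' informative probes), gain, loss and any CNA (of all probes). Gain and
#' loss percentages sum to the CNA percentage by construction.
#'
#' @param callset A [build_callset()] result.
#' @return List with `per_sample` (data frame: `sample`, `pct_loh`,
#'   `pct_cna`, `pct_gain`, `pct_loss`) and `summary` (cross-sample mean and
#'   sd per burden type).
#' @export
burden <- function(callset) {
  stopifnot(inherits(callset, "lohscan_callset"))
  n_p <- nrow(callset$cna_class)
  n_inf <- colSums(callset$loh != "N")
  pct_loh <- ifelse(n_inf > 0, 100 * colSums(callset$loh == "L") / n_inf, 0)
  pct_gain <- 100 * colSums(callset$cna_class == "GAIN") / n_p
  pct_loss <- 100 * colSums(callset$cna_class == "LOSS") / n_p
  per_sample <- data.frame(sample = colnames(callset$loh),
                           pct_loh = unname(pct_loh),
                           pct_cna = unname(pct_gain + pct_loss),
                           pct_gain = unname(pct_gain),
                           pct_loss = unname(pct_loss),
                           stringsAsFactors = FALSE)
  summary <- data.frame(
    burden = c("pct_loh", "pct_cna", "pct_gain", "pct_loss"),
    mean = vapply(per_sample[, -1L], mean, numeric(1)),
    sd = vapply(per_sample[, -1L], stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_sample = per_sample, summary = summary)
}

#' Top-k most frequent events, annotated
#'
#' The k probes with the highest consensus fraction for each event type,
#' annotated with cytoband and gene. Ties are broken by genomic order
#' (annotation row order). Requesting more probes than exist returns the
#' full sorted table with a warning.
#'
#' @param consensus A [consensus_frequencies()] result.
#' @param annotation Annotation table (`probe_id`, `chrom`, `position`,
#'   `cytoband`, `gene`).
#' @param k Number of probes per table (default 100).
#' @return Named list of data frames (`loh`, `gain`, `loss`), each with
#'   `rank`, `probe_id`, `chrom`, `position`, `cytoband`, `gene`,
#'   `fraction`.
#' @export
top_k_tables <- function(consensus, annotation, k = 100L) {
  k <- .check_count(k, "k")
  hit <- match(consensus$probe_id, annotation$probe_id)
  if (anyNA(hit))
    .err("lohscan_annotation_error", "consensus probes missing from annotation")
  genome_order <- order(hit)  # annotation rows are genome-ordered
  if (k > nrow(consensus)) {
    warning(sprintf("k = %d exceeds probe count %d; returning all probes",
                    k, nrow(consensus)))
    k <- nrow(consensus)
  }
  one <- function(frac_col) {
    f <- consensus[[frac_col]]
    f[is.na(f)] <- -Inf
    ord <- order(-f[genome_order])          # stable: ties keep genome order
    pick <- genome_order[ord][seq_len(k)]
    ann <- annotation[hit[pick], ]
    data.frame(rank = seq_len(k),
               probe_id = consensus$probe_id[pick],
               chrom = ann$chrom, position = ann$position,
               cytoband = ann$cytoband, gene = ann$gene,
               fraction = consensus[[frac_col]][pick],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(loh = one("loh_frac"), gain = one("gain_frac"), loss = one("loss_frac"))
}
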