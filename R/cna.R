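# CNA calling: blood-null empirical FDR cutoff selection, final gain/loss
# calls, high-level amplification flags, and joint LOH-by-CNA classes.

#' Empirical FDR curve from blood-null surviving-probe counts
#'
#' Treats the blood sample as free of true copy-number change. For each
#' subject and each magnitude cutoff `c`, the blood count is the number of
#' probes with `|segmented blood deviation| >= c` and the tumor count the
#' number with `|segmented tumor deviation| >= c`; the subject's estimated
#' FDR is their ratio (0 when the tumor count is 0: no calls, nothing
#' false), capped at 1 for reporting. The cross-subject mean FDR drives
#' cutoff selection.
#'
#' @param tumor_delta,blood_delta Matrices of per-probe segmented deviations
#'   from [segment_cohort()].
#' @param grid Strictly increasing numeric vector of candidate cutoffs
#'   (default 0.05 to 2.0 in steps of 0.05, CN scale).
#' @return List of class `"lohscan_fdr_curve"` with `grid`, `blood_counts`
#'   and `tumor_counts` (cutoff x subject matrices), `subject_fdr` (capped
#'   ratios), and `mean_fdr` (per-cutoff cross-subject mean).
#' @export
estimate_fdr_curve <- function(tumor_delta, blood_delta,
                               grid = seq(0.05, 2, by = 0.05)) {
  if (length(grid) == 0L) .config_err("empty cutoff grid")
  if (any(diff(grid) <= 0) || any(grid <= 0))
    .config_err("cutoff grid must be positive and strictly increasing")
  stopifnot(identical(dim(tumor_delta), dim(blood_delta)))
  at <- abs(tumor_delta)
  ab <- abs(blood_delta)
  n_s <- ncol(tumor_delta)
  bc <- matrix(vapply(grid, function(c) colSums(ab >= c), numeric(n_s)),
               nrow = length(grid), ncol = n_s, byrow = TRUE)
  tc <- matrix(vapply(grid, function(c) colSums(at >= c), numeric(n_s)),
               nrow = length(grid), ncol = n_s, byrow = TRUE)
  fdr <- ifelse(tc > 0, bc / tc, 0)
  fdr <- pmin(fdr, 1)
  structure(list(grid = grid, blood_counts = bc, tumor_counts = tc,
                 subject_fdr = fdr, mean_fdr = rowMeans(fdr)),
            class = "lohscan_fdr_curve")
}

#' Select the gain/loss magnitude cutoff at a target mean FDR
#'
#' Default (global) mode: the smallest grid cutoff whose cross-subject mean
#' estimated FDR is at or below the target. The per-subject FDRs at that
#' cutoff are reported alongside (their range and median characterize the
#' spread across patients). A per-subject mode selects the smallest cutoff
#' separately for each subject.
#'
#' @param fdr_curve A [estimate_fdr_curve()] result.
#' @param target Target mean FDR (default 0.10).
#' @param per_subject Logical; select subject-specific cutoffs instead of
#'   one global cutoff.
#' @return Global mode: list with `cutoff`, `mean_fdr`, `subject_fdr`
#'   (vector at the chosen cutoff). Per-subject mode: list with `cutoffs`
#'   (vector) and `subject_fdr`.
#' @export
select_cutoff <- function(fdr_curve, target = 0.10, per_subject = FALSE) {
  stopifnot(inherits(fdr_curve, "lohscan_fdr_curve"))
  .check_number(target, "target", 0, 1)
  if (per_subject) {
    picks <- apply(fdr_curve$subject_fdr, 2, function(f) {
      i <- which(f <= target)[1L]
      if (is.na(i)) NA_integer_ else i
    })
    if (anyNA(picks))
      .err("lohscan_cutoff_error",
           "no grid cutoff attains the target FDR for %d subject(s); extend the grid or raise the target",
           sum(is.na(picks)))
    list(cutoffs = fdr_curve$grid[picks],
         subject_fdr = fdr_curve$subject_fdr[cbind(picks, seq_along(picks))])
  } else {
    i <- which(fdr_curve$mean_fdr <= target)[1L]
    if (is.na(i))
      .err("lohscan_cutoff_error",
           "no grid cutoff attains the target mean FDR %.3g; extend the grid or raise the target",
           target)
    list(cutoff = fdr_curve$grid[i],
         mean_fdr = fdr_curve$mean_fdr[i],
         subject_fdr = fdr_curve$subject_fdr[i, ])
  }
}

#' Final CNA calls at a chosen cutoff
#'
#' Per probe and sample, with `delta` the segmented tumor-minus-blood
#' deviation: `GAIN` when `delta >= cutoff`, `LOSS` when `delta <= -cutoff`,
#' else `NEUTRAL`. High-level amplification is flagged where `delta >= 5`.
#'
#' @param tumor_delta Segmented deviation matrix.
#' @param cutoff Positive magnitude cutoff (from [select_cutoff()]).
#' @return List of class `"lohscan_cna_calls"` with `class` (character
#'   matrix `GAIN`/`LOSS`/`NEUTRAL`), `delta`, `high_amp` (logical matrix),
#'   and `cutoff`.
#' @export
call_cna <- function(tumor_delta, cutoff) {
  .check_number(cutoff, "cutoff", 0, Inf, lo_open = TRUE)
  cls <- matrix("NEUTRAL", nrow(tumor_delta), ncol(tumor_delta),
                dimnames = dimnames(tumor_delta))
  cls[tumor_delta >= cutoff] <- "GAIN"
  cls[tumor_delta <= -cutoff] <- "LOSS"
  structure(list(class = cls, delta = tumor_delta,
                 high_amp = tumor_delta >= 5, cutoff = cutoff),
            class = "lohscan_cna_calls")
}

#' Joint LOH-by-CNA classification
#'
#' Total mapping of (LOH status, CNA class) to seven joint classes. A
#' non-informative LOH status maps to `UNINFORMATIVE` regardless of the CNA
#' class; LOH combines with gain, loss and neutral copy number (the last
#' being copy-neutral LOH).
#'
#' @param loh LOH status matrix (`L`/`R`/`N`).
#' @param cna A [call_cna()] result or a CNA class matrix aligned to `loh`.
#' @return Character matrix over `CN_GAIN_LOH`, `CN_LOSS_LOH`,
#'   `CN_NEUTRAL_LOH`, `GAIN_NO_LOH`, `LOSS_NO_LOH`, `NEUTRAL_NO_LOH`,
#'   `UNINFORMATIVE`.
#' @export
classify_joint <- function(loh, cna) {
  cls <- if (inherits(cna, "lohscan_cna_calls")) cna$class else cna
  if (!identical(dim(loh), dim(cls)))
    .err("lohscan_alignment_error",
         "LOH and CNA matrices have different dimensions")
  out <- matrix("UNINFORMATIVE", nrow(loh), ncol(loh), dimnames = dimnames(loh))
  out[loh == "L" & cls == "GAIN"] <- "CN_GAIN_LOH"
  out[loh == "L" & cls == "LOSS"] <- "CN_LOSS_LOH"
  out[loh == "L" & cls == "NEUTRAL"] <- "CN_NEUTRAL_LOH"
  out[loh == "R" & cls == "GAIN"] <- "GAIN_NO_LOH"
  out[loh == "R" & cls == "LOSS"] <- "LOSS_NO_LOH"
  out[loh == "R" & cls == "NEUTRAL"] <- "NEUTRAL_NO_LOH"
  out
}

#' Assemble a call set
#'
#' Bundles aligned LOH status, CNA calls and the joint classification into
#' the container consumed by the landscape, clustering and screening stages.
#'
#' @param loh LOH status matrix.
#' @param cna A [call_cna()] result.
#' @return List of class `"lohscan_callset"` with `loh`, `cna_class`,
#'   `delta`, `high_amp`, `joint`, `cutoff`.
#' @export
build_callset <- function(loh, cna) {
  stopifnot(inherits(cna, "lohscan_cna_calls"))
  structure(list(loh = loh,
                 cna_class = cna$class,
                 delta = cna$delta,
                 high_amp = cna$high_amp,
                 joint = classify_joint(loh, cna),
                 cutoff = cna$cutoff),
            class = "lohscan_callset")
}
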