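# LOH inference from paired genotype calls.
#
# Status codes: "L" = LOH (blood AB, tumor homozygous), "R" = retained
# (blood AB, tumor AB), "N" = non-informative (blood homozygous, or a
# no-call in either tissue). A probe can only evidence LOH in a patient
# whose germline is heterozygous there.

.GENO_CODES <- c("AA", "AB", "BB", "NC")

#' Call LOH from paired blood/tumor genotype matrices
#'
#' Per probe and sample: blood `AB` with tumor `AA`/`BB` is LOH (`L`);
#' blood `AB` with tumor `AB` is retained heterozygosity (`R`); a
#' homozygous blood call or a no-call in either tissue is non-informative
#' (`N`).
#'
#' @param blood,tumor Character matrices (probes x samples) with entries in
#'   `AA`, `AB`, `BB`, `NC` and identical dimnames.
#' @param exclude_probes Optional character vector of probe identifiers to
#'   drop before calling (e.g. a platform quality blacklist).
#' @return Character matrix of `L`/`R`/`N` codes with the (possibly
#'   filtered) probe rows and original sample columns.
#' @export
call_loh <- function(blood, tumor, exclude_probes = NULL) {
  if (!is.matrix(blood) || !is.matrix(tumor))
    .err("lohscan_alignment_error", "genotype inputs must be matrices")
  if (!identical(dim(blood), dim(tumor)) ||
      !identical(rownames(blood), rownames(tumor)) ||
      !identical(colnames(blood), colnames(tumor))) {
    bad_p <- union(setdiff(rownames(blood), rownames(tumor)),
                   setdiff(rownames(tumor), rownames(blood)))
    bad_s <- union(setdiff(colnames(blood), colnames(tumor)),
                   setdiff(colnames(tumor), colnames(blood)))
    .err("lohscan_alignment_error",
         "blood/tumor matrices are not aligned (probes off: %s; samples off: %s)",
         paste(utils::head(bad_p, 5), collapse = ","),
         paste(utils::head(bad_s, 5), collapse = ","))
  }
  bad <- !(blood %in% .GENO_CODES) | !(tumor %in% .GENO_CODES)
  if (any(bad))
    .err("lohscan_alignment_error", "unknown genotype codes in %d cells",
         sum(bad))
  if (!is.null(exclude_probes)) {
    keep <- !(rownames(blood) %in% exclude_probes)
    blood <- blood[keep, , drop = FALSE]
    tumor <- tumor[keep, , drop = FALSE]
  }
  status <- matrix("N", nrow(blood), ncol(blood), dimnames = dimnames(blood))
  informative <- blood == "AB" & tumor != "NC"
  status[informative & (tumor == "AA" | tumor == "BB")] <- "L"
  status[informative & tumor == "AB"] <- "R"
  status
}

#' Drop probes that are uninformative in every sample
#'
#' Removes every probe whose LOH status is `N` in all samples; such probes
#' cannot evidence LOH in any patient. Idempotent.
#'
#' @param loh LOH status matrix from [call_loh()].
#' @return List with `matrix` (the filtered status matrix), `retained` and
#'   `excluded` (character vectors of probe identifiers).
#' @export
filter_uninformative_snps <- function(loh) {
  if (nrow(loh) == 0L) {
    warning("empty LOH matrix: nothing to filter")
    return(list(matrix = loh, retained = character(0),
                excluded = character(0)))
  }
  keep <- rowSums(loh != "N") > 0L
  list(matrix = loh[keep, , drop = FALSE],
       retained = rownames(loh)[keep],
       excluded = rownames(loh)[!keep])
}

#' Per-probe LOH frequency
#'
#' Fraction of samples with LOH at each probe. The default denominator is
#' the number of informative samples (germline-heterozygous with both calls
#' present): a germline-homozygous patient cannot evidence LOH. The `"all"`
#' mode divides by the total sample count instead.
#'
#' @param loh LOH status matrix.
#' @param denominator `"informative"` (default) or `"all"`.
#' @return Named numeric vector of fractions in \[0, 1\]; `NA` where a probe
#'   has zero informative samples (informative mode).
#' @export
loh_frequency <- function(loh, denominator = c("informative", "all")) {
  if (identical(denominator, c("informative", "all")))
    denominator <- "informative"
  if (length(denominator) != 1L || !denominator %in% c("informative", "all"))
    .config_err("'denominator' must be \"informative\" or \"all\"")
  n_loh <- rowSums(loh == "L")
  if (denominator == "all") return(n_loh / ncol(loh))
  n_inf <- n_loh + rowSums(loh == "R")
  ifelse(n_inf > 0L, n_loh / n_inf, NA_real_)
}
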