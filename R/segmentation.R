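# Recursive binary segmentation of a per-probe difference series.
#
# The tumor is segmented on d = tumor - blood (the paired difference); the
# blood sample runs through the identical procedure on d = blood - 2, so
# both tissues are segmented with the same parameters and the blood-null
# FDR curve compares like with like.

# Change-point positions (last index of the left child) for one series.
.bseg_breaks <- function(x, t_threshold, min_seg_len) {
  n <- length(x)
  breaks <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1L]; hi <- seg[2L]
    m <- hi - lo + 1L
    if (m < 2L * min_seg_len) next
    xs <- x[lo:hi]
    s <- cumsum(xs)
    ss <- cumsum(xs * xs)
    k <- min_seg_len:(m - min_seg_len)
    n1 <- k
    n2 <- m - k
    m1 <- s[k] / n1
    m2 <- (s[m] - s[k]) / n2
    rss1 <- pmax(ss[k] - n1 * m1 * m1, 0)
    rss2 <- pmax((ss[m] - ss[k]) - n2 * m2 * m2, 0)
    se <- sqrt(((rss1 + rss2) / (m - 2L)) * (1 / n1 + 1 / n2))
    dm <- abs(m1 - m2)
    tt <- ifelse(se > 0, dm / se, ifelse(dm > 1e-12, Inf, 0))
    best <- which.max(tt)  # first maximum: deterministic tie-break
    if (tt[best] > t_threshold) {
      cut <- lo + k[best] - 1L
      breaks <- c(breaks, cut)
      stack <- c(stack, list(c(lo, cut), c(cut + 1L, hi)))
    }
  }
  sort(breaks)
}

#' Segment a paired copy-number difference series
#'
#' Recursive binary segmentation of `d = tumor - blood`: at each step the
#' split maximizing the two-sample t-statistic (pooled variance) between the
#' flanks is accepted iff `|t| > t_threshold` and both children have at
#' least `min_seg_len` probes. Chromosomes are segmented independently when
#' `chrom` is supplied. Deterministic; ties go to the left-most split.
#'
#' To segment a blood sample against its diploid reference, pass the blood
#' signal as `tumor` and a constant 2 as `blood`.
#'
#' @param tumor,blood Numeric vectors of per-probe signal, CN scale, in
#'   genome order. `blood` may be a single number (a constant reference).
#' @param chrom Optional vector of chromosome labels per probe; segmentation
#'   never crosses a chromosome boundary.
#' @param t_threshold Minimum |t| to accept a split (default 4.0).
#' @param min_seg_len Minimum probes per segment (default 10). A chromosome
#'   shorter than this yields a single segment with a warning.
#' @return List with `segments`, a data frame (`chrom`, `start`, `end`,
#'   `n_probes`, `seg_mean` -- 1-based inclusive probe indices, global) and
#'   `delta`, the per-probe segment mean of `d`.
#' @export
segment_paired <- function(tumor, blood = 2, chrom = NULL,
                           t_threshold = 4.0, min_seg_len = 10L) {
  .check_number(t_threshold, "t_threshold", 0, Inf)
  min_seg_len <- .check_count(min_seg_len, "min_seg_len")
  d <- tumor - blood
  n <- length(d)
  if (n == 0L) .config_err("empty signal vector")
  if (is.null(chrom)) chrom <- rep("chr", n)
  if (length(chrom) != n) .config_err("'chrom' length does not match signal")
  if (anyNA(d)) .config_err("signal contains missing values")

  chrom <- factor(chrom, levels = unique(chrom))
  delta <- numeric(n)
  seg_rows <- vector("list", nlevels(chrom))
  offset <- 0L
  for (li in seq_len(nlevels(chrom))) {
    idx <- which(as.integer(chrom) == li)
    x <- d[idx]
    if (length(x) < min_seg_len)
      warning(sprintf("chromosome %s has fewer probes (%d) than min_seg_len; returning one segment",
                      levels(chrom)[li], length(x)))
    br <- if (length(x) >= 2L * min_seg_len)
      .bseg_breaks(x, t_threshold, min_seg_len) else integer(0)
    starts <- c(1L, br + 1L)
    ends <- c(br, length(x))
    means <- vapply(seq_along(starts),
                    function(i) mean(x[starts[i]:ends[i]]), numeric(1))
    for (i in seq_along(starts))
      delta[idx[starts[i]:ends[i]]] <- means[i]
    seg_rows[[li]] <- data.frame(chrom = levels(chrom)[li],
                                 start = offset + starts,
                                 end = offset + ends,
                                 n_probes = ends - starts + 1L,
                                 seg_mean = means,
                                 stringsAsFactors = FALSE)
    offset <- offset + length(x)
  }
  list(segments = do.call(rbind, seg_rows), delta = delta)
}

#' Segment every sample of a paired cohort
#'
#' Runs [segment_paired()] on each sample twice: the tumor against its
#' matched blood (difference series) and the blood against the constant
#' diploid reference 2, with identical parameters. The two per-probe
#' segment-mean matrices feed the blood-null FDR curve.
#'
#' @param tumor_signal,blood_signal Numeric matrices (probes x samples).
#' @param annotation Annotation data frame with a `chrom` column in the
#'   matrices' probe order.
#' @param t_threshold,min_seg_len Passed to [segment_paired()].
#' @return List with `tumor_delta` and `blood_delta`, numeric matrices of
#'   per-probe segmented deviations (tumor minus blood; blood minus 2), and
#'   `segments`, a per-sample list of tumor segment tables.
#' @export
segment_cohort <- function(tumor_signal, blood_signal, annotation,
                           t_threshold = 4.0, min_seg_len = 10L) {
  stopifnot(is.matrix(tumor_signal), is.matrix(blood_signal),
            identical(dim(tumor_signal), dim(blood_signal)))
  if (nrow(annotation) != nrow(tumor_signal))
    .err("lohscan_annotation_error",
         "annotation has %d probes but signal has %d rows",
         nrow(annotation), nrow(tumor_signal))
  chrom <- annotation$chrom
  n_s <- ncol(tumor_signal)
  tumor_delta <- matrix(0, nrow(tumor_signal), n_s,
                        dimnames = dimnames(tumor_signal))
  blood_delta <- tumor_delta
  segments <- vector("list", n_s)
  names(segments) <- colnames(tumor_signal)
  for (j in seq_len(n_s)) {
    st <- segment_paired(tumor_signal[, j], blood_signal[, j], chrom,
                         t_threshold, min_seg_len)
    sb <- segment_paired(blood_signal[, j], 2, chrom,
                         t_threshold, min_seg_len)
    tumor_delta[, j] <- st$delta
    blood_delta[, j] <- sb$delta
    segments[[j]] <- st$segments
  }
  list(tumor_delta = tumor_delta, blood_delta = blood_delta,
       segments = segments)
}
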