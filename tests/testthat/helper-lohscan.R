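# Shared fixtures built in code.

# One small chromosome pair, n_p probes total (half p, half q).
small_layout <- function(n_p = 200L) {
  data.frame(chrom = c("chr1", "chr1"), arm = c("p", "q"),
             n_probes = c(n_p %/% 2L, n_p - n_p %/% 2L),
             stringsAsFactors = FALSE)
}

small_config <- function(n_samples = 30L, n_p = 200L, seed = 1L, ...) {
  cohort_config(n_samples = n_samples, chrom_layout = small_layout(n_p),
                aberration_spec = list(), seed = seed, ...)
}

# Build a callset directly from an LOH status matrix and a ternary CNA code
# matrix (the code doubles as the segmented delta).
callset_from <- function(loh, code, cutoff = 0.5) {
  dimnames(code) <- dimnames(loh)
  build_callset(loh, call_cna(code, cutoff))
}

# Random but seeded LOH / CNA matrices for screen-level tests.
random_callset <- function(n_p, n_s, seed,
                           p_loh = 0.25, p_ret = 0.45,
                           p_gain = 0.2, p_loss = 0.2) {
  set.seed(seed)
  loh <- matrix(sample(c("L", "R", "N"), n_p * n_s, TRUE,
                       prob = c(p_loh, p_ret, 1 - p_loh - p_ret)),
                n_p, n_s,
                dimnames = list(sprintf("P%05d", seq_len(n_p)),
                                sprintf("S%03d", seq_len(n_s))))
  code <- matrix(sample(c(1, -1, 0), n_p * n_s, TRUE,
                        prob = c(p_gain, p_loss, 1 - p_gain - p_loss)),
                 n_p, n_s)
  callset_from(loh, code)
}

# Minimal clinical table for hand-built survival designs.
toy_clinical <- function(time, event, sex = NULL, age = NULL,
                         smoking = NULL) {
  n <- length(time)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             sex = sex %||% rep(c("male", "female"), length.out = n),
             age = age %||% seq(45, 75, length.out = n),
             smoking = smoking %||% rep(c("never", "former", "current"),
                                        length.out = n),
             alcohol = "yes", stage = "II", site = "oral_cavity",
             nodal = "negative",
             time_months = time,
             vital_status = ifelse(event == 1, "OSCC_death", "censored"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
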