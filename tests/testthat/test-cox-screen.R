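# Cox screen: design encoding, partial-likelihood fitting against an
# independent Newton oracle, nested LRTs, and the genome-wide screen.

test_that("design encoding follows the ternary CNA / binary LOH convention", {
  loh <- matrix(c("L", "R", "N"), 3, 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "P3"),
                                c("S001", "S002", "S003")))
  code <- matrix(c(1, 0, -1), 3, 3, byrow = TRUE)
  cs <- callset_from(loh, code)
  clin <- toy_clinical(time = c(10, 20, 30), event = c(1, 0, 1))
  clin$vital_status[2] <- "other_death"
  d <- encode_design(cs, clin, "P1")
  expect_equal(d$cna, c(1, 0, -1))
  expect_equal(d$loh, c(1, 0, 0))          # N counts as no evidence of LOH
  expect_equal(d$event, c(1, 0, 1))        # other-cause death censored
  expect_equal(d$time[2], 20)
  expect_equal(d$smoke_former, c(0, 1, 0))
  expect_equal(d$smoke_current, c(0, 0, 1))
})

test_that("a sample missing from the clinical table is a join error", {
  cs <- random_callset(3L, 3L, seed = 70L)
  clin <- toy_clinical(time = c(10, 20), event = c(1, 0))
  expect_error(encode_design(cs, clin, "P00001"), "S003",
               class = "lohscan_join_error")
})

test_that("fitted beta matches an independent Newton partial-likelihood oracle", {
  # small dataset, distinct times, one binary covariate
  d <- data.frame(time = c(2, 5, 7, 10, 12, 16, 19, 23),
                  event = c(1, 1, 0, 1, 1, 0, 1, 1),
                  x = c(1, 0, 1, 1, 0, 0, 1, 0))
  # Breslow-free oracle: no ties, so the partial likelihood is exact
  logpl <- function(b) {
    ll <- 0
    for (i in which(d$event == 1)) {
      risk <- d$time >= d$time[i]
      ll <- ll + b * d$x[i] - log(sum(exp(b * d$x[risk])))
    }
    ll
  }
  oracle <- stats::optimize(logpl, c(-5, 5), maximum = TRUE)$maximum
  fit <- fit_cox(d, "x")
  expect_equal(unname(fit$coef[["x"]]), oracle, tolerance = 1e-4)
  expect_equal(fit$loglik, logpl(oracle), tolerance = 1e-6)
})

test_that("beta is recovered from a proportional-hazards simulation", {
  set.seed(71)
  n <- 400L
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.02 * exp(0.8 * x))
  cens <- runif(n, 0, 80)
  d <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens), x = x)
  fit <- fit_cox(d, "x")
  expect_lt(abs(fit$coef[["x"]] - 0.8), 0.25)
})

test_that("degenerate designs raise classed errors", {
  d <- data.frame(time = 1:5, event = c(1, 0, 1, 0, 1), x = 1)
  expect_error(fit_cox(d, "x"), class = "lohscan_degenerate_design")
  d0 <- data.frame(time = 1:5, event = 0, x = rnorm(5))
  expect_error(fit_cox(d0, "x"), class = "lohscan_degenerate_design")
})

test_that("the LRT matches the chi-square tail and rejects non-nested input", {
  f1 <- list(loglik = -10, terms = c("a", "b"))
  expect_equal(lrt(f1, f1)$p_value, 1)
  f0 <- list(loglik = -11.92, terms = "a")
  res <- lrt(f1, f0, df = 1L)
  expect_equal(res$statistic, 3.84, tolerance = 1e-9)
  expect_equal(res$p_value, stats::pchisq(3.84, 1, lower.tail = FALSE))
  expect_error(lrt(f1, list(loglik = -9, terms = "z")),
               class = "lohscan_usage_error")
})

test_that("the screen filters on the LOH-count boundary (fewer than 5)", {
  n_s <- 60L
  set.seed(72)
  loh <- matrix(sample(c("R", "N"), 6 * n_s, TRUE), 6, n_s,
                dimnames = list(sprintf("P%d", 1:6), sprintf("S%03d", 1:n_s)))
  loh[1, 1:4] <- "L"   # 4 carriers: excluded
  loh[2, 1:5] <- "L"   # 5 carriers: retained
  loh[3, 1:20] <- "L"
  code <- matrix(sample(c(-1, 0, 1), 6 * n_s, TRUE), 6, n_s)
  cs <- callset_from(loh, code)
  set.seed(73)
  clin <- toy_clinical(time = rexp(n_s, 0.02), event = rbinom(n_s, 1, 0.5))
  res <- screen(cs, clin, min_loh_samples = 5L)
  expect_false("P1" %in% res$probe_id)
  expect_true("P2" %in% res$probe_id)
  expect_true(all(res$p_all > 0 & res$p_all <= 1))
  expect_equal(attr(res, "bonferroni_cutoff"), 0.05 / nrow(res))
})

test_that("a planted opposite-sign interaction is reported per stratum", {
  # gain raises the hazard under LOH and lowers it without LOH
  region <- 40:80
  abs_l <- list(
    aberration("chr1", 40L, 80L, "LOH_gain", carriers = 1:60),
    aberration("chr1", 40L, 80L, "gain_only", carriers = 61:120),
    aberration("chr1", 40L, 80L, "LOH_neutral", carriers = 121:180))
  sp <- survival_spec(baseline_rate = 0.01, effect_probes = 60L,
                      beta_cna = -1.2, beta_loh = 0.3,
                      beta_interaction = 2.4)
  cc <- cohort_config(n_samples = 240L, chrom_layout = small_layout(200L),
                      aberration_spec = abs_l, survival_spec = sp,
                      seed = 74L)
  coh <- simulate_cohort(cc)
  seg <- segment_cohort(coh$tumor_signal, coh$blood_signal, coh$annotation)
  calls <- call_cna(seg$tumor_delta,
                    select_cutoff(estimate_fdr_curve(seg$tumor_delta,
                                                     seg$blood_delta))$cutoff)
  cs <- build_callset(call_loh(coh$blood_genotype, coh$tumor_genotype), calls)
  d <- encode_design(cs, coh$clinical, "P00060")
  fit <- fit_cox(d, c("cna", "loh", "cna:loh",
                      "sex_male", "age", "smoke_former", "smoke_current"))
  expect_lt(fit$coef[["cna"]], 0)
  expect_gt(fit$coef[["cna"]] + fit$coef[["cna:loh"]], 0)
})
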