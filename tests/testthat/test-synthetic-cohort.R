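# Synthetic paired-cohort generator: determinism, boundary behavior,
# implantation semantics, conservation, and the survival model.

test_that("generation is a pure function of the configuration", {
  cc <- small_config(seed = 11L)
  g1 <- generate_germline(cc)
  g2 <- generate_germline(cc)
  expect_identical(g1, g2)
  c1 <- simulate_cohort(cc)
  c2 <- simulate_cohort(cc)
  expect_identical(c1$tumor_signal, c2$tumor_signal)
  expect_identical(c1$clinical, c2$clinical)
})

test_that("het_rate boundary: zero heterozygosity means zero AB calls", {
  cc <- small_config(het_rate = 0, seed = 3L)
  g <- generate_germline(cc)
  expect_false(any(g == "AB"))
})

test_that("observed het fraction concentrates at het_rate", {
  lay <- data.frame(chrom = "chr1", arm = c("p", "q"),
                    n_probes = c(500L, 500L))
  cc <- cohort_config(n_samples = 1000L, chrom_layout = lay,
                      het_rate = 0.3, nc_rate = 0,
                      aberration_spec = list(), seed = 5L)
  g <- generate_germline(cc)
  n <- length(g)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(g == "AB") - 0.3), 3 * se)
})

test_that("null cohort with zero noise is exactly diploid and unmutated", {
  cc <- small_config(cn_noise_sd = 0, genotype_error_rate = 0, seed = 2L)
  g <- generate_germline(cc)
  imp <- implant_aberrations(g, cc)
  expect_true(all(imp$tumor_signal == 2))
  expect_true(all(imp$blood_signal == 2))
  expect_identical(imp$tumor_genotype, g)
  expect_true(all(imp$truth$true_cn == 2L))
})

test_that("copy-neutral LOH at carrier fraction 1 homozygoses every blood-het probe", {
  ab <- aberration("chr1", 30L, 80L, "LOH_neutral", carrier_fraction = 1)
  cc <- cohort_config(n_samples = 20L, chrom_layout = small_layout(200L),
                      genotype_error_rate = 0, nc_rate = 0,
                      aberration_spec = list(ab), seed = 4L)
  g <- generate_germline(cc)
  imp <- implant_aberrations(g, cc)
  inside <- 30:80
  het <- g[inside, ] == "AB"
  expect_true(all(imp$tumor_genotype[inside, ][het] %in% c("AA", "BB")))
  expect_true(all(imp$truth$true_cn[inside, ] == 2L))
  # LOH truth is recorded exactly at the observable (blood-het) loci
  expect_identical(imp$truth$true_loh[inside, ], het)
})

test_that("high-level amplification implants tumor-minus-blood CN of at least 5", {
  ab <- aberration("chr1", 120L, 160L, "high_amp", carrier_fraction = 0.5)
  cc <- cohort_config(n_samples = 20L, chrom_layout = small_layout(200L),
                      aberration_spec = list(ab), seed = 6L)
  imp <- implant_aberrations(generate_germline(cc), cc)
  carriers <- imp$truth$segments[[1L]]$carriers
  expect_true(all(imp$truth$true_cn[120:160, carriers] - 2L >= 5L))
})

test_that("contradictory overlapping aberrations are rejected", {
  abs_bad <- list(
    aberration("chr1", 10L, 60L, "LOH_neutral", carriers = 1:5),
    aberration("chr1", 40L, 90L, "gain_only", carriers = 3:8))
  cc <- cohort_config(n_samples = 10L, chrom_layout = small_layout(200L),
                      aberration_spec = abs_bad, seed = 1L)
  expect_error(implant_aberrations(generate_germline(cc), cc),
               class = "lohscan_generation_error")
  # disjoint carriers over the same probes are fine
  abs_ok <- list(
    aberration("chr1", 10L, 60L, "LOH_neutral", carriers = 1:5),
    aberration("chr1", 40L, 90L, "gain_only", carriers = 6:8))
  cc2 <- cohort_config(n_samples = 10L, chrom_layout = small_layout(200L),
                       aberration_spec = abs_ok, seed = 1L)
  expect_no_error(implant_aberrations(generate_germline(cc2), cc2))
})

test_that("LOH conservation: truth count equals carriers x blood-het probes", {
  ab <- aberration("chr1", 50L, 150L, "LOH_loss", carrier_fraction = 0.4)
  cc <- cohort_config(n_samples = 25L, chrom_layout = small_layout(200L),
                      genotype_error_rate = 0.05,  # errors must not touch truth
                      aberration_spec = list(ab), seed = 9L)
  g <- generate_germline(cc)
  imp <- implant_aberrations(g, cc)
  seg <- imp$truth$segments[[1L]]
  expected <- sum(g[seg$probes, seg$carriers] == "AB")
  expect_identical(sum(imp$truth$true_loh), expected)
})

test_that("invalid configuration fields raise errors naming the field", {
  expect_error(small_config(het_rate = 1.2), "het_rate",
               class = "lohscan_config_error")
  expect_error(small_config(genotype_error_rate = 0.3),
               "genotype_error_rate", class = "lohscan_config_error")
  expect_error(survival_spec(baseline_rate = -1), "baseline_rate",
               class = "lohscan_config_error")
  expect_error(
    cohort_config(chrom_layout = small_layout(100L),
                  aberration_spec = list(
                    aberration("chr1", 50L, 150L, "gain_only",
                               carrier_fraction = 0.5))),
    class = "lohscan_config_error")
  expect_error(small_config(seed = 2^31), class = "lohscan_config_error")
})

test_that("null survival model yields exponential tumor-death times", {
  sp <- survival_spec(baseline_rate = 0.01, other_death_rate = 0,
                      censor_min = Inf, censor_max = Inf,
                      beta_sex = 0, beta_age = 0,
                      beta_smoke_former = 0, beta_smoke_current = 0)
  cc <- small_config(n_samples = 400L, seed = 21L, survival_spec = sp)
  coh <- simulate_cohort(cc)
  expect_true(all(coh$clinical$vital_status == "OSCC_death"))
  # mean of Exp(0.01) is 100 with se 100/sqrt(n)
  expect_lt(abs(mean(coh$clinical$time_months) - 100), 3 * 100 / sqrt(400))
})

test_that("a strong LOH effect shortens carrier survival", {
  ab <- aberration("chr1", 90L, 110L, "LOH_neutral", carriers = 1:100)
  sp <- survival_spec(baseline_rate = 0.01, other_death_rate = 0,
                      censor_min = Inf, censor_max = Inf,
                      effect_probes = 100L, beta_loh = 1.5,
                      beta_sex = 0, beta_age = 0,
                      beta_smoke_former = 0, beta_smoke_current = 0)
  cc <- cohort_config(n_samples = 250L, chrom_layout = small_layout(200L),
                      aberration_spec = list(ab), survival_spec = sp,
                      seed = 22L)
  coh <- simulate_cohort(cc)
  loh_here <- coh$truth$true_loh[100L, ]
  expect_gt(sum(loh_here), 10)
  t_loh <- coh$clinical$time_months[loh_here]
  t_other <- coh$clinical$time_months[!loh_here]
  expect_lt(median(t_loh), median(t_other))
  expect_equal(unname(attr(coh$clinical, "true_lp")),
               1.5 * as.numeric(loh_here))
})
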