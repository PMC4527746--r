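# Clustering and association: planted partitions, hand-worked linkage,
# Fisher enumeration, log-rank risk-table oracle, and the cluster Cox LRT.

test_that("a planted two-block CNA structure is recovered", {
  ab <- aberration("chr1", 120L, 160L, "high_amp", carriers = 1:10,
                   defines_cluster = TRUE)
  cc <- cohort_config(n_samples = 30L, chrom_layout = small_layout(200L),
                      cn_noise_sd = 0, aberration_spec = list(ab),
                      seed = 91L)
  coh <- simulate_cohort(cc)
  seg <- segment_cohort(coh$tumor_signal, coh$blood_signal, coh$annotation)
  cs <- build_callset(call_loh(coh$blood_genotype, coh$tumor_genotype),
                      call_cna(seg$tumor_delta, 0.5))
  cl <- cluster_samples(cs, "cna")
  agree <- max(mean(cl$labels == coh$truth$true_cluster),
               mean(cl$labels == 3L - coh$truth$true_cluster))
  expect_equal(agree, 1)
})

test_that("the partition is invariant to sample order", {
  cs <- random_callset(80L, 20L, seed = 92L)
  cl1 <- cluster_samples(cs, "loh")
  perm <- sample(20L)
  cs2 <- cs
  cs2$loh <- cs$loh[, perm]
  cs2$delta <- cs$delta[, perm]
  cs2$cna_class <- cs$cna_class[, perm]
  cl2 <- cluster_samples(cs2, "loh")
  a <- cl1$labels[colnames(cs2$loh)]
  b <- cl2$labels
  expect_true(all(a == b) || all(a == 3L - b))
})

test_that("merge heights match a hand-worked complete-linkage pass", {
  # 4 samples in one dimension at positions 0, 1, 5, 9
  delta <- matrix(c(0, 1, 5, 9), nrow = 1,
                  dimnames = list("P1", c("A", "B", "C", "D")))
  loh <- matrix("R", 1, 4, dimnames = dimnames(delta))
  cs <- build_callset(loh, call_cna(delta, 0.5))
  cl <- cluster_samples(cs, "cna")
  # by hand: merge A,B at 1; then C,D at 4; then both at max dist 9
  expect_equal(sort(cl$hclust$height), c(1, 4, 9))
  expect_equal(unname(cl$labels), c(1L, 1L, 2L, 2L))
})

test_that("identical samples give a flagged single-cluster result", {
  delta <- matrix(1, 5, 4, dimnames = list(sprintf("P%d", 1:5),
                                           c("A", "B", "C", "D")))
  loh <- matrix("R", 5, 4, dimnames = dimnames(delta))
  cs <- build_callset(loh, call_cna(delta, 0.5))
  cl <- cluster_samples(cs, "cna")
  expect_true(cl$degenerate)
  expect_equal(unname(cl$labels), rep(1L, 4))
})

test_that("Fisher exact agrees with direct hypergeometric enumeration", {
  # balanced table: no association
  expect_equal(fisher_exact(rep(1:2, each = 10),
                            rep(c("x", "y"), 10))$p_value, 1)
  # 2x2 [[5,1],[1,5]]: enumerate tables with fixed margins 6/6, 6/6
  probs <- dhyper(0:6, 6, 6, 6)
  expect_equal(sum(probs), 1, tolerance = 1e-10)  # probability conservation
  p_oracle <- sum(probs[probs <= dhyper(5, 6, 6, 6) + 1e-12])
  labels <- rep(c(1, 2), each = 6)
  covar <- c(rep("x", 5), "y", "x", rep("y", 5))
  expect_equal(fisher_exact(labels, covar)$p_value, p_oracle,
               tolerance = 1e-10)
  # 2x3 with identical rows
  lab <- rep(1:2, each = 6)
  cov3 <- rep(c("a", "b", "c"), 4)
  expect_equal(fisher_exact(lab, cov3)$p_value, 1)
})

test_that("log-rank output matches a hand-worked risk table", {
  # 6 patients: group A times 2+, 4+, 6c; group B 1+, 3+, 5c (+ = death)
  clin <- toy_clinical(time = c(2, 4, 6, 1, 3, 5),
                       event = c(1, 1, 0, 1, 1, 0))
  labels <- c(1, 1, 1, 2, 2, 2)
  res <- compare_mortality(labels, clin)
  # risk table by hand (O and E for group A, hypergeometric variance):
  # t=1: n=6 nA=3, d=1 in B -> E += 3/6,  V += (3/6)(3/6)(5/5)
  # t=2: n=5 nA=3, d=1 in A -> E += 3/5,  V += (3/5)(2/5)(4/4)
  # t=3: n=4 nA=2, d=1 in B -> E += 2/4,  V += (2/4)(2/4)(3/3)
  # t=4: n=3 nA=2, d=1 in A -> E += 2/3,  V += (2/3)(1/3)(2/2)
  E <- 3 / 6 + 3 / 5 + 2 / 4 + 2 / 3
  V <- 0.25 + 0.24 + 0.25 + 2 / 9
  stat <- (2 - E)^2 / V
  expect_equal(res$statistic, stat, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE))
  expect_equal(res$observed, c(2, 2))
  # invariant under group relabeling
  res2 <- compare_mortality(3 - labels, clin)
  expect_equal(res2$statistic, res$statistic)
  # cumulative incidence is 1 - KM per cluster
  expect_true(all(res$curves$cum_incidence >= 0 &
                    res$curves$cum_incidence <= 1))
})

test_that("identical groups and event-free groups degrade gracefully", {
  clin <- toy_clinical(time = rep(c(3, 6, 9), 2), event = rep(c(1, 1, 0), 2))
  res <- compare_mortality(rep(1:2, each = 3), clin[c(1:3, 1:3), ])
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  clin0 <- toy_clinical(time = 1:6, event = rep(0, 6))
  expect_warning(res0 <- compare_mortality(rep(1:2, 3), clin0), "no tumor")
  expect_equal(res0$p_value, 1)
})

test_that("the cluster Cox LRT matches the nested-model computation", {
  set.seed(93)
  n <- 80L
  grp <- rep(1:2, each = n / 2)
  t <- rexp(n, 0.02 * exp(0.9 * (grp == 2)))
  clin <- toy_clinical(time = pmin(t, 60), event = as.integer(t <= 60))
  res <- cluster_covariate_cox(grp, clin, adjusters = character(0))
  d <- data.frame(time = clin$time_months,
                  event = as.integer(clin$vital_status == "OSCC_death"),
                  cluster2 = as.integer(grp == 2))
  fit <- fit_cox(d, "cluster2")
  stat <- 2 * (fit$loglik - fit$loglik_null)
  expect_equal(res$statistic, stat, tolerance = 1e-8)
  expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE))
})

test_that("a cluster label duplicating an adjuster is rejected", {
  clin <- toy_clinical(time = c(5, 8, 12, 20), event = c(1, 1, 0, 1),
                       sex = c("male", "male", "female", "female"))
  labels <- c(2, 2, 1, 1)  # cluster2 == sex_male exactly
  expect_error(cluster_covariate_cox(labels, clin, adjusters = "sex"),
               class = "lohscan_degenerate_design")
})

test_that("a strong planted survival difference is detected by log-rank", {
  hits <- 0L
  for (r in 1:10) {
    set.seed(200 + r)
    n <- 150L
    grp <- rep(1:2, c(50L, 100L))
    t <- rexp(n, 0.015 * exp(1.2 * (grp == 1)))
    cens <- runif(n, 40, 100)
    clin <- toy_clinical(time = pmin(t, cens), event = as.integer(t <= cens))
    if (compare_mortality(grp, clin)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})
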