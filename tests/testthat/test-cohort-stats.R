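test_that("signed-rank test reproduces enumeration on canonical cases", {
  allPos <- wilcoxonSignedRank(c(0.4, 1.1, 2.3, 3.1, 4.7, 5.2))
  expect_equal(allPos$p_two_tailed, 2 / 64)
  expect_equal(allPos$statistic, 21)
  expect_equal(allPos$method, "exact")
  # antisymmetric differences sit at the null centre
  anti <- wilcoxonSignedRank(c(1.5, -1.5, 2.5, -2.5))
  expect_equal(anti$p_two_tailed, 1)
  expect_error(wilcoxonSignedRank(rep(0, 5)), "degenerate")
  # zeros are dropped before ranking
  expect_equal(wilcoxonSignedRank(c(0, 0, 1, 2, 3))$n_effective, 3)
})

test_that("exact signed-rank p equals brute-force sign enumeration", {
  set.seed(53)
  for (i in 1:50) {
    n <- sample(3:10, 1)
    d <- round(rnorm(n, sd = 3), if (i %% 2) 3 else 0)  # even i: many ties
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxonSignedRank(d)$p_two_tailed, bruteSignedRankP(d),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with the stats reference when ties are absent", {
  set.seed(59)
  for (i in 1:20) {
    d <- rnorm(sample(4:12, 1))
    expect_equal(wilcoxonSignedRank(d)$p_two_tailed,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # large n goes through the tie-corrected normal approximation
  d <- rnorm(40)
  res <- wilcoxonSignedRank(d)
  expect_equal(res$method, "normal-approximation")
  expect_equal(res$p_two_tailed,
               wilcox.test(d, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("Mann-Whitney U reproduces enumeration on canonical cases", {
  res <- mannWhitneyU(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_tailed, 2 / choose(6, 3))
  same <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_two_tailed, 1)
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney p equals brute-force labeling enumeration", {
  set.seed(61)
  for (i in 1:50) {
    nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    a <- rnorm(nA); b <- rnorm(nB, mean = sample(c(0, 2), 1))
    expect_equal(mannWhitneyU(a, b)$p_two_tailed, bruteMannWhitneyP(a, b),
                 tolerance = 1e-12)
    expect_equal(mannWhitneyU(a, b)$p_two_tailed,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("p-values live in (0, 1] for adversarial inputs", {
  set.seed(67)
  for (i in 1:30) {
    d <- sample(c(-2, -1, 1, 2, 5), sample(2:30, 1), replace = TRUE)
    p <- wilcoxonSignedRank(d)$p_two_tailed
    expect_gt(p, 0); expect_lte(p, 1)
    a <- sample(5, sample(2:15, 1), TRUE)
    b <- sample(5, sample(2:15, 1), TRUE)
    p2 <- mannWhitneyU(a, b)$p_two_tailed
    expect_gt(p2, 0); expect_lte(p2, 1)
  }
})

test_that("median split keeps ties in the low group", {
  g <- medianSplit(c(1, 2, 3))
  expect_equal(as.character(g), c("low", "low", "high"))
  g2 <- medianSplit(c(1, 1, 1, 5))
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  expect_equal(attr(g2, "cutoff"), 1)
  expect_warning(medianSplit(c(2, 2, 2)), "degenerate")
  # n = 15 gives the 8/7 split
  expect_equal(as.numeric(table(medianSplit(1:15))), c(7, 8))
})

test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- kaplanMeier(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))
  cens <- kaplanMeier(c(3, 5, 8), c(0, 0, 0))
  expect_equal(cens$survival, rep(1, 3))
  # duplicating every subject leaves the curve unchanged
  t0 <- c(1, 3, 4, 7); e0 <- c(1, 0, 1, 1)
  km1 <- kaplanMeier(t0, e0)
  km2 <- kaplanMeier(rep(t0, 2), rep(e0, 2))
  expect_equal(km2$survival, km1$survival)
  expect_error(kaplanMeier(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  set.seed(71)
  tt <- sample(1:20, 12, replace = TRUE)
  km <- kaplanMeier(tt, rep(1, 12))
  ecdfS <- vapply(km$time, function(t) mean(tt > t), numeric(1))
  expect_equal(km$survival, ecdfS)
})

test_that("Kaplan-Meier agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(73)
  tt <- round(rexp(25, 0.1), 1); ev <- rbinom(25, 1, 0.7)
  km <- kaplanMeier(tt, ev)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  at <- match(km$time, sf$time)
  expect_equal(km$survival, sf$surv[at], tolerance = 1e-12)
})

test_that("log-rank matches the hand-computed toy table", {
  # group A: events at 1 and 4; group B: event at 2, censored at 5
  times <- c(1, 4, 2, 5); events <- c(1, 1, 1, 0)
  group <- c("A", "A", "B", "B")
  lr <- logRankTest(times, events, group)
  # O_A = 2; E_A = 1/2 + 1/3 + 1/2 = 4/3; V = 1/4 + 2/9 + 1/4 = 13/18
  expect_equal(lr$observed[1], 2)
  expect_equal(lr$expected[1], 4 / 3, tolerance = 1e-12)
  expect_equal(lr$chisq, (2 - 4 / 3)^2 / (13 / 18), tolerance = 1e-12)
  expect_equal(lr$p_two_tailed, pchisq((2 - 4 / 3)^2 / (13 / 18), 1,
                                       lower.tail = FALSE))
})

test_that("identical groups give chi-square zero, p = 1", {
  times <- c(1, 2, 3, 1, 2, 3); events <- c(1, 1, 0, 1, 1, 0)
  lr <- logRankTest(times, events, rep(c("A", "B"), each = 3))
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p_two_tailed, 1)
  expect_error(logRankTest(c(1, 2), c(0, 0), c("A", "B")), "degenerate")
})

test_that("log-rank agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(79)
  for (i in 1:10) {
    n <- sample(8:30, 1)
    tt <- round(rexp(n, 0.1), 1)
    ev <- rbinom(n, 1, 0.8)
    gg <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(gg)) < 2 || sum(ev) == 0) next
    lr <- logRankTest(tt, ev, gg)
    sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ gg)
    expect_equal(lr$chisq, unname(sd_$chisq), tolerance = 1e-9)
  }
})

test_that("covariate comparison splits the clinical cohort as published", {
  md <- readMetadata(system.file("extdata", "lung15_clinical.tsv",
                                 package = "TCRcompare"))
  set.seed(83)
  di <- setNames(rlnorm(15, 5, 1), md$patient_id)
  res <- compareByCovariate(di, md, "age")
  expect_equal(res$summaries$n, c(6, 9))
  expect_equal(res$test_name, "mann_whitney_u")
  # three TNM groups fall through to Kruskal-Wallis
  res3 <- compareByCovariate(di, md, "tnm_stage")
  expect_equal(res3$test_name, "kruskal_wallis")
  expect_equal(sum(res3$summaries$n), 15)
  # unknown differentiation is excluded
  resD <- compareByCovariate(di, md, "differentiation")
  expect_equal(sum(resD$summaries$n), 14)
})

test_that("a constant metric is never significant", {
  md <- readMetadata(system.file("extdata", "lung15_clinical.tsv",
                                 package = "TCRcompare"))
  di <- setNames(rep(5, 15), md$patient_id)
  res <- compareByCovariate(di, md, "age")
  expect_equal(res$p_two_tailed, 1)
})

test_that("a planted age effect on diversity is recovered", {
  md <- readMetadata(system.file("extdata", "lung15_clinical.tsv",
                                 package = "TCRcompare"))
  set.seed(89)
  di <- setNames(ifelse(md$age <= 60, 600, 250) + rnorm(15, 0, 60),
                 md$patient_id)
  res <- compareByCovariate(di, md, "age")
  expect_lt(res$p_two_tailed, 0.05)
  expect_gt(res$summaries$mean[1], res$summaries$mean[2])
})

test_that("diversity-stratified survival wires split, KM and log-rank", {
  set.seed(97)
  di <- setNames(c(rlnorm(8, 6, 0.3), rlnorm(7, 4, 0.3)), paste0("P", 1:15))
  times <- c(rexp(8, 0.2), rexp(7, 0.02))
  events <- rbinom(15, 1, 0.9)
  res <- diStratifiedSurvival(di, times, events)
  expect_setequal(names(res$km), c("low", "high"))
  expect_true(all(diff(res$km$low$survival) <= 0))
  expect_true(all(diff(res$km$high$survival) <= 0))
  expect_equal(res$cutoff, median(di))
  expect_true(res$logrank$p_two_tailed <= 1)
})
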