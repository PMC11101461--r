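test_that("dichotomization applies the mean +/- 0.25 SD band", {
  g <- dichotomize(c(-1, 0, 1))  # mean 0, sd 1, cutoffs -0.25 / +0.25
  expect_equal(g$group, c("low", "excluded", "high"))
  expect_equal(attr(g, "lower"), -0.25)
  expect_equal(attr(g, "upper"), 0.25)
  out <- dichotomize(c(rep(0, 9), 10))  # extreme outlier lands in high
  expect_equal(out$group[10], "high")
  expect_true(all(out$group %in% c("low", "high", "excluded")))
  single <- dichotomize(c(-1, 0.01, 1), rule = "single")
  expect_equal(single$group, c("low", "high", "high"))
  expect_error(dichotomize(rep(2, 5)), "constant")
  expect_error(dichotomize(c(1, 2)), "at least 3")
})

test_that("Kaplan-Meier matches the hand product-limit and its invariants", {
  flat <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(flat$surv == 1))
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # without censoring the estimator is the empirical survival function
  set.seed(20)
  t <- rexp(50)
  km2 <- km_estimate(t, rep(1, 50))
  emp <- vapply(km2$time, function(x) mean(t > x), numeric(1))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
  # bounded, nonincreasing
  set.seed(21)
  km3 <- km_estimate(rexp(40), rbinom(40, 1, 0.6))
  expect_true(all(km3$surv >= 0 & km3$surv <= 1))
  expect_true(all(diff(km3$surv) <= 1e-12))
})

test_that("log-rank matches the risk-table oracle and obvious cases", {
  # identical groups: statistic 0, p = 1
  t0 <- c(1, 2, 3, 4)
  e0 <- c(1, 1, 0, 1)
  out <- logrank_test(c(t0, t0), c(e0, e0), rep(c("A", "B"), each = 4))
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)

  # 6-patient worked example vs the hand risk-table computation
  time <- c(6, 13, 21, 30, 37, 38)
  event <- c(1, 1, 1, 1, 0, 1)
  group <- c("A", "A", "A", "B", "B", "B")
  out2 <- logrank_test(time, event, group)
  expect_equal(out2$statistic, logrank_oracle(time, event, group),
               tolerance = 1e-10)
  expect_equal(out2$p_value,
               pchisq(out2$statistic, 1, lower.tail = FALSE))

  # strong separation: all A events precede all B events
  tA <- 1:20; tB <- 101:120
  out3 <- logrank_test(c(tA, tB), rep(1, 40), rep(c("A", "B"), each = 20))
  expect_lt(out3$p_value, 0.001)
  expect_equal(out3$statistic,
               logrank_oracle(c(tA, tB), rep(1, 40), rep(c("A", "B"), each = 20)),
               tolerance = 1e-10)

  # invariance to common time rescaling
  out4 <- logrank_test(c(tA, tB) * 365.25, rep(1, 40), rep(c("A", "B"), each = 20))
  expect_equal(out4$statistic, out3$statistic, tolerance = 1e-10)

  expect_warning(nul <- logrank_test(1:6, rep(0, 6), rep(c("A", "B"), 3)),
                 "no events")
  expect_equal(nul$p_value, 1)
})

test_that("chi-square association matches closed forms", {
  # independence: [[10,10],[10,10]] -> statistic 0
  g <- rep(c("low", "high"), each = 20)
  s <- rep(c("1", "4", "1", "4"), each = 10)
  out <- chi_square_association(g, s)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)

  # perfect association: [[20,0],[0,20]] -> sum (O-E)^2/E = 40, df 1
  g2 <- rep(c("low", "high"), each = 20)
  s2 <- rep(c("1", "4"), each = 20)
  out2 <- chi_square_association(g2, s2)
  expect_equal(out2$statistic, 40, tolerance = 1e-12)
  expect_equal(out2$df, 1)

  # swapping rows leaves the statistic unchanged
  out3 <- chi_square_association(ifelse(g2 == "low", "high", "low"), s2)
  expect_equal(out3$statistic, out2$statistic)

  # excluded patients are dropped before tabulation
  g4 <- c(g2, rep("excluded", 5))
  s4 <- c(s2, rep("1", 5))
  expect_equal(chi_square_association(g4, s4)$statistic, 40, tolerance = 1e-12)
})

test_that("AUC equals the Mann-Whitney statistic and keeps its direction", {
  perfect <- roc_auc(c(1, 2, 3, 11, 12, 13), rep(c(FALSE, TRUE), each = 3))
  expect_equal(perfect$auc, 1)
  # anti-predictive scores give AUC below 0.5, never flipped
  anti <- roc_auc(c(11, 12, 13, 1, 2, 3), rep(c(FALSE, TRUE), each = 3))
  expect_equal(anti$auc, 0)
  for (seed in 1:10) {
    set.seed(seed)
    sc <- rnorm(40)
    lab <- rbinom(40, 1, 0.5) == 1
    if (!any(lab) || all(lab)) next
    u <- sum(rank(sc)[lab]) - sum(lab) * (sum(lab) + 1) / 2
    expect_equal(roc_auc(sc, lab)$auc, u / (sum(lab) * sum(!lab)))
    # complement identity (no ties almost surely)
    expect_equal(roc_auc(sc, lab)$auc + roc_auc(-sc, lab)$auc, 1)
  }
  # agreement with an established ROC implementation
  set.seed(31)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.4) == 1
  expect_equal(
    roc_auc(sc, lab)$auc,
    as.numeric(pROC::auc(pROC::roc(lab, sc, direction = "<", quiet = TRUE)))
  )
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("random scores give AUC near one half", {
  set.seed(32)
  sc <- rnorm(2000)
  lab <- rbinom(2000, 1, 0.5) == 1
  expect_lt(abs(roc_auc(sc, lab)$auc - 0.5), 0.05)
})

test_that("biomarker validation composes grouping, survival and stage tests", {
  co <- generate_cohort(small_spec(seed = 71))
  pre <- preprocess_layer(co$layers$mrna)
  v <- pre$matrix$values[co$truth$mrna[1], ]
  out <- validate_biomarker(v, co$clinical)
  expect_true(all(c("lr_p", "chisq_p") %in% names(out)))
  expect_equal(out$n_low + out$n_high + out$n_excluded, 80)
  expect_true(is.na(out$lr_p) || (out$lr_p >= 0 && out$lr_p <= 1))
})
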