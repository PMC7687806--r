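test_that("confusion tables partition the cohort and catch degenerate input", {
  cf <- confusion(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(c(cf$tp, cf$fp, cf$fn, cf$tn), c(2, 0, 0, 1))

  # 45 deaths of which 44 score-positive
  pred <- c(rep(TRUE, 44), FALSE, rep(FALSE, 100))
  outc <- c(rep(TRUE, 45), rep(FALSE, 100))
  cf <- confusion(pred, outc)
  expect_equal(cf$tp, 44)
  expect_equal(cf$fn, 1)
  expect_equal(unname(round_half_away(sens_spec(cf)["sensitivity"], 3)),
               0.978)

  expect_error(confusion(logical(0), logical(0)), "empty")
  expect_error(confusion(TRUE, c(TRUE, FALSE)), "length")
})

test_that("two-point AUC is the half-sum, symmetric, and the Mann-Whitney statistic", {
  expect_equal(binary_auc(1.00, 0.44), 0.72)
  expect_equal(binary_auc(0.33, 0.97), 0.65)
  expect_equal(binary_auc(1, 1), 1)
  expect_equal(binary_auc(0.5, 0.5), 0.5)
  expect_error(binary_auc(1.2, 0.5), "\\[0, 1\\]")

  set.seed(406)
  for (rep in 1:25) {
    n <- 80
    pred <- runif(n) < 0.4
    outc <- runif(n) < 0.5
    if (!any(outc) || all(outc)) next
    ss <- sens_spec(confusion(pred, outc))
    a <- binary_auc(ss[["sensitivity"]], ss[["specificity"]])
    expect_equal(a, binary_auc(ss[["specificity"]], ss[["sensitivity"]]))
    # Mann-Whitney on the raw 0/1 predictions
    xp <- as.numeric(pred[outc]); xn <- as.numeric(pred[!outc])
    u <- sum(outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(a, u / (length(xp) * length(xn)))
  }
})

test_that("Hanley-McNeil intervals cover the AUC, clip at 1, narrow with n", {
  big <- confusion(c(rep(TRUE, 180), rep(FALSE, 20), rep(TRUE, 70),
                     rep(FALSE, 130)),
                   c(rep(TRUE, 200), rep(FALSE, 200)))
  ci_big <- auc_ci(big)
  expect_lte(ci_big[["ci_low"]], ci_big[["auc"]])
  expect_gte(ci_big[["ci_high"]], ci_big[["auc"]])

  small <- confusion(c(rep(TRUE, 18), rep(FALSE, 2), rep(TRUE, 7),
                       rep(FALSE, 13)),
                     c(rep(TRUE, 20), rep(FALSE, 20)))
  ci_small <- auc_ci(small)
  expect_lt(ci_big[["ci_high"]] - ci_big[["ci_low"]],
            ci_small[["ci_high"]] - ci_small[["ci_low"]])

  perfect <- confusion(c(rep(TRUE, 30), rep(FALSE, 30)),
                       c(rep(TRUE, 30), rep(FALSE, 30)))
  expect_equal(auc_ci(perfect)[["ci_high"]], 1)
})

test_that("paired DeLong test matches pROC and gives p = 1 against itself", {
  skip_if_not_installed("pROC")
  set.seed(407)
  n <- 300
  outc <- runif(n) < 0.35
  pa <- ifelse(outc, runif(n) < 0.8, runif(n) < 0.35)
  pb <- ifelse(outc, runif(n) < 0.7, runif(n) < 0.30)

  got <- compare_auc(pa, pb, outc)
  ref <- pROC::roc.test(pROC::roc(outc, as.numeric(pa), quiet = TRUE),
                        pROC::roc(outc, as.numeric(pb), quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-8)
  expect_equal(got$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-10)

  self <- compare_auc(pa, pa, outc)
  expect_equal(self$p_value, 1)

  # strongly separated vs chance classifier at n = 500 -> p < 0.001
  set.seed(408)
  outc <- rep(c(TRUE, FALSE), each = 250)
  good <- ifelse(outc, runif(500) < 0.9, runif(500) < 0.1)
  coin <- runif(500) < 0.5
  expect_lt(compare_auc(good, coin, outc)$p_value, 0.001)
})

test_that("association test dispatches on expected counts and matches the closed form", {
  r <- association_test(matrix(c(20, 5, 5, 20), 2, 2))
  expect_equal(r$method, "chi-squared")
  expect_equal(r$statistic, 18.0)
  expect_equal(r$p_value, pchisq(18, 1, lower.tail = FALSE))

  r <- association_test(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # an expected cell of 2.5 forces the Fisher branch
  m <- matrix(c(1, 4, 9, 6), 2, 2)
  expect_true(any(outer(rowSums(m), colSums(m)) / sum(m) < 5))
  r <- association_test(m)
  expect_equal(r$method, "fisher")
  expect_equal(r$p_value, fisher.test(m)$p.value)

  expect_error(association_test(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})

test_that("chi-squared branch equals sum((O-E)^2/E) on random well-filled tables", {
  set.seed(409)
  for (rep in 1:40) {
    m <- matrix(sample(5:50, 4, replace = TRUE), 2, 2)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(e < 5)) next
    r <- association_test(m)
    expect_equal(r$statistic, sum((m - e)^2 / e))
  }
})

test_that("AUC grades partition [0, 1] at the documented boundaries", {
  expect_equal(grade_auc(c(0.82, 0.73, 0.90)),
               c("sufficient", "adequate", "excellent"))
  expect_equal(grade_auc(c(0, 0.50, 0.509)), rep("not discriminative", 3))
  expect_equal(grade_auc(c(0.51, 0.699)), c("poor", "poor"))
  expect_equal(grade_auc(c(0.70, 0.799)), c("adequate", "adequate"))
  expect_equal(grade_auc(c(0.80, 0.899)), c("sufficient", "sufficient"))
  expect_equal(grade_auc(1), "excellent")
  # no gaps: every AUC on a fine grid receives exactly one grade
  g <- grade_auc(seq(0, 1, by = 0.001))
  expect_false(anyNA(g))
  expect_error(grade_auc(1.01), "\\[0, 1\\]")
})

test_that("cohort summary uses type-7 quantiles, SD, and printed-percentage formats", {
  enc <- data.table::data.table(
    encounter_id = sprintf("E%03d", 1:100), unit = "IMCU",
    skewed = exp(rnorm(100, 0, 1)), flat = 1:100,
    died = c(rep(TRUE, 3), rep(FALSE, 97)))
  s <- cohort_summary(enc, variables = c("flat", "died"), digits = 2)
  expect_equal(s[s$variable == "flat", ][["IMCU"]], "50.50 [25.75–75.25]")
  expect_equal(s[s$variable == "died", ][["IMCU"]], "3.0%")

  same <- data.table::data.table(encounter_id = "E1", unit = "ICU",
                                 v = rep(7, 10))
  s <- cohort_summary(same, variables = "v")
  expect_equal(s[["ICU"]], "7.0 ± 0.0")

  expect_error(cohort_summary(enc[0]), "empty")
})

test_that("printed percentages reproduce count arithmetic", {
  expect_equal(fmt_percent(4405, 13780), "32.0%")
  expect_equal(fmt_percent(458, 13780), "3.3%")
  expect_equal(fmt_percent(44, 45), "97.8%")
})
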