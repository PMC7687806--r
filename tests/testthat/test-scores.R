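test_that("qSOFA flags use inclusive RR, strict SBP, and the RASS fall-back", {
  f <- qsofa_flags(rr = c(22, 21.9), sbp = c(120, 120),
                   altered_mentation = c(FALSE, FALSE))
  expect_equal(f$rr, c(TRUE, FALSE))

  f <- qsofa_flags(rr = 15, sbp = c(100, 99.9), altered_mentation = FALSE)
  expect_equal(f$sbp, c(FALSE, TRUE))
  f2 <- qsofa_flags(rr = 15, sbp = 100, altered_mentation = FALSE,
                    sbp_inclusive = TRUE)
  expect_true(f2$sbp)

  # no GCS documented, RASS -1 -> altered mentation
  times <- grid_times(3)
  cons <- data.frame(timestamp = times[1], scale = "RASS", value = -1)
  expect_true(all(mentation_series(times, cons)))
  cons0 <- data.frame(timestamp = times[1], scale = "RASS", value = 0)
  expect_false(any(mentation_series(times, cons0)))
  # GCS present: 15 is not altered, 14 is; GCS wins over RASS
  consg <- data.frame(timestamp = rep(times[1], 2),
                      scale = c("GCS", "RASS"), value = c(15, -2))
  expect_false(any(mentation_series(times, consg)))

  # missing inputs never raise a flag
  f <- qsofa_flags(rr = NA, sbp = NA, altered_mentation = NA)
  expect_equal(f$n_fulfilled, 0L)
})

test_that("SIRS flags follow the consensus thresholds with disjunctive respiration", {
  f <- sirs_flags(temp = 36.5, hr = 80, rr = 14, wbc = 8, paco2 = 40)
  expect_equal(f$n_fulfilled, 0L)

  f <- sirs_flags(temp = c(38.1, 38.0, 35.9, 36.0), hr = 80, rr = 14,
                  wbc = 8, paco2 = 40)
  expect_equal(f$temp, c(TRUE, FALSE, TRUE, FALSE))

  f <- sirs_flags(temp = 37, hr = c(91, 90), rr = 14, wbc = 8, paco2 = 40)
  expect_equal(f$hr, c(TRUE, FALSE))

  # RR 18 is quiet but paCO2 30 still fulfils the respiratory criterion
  f <- sirs_flags(temp = 37, hr = 80, rr = 18, wbc = 8, paco2 = 30)
  expect_true(f$resp)
  expect_equal(f$n_fulfilled, 1L)

  f <- sirs_flags(temp = 37, hr = 80, rr = 14, wbc = c(12.1, 12, 3.9, 4),
                  paco2 = 40)
  expect_equal(f$wbc, c(TRUE, FALSE, TRUE, FALSE))

  f <- sirs_flags(temp = NA, hr = NA, rr = NA, wbc = NA, paco2 = NA)
  expect_equal(f$n_fulfilled, 0L)
})

test_that("lab look-back carries values forward only within the horizon", {
  times <- grid_times(12)                     # 0 .. 165 min
  lt <- times[1]
  v <- lab_lookback(times, lt, 9, horizon_hours = 1)
  expect_equal(v, c(rep(9, 5), rep(NA_real_, 7)))  # valid through 60 min
  v <- lab_lookback(times, lt, 9, horizon_hours = Inf)
  expect_equal(v, rep(9, 12))
  # value in the future is never used
  v <- lab_lookback(times[1], times[5], 9, horizon_hours = 24)
  expect_true(is.na(v))
})

test_that("the 30-minute rule needs three consecutive qualifying grid points", {
  times <- grid_times(5)
  r <- sustained_positive(c(2, 2, 2), times[1:3])
  expect_true(r$positive)
  expect_equal(r$first_positive_time, times[1])

  expect_false(sustained_positive(c(2, 1, 2, 1, 2), times)$positive)
  expect_false(sustained_positive(c(0, 0, 0, 0, 0), times)$positive)
  expect_false(sustained_positive(c(2, 2), times[1:2])$positive)
  expect_false(sustained_positive(integer(0))$positive)
  # NA counts as not qualifying
  expect_false(sustained_positive(c(2, NA, 2, 2), times[1:4])$positive)
  r <- sustained_positive(c(1, 2, 2, 2), times[1:4])
  expect_equal(r$first_positive_time, times[2])
})

test_that("sustained positivity agrees with exhaustive run enumeration", {
  set.seed(402)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    nf <- sample(c(0:3, NA), n, replace = TRUE)
    got <- sustained_positive(nf, grid_times(n))
    want <- oracle_sustained(nf)
    expect_equal(got$positive, want$positive)
    expect_equal(got$first_positive_index, want$first)
  }
})

test_that("adding a fulfilled criterion never turns a positive determination negative", {
  set.seed(403)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    nf <- sample(0:3, n, replace = TRUE)
    base <- sustained_positive(nf)$positive
    i <- sample(n, 1)
    bumped <- nf
    bumped[i] <- bumped[i] + 1L
    expect_true(!base || sustained_positive(bumped)$positive)
  }
})

test_that("SOFA component table maps the worked example and the extremes", {
  x <- sofa_total(data.frame(pao2fio2 = 250, platelets = 80,
                             bilirubin = 2.5, map = 68, vaso = "none",
                             gcs = 13, creatinine = 2.2, urine24 = 1500))
  expect_equal(x$sofa_resp, 2L)
  expect_equal(x$sofa_coag, 2L)
  expect_equal(x$sofa_liver, 2L)
  expect_equal(x$sofa_cardio, 1L)
  expect_equal(x$sofa_cns, 1L)
  expect_equal(x$sofa_renal, 2L)
  expect_equal(x$sofa_total, 10L)

  normal <- sofa_total(data.frame(pao2fio2 = 450, platelets = 250,
                                  bilirubin = 0.5, map = 85, vaso = "none",
                                  gcs = 15, creatinine = 0.8,
                                  urine24 = 2000))
  expect_equal(normal$sofa_total, 0L)

  worst <- sofa_total(data.frame(pao2fio2 = 80, platelets = 10,
                                 bilirubin = 15, map = 40, vaso = "high",
                                 gcs = 3, creatinine = 6, urine24 = 100))
  expect_equal(worst$sofa_total, 24L)

  # missing components score 0 and are counted
  m <- sofa_total(data.frame(pao2fio2 = NA, platelets = 80, bilirubin = NA,
                             map = NA, vaso = NA, gcs = NA, creatinine = NA,
                             urine24 = NA))
  expect_equal(m$sofa_total, 2L)
  expect_equal(m$n_missing, 5L)

  expect_error(sofa_total(data.frame(gcs = 17)), "GCS")
})

test_that("SOFA totals conserve component sums and stay within 0-24", {
  set.seed(404)
  d <- data.frame(pao2fio2 = runif(200, 40, 500),
                  platelets = runif(200, 5, 400),
                  bilirubin = runif(200, 0.1, 20),
                  map = runif(200, 40, 110),
                  vaso = sample(c("none", "low", "mid", "high"), 200, TRUE),
                  gcs = sample(3:15, 200, TRUE),
                  creatinine = runif(200, 0.3, 8),
                  urine24 = runif(200, 50, 4000))
  x <- sofa_total(d)
  comp <- x[, .(sofa_resp, sofa_coag, sofa_liver, sofa_cardio, sofa_cns,
                sofa_renal)]
  expect_true(all(as.matrix(comp) >= 0 & as.matrix(comp) <= 4))
  expect_equal(x$sofa_total, rowSums(comp))
  expect_true(all(x$sofa_total >= 0 & x$sofa_total <= 24))
})

test_that("the day-over-day SOFA rule rates only increases of two or more positive", {
  d <- as.Date("2015-03-01") + 0:1
  expect_true(sofa_delta_positive(c(4, 6), d)$positive)
  expect_false(sofa_delta_positive(c(4, 5), d)$positive)
  expect_false(sofa_delta_positive(c(6, 4), d)$positive)
  r <- sofa_delta_positive(c(4, 6), d)
  expect_equal(r$first_positive_time,
               as.POSIXct(as.Date("2015-03-02"), tz = "UTC"))
  # day 1 has no previous day: not rated by default, rated vs 0 on request
  expect_false(sofa_delta_positive(c(4), d[1])$positive)
  expect_true(sofa_delta_positive(c(4), d[1], baseline = 0)$positive)
  expect_false(sofa_delta_positive(c(1, 2, 3), as.Date("2015-03-01") + 0:2)$positive)
  expect_false(sofa_delta_positive(numeric(0))$positive)
})

test_that("episode windows restrict score determinations", {
  t0 <- as.POSIXct("2015-03-01 00:00:00", tz = "UTC")
  adm <- t0; disch <- t0 + 5 * 86400
  enc <- data.table::data.table(encounter_id = "E1", admission = adm,
                                discharge = disch)
  # qSOFA-positive run during hours 2-4 only
  grid <- seq(adm, disch, by = 900)
  rr <- rep(14, length(grid))
  sbp <- rep(130, length(grid))
  run <- grid >= t0 + 2 * 3600 & grid < t0 + 4 * 3600
  rr[run] <- 28; sbp[run] <- 85
  vit <- data.table::rbindlist(list(
    data.table::data.table(encounter_id = "E1", timestamp = grid,
                           channel = "RR", value = rr),
    data.table::data.table(encounter_id = "E1", timestamp = grid,
                           channel = "SBP", value = sbp)))
  cleaned <- clean_vitals(vit, enc)
  labs <- data.table::data.table(encounter_id = character(),
                                 timestamp = as.POSIXct(character(), tz = "UTC"),
                                 analyte = character(), value = numeric())
  cons <- data.table::data.table(encounter_id = "E1", timestamp = adm,
                                 scale = "GCS", value = 15)
  sofa <- data.table::data.table(encounter_id = "E1",
                                 date = as.Date(adm) + 0:4,
                                 pao2fio2 = 450, platelets = 250,
                                 bilirubin = 0.5, map = 85, vaso = "none",
                                 gcs = 15, creatinine = 0.8, urine24 = 2000)

  in_window <- data.table::data.table(encounter_id = "E1", episode_id = 1L,
                                      start_time = t0 + 3600,
                                      end_time = t0 + 3600 + 72 * 3600)
  det <- score_cohort(cleaned, labs, cons, sofa, enc, in_window)
  expect_true(det[score == "QSOFA"]$positive)

  # the identical run entirely before the episode start -> negative
  late <- data.table::data.table(encounter_id = "E1", episode_id = 1L,
                                 start_time = t0 + 6 * 3600,
                                 end_time = disch)
  det <- score_cohort(cleaned, labs, cons, sofa, enc, late)
  expect_false(det[score == "QSOFA"]$positive)

  # two episodes, run only inside the second
  two <- data.table::data.table(encounter_id = "E1", episode_id = 1:2,
                                start_time = c(t0, t0 + 3600),
                                end_time = c(t0 + 1800, t0 + 6 * 3600))
  det <- score_cohort(cleaned, labs, cons, sofa, enc, two)
  expect_equal(det[score == "QSOFA"][order(episode_id)]$positive,
               c(FALSE, TRUE))

  # no episodes -> scored over the full stay and flagged non-episode
  det <- score_cohort(cleaned, labs, cons, sofa, enc, two[0])
  expect_true(all(det$non_episode))
  expect_true(det[score == "QSOFA"]$positive)
})
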