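test_that("generation is deterministic given the seed and validates its config", {
  cfg <- cohort_config(n_encounters = 25, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (tb in c("encounters", "vitals", "labs", "consciousness", "sofa_daily",
               "medications", "truth")) {
    expect_identical(a[[tb]], b[[tb]], label = tb)
  }
  c2 <- generate_cohort(cohort_config(n_encounters = 25, seed = 78))
  expect_false(identical(a$vitals$value, c2$vitals$value))

  expect_error(cohort_config(n_encounters = 0), "positive")
  expect_error(cohort_config(10, unit_mix = c(IMCU = 0.7, ICU = 0.7,
                                              `IMCU/ICU` = -0.4)),
               "unit_mix")
  expect_error(cohort_config(10, infection_prevalence = c(IMCU = 1.2,
                                                          ICU = 0.3,
                                                          `IMCU/ICU` = 0.5)))
})

test_that("zero prevalence yields no antibiotic starts from infection and no deaths", {
  cfg <- cohort_config(n_encounters = 30, seed = 5,
                       infection_prevalence = c(IMCU = 0, ICU = 0,
                                                `IMCU/ICU` = 0),
                       excluded_ab_rate = 0, unknown_ab_rate = 0)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$medications), 0)
  expect_false(any(coh$truth$infected))
  expect_false(any(coh$encounters$died))
})

test_that("every infected encounter has a qualifying broad-spectrum start at onset", {
  coh <- tiny_cohort(n = 80, seed = 9)
  cat <- antibiotic_catalog()
  tr <- coh$truth[coh$truth$infected == TRUE]
  expect_gt(nrow(tr), 0)
  med <- coh$medications
  for (i in seq_len(nrow(tr))) {
    m <- med[med$encounter_id == tr$encounter_id[i] &
               med$start_time == tr$infection_onset[i]]
    expect_gte(nrow(m), 1)
    expect_true(any(classify_antibiotic(m$drug_name, cat) == "broad"))
  }
  # deaths only among infected encounters
  dead <- coh$encounters[coh$encounters$died == TRUE]$encounter_id
  expect_true(all(dead %in% tr$encounter_id))
})

test_that("quota assignment reproduces configured prevalences within binomial intervals", {
  cfg <- cohort_config(n_encounters = 2400, seed = 31)
  coh <- generate_cohort(cfg)
  tab <- merge(coh$encounters[, c("encounter_id", "unit")], coh$truth,
               by = "encounter_id")
  for (u in unique(tab$unit)) {
    sub <- tab[tab$unit == u]
    p <- cfg$infection_prevalence[[u]]
    ci <- binom.test(sum(sub$infected), nrow(sub), p)$conf.int
    expect_true(p >= ci[1] && p <= ci[2], label = paste("infection", u))
    inf <- sub[sub$infected == TRUE]
    pm <- cfg$mortality_given_infection[[u]]
    cim <- binom.test(sum(inf$dies), nrow(inf), pm)$conf.int
    expect_true(pm >= cim[1] && pm <= cim[2], label = paste("mortality", u))
  }
})

test_that("artifact injection is identity at zero rates and fully logged", {
  t0 <- as.POSIXct("2015-03-01", tz = "UTC")
  s <- vital_stream(rep(80, 96 * 3), "HR", t0)
  out <- inject_artifacts(s, spike_rate = 0, dislocation_rate = 0)
  expect_identical(out$stream$values, s$values)
  expect_equal(nrow(out$log), 0)
  expect_error(inject_artifacts(s, spike_rate = -1), "negative")

  out <- inject_artifacts(s, spike_rate = 4, seed = 12)
  expect_gt(nrow(out$log), 0)
  # exactly the logged samples differ from baseline
  expect_equal(sort(which(out$stream$values != 80)), sort(out$log$index))
  expect_equal(out$stream$values[out$log$index], out$log$injected)

  tmp <- vital_stream(rep(36.8, 96 * 3), "TEMP", t0)
  out <- inject_artifacts(tmp, spike_rate = 0, dislocation_rate = 3,
                          seed = 13)
  dis <- out$log[out$log$type == "dislocation"]
  expect_gt(nrow(dis), 0)
  expect_true(all(dis$injected <= 31))
  # dislocations are refused on non-temperature channels
  expect_error(inject_artifacts(s, dislocation_rate = 1), "TEMP")
})

test_that("calibrated shifts push single samples across thresholds with the target probability", {
  sh <- calibrate_shift(100, 125, 6, "below", p_exceed = 0.999, circ_amp = 4)
  expect_lt(sh, 0)
  # at the least favourable circadian phase the crossing probability is met
  expect_equal(pnorm(100, 125 + 4 + sh, 6), 0.999, tolerance = 1e-6)
  sh <- calibrate_shift(38, 36.8, 0.15, "above", p_exceed = 0.999,
                        circ_amp = 0.3)
  expect_equal(1 - pnorm(38, 36.8 - 0.3 + sh, 0.15), 0.999,
               tolerance = 1e-6)
})

test_that("the generator's intents are recovered by the scoring pipeline", {
  coh <- tiny_cohort(n = 100, seed = 303)
  res <- run_pipeline(pipeline_config(coh$config), cohort = coh)
  pos <- res$determinations[, .(positive = any(positive)),
                            by = .(encounter_id, score)]
  m <- merge(pos, coh$truth, by = "encounter_id")
  expect_equal(m[score == "QSOFA", mean(positive == qsofa_intent)], 1)
  expect_equal(m[score == "SOFA", mean(positive == sofa_intent)], 1)
  expect_gte(m[score == "SIRS", mean(positive == sirs_intent)], 0.97)
})
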