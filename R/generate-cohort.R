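# Quota (balanced) assignment: exactly round(p * n) of n units are flagged,
# chosen uniformly at random, so configured conditional rates hold exactly in
# every realization up to rounding.
quota_flags <- function(n, p) {
  out <- rep(FALSE, n)
  k <- round(p * n)
  if (k > 0L) out[sample.int(n, k)] <- TRUE
  out
}

# Largest-remainder apportionment of n over proportions p.
apportion <- function(n, p) {
  k <- floor(n * p)
  r <- n * p - k
  left <- n - sum(k)
  if (left > 0) {
    add <- order(r, decreasing = TRUE)[seq_len(left)]
    k[add] <- k[add] + 1L
  }
  as.integer(k)
}

# AR(1) noise with marginal SD `sd` and lag-1 correlation `phi`.
ar1_noise <- function(n, sd, phi) {
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  innov[1L] <- rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

circadian <- function(times, amp, peak_hour = 16) {
  h <- (as.numeric(times) %% 86400) / 3600
  amp * sin(2 * pi * (h - (peak_hour - 6)) / 24)
}

# Core artifact injection on a value vector; returns values + log.
.inject_artifacts_core <- function(values, channel, spike_rate,
                                   dislocation_rate, interval_min) {
  if (spike_rate < 0 || dislocation_rate < 0) {
    stop("inject_artifacts(): negative artifact rate")
  }
  n <- length(values)
  days <- n * interval_min / 1440
  log <- list()
  if (spike_rate > 0 && n > 0) {
    k <- rpois(1, spike_rate * days)
    if (k > 0) {
      idx <- sample.int(n, min(k, n))
      spike <- switch(channel,
        HR = ifelse(runif(length(idx)) < 0.7, runif(length(idx), 160, 240),
                    runif(length(idx), 10, 25)),
        RR = runif(length(idx), 45, 70),
        SBP = ifelse(runif(length(idx)) < 0.7, runif(length(idx), 220, 300),
                     runif(length(idx), 20, 40)),
        TEMP = runif(length(idx), 41.5, 43))
      log[[length(log) + 1L]] <- data.table(
        index = idx, type = "spike", original = values[idx],
        injected = spike)
      values[idx] <- spike
    }
  }
  if (dislocation_rate > 0 && n > 0) {
    if (channel != "TEMP") {
      stop("inject_artifacts(): dislocation artifacts apply to TEMP only")
    }
    k <- rpois(1, dislocation_rate * days)
    for (j in seq_len(k)) {
      len <- min(n, 1L + rpois(1, 7))        # ~2 h runs on a 15-min grid
      start <- sample.int(max(1L, n - len + 1L), 1L)
      idx <- start:(start + len - 1L)
      vals <- runif(len, 24, 31)             # dislocated probe reads <= 31 C
      log[[length(log) + 1L]] <- data.table(
        index = idx, type = "dislocation", original = values[idx],
        injected = vals)
      values[idx] <- vals
    }
  }
  list(values = values,
       log = if (length(log)) rbindlist(log) else
         data.table(index = integer(), type = character(),
                    original = numeric(), injected = numeric()))
}

#' Inject measurement artifacts into a vital-sign stream
#'
#' Adds two artifact types the cleaning stage must remove: single-sample
#' spikes with channel-appropriate extreme values, and (temperature only)
#' probe-dislocation runs whose values are all at or below 31 degrees C. The
#' returned injection log allows sample-by-sample validation of the cleaning.
#'
#' @param stream a [vital_stream()].
#' @param spike_rate expected spikes per day (>= 0).
#' @param dislocation_rate expected dislocation episodes per day (TEMP only).
#' @param seed optional RNG seed for a reproducible injection.
#' @return list with `stream` (modified [vital_stream()]) and `log`
#'   (data.table `index, type, original, injected`).
#' @export
inject_artifacts <- function(stream, spike_rate = 0.5, dislocation_rate = 0,
                             seed = NULL) {
  stopifnot(inherits(stream, "vital_stream"))
  run <- function() .inject_artifacts_core(stream$values, stream$channel,
                                           spike_rate, dislocation_rate,
                                           stream$interval_min)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  stream$values <- res$values
  list(stream = stream, log = res$log)
}

# Representative raw values for a target SOFA component score (uniform draw
# strictly inside the band, so the shipped table recovers the score exactly).
.sofa_band_value <- function(component, score) {
  pick <- function(lo, hi) runif(length(score), lo, hi)
  switch(component,
    resp = c(450, 350, 250, 150, 60)[score + 1L] + pick(-35, 35),
    coag = c(240, 125, 75, 35, 10)[score + 1L] + pick(-5, 5),
    stop("unknown component"))
}

.generate_encounter <- function(i, ctx) {
  cfg <- ctx$cfg
  iv <- cfg$sampling_interval
  secs <- iv * 60
  adm <- ctx$admission[i]; disch <- ctx$discharge[i]
  stay <- as.numeric(disch) - as.numeric(adm)
  grid <- seq(adm, disch, by = secs)
  nt <- length(grid)
  infected <- ctx$infected[i]
  onset <- ctx$onset[i]

  place_window <- function(w_hours) {
    w <- w_hours * 3600
    if (infected) {
      lo <- as.numeric(onset)
      hi <- min(as.numeric(onset) + 72 * 3600, as.numeric(disch)) - w
    } else {
      lo <- as.numeric(adm) + 0.05 * stay
      hi <- as.numeric(disch) - w - 3600
    }
    if (hi <= lo) hi <- lo
    ws <- lo + runif(1, 0, min(hi - lo, 24 * 3600))
    c(ws, ws + w)
  }

  q_win <- if (ctx$intent[i, "QSOFA"]) place_window(cfg$qsofa_window_hours)
  s_win <- if (ctx$intent[i, "SIRS"]) place_window(cfg$sirs_window_hours)

  vit_rows <- vector("list", 4L)
  art_logs <- list()
  gnum <- as.numeric(grid)
  for (ci in seq_along(VITAL_CHANNELS)) {
    ch <- VITAL_CHANNELS[ci]
    p <- cfg$vitals[[ch]]
    x <- p$baseline + circadian(grid, p$circ_amp) + ar1_noise(nt, p$sd, p$phi)
    if (!is.null(q_win) && ch == "SBP") {
      idx <- gnum >= q_win[1] & gnum < q_win[2]
      x[idx] <- x[idx] + ctx$shifts$sbp
    }
    if (!is.null(s_win) && ch %in% c("TEMP", "HR")) {
      idx <- gnum >= s_win[1] & gnum < s_win[2]
      x[idx] <- x[idx] + if (ch == "TEMP") ctx$shifts$temp else ctx$shifts$hr
    }
    res <- .inject_artifacts_core(
      x, ch, cfg$artifact_spike_rate,
      if (ch == "TEMP") cfg$temp_dislocation_rate else 0, iv)
    x <- res$values
    if (nrow(res$log)) {
      res$log[, `:=`(encounter_id = ctx$id[i], channel = ch)]
      art_logs[[length(art_logs) + 1L]] <- res$log
    }
    keep <- runif(nt) >= cfg$missing_rate
    vit_rows[[ci]] <- data.table(encounter_id = ctx$id[i],
                                 timestamp = grid[keep], channel = ch,
                                 value = x[keep])
  }

  # consciousness: q8h assessments; altered during the qSOFA window
  use_rass <- ctx$rass_only[i]
  base_val <- if (use_rass) 0 else 15
  alt_val <- if (use_rass) -2 else 13
  ct <- seq(adm, disch, by = 8 * 3600)
  cv <- rep(base_val, length(ct))
  if (!is.null(q_win)) {
    inw <- as.numeric(ct) >= q_win[1] & as.numeric(ct) < q_win[2]
    cv[inw] <- alt_val
    ct <- c(ct, as_utc(q_win[1]), as_utc(q_win[2]))
    cv <- c(cv, alt_val, base_val)
    o <- order(ct); ct <- ct[o]; cv <- cv[o]
  }
  cons <- data.table(encounter_id = ctx$id[i], timestamp = ct,
                     scale = if (use_rass) "RASS" else "GCS", value = cv)

  # labs: daily 08:00 leucocytes, 12-hourly blood-gas CO2
  all_days <- seq(as.Date(adm), as.Date(disch), by = 1)
  wbc_t <- as_utc(as.POSIXct(all_days, tz = "UTC")) + 8 * 3600
  wbc_t <- wbc_t[wbc_t >= adm & wbc_t <= disch]
  if (!length(wbc_t)) wbc_t <- adm
  paco2_t <- seq(adm, disch, by = 12 * 3600)
  labs <- rbind(
    data.table(encounter_id = ctx$id[i], timestamp = wbc_t, analyte = "WBC",
               value = pmin(pmax(rnorm(length(wbc_t), 8, 1.5), 0.5), 30)),
    data.table(encounter_id = ctx$id[i], timestamp = paco2_t,
               analyte = "PACO2",
               value = pmin(pmax(rnorm(length(paco2_t), 40, 3), 20), 80)))

  # daily worst SOFA component inputs
  nd <- length(all_days)
  b <- if (ctx$intent[i, "QSOFA"]) 0L else sample(0:1, 1L)
  resp_sc <- rep(b, nd); coag_sc <- rep(0L, nd)
  if (ctx$intent[i, "SOFA"]) {
    jday <- if (infected) {
      max(1L, match(as.Date(onset), all_days, nomatch = 1L))
    } else if (nd >= 2L) sample(2:nd, 1L) else 1L
    # the day-over-day rule cannot fire on day 1; realize the rise on day 2+
    if (nd >= 2L) jday <- min(max(2L, jday), nd)
    resp_sc[jday:nd] <- resp_sc[jday:nd] + 2L
    coag_sc[jday:nd] <- coag_sc[jday:nd] + 1L
  }
  gcs_daily <- rep(NA_real_, nd)
  if (!use_rass) {
    dmin <- cons[, .(g = min(value)), by = .(d = as.Date(timestamp))]
    gcs_daily <- dmin$g[match(all_days, dmin$d)]
    gcs_daily[is.na(gcs_daily)] <- 15
  }
  sofa_daily <- data.table(
    encounter_id = ctx$id[i], date = all_days,
    pao2fio2 = .sofa_band_value("resp", resp_sc),
    platelets = .sofa_band_value("coag", coag_sc),
    bilirubin = runif(nd, 0.2, 1.0),
    map = runif(nd, 75, 95), vaso = "none",
    gcs = gcs_daily, creatinine = runif(nd, 0.5, 1.1),
    urine24 = runif(nd, 1200, 2800))

  # antibiotic administrations
  med <- list()
  if (infected) {
    med[[1]] <- data.table(encounter_id = ctx$id[i],
                           drug_name = sample(ctx$broad_drugs, 1L),
                           start_time = onset)
    if (runif(1) < cfg$restart_ab_rate) {
      t2 <- as.numeric(onset) + runif(1, 12, 60) * 3600
      if (t2 < min(as.numeric(disch), as.numeric(onset) + 72 * 3600)) {
        med[[2]] <- data.table(encounter_id = ctx$id[i],
                               drug_name = sample(ctx$broad_drugs, 1L),
                               start_time = as_utc(t2))
      }
    }
  }
  if (runif(1) < cfg$excluded_ab_rate) {
    med[[length(med) + 1L]] <- data.table(
      encounter_id = ctx$id[i], drug_name = sample(ctx$excluded_drugs, 1L),
      start_time = as_utc(as.numeric(adm) + runif(1) * stay))
  }
  if (runif(1) < cfg$unknown_ab_rate) {
    med[[length(med) + 1L]] <- data.table(
      encounter_id = ctx$id[i],
      drug_name = sample(c("nystatin", "novobiocin", "rifaximin"), 1L),
      start_time = as_utc(as.numeric(adm) + runif(1) * stay))
  }

  list(vitals = rbindlist(vit_rows), consciousness = cons, labs = labs,
       sofa_daily = sofa_daily,
       medications = if (length(med)) rbindlist(med) else NULL,
       artifact_log = if (length(art_logs)) rbindlist(art_logs) else NULL)
}

#' Generate a synthetic IMCU/ICU cohort
#'
#' Draws encounters per the configured stratum mix, assigns latent infection,
#' mortality and per-score positivity intents by exact quota within each
#' stratum and outcome cell, and realizes them in 15-minute vital-sign
#' streams (baseline + circadian + AR(1) noise, with additive criterion
#' shifts during sustained windows calibrated via [calibrate_shift()]), lab
#' and consciousness records, daily SOFA inputs, antibiotic administrations
#' and measurement artifacts. Every infected encounter receives a
#' broad-spectrum antibiotic start at its infection onset.
#'
#' @param config a [cohort_config()].
#' @return object of class `sepsis_cohort`: list of data.tables
#'   (`encounters`, `vitals`, `labs`, `consciousness`, `sofa_daily`,
#'   `medications`, `truth`, `artifact_log`) plus the `config`. The `truth`
#'   table (latent states and intents) is for validation only and is never
#'   read by the scoring pipeline.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  n <- cfg$n_encounters
  units <- names(cfg$unit_mix)
  counts <- apportion(n, cfg$unit_mix)
  unit <- sample(rep(units, counts))
  id <- sprintf("E%05d", seq_len(n))

  infected <- logical(n); dies <- logical(n)
  intent <- matrix(FALSE, n, 3, dimnames = list(NULL, SCORES))
  for (u in units) {
    iu <- which(unit == u)
    if (!length(iu)) next
    infected[iu] <- quota_flags(length(iu), cfg$infection_prevalence[[u]])
    inf_u <- iu[infected[iu]]
    if (length(inf_u)) {
      dies[inf_u] <- quota_flags(length(inf_u),
                                 cfg$mortality_given_infection[[u]])
    }
    tg <- cfg$score_targets[stratum == u]
    for (s in SCORES) {
      t_s <- tg[score == s]
      if (nrow(t_s) == 0L) next
      cells <- list(
        list(idx = iu[!infected[iu]], p = 1 - t_s$spec_infection),
        list(idx = iu[infected[iu] & dies[iu]], p = t_s$sens_mortality),
        list(idx = iu[infected[iu] & !dies[iu]], p = 1 - t_s$spec_mortality))
      for (cell in cells) {
        if (length(cell$idx)) {
          intent[cell$idx, s] <- quota_flags(length(cell$idx), cell$p)
        }
      }
    }
  }

  secs <- cfg$sampling_interval * 60
  rng <- as_utc(cfg$admission_range)
  admission <- floor_to_interval(
    as_utc(as.numeric(rng[1]) + runif(n) * (as.numeric(rng[2]) -
                                              as.numeric(rng[1]))),
    cfg$sampling_interval)
  stay_days <- pmin(pmax(rlnorm(n, cfg$stay_meanlog[unit], cfg$stay_sdlog),
                         cfg$stay_min_days), cfg$stay_cap_days)
  discharge <- admission + round(stay_days * 86400 / secs) * secs
  onset <- as_utc(rep(NA_real_, n))
  if (any(infected)) {
    stay_secs <- as.numeric(discharge) - as.numeric(admission)
    onset[infected] <- as_utc(as.numeric(admission[infected]) +
                                runif(sum(infected), 0.1, 0.4) *
                                  stay_secs[infected])
  }

  vm <- cfg$vitals
  shifts <- list(
    sbp = calibrate_shift(100, vm$SBP$baseline, vm$SBP$sd, "below",
                          cfg$p_exceed, vm$SBP$circ_amp),
    temp = calibrate_shift(38, vm$TEMP$baseline, vm$TEMP$sd, "above",
                           cfg$p_exceed, vm$TEMP$circ_amp),
    hr = calibrate_shift(90, vm$HR$baseline, vm$HR$sd, "above",
                         cfg$p_exceed, vm$HR$circ_amp))

  catalog <- antibiotic_catalog()
  ctx <- list(cfg = cfg, id = id, admission = admission,
              discharge = discharge, infected = infected, onset = onset,
              intent = intent, shifts = shifts,
              rass_only = runif(n) < cfg$rass_only_rate,
              broad_drugs = sort(unique(unlist(catalog$broad))),
              excluded_drugs = sort(catalog$excluded))

  parts <- lapply(seq_len(n), .generate_encounter, ctx = ctx)
  get_part <- function(nm) rbindlist(lapply(parts, `[[`, nm))

  encounters <- data.table(
    encounter_id = id, unit = unit, admission = admission,
    discharge = discharge,
    age = pmin(pmax(round(rnorm(n, c(IMCU = 58, ICU = 63,
                                     `IMCU/ICU` = 67)[unit], 18)), 18), 100),
    bmi = round(pmin(pmax(rlnorm(n, log(26.6), 0.18), 14), 60), 1),
    apache2 = pmin(pmax(round(rnorm(n, c(IMCU = 6, ICU = 12,
                                         `IMCU/ICU` = 18)[unit], 6)), 0), 45),
    invasive_ventilation = runif(n) < c(IMCU = 0.019, ICU = 0.523,
                                        `IMCU/ICU` = 0.670)[unit],
    catecholamines = runif(n) < c(IMCU = 0.043, ICU = 0.380,
                                  `IMCU/ICU` = 0.571)[unit],
    died = dies)

  truth <- data.table(encounter_id = id, infected = infected,
                      infection_onset = onset, dies = dies,
                      qsofa_intent = intent[, "QSOFA"],
                      sirs_intent = intent[, "SIRS"],
                      sofa_intent = intent[, "SOFA"])

  structure(list(encounters = encounters, vitals = get_part("vitals"),
                 labs = get_part("labs"),
                 consciousness = get_part("consciousness"),
                 sofa_daily = get_part("sofa_daily"),
                 medications = get_part("medications"), truth = truth,
                 artifact_log = get_part("artifact_log"), config = cfg),
            class = "sepsis_cohort")
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat(sprintf("<sepsis_cohort> %d encounters (%s), %d vitals samples, %d antibiotic events\n",
              nrow(x$encounters),
              paste(sprintf("%s %d", names(table(x$encounters$unit)),
                            as.integer(table(x$encounters$unit))),
                    collapse = ", "),
              nrow(x$vitals), nrow(x$medications)))
  cat(sprintf("  infected %d (%.1f%%), died %d (%.1f%%)\n",
              sum(x$truth$infected), 100 * mean(x$truth$infected),
              sum(x$truth$dies), 100 * mean(x$truth$dies)))
  invisible(x)
}
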