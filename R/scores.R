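SCORES <- c("SIRS", "QSOFA", "SOFA")

#' Default SIRS criterion thresholds (1992 consensus)
#'
#' Shipped as an explicit, overridable table. The immature-band-form criterion
#' is omitted: only the routine leucocyte count is carried, so the band
#' fraction is never available.
#'
#' @return a named list of thresholds: `temp_high` (> 38 C), `temp_low`
#'   (< 36 C), `hr_high` (> 90 /min), `rr_high` (> 20 /min), `paco2_low`
#'   (< 32 mmHg), `wbc_high` (> 12 x 10^9/L), `wbc_low` (< 4 x 10^9/L).
#' @export
sirs_thresholds <- function() {
  list(temp_high = 38, temp_low = 36, hr_high = 90, rr_high = 20,
       paco2_low = 32, wbc_high = 12, wbc_low = 4)
}

#' Per-time-point qSOFA criterion flags
#'
#' Flags are missing-aware: an unavailable input never counts as fulfilled.
#' The systolic-pressure rule is strict `< 100 mmHg` by default; set
#' `sbp_inclusive = TRUE` for the `<= 100` variant used by the original qSOFA
#' derivation.
#'
#' @param rr cleaned respiratory rate (1/min), numeric vector.
#' @param sbp cleaned systolic blood pressure (mmHg), aligned with `rr`.
#' @param altered_mentation logical vector (see [mentation_series()]); `NA`
#'   treated as not altered.
#' @param rr_threshold respiratory-rate cut-off (default 22, inclusive).
#' @param sbp_threshold systolic cut-off (default 100).
#' @param sbp_inclusive logical; strict `<` when `FALSE` (default).
#' @return data.table with logical columns `rr`, `sbp`, `mentation` and
#'   integer `n_fulfilled`.
#' @export
qsofa_flags <- function(rr, sbp, altered_mentation, rr_threshold = 22,
                        sbp_threshold = 100, sbp_inclusive = FALSE) {
  n <- max(length(rr), length(sbp), length(altered_mentation))
  rr <- rep_len(as.numeric(rr), n)
  sbp <- rep_len(as.numeric(sbp), n)
  am <- rep_len(as.logical(altered_mentation), n)
  f_rr <- !is.na(rr) & rr >= rr_threshold
  f_sbp <- if (sbp_inclusive) !is.na(sbp) & sbp <= sbp_threshold else
    !is.na(sbp) & sbp < sbp_threshold
  f_m <- !is.na(am) & am
  data.table(rr = f_rr, sbp = f_sbp, mentation = f_m,
             n_fulfilled = as.integer(f_rr) + as.integer(f_sbp) +
               as.integer(f_m))
}

#' Per-time-point SIRS criterion flags
#'
#' Four criteria of the 1992 consensus definition; the respiratory criterion
#' is disjunctive (tachypnoea or hypocapnia) and each flag is missing-aware.
#'
#' @param temp cleaned temperature (C).
#' @param hr cleaned heart rate (1/min).
#' @param rr cleaned respiratory rate (1/min).
#' @param wbc leucocyte count (10^9/L) aligned to the grid (see
#'   [lab_lookback()]).
#' @param paco2 arterial CO2 partial pressure (mmHg), aligned likewise.
#' @param thresholds threshold table, see [sirs_thresholds()].
#' @return data.table with logical columns `temp`, `hr`, `resp`, `wbc` and
#'   integer `n_fulfilled`.
#' @export
sirs_flags <- function(temp, hr, rr, wbc, paco2,
                       thresholds = sirs_thresholds()) {
  n <- max(length(temp), length(hr), length(rr), length(wbc), length(paco2))
  temp <- rep_len(as.numeric(temp), n); hr <- rep_len(as.numeric(hr), n)
  rr <- rep_len(as.numeric(rr), n); wbc <- rep_len(as.numeric(wbc), n)
  paco2 <- rep_len(as.numeric(paco2), n)
  th <- thresholds
  f_t <- !is.na(temp) & (temp > th$temp_high | temp < th$temp_low)
  f_h <- !is.na(hr) & hr > th$hr_high
  f_r <- (!is.na(rr) & rr > th$rr_high) | (!is.na(paco2) & paco2 < th$paco2_low)
  f_w <- !is.na(wbc) & (wbc > th$wbc_high | wbc < th$wbc_low)
  data.table(temp = f_t, hr = f_h, resp = f_r, wbc = f_w,
             n_fulfilled = as.integer(f_t) + as.integer(f_h) +
               as.integer(f_r) + as.integer(f_w))
}

#' Carry the most recent laboratory value onto a time grid
#'
#' For each grid time the latest measurement at or before it is used, but only
#' while it is younger than the validity horizon (24 h for a daily leucocyte
#' draw, 12 h for blood-gas CO2 are the pipeline defaults). Older or absent
#' values yield `NA`.
#'
#' @param times POSIXct grid times (sorted).
#' @param lab_times POSIXct measurement times.
#' @param lab_values numeric measurements.
#' @param horizon_hours validity horizon; `Inf` disables expiry.
#' @return numeric vector aligned with `times`.
#' @export
lab_lookback <- function(times, lab_times, lab_values, horizon_hours = 24) {
  if (length(lab_times) == 0L) return(rep(NA_real_, length(times)))
  ord <- order(lab_times)
  lab_times <- as_utc(lab_times)[ord]
  lab_values <- lab_values[ord]
  idx <- findInterval(as.numeric(as_utc(times)), as.numeric(lab_times))
  out <- rep(NA_real_, length(times))
  has <- idx >= 1L
  out[has] <- lab_values[idx[has]]
  if (is.finite(horizon_hours)) {
    age <- as.numeric(as_utc(times)) - as.numeric(lab_times)[pmax(idx, 1L)]
    out[has & age > horizon_hours * 3600] <- NA_real_
  }
  out
}

#' Altered-mentation series from consciousness assessments
#'
#' For each grid time the most recent assessment at or before it decides the
#' flag: Glasgow Coma Scale `< 15` is altered; when no GCS assessment exists
#' for the encounter, Richmond Agitation Sedation Scale `!= 0` is the
#' fall-back surrogate. No assessment at all yields `NA` (never positive).
#'
#' @param times POSIXct grid times.
#' @param consciousness data.frame with `timestamp`, `scale`
#'   (`"GCS"`/`"RASS"`), `value` for one encounter.
#' @param gcs_threshold altered when GCS strictly below this (default 15).
#' @return logical vector aligned with `times` (`NA` = unknown).
#' @export
mentation_series <- function(times, consciousness, gcs_threshold = 15) {
  cons <- as.data.table(consciousness)
  if (nrow(cons) == 0L) return(rep(NA, length(times)))
  gcs <- cons[scale == "GCS"]
  if (nrow(gcs) > 0L) {
    v <- lab_lookback(times, gcs$timestamp, gcs$value, horizon_hours = Inf)
    return(ifelse(is.na(v), NA, v < gcs_threshold))
  }
  rass <- cons[scale == "RASS"]
  if (nrow(rass) == 0L) return(rep(NA, length(times)))
  v <- lab_lookback(times, rass$timestamp, rass$value, horizon_hours = Inf)
  ifelse(is.na(v), NA, v != 0)
}

#' Sustained positivity of a criterion series
#'
#' A score is rated positive when at least `min_criteria` criteria are
#' fulfilled continuously for at least `min_duration_min` minutes. On a
#' `interval_min`-minute grid a run of `k` consecutive qualifying points spans
#' `(k - 1) * interval_min` minutes, so the default 30-minute rule on a
#' 15-minute grid requires three consecutive qualifying points.
#'
#' @param n_fulfilled integer vector of fulfilled-criterion counts on the
#'   grid (time-ordered; `NA` counts as not qualifying).
#' @param times optional POSIXct grid times used for `first_positive_time`.
#' @param min_criteria minimum simultaneous criteria (default 2).
#' @param min_duration_min minimum sustained duration in minutes (default 30).
#' @param interval_min grid spacing in minutes (default 15).
#' @return list with `positive` (logical), `first_positive_index` and
#'   `first_positive_time` (`NA` when negative).
#' @export
sustained_positive <- function(n_fulfilled, times = NULL, min_criteria = 2,
                               min_duration_min = 30, interval_min = 15) {
  k_req <- as.integer(ceiling(min_duration_min / interval_min)) + 1L
  ok <- !is.na(n_fulfilled) & n_fulfilled >= min_criteria
  res <- list(positive = FALSE, first_positive_index = NA_integer_,
              first_positive_time = as_utc(NA))
  if (!length(ok) || !any(ok)) return(res)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= k_req)
  if (!length(hit)) return(res)
  i0 <- starts[hit[1L]]
  res$positive <- TRUE
  res$first_positive_index <- i0
  if (!is.null(times)) res$first_positive_time <- as_utc(times)[i0]
  res
}

#' The shipped SOFA component table
#'
#' Standard six-system SOFA bands as cut-offs on the daily worst values.
#' Respiration is banded purely by the PaO2/FiO2 ratio (the
#' ventilatory-support qualifier of the 3- and 4-point bands is not modelled);
#' cardiovascular support is carried as a categorical vasopressor exposure
#' (`none`/`low`/`mid`/`high`) rather than doses; the renal component is the
#' worse of the creatinine and 24-h urine-output bands.
#'
#' @return a list of per-component cut-off descriptors (documented defaults;
#'   users may supply an edited copy to [sofa_total()]).
#' @export
sofa_component_table <- function() {
  list(
    respiration = list(breaks = c(100, 200, 300, 400),  # PaO2/FiO2 mmHg
                       scores = c(4L, 3L, 2L, 1L, 0L)),
    coagulation = list(breaks = c(20, 50, 100, 150),     # platelets 10^9/L
                       scores = c(4L, 3L, 2L, 1L, 0L)),
    liver = list(breaks = c(1.2, 2.0, 6.0, 12.0),        # bilirubin mg/dL
                 scores = c(0L, 1L, 2L, 3L, 4L)),
    cardiovascular = list(map_break = 70,                # MAP mmHg
                          vaso_scores = c(none = NA, low = 2L, mid = 3L,
                                          high = 4L)),
    cns = list(breaks = c(6, 10, 13, 15),                # GCS
               scores = c(4L, 3L, 2L, 1L, 0L)),
    renal = list(crea_breaks = c(1.2, 2.0, 3.5, 5.0),    # creatinine mg/dL
                 crea_scores = c(0L, 1L, 2L, 3L, 4L),
                 uo_breaks = c(200, 500),                # urine mL/day
                 uo_scores = c(4L, 3L, 0L))
  )
}

.band_low_worse <- function(x, breaks, scores) {
  # scores ordered for intervals (-Inf, b1), [b1, b2), ..., [bk, Inf)
  scores[findInterval(x, breaks) + 1L]
}

#' Daily SOFA component scores and total
#'
#' Maps daily worst physiologic values to the six 0-4 component scores using
#' [sofa_component_table()] and sums them (0-24). A missing component input is
#' scored 0 and counted in the `n_missing` column (no imputation).
#'
#' @param inputs data.frame with one row per encounter-day and columns
#'   `pao2fio2` (mmHg), `platelets` (10^9/L), `bilirubin` (mg/dL), `map`
#'   (mmHg), `vaso` (`"none"`,`"low"`,`"mid"`,`"high"`), `gcs`, `creatinine`
#'   (mg/dL), `urine24` (mL/day). Extra columns are carried through.
#' @param table component cut-off table, default [sofa_component_table()].
#' @return data.table of `inputs` plus integer columns `sofa_resp`,
#'   `sofa_coag`, `sofa_liver`, `sofa_cardio`, `sofa_cns`, `sofa_renal`,
#'   `sofa_total`, `n_missing`.
#' @examples
#' sofa_total(data.frame(pao2fio2 = 250, platelets = 80, bilirubin = 2.5,
#'                       map = 68, vaso = "none", gcs = 13, creatinine = 2.2,
#'                       urine24 = 1500))$sofa_total # 10
#' @export
sofa_total <- function(inputs, table = sofa_component_table()) {
  d <- as.data.table(inputs)
  need <- c("pao2fio2", "platelets", "bilirubin", "map", "vaso", "gcs",
            "creatinine", "urine24")
  for (cn in setdiff(need, names(d))) d[, (cn) := NA]
  .chk <- function(x, lo, hi, what) {
    bad <- !is.na(x) & (x < lo | x > hi)
    if (any(bad)) stop("sofa_total(): ", what, " out of physiologic range: ",
                       paste(unique(x[bad]), collapse = ", "))
  }
  .chk(d$gcs, 3, 15, "GCS")
  .chk(d$pao2fio2, 0, 1000, "PaO2/FiO2")
  .chk(d$platelets, 0, 5000, "platelets")
  .chk(d$bilirubin, 0, 100, "bilirubin")
  .chk(d$creatinine, 0, 50, "creatinine")
  .chk(d$map, 0, 300, "MAP")
  .chk(d$urine24, 0, 50000, "urine output")

  z <- function(x) ifelse(is.na(x), 0L, x)
  resp <- .band_low_worse(d$pao2fio2, table$respiration$breaks,
                          table$respiration$scores)
  coag <- .band_low_worse(d$platelets, table$coagulation$breaks,
                          table$coagulation$scores)
  liver <- .band_low_worse(d$bilirubin, table$liver$breaks,
                           table$liver$scores)
  vs <- table$cardiovascular$vaso_scores[as.character(d$vaso)]
  map_sc <- ifelse(!is.na(d$map) & d$map < table$cardiovascular$map_break,
                   1L, ifelse(is.na(d$map), NA_integer_, 0L))
  cardio <- ifelse(!is.na(vs), vs, map_sc)
  cns <- .band_low_worse(d$gcs, table$cns$breaks, table$cns$scores)
  crea <- .band_low_worse(d$creatinine, table$renal$crea_breaks,
                          table$renal$crea_scores)
  uo <- .band_low_worse(d$urine24, table$renal$uo_breaks,
                        table$renal$uo_scores)
  renal <- pmax(z(crea), z(uo))
  renal[is.na(crea) & is.na(uo)] <- NA_integer_

  comp <- data.table(sofa_resp = resp, sofa_coag = coag, sofa_liver = liver,
                     sofa_cardio = as.integer(cardio), sofa_cns = cns,
                     sofa_renal = as.integer(renal))
  n_missing <- rowSums(is.na(comp))
  for (cn in names(comp)) comp[[cn]] <- z(comp[[cn]])
  out <- cbind(d, comp)
  out[, `:=`(sofa_total = comp$sofa_resp + comp$sofa_coag + comp$sofa_liver +
               comp$sofa_cardio + comp$sofa_cns + comp$sofa_renal,
             n_missing = as.integer(n_missing))]
  out[]
}

#' Day-over-day SOFA increase rule
#'
#' Each day's total is compared with the previous day's; an increase of at
#' least `delta` (default 2) points is rated positive. The first day has no
#' previous day and by default is not evaluated (`baseline = NA`); set
#' `baseline = 0` to additionally rate a first-day total of `delta` or more
#' positive (no-prior-dysfunction convention). `first_positive_time` is
#' midnight (UTC) of the first qualifying day.
#'
#' @param totals integer vector of daily SOFA totals, in day order.
#' @param dates Date vector aligned with `totals` (optional).
#' @param delta minimum day-over-day increase (default 2).
#' @param baseline value the first day is compared against (default `NA`:
#'   day one is never rated on its own).
#' @return list with `positive`, `first_positive_day` (index),
#'   `first_positive_time`, and `qualifying_days` (logical per day).
#' @export
sofa_delta_positive <- function(totals, dates = NULL, delta = 2,
                                baseline = NA_real_) {
  if (!length(totals)) {
    return(list(positive = FALSE, first_positive_day = NA_integer_,
                first_positive_time = as_utc(NA),
                qualifying_days = logical(0)))
  }
  prev <- c(baseline, totals[-length(totals)])
  qual <- !is.na(totals) & !is.na(prev) & (totals - prev) >= delta
  i0 <- if (any(qual)) which(qual)[1L] else NA_integer_
  t0 <- as_utc(NA)
  if (!is.na(i0) && !is.null(dates)) {
    t0 <- as_utc(as.POSIXct(as.Date(dates[i0]), tz = "UTC"))
  }
  list(positive = any(qual), first_positive_day = i0,
       first_positive_time = t0, qualifying_days = qual)
}

# Determinations for one encounter across all scores and episode windows.
# Internal work-horse used by score_cohort(); inputs are pre-split tables.
.score_one_encounter <- function(enc_id, admission, discharge, cleaned, labs,
                                 consciousness, sofa_daily, episodes, opts) {
  interval <- opts$interval_min
  grid <- seq(from = admission, to = discharge, by = interval * 60)
  nt <- length(grid)
  chan <- function(ch) {
    x <- rep(NA_real_, nt)
    sub <- cleaned[channel == ch]
    if (nrow(sub)) {
      idx <- as.integer(round((as.numeric(sub$timestamp) -
                                 as.numeric(admission)) / (interval * 60))) + 1L
      keep <- idx >= 1L & idx <= nt
      x[idx[keep]] <- sub$value[keep]
    }
    x
  }
  v_rr <- chan("RR"); v_sbp <- chan("SBP"); v_hr <- chan("HR")
  v_temp <- chan("TEMP")
  wbc <- lab_lookback(grid, labs[analyte == "WBC"]$timestamp,
                      labs[analyte == "WBC"]$value,
                      opts$wbc_horizon_hours)
  paco2 <- lab_lookback(grid, labs[analyte == "PACO2"]$timestamp,
                        labs[analyte == "PACO2"]$value,
                        opts$paco2_horizon_hours)
  ment <- mentation_series(grid, consciousness, opts$gcs_threshold)

  nq <- qsofa_flags(v_rr, v_sbp, ment, opts$qsofa_rr_threshold,
                    opts$qsofa_sbp_threshold,
                    opts$qsofa_sbp_inclusive)$n_fulfilled
  ns <- sirs_flags(v_temp, v_hr, v_rr, wbc, paco2,
                   opts$sirs_thresholds)$n_fulfilled

  sofa <- NULL
  if (nrow(sofa_daily)) {
    sofa_daily <- sofa_daily[order(date)]
    sc <- sofa_total(sofa_daily, opts$sofa_table)
    sofa <- sofa_delta_positive(sc$sofa_total, sc$date,
                                delta = opts$sofa_delta,
                                baseline = opts$sofa_baseline)
    sofa$dates <- as.Date(sc$date)
  }

  windows <- if (nrow(episodes)) {
    episodes[, .(episode_id, start = start_time, end = end_time)]
  } else {
    data.table(episode_id = NA_integer_, start = admission,
               end = discharge + interval * 60)
  }
  non_episode <- nrow(episodes) == 0L

  res <- vector("list", nrow(windows) * 3L)
  k <- 0L
  for (w in seq_len(nrow(windows))) {
    inw <- grid >= windows$start[w] & grid < windows$end[w]
    for (score in c("SIRS", "QSOFA")) {
      nf <- if (score == "SIRS") ns else nq
      det <- sustained_positive(nf[inw], grid[inw], opts$min_criteria,
                                opts$min_duration_min, interval)
      k <- k + 1L
      res[[k]] <- data.table(encounter_id = enc_id,
                             episode_id = windows$episode_id[w],
                             score = score, positive = det$positive,
                             first_positive_time = det$first_positive_time,
                             non_episode = non_episode)
    }
    # SOFA: a qualifying day counts for this window when the day's in-stay
    # interval overlaps it (midnight alone may precede a same-day onset).
    pos <- FALSE; t0 <- as_utc(NA)
    if (!is.null(sofa) && any(sofa$qualifying_days)) {
      day_start <- as_utc(as.POSIXct(sofa$dates, tz = "UTC"))
      day_end <- day_start + 86400
      lo <- pmax(as.numeric(day_start), as.numeric(admission))
      hi <- pmin(as.numeric(day_end), as.numeric(discharge) + 86400 / 96)
      ov <- sofa$qualifying_days &
        lo < as.numeric(windows$end[w]) & hi > as.numeric(windows$start[w])
      if (any(ov)) {
        pos <- TRUE
        t0 <- day_start[which(ov)[1L]]
      }
    }
    k <- k + 1L
    res[[k]] <- data.table(encounter_id = enc_id,
                           episode_id = windows$episode_id[w],
                           score = "SOFA", positive = pos,
                           first_positive_time = t0,
                           non_episode = non_episode)
  }
  rbindlist(res)
}

#' Default scoring options
#'
#' All constants of the positivity rules in one place: the 30-minute
#' sustained-positivity rule, the `>= 2` criterion counts, the qSOFA
#' thresholds (strict `SBP < 100` as the reproduced analysis prints it), the
#' SIRS threshold table, lab validity horizons (24 h leucocytes, 12 h CO2),
#' the SOFA day-over-day delta (2) and the day-1 baseline (`NA`: the first
#' day is not rated on its own).
#'
#' @return named list of options accepted by [score_cohort()].
#' @export
score_options <- function() {
  list(interval_min = 15, min_criteria = 2, min_duration_min = 30,
       qsofa_rr_threshold = 22, qsofa_sbp_threshold = 100,
       qsofa_sbp_inclusive = FALSE, gcs_threshold = 15,
       sirs_thresholds = sirs_thresholds(), wbc_horizon_hours = 24,
       paco2_horizon_hours = 12, sofa_delta = 2, sofa_baseline = NA_real_,
       sofa_table = sofa_component_table())
}

#' Score every encounter of a cohort
#'
#' Computes SIRS, qSOFA and SOFA-delta determinations per suspected-infection
#' episode; encounters without any episode are scored over the full stay and
#' flagged `non_episode` (they form the score-negative exposure stratum of
#' the evaluation).
#'
#' @param cleaned cleaned vitals table from [clean_vitals()].
#' @param labs table `encounter_id, timestamp, analyte, value`.
#' @param consciousness table `encounter_id, timestamp, scale, value`.
#' @param sofa_daily table of daily worst SOFA inputs (see [sofa_total()])
#'   with `encounter_id` and `date` columns.
#' @param encounters table with `encounter_id`, `admission`, `discharge`.
#' @param episodes episode table from [detect_episodes()].
#' @param opts options list, see [score_options()].
#' @return data.table `encounter_id, episode_id, score, positive,
#'   first_positive_time, non_episode`.
#' @export
score_cohort <- function(cleaned, labs, consciousness, sofa_daily, encounters,
                         episodes, opts = score_options()) {
  encounters <- as.data.table(encounters)
  cleaned <- as.data.table(cleaned)
  labs <- as.data.table(labs)
  consciousness <- as.data.table(consciousness)
  sofa_daily <- as.data.table(sofa_daily)
  episodes <- as.data.table(episodes)

  sp <- function(d) split(d, by = "encounter_id", keep.by = TRUE)
  cl_s <- sp(cleaned); lb_s <- sp(labs); cs_s <- sp(consciousness)
  sd_s <- sp(sofa_daily); ep_s <- sp(episodes)
  empty <- function(l, id, proto) if (id %in% names(l)) l[[id]] else proto[0]

  out <- vector("list", nrow(encounters))
  for (i in seq_len(nrow(encounters))) {
    id <- encounters$encounter_id[i]
    out[[i]] <- .score_one_encounter(
      id, encounters$admission[i], encounters$discharge[i],
      empty(cl_s, id, cleaned), empty(lb_s, id, labs),
      empty(cs_s, id, consciousness), empty(sd_s, id, sofa_daily),
      empty(ep_s, id, episodes), opts)
  }
  det <- rbindlist(out)
  pipeline_log("score_cohort: %d determinations for %d encounters",
               nrow(det), nrow(encounters))
  det
}
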