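#' Default per-score operating-characteristic targets
#'
#' The generator controls how strongly the latent infection/death state
#' drives the vital signs through per-score targets with conditional
#' semantics: `sens_mortality = P(score positive | infected, died)`,
#' `spec_mortality = 1 - P(positive | infected, survived)` and
#' `spec_infection = 1 - P(positive | not infected)`. Defaults are the
#' published IMCU/ICU/IMCU-ICU operating points of the three scores.
#'
#' @return data.table with columns `score`, `stratum`, `sens_mortality`,
#'   `spec_mortality`, `spec_infection`.
#' @export
default_score_targets <- function() {
  rbindlist(list(
    data.table(score = "SIRS", stratum = c("IMCU", "ICU", "IMCU/ICU"),
               sens_mortality = c(1.00, 0.96, 1.00),
               spec_mortality = c(0.44, 0.24, 0.07),
               spec_infection = c(0.48, 0.32, 0.13)),
    data.table(score = "SOFA", stratum = c("IMCU", "ICU", "IMCU/ICU"),
               sens_mortality = c(0.27, 0.49, 0.73),
               spec_mortality = c(0.98, 0.89, 0.74),
               spec_infection = c(0.99, 0.97, 0.92)),
    data.table(score = "QSOFA", stratum = c("IMCU", "ICU", "IMCU/ICU"),
               sens_mortality = c(0.98, 0.96, 1.00),
               spec_mortality = c(0.65, 0.42, 0.17),
               spec_infection = c(0.70, 0.51, 0.30))
  ))
}

#' Default vital-sign generative model parameters
#'
#' Per channel: baseline, marginal noise SD, first-order autocorrelation
#' `phi` of the noise at the 15-minute step, and circadian (24-h sinusoid)
#' amplitude peaking at 16:00. Values chosen once as physiologically
#' plausible resting adult levels with enough short-range correlation that
#' the rolling-median filters have realistic work to do.
#'
#' @return named list per channel with `baseline`, `sd`, `phi`, `circ_amp`.
#' @export
default_vitals_model <- function() {
  list(HR = list(baseline = 78, sd = 5, phi = 0.8, circ_amp = 3),
       RR = list(baseline = 16, sd = 2, phi = 0.8, circ_amp = 1),
       SBP = list(baseline = 125, sd = 6, phi = 0.8, circ_amp = 4),
       TEMP = list(baseline = 36.8, sd = 0.15, phi = 0.9, circ_amp = 0.3))
}

#' Calibrate an additive infection shift by root-finding
#'
#' Finds the additive shift that makes a single Gaussian sample cross the
#' criterion threshold with probability `p_exceed`, at the least favourable
#' circadian phase. Used by the generator so that an intended sustained
#' criterion window is detected essentially surely after median filtering,
#' while baseline streams essentially never cross.
#'
#' @param threshold criterion threshold.
#' @param baseline channel baseline.
#' @param sd marginal noise SD.
#' @param direction `"above"` (criterion is value above threshold) or
#'   `"below"`.
#' @param p_exceed target per-sample crossing probability (default 0.999).
#' @param circ_amp circadian amplitude included at its worst phase.
#' @return the additive shift (negative for `direction = "below"`).
#' @export
calibrate_shift <- function(threshold, baseline, sd, direction = c("above", "below"),
                            p_exceed = 0.999, circ_amp = 0) {
  direction <- match.arg(direction)
  worst_base <- if (direction == "above") baseline - circ_amp else
    baseline + circ_amp
  f <- function(shift) {
    mu <- worst_base + shift
    p <- if (direction == "above") 1 - pnorm((threshold - mu) / sd) else
      pnorm((threshold - mu) / sd)
    p - p_exceed
  }
  uniroot(f, interval = c(-500, 500), tol = 1e-8)$root
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated IMCU/ICU cohort: stratum
#' mix and stay lengths, infection prevalence and mortality among infected
#' per stratum, per-score operating targets (see [default_score_targets()]),
#' the vital-sign model, artifact rates and the sampling grid.
#'
#' @param n_encounters number of encounters (> 0).
#' @param unit_mix proportions over `IMCU`, `ICU`, `IMCU/ICU` (sum 1).
#' @param infection_prevalence per-stratum probability of suspected
#'   infection.
#' @param mortality_given_infection per-stratum probability of hospital
#'   death among infected encounters (deaths are generated only among
#'   infected encounters).
#' @param score_targets per-score/stratum operating targets.
#' @param sampling_interval grid spacing in minutes (must divide 60).
#' @param artifact_spike_rate expected single-sample spikes per channel per
#'   day.
#' @param temp_dislocation_rate expected temperature-probe dislocation
#'   episodes per day.
#' @param missing_rate per-sample probability of a missing vitals record.
#' @param stay_meanlog,stay_sdlog per-stratum log-normal stay-length (days)
#'   parameters; stays are clipped to `[stay_min_days, stay_cap_days]`.
#' @param stay_min_days,stay_cap_days stay-length bounds in days.
#' @param vitals vital-sign model, see [default_vitals_model()].
#' @param qsofa_window_hours,sirs_window_hours length of the injected
#'   sustained criterion windows.
#' @param p_exceed per-sample crossing probability used by
#'   [calibrate_shift()].
#' @param excluded_ab_rate probability an encounter receives a
#'   non-broad-spectrum (excluded-list) antibiotic.
#' @param unknown_ab_rate probability of an off-catalog drug event.
#' @param restart_ab_rate probability an infected encounter has a second
#'   broad start inside its 72-h window (absorbed, exercises episode logic).
#' @param rass_only_rate fraction of encounters documented with RASS instead
#'   of GCS.
#' @param admission_range character or POSIXct length-2 admission window.
#' @param seed integer RNG seed (< 2^31).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_encounters,
                          unit_mix = c(IMCU = 0.518, ICU = 0.279,
                                       `IMCU/ICU` = 0.203),
                          infection_prevalence = c(IMCU = 0.183, ICU = 0.355,
                                                   `IMCU/ICU` = 0.620),
                          mortality_given_infection = c(IMCU = 0.034,
                                                        ICU = 0.153,
                                                        `IMCU/ICU` = 0.094),
                          score_targets = default_score_targets(),
                          sampling_interval = 15,
                          artifact_spike_rate = 0.5,
                          temp_dislocation_rate = 0.2,
                          missing_rate = 0.01,
                          stay_meanlog = c(IMCU = log(2.5), ICU = log(3.5),
                                           `IMCU/ICU` = log(5)),
                          stay_sdlog = 0.7,
                          stay_min_days = 1, stay_cap_days = 14,
                          vitals = default_vitals_model(),
                          qsofa_window_hours = 3, sirs_window_hours = 8,
                          p_exceed = 0.999,
                          excluded_ab_rate = 0.15, unknown_ab_rate = 0.05,
                          restart_ab_rate = 0.3, rass_only_rate = 0.2,
                          admission_range = c("2012-01-01", "2018-09-30"),
                          seed = 1L) {
  units <- c("IMCU", "ICU", "IMCU/ICU")
  if (length(n_encounters) != 1L || is.na(n_encounters) || n_encounters < 1) {
    stop("cohort_config(): n_encounters must be a positive count")
  }
  if (abs(sum(unit_mix) - 1) > 1e-8 || any(unit_mix < 0)) {
    stop("cohort_config(): unit_mix must be non-negative and sum to 1")
  }
  stopifnot(all(names(unit_mix) %in% units),
            all(infection_prevalence >= 0 & infection_prevalence <= 1),
            all(mortality_given_infection >= 0 &
                  mortality_given_infection <= 1),
            60 %% sampling_interval == 0,
            artifact_spike_rate >= 0, temp_dislocation_rate >= 0,
            missing_rate >= 0, missing_rate < 1,
            stay_min_days > 0, stay_cap_days >= stay_min_days)
  st <- as.data.table(score_targets)
  stopifnot(all(c("score", "stratum", "sens_mortality", "spec_mortality",
                  "spec_infection") %in% names(st)))
  cfg <- list(n_encounters = as.integer(n_encounters), unit_mix = unit_mix,
              infection_prevalence = infection_prevalence,
              mortality_given_infection = mortality_given_infection,
              score_targets = st, sampling_interval = sampling_interval,
              artifact_spike_rate = artifact_spike_rate,
              temp_dislocation_rate = temp_dislocation_rate,
              missing_rate = missing_rate, stay_meanlog = stay_meanlog,
              stay_sdlog = stay_sdlog, stay_min_days = stay_min_days,
              stay_cap_days = stay_cap_days, vitals = vitals,
              qsofa_window_hours = qsofa_window_hours,
              sirs_window_hours = sirs_window_hours, p_exceed = p_exceed,
              excluded_ab_rate = excluded_ab_rate,
              unknown_ab_rate = unknown_ab_rate,
              restart_ab_rate = restart_ab_rate,
              rass_only_rate = rass_only_rate,
              admission_range = admission_range, seed = as.integer(seed))
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d encounters, seed %d\n", x$n_encounters,
              x$seed))
  cat("  unit mix: ", paste(sprintf("%s %.1f%%", names(x$unit_mix),
                                    100 * x$unit_mix), collapse = ", "), "\n")
  cat("  infection prevalence: ",
      paste(sprintf("%s %.1f%%", names(x$infection_prevalence),
                    100 * x$infection_prevalence), collapse = ", "), "\n")
  invisible(x)
}
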