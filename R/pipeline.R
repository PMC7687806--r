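#' Pipeline configuration
#'
#' Gathers every constant of the analysis in one place so sensitivity
#' analyses (e.g. `SBP <= 100` instead of `< 100`) are one-line changes:
#' cleaning windows (3 samples for HR/RR/SBP, 17 for temperature), the 31 C
#' temperature artifact threshold, the 30-minute sustained-positivity rule,
#' the SOFA day-over-day delta of 2, the 72-hour episode length, the
#' antibiotic catalog, and evaluation options.
#'
#' @param cohort a [cohort_config()] for the `simulate` stage (optional when
#'   driving the pipeline from files).
#' @param windows named cleaning windows per channel.
#' @param temp_threshold temperature artifact cut-off (C).
#' @param scoring scoring options, see [score_options()].
#' @param catalog_path optional path to an antibiotic catalog YAML.
#' @param episode_hours suspected-infection episode length (h).
#' @param mortality_within_infection see [evaluate_scores()].
#' @param ci_method `"hanley"` or `"bootstrap"`.
#' @param seed integer seed (defaults to the cohort config's seed).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL,
                            windows = c(HR = 3, RR = 3, SBP = 3, TEMP = 17),
                            temp_threshold = 31,
                            scoring = score_options(),
                            catalog_path = NULL,
                            episode_hours = 72,
                            mortality_within_infection = TRUE,
                            ci_method = "hanley",
                            seed = NULL) {
  stopifnot(all(windows %% 2 == 1), all(windows >= 1), episode_hours > 0,
            scoring$min_duration_min > 0)
  structure(list(cohort = cohort, windows = windows,
                 temp_threshold = temp_threshold, scoring = scoring,
                 catalog_path = catalog_path, episode_hours = episode_hours,
                 mortality_within_infection = mortality_within_infection,
                 ci_method = ci_method,
                 seed = as.integer(seed %||% cohort$seed %||% 1L)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; a `cohort` block
#' is passed to [cohort_config()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    cargs <- y$cohort
    for (nm in c("unit_mix", "infection_prevalence",
                 "mortality_given_infection", "stay_meanlog")) {
      if (!is.null(cargs[[nm]])) cargs[[nm]] <- unlist(cargs[[nm]])
    }
    if (!is.null(cargs$score_targets)) {
      cargs$score_targets <- rbindlist(lapply(cargs$score_targets,
                                              as.data.table))
    }
    cohort <- do.call(cohort_config, cargs)
  }
  scoring <- score_options()
  for (nm in intersect(names(y$scoring %||% list()), names(scoring))) {
    scoring[[nm]] <- y$scoring[[nm]]
  }
  args <- list(cohort = cohort, scoring = scoring)
  for (nm in c("temp_threshold", "episode_hours",
               "mortality_within_infection", "ci_method", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$windows)) args$windows <- unlist(y$windows)
  if (!is.null(y$catalog_path)) args$catalog_path <- y$catalog_path
  do.call(pipeline_config, args)
}

#' Run the full screening pipeline
#'
#' Stages, in order: simulate (or accept an existing cohort), clean the
#' vitals, detect suspected-infection episodes, score SIRS/qSOFA/SOFA per
#' episode, and evaluate discrimination per stratum. Fully reproducible for
#' a fixed configuration seed.
#'
#' @param config a [pipeline_config()] whose `cohort` field is set, or a
#'   [cohort_config()] (wrapped with defaults).
#' @param cohort optionally, an existing `sepsis_cohort` or a list of cohort
#'   tables (as from [read_cohort()]) to analyse instead of simulating.
#' @param out_dir optional directory; when given, every stage writes its
#'   output CSV there.
#' @return object of class `sepsis_screen` with elements `cohort`,
#'   `cleaned`, `episodes`, `determinations`, `evaluation`, `summary`,
#'   `config`.
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL) {
  if (inherits(config, "cohort_config")) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$cohort)) {
      stop("run_pipeline(): no cohort config and no cohort data given")
    }
    pipeline_log("stage simulate: %d encounters", config$cohort$n_encounters)
    cohort <- generate_cohort(config$cohort)
  }
  tabs <- if (inherits(cohort, "sepsis_cohort")) unclass(cohort) else cohort
  if (!is.null(out_dir) && inherits(cohort, "sepsis_cohort")) {
    write_cohort(cohort, out_dir)
  }

  cleaned <- clean_vitals(tabs$vitals, tabs$encounters,
                          windows = config$windows,
                          temp_threshold = config$temp_threshold,
                          interval_min = config$scoring$interval_min)
  catalog <- antibiotic_catalog(config$catalog_path)
  episodes <- detect_episodes(tabs$medications, tabs$encounters, catalog,
                              config$episode_hours)
  determinations <- score_cohort(cleaned, tabs$labs, tabs$consciousness,
                                 tabs$sofa_daily, tabs$encounters, episodes,
                                 config$scoring)
  evaluation <- evaluate_scores(
    determinations, episodes, tabs$encounters,
    mortality_within_infection = config$mortality_within_infection,
    ci_method = config$ci_method)
  summary_tab <- cohort_summary(tabs$encounters)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(cleaned, file.path(out_dir, "cleaned_vitals.csv"), "vitals")
    write_table(episodes, file.path(out_dir, "episodes.csv"), "episodes")
    write_table(determinations, file.path(out_dir, "determinations.csv"),
                "determinations")
    write_table(as.data.table(unclass(evaluation)),
                file.path(out_dir, "results.csv"), "results")
    fwrite(summary_tab, file.path(out_dir, "cohort_summary.csv"))
  }

  structure(list(cohort = cohort, cleaned = cleaned, episodes = episodes,
                 determinations = determinations, evaluation = evaluation,
                 summary = summary_tab, config = config),
            class = "sepsis_screen")
}

#' @export
print.sepsis_screen <- function(x, ...) {
  enc <- as.data.table(x$cohort$encounters %||% x$cohort[["encounters"]])
  cat(sprintf("<sepsis_screen> %d encounters, %d episodes, %d determinations\n",
              nrow(enc), nrow(x$episodes), nrow(x$determinations)))
  print(x$evaluation)
  invisible(x)
}

#' @export
summary.sepsis_screen <- function(object, ...) {
  cat("Cohort summary (per unit stratum)\n")
  print(as.data.frame(object$summary), row.names = FALSE)
  cat("\n")
  print(object$evaluation)
  cmp <- attr(object$evaluation, "comparisons")
  if (!is.null(cmp) && nrow(cmp)) {
    cat("\nPairwise AUC comparisons (paired DeLong)\n")
    print(as.data.frame(cmp[, .(stratum, outcome, score_a, score_b,
                                p_value = signif(p_value, 3))]),
          row.names = FALSE)
  }
  invisible(object)
}
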