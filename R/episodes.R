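#' Default broad-spectrum antibiotic catalog
#'
#' Inclusion list: carbapenems, glycopeptides, quinolones,
#' piperacillin/sulbactam (with piperacillin/tazobactam as a class member,
#' since the former combination is not a marketed product), ceftazidime,
#' cefepime, linezolid, tigecycline, daptomycin and fosfomycin. Exclusion
#' list: ampicillin, cefazolin, cefuroxime, colistin, metronidazole,
#' erythromycin, trimethoprim/sulfamethoxazole and azithromycin. Class names
#' are expanded to concrete products via an editable YAML file shipped with
#' the package; pass your own file to override either list.
#'
#' @param path optional path to a YAML catalog with keys `broad_spectrum`
#'   (mapping class/drug -> members) and `excluded` (list of names).
#' @return object of class `antibiotic_catalog`: list with `broad`
#'   (named list class -> member drugs), `excluded` (character).
#' @export
antibiotic_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "antibiotic_catalog.yaml",
                                package = "sepsiscreen")
  raw <- yaml::read_yaml(path)
  norm <- function(x) trimws(tolower(x))
  broad <- lapply(raw$broad_spectrum, function(m) norm(unlist(m)))
  names(broad) <- norm(names(raw$broad_spectrum))
  excluded <- norm(unlist(raw$excluded))
  overlap <- intersect(c(names(broad), unlist(broad)), excluded)
  if (length(overlap)) {
    stop("antibiotic_catalog(): drugs on both lists: ",
         paste(overlap, collapse = ", "))
  }
  structure(list(broad = broad, excluded = excluded),
            class = "antibiotic_catalog")
}

#' @export
print.antibiotic_catalog <- function(x, ...) {
  cat(sprintf("<antibiotic_catalog> %d broad-spectrum classes (%d products), %d excluded\n",
              length(x$broad), length(unlist(x$broad)), length(x$excluded)))
  invisible(x)
}

#' Classify an antibiotic name
#'
#' Case-insensitive after trimming. A name matching a broad-spectrum class or
#' any of its members is `"broad"`; a name on the exclusion list is
#' `"excluded"`; anything else is `"unknown"` (logged by the caller, never
#' silently treated as broad).
#'
#' @param drug_name character vector of drug names (non-empty).
#' @param catalog an [antibiotic_catalog()].
#' @return character vector in `c("broad", "excluded", "unknown")`.
#' @examples
#' \dontrun{classify_antibiotic("Meropenem", antibiotic_catalog()) # "broad"}
#' @export
classify_antibiotic <- function(drug_name, catalog = antibiotic_catalog()) {
  x <- trimws(tolower(drug_name))
  if (any(is.na(x) | x == "")) {
    stop("classify_antibiotic(): empty drug name")
  }
  broad_names <- unique(c(names(catalog$broad), unlist(catalog$broad)))
  out <- rep("unknown", length(x))
  out[x %in% broad_names] <- "broad"
  out[x %in% catalog$excluded] <- "excluded"
  out
}

#' Detect suspected-infection episodes from antibiotic starts
#'
#' A suspected-infection episode is the first 72 hours after the start of a
#' broad-spectrum antibiotic. The earliest broad start of an encounter opens
#' an episode `[start, start + 72 h)`; broad starts inside an open episode
#' are absorbed; a broad start after the open episode's end opens a new one,
#' so episodes of one encounter never overlap. Excluded and unknown drugs
#' never open episodes. Episodes are truncated at discharge and flagged.
#' Same-timestamp events are processed in lexicographic drug-name order.
#'
#' @param medications table `encounter_id, drug_name, start_time`.
#' @param encounters table with `encounter_id`, `discharge` used for
#'   truncation (optional; no truncation when absent).
#' @param catalog an [antibiotic_catalog()].
#' @param episode_hours episode length in hours (default 72).
#' @return data.table `encounter_id, episode_id, start_time, end_time,
#'   triggering_drug, truncated`; attribute `"unknown_drugs"` lists names
#'   that matched neither catalog list.
#' @export
detect_episodes <- function(medications, encounters = NULL,
                            catalog = antibiotic_catalog(),
                            episode_hours = 72) {
  med <- as.data.table(medications)
  proto <- data.table(encounter_id = character(), episode_id = integer(),
                      start_time = as_utc(character()),
                      end_time = as_utc(character()),
                      triggering_drug = character(), truncated = logical())
  if (nrow(med) == 0L) {
    setattr(proto, "unknown_drugs", character(0))
    return(proto)
  }
  med[, class := classify_antibiotic(drug_name, catalog)]
  unknown <- sort(unique(med[class == "unknown"]$drug_name))
  if (length(unknown)) {
    pipeline_log("detect_episodes: %d unknown drug names (never broad): %s",
                 length(unknown), paste(unknown, collapse = ", "))
  }
  disch <- NULL
  if (!is.null(encounters)) {
    enc <- as.data.table(encounters)
    disch <- setNames(enc$discharge, enc$encounter_id)
  }
  med <- med[class == "broad"][order(encounter_id, start_time, drug_name)]
  out <- med[, {
    starts <- start_time; drugs <- drug_name
    keep <- integer(0); open_end <- -Inf
    for (j in seq_along(starts)) {
      if (as.numeric(starts[j]) >= open_end) {
        keep <- c(keep, j)
        open_end <- as.numeric(starts[j]) + episode_hours * 3600
      }
    }
    list(episode_id = seq_along(keep), start_time = starts[keep],
         end_time = starts[keep] + episode_hours * 3600,
         triggering_drug = drugs[keep])
  }, by = encounter_id]
  out[, truncated := FALSE]
  if (!is.null(disch) && nrow(out)) {
    dd <- as_utc(disch[out$encounter_id])
    trunc <- !is.na(dd) & out$end_time > dd
    out[trunc, `:=`(end_time = dd[trunc], truncated = TRUE)]
  }
  setattr(out, "unknown_drugs", unknown)
  pipeline_log("detect_episodes: %d episodes across %d encounters",
               nrow(out), uniqueN(out$encounter_id))
  out[]
}
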