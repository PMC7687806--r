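VITAL_CHANNELS <- c("HR", "RR", "SBP", "TEMP")

#' Construct a single-channel vital-sign stream
#'
#' A `vital_stream` is one encounter's values for one channel on a regular
#' sampling grid. Missing slots are `NA`.
#'
#' @param values numeric vector (may contain `NA`).
#' @param channel one of `"HR"`, `"RR"`, `"SBP"`, `"TEMP"`.
#' @param start POSIXct timestamp of the first grid slot.
#' @param interval_min grid spacing in minutes (default 15).
#' @param encounter_id optional encounter identifier.
#' @return an object of class `vital_stream`.
#' @export
vital_stream <- function(values, channel, start, interval_min = 15,
                         encounter_id = NA_character_) {
  channel <- match.arg(channel, VITAL_CHANNELS)
  stopifnot(is.numeric(values), interval_min > 0, 60 %% interval_min == 0)
  structure(list(values = as.numeric(values), channel = channel,
                 start = as_utc(start), interval_min = interval_min,
                 encounter_id = encounter_id),
            class = "vital_stream")
}

#' @export
print.vital_stream <- function(x, ...) {
  cat(sprintf("<vital_stream> %s, %d samples @ %d min, start %s (%d missing)\n",
              x$channel, length(x$values), x$interval_min,
              format(x$start, "%Y-%m-%d %H:%M", tz = "UTC"),
              sum(is.na(x$values))))
  invisible(x)
}

# Grid timestamps of a stream.
stream_times <- function(s) {
  s$start + (seq_along(s$values) - 1L) * s$interval_min * 60
}

#' Snap irregular samples onto a regular grid
#'
#' Each sample is assigned to the grid slot containing its timestamp; when
#' several samples fall in one slot the last observation is kept. Slots
#' without any sample are `NA` — no interpolation is performed.
#'
#' @param timestamps POSIXct sample times.
#' @param values numeric sample values (same length).
#' @param channel channel name for the resulting stream.
#' @param interval_min grid spacing in minutes.
#' @param start,end optional grid bounds (POSIXct); default to the floored
#'   first and last sample times.
#' @param encounter_id optional encounter identifier.
#' @return a [vital_stream()].
#' @export
regularize_vitals <- function(timestamps, values, channel = "HR",
                              interval_min = 15, start = NULL, end = NULL,
                              encounter_id = NA_character_) {
  if (length(timestamps) == 0L && is.null(start)) {
    stop("regularize_vitals(): empty input and no grid bounds given")
  }
  stopifnot(length(timestamps) == length(values))
  timestamps <- as_utc(timestamps)
  start <- floor_to_interval(start %||% min(timestamps), interval_min)
  end <- floor_to_interval(end %||% max(timestamps), interval_min)
  if (end < start) stop("regularize_vitals(): end precedes start")
  secs <- interval_min * 60
  n <- as.integer(floor((as.numeric(end) - as.numeric(start)) / secs)) + 1L
  out <- rep(NA_real_, n)
  if (length(timestamps)) {
    idx <- floor((as.numeric(timestamps) - as.numeric(start)) / secs) + 1
    keep <- idx >= 1 & idx <= n
    ord <- order(timestamps[keep])          # later samples overwrite earlier
    out[idx[keep][ord]] <- values[keep][ord]
  }
  vital_stream(out, channel, start, interval_min, encounter_id)
}

#' Mark low-temperature artifacts as missing
#'
#' Body-temperature readings at or below the artifact threshold (default
#' 31 degrees C, typical of a dislocated probe) are replaced by `NA` before any
#' smoothing. The rule is inclusive: exactly 31.0 is excluded.
#'
#' @param x a numeric vector or a [vital_stream()] (channel must be `TEMP`).
#' @param threshold artifact cut-off in degrees C (default 31).
#' @return object of the same type with artifacts set to `NA`.
#' @export
exclude_temp_artifacts <- function(x, threshold = 31) {
  UseMethod("exclude_temp_artifacts")
}

#' @export
exclude_temp_artifacts.default <- function(x, threshold = 31) {
  stopifnot(is.numeric(x))
  x[!is.na(x) & x <= threshold] <- NA_real_
  x
}

#' @export
exclude_temp_artifacts.vital_stream <- function(x, threshold = 31) {
  if (x$channel != "TEMP") {
    stop("exclude_temp_artifacts(): stream channel is ", x$channel,
         ", artifact rule applies to TEMP only")
  }
  x$values <- exclude_temp_artifacts(x$values, threshold)
  x
}

# Median of <= 2 values handled inline; general centered window with shrinking
# edges and missing-aware medians (even counts -> mean of the middle two).
.median_sorted <- function(w) {
  w <- w[!is.na(w)]
  m <- length(w)
  if (m == 0L) return(NA_real_)
  s <- sort.int(w, method = "quick")
  h <- m %/% 2L
  if (m %% 2L == 1L) s[h + 1L] else (s[h] + s[h + 1L]) / 2
}

#' Centered rolling median with shrinking edges
#'
#' The de-spiking filter applied to the 15-minute vital-sign grid: each output
#' value is the median of the non-missing values in a centered window of
#' `window` samples (`window = 3` for HR/RR/SBP, `17` for temperature).
#' Windows shrink at the stream boundaries; a window with no non-missing value
#' yields `NA`; an even number of available values yields the mean of the two
#' middle order statistics.
#'
#' @param x numeric vector or [vital_stream()].
#' @param window odd positive window length in samples.
#' @return filtered object of the same type and length.
#' @examples
#' rolling_median(c(10, 100, 12, 11), 3) # 55, 12, 12, 11.5
#' @export
rolling_median <- function(x, window) {
  UseMethod("rolling_median")
}

#' @export
rolling_median.vital_stream <- function(x, window) {
  x$values <- rolling_median(x$values, window)
  x
}

#' @export
rolling_median.default <- function(x, window) {
  if (is.logical(x) && all(is.na(x))) x <- as.numeric(x)
  stopifnot(is.numeric(x))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("rolling_median(): window must be a single odd positive integer")
  }
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (window == 1L) return(as.numeric(x))
  h <- window %/% 2L
  out <- rep(NA_real_, n)

  if (window == 3L && n >= 3L) {
    # vectorized interior for the high-volume 3-point case
    a <- x[1:(n - 2L)]; b <- x[2:(n - 1L)]; cc <- x[3:n]
    na_n <- (!is.na(a)) + (!is.na(b)) + (!is.na(cc))
    s <- ifelse(is.na(a), 0, a) + ifelse(is.na(b), 0, b) +
      ifelse(is.na(cc), 0, cc)
    mid <- rep(NA_real_, n - 2L)
    full <- na_n == 3L
    if (any(full)) {
      # exact median-of-three (middle order statistic, no arithmetic)
      mid[full] <- pmax(pmin(a[full], b[full]),
                        pmin(pmax(a[full], b[full]), cc[full]))
    }
    part <- na_n > 0L & !full
    mid[part] <- s[part] / na_n[part]
    out[2:(n - 1L)] <- mid
    out[1L] <- .median_sorted(x[1:2])
    out[n] <- .median_sorted(x[(n - 1L):n])
    return(out)
  }

  for (i in seq_len(n)) {
    out[i] <- .median_sorted(x[max(1L, i - h):min(n, i + h)])
  }
  out
}

#' Clean one encounter-channel stream
#'
#' Applies the channel-appropriate cleaning: temperature gets the artifact
#' exclusion (values <= 31 degrees C dropped) followed by a 17-point rolling
#' median; heart rate, respiratory rate and systolic pressure get a 3-point
#' rolling median. No absolute outlier thresholds are applied to HR/RR/SBP.
#'
#' @param stream a [vital_stream()].
#' @param windows named integer vector of window lengths per channel.
#' @param temp_threshold artifact cut-off in degrees C for TEMP.
#' @return the cleaned [vital_stream()].
#' @export
clean_stream <- function(stream,
                         windows = c(HR = 3, RR = 3, SBP = 3, TEMP = 17),
                         temp_threshold = 31) {
  stopifnot(inherits(stream, "vital_stream"))
  if (stream$channel == "TEMP") {
    stream <- exclude_temp_artifacts(stream, temp_threshold)
  }
  rolling_median(stream, windows[[stream$channel]])
}

#' Clean a long-format vitals table
#'
#' Regularizes every (encounter, channel) series onto the encounter's
#' 15-minute grid (admission to discharge when `encounters` is supplied,
#' otherwise the observed span) and applies [clean_stream()]. The returned
#' table has one row per grid slot, including slots that remain missing, so
#' downstream scoring can align channels.
#'
#' @param vitals data.frame/data.table with columns `encounter_id`,
#'   `timestamp` (POSIXct), `channel`, `value`.
#' @param encounters optional table with `encounter_id`, `admission`,
#'   `discharge` defining the grid bounds.
#' @param windows,temp_threshold see [clean_stream()].
#' @param interval_min grid spacing in minutes.
#' @return data.table `encounter_id, timestamp, channel, value` (cleaned);
#'   attribute `"log"` holds per-stage counts (rows in, temperature artifacts
#'   excluded, slots filled).
#' @export
clean_vitals <- function(vitals, encounters = NULL,
                         windows = c(HR = 3, RR = 3, SBP = 3, TEMP = 17),
                         temp_threshold = 31, interval_min = 15) {
  vitals <- as.data.table(vitals)
  req <- c("encounter_id", "timestamp", "channel", "value")
  if (!all(req %in% names(vitals))) {
    stop("clean_vitals(): vitals must have columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(vitals) == 0L) {
    out <- vitals[, req, with = FALSE]
    setattr(out, "log", data.table(rows_in = 0L, temp_artifacts = 0L,
                                   rows_out = 0L))
    return(out)
  }
  bounds <- NULL
  if (!is.null(encounters)) {
    enc <- as.data.table(encounters)
    bounds <- enc[, .(encounter_id, admission, discharge)]
    setkey(bounds, encounter_id)
  }
  n_art <- 0L
  out <- vitals[order(encounter_id, channel, timestamp), {
    st <- en <- NULL
    if (!is.null(bounds)) {
      b <- bounds[.BY$encounter_id]
      st <- b$admission[1L]; en <- b$discharge[1L]
    }
    s <- regularize_vitals(timestamp, value, channel = .BY$channel,
                           interval_min = interval_min, start = st, end = en,
                           encounter_id = .BY$encounter_id)
    if (.BY$channel == "TEMP") {
      n_art <<- n_art + sum(!is.na(s$values) & s$values <= temp_threshold)
    }
    s <- clean_stream(s, windows, temp_threshold)
    list(timestamp = stream_times(s), value = s$values)
  }, by = .(encounter_id, channel)]
  setcolorder(out, req)
  setattr(out, "log",
          data.table(rows_in = nrow(vitals), temp_artifacts = n_art,
                     rows_out = nrow(out)))
  pipeline_log("clean_vitals: %d rows in, %d temperature artifacts excluded, %d grid rows out",
               nrow(vitals), n_art, nrow(out))
  out[]
}
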