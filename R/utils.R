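#' Round half away from zero
#'
#' Commercial rounding as used for reported rates and AUCs: exact halves are
#' rounded away from zero (base R's [round()] rounds halves to even). A small
#' absolute guard (1e-8) absorbs binary-representation error so that values
#' like `(0.98 + 0.65) / 2` round to `0.82`.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_away(0.815, 2) # 0.82
#' round_half_away(2.5, 0)   # 3
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Format a count as a percentage string
#'
#' @param num numerator count.
#' @param den denominator count (> 0).
#' @param digits decimal places (default 1, matching report style).
#' @return character vector like `"32.0%"`.
#' @examples
#' fmt_percent(4405, 13780) # "32.0%"
#' @export
fmt_percent <- function(num, den, digits = 1) {
  stopifnot(all(den > 0))
  sprintf(paste0("%.", digits, "f%%"), round_half_away(100 * num / den, digits))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# POSIXct helpers: the whole package works on a UTC 15-minute grid.
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

floor_to_interval <- function(t, interval_min) {
  secs <- as.numeric(interval_min) * 60
  as_utc(structure(floor(as.numeric(t) / secs) * secs,
                   class = c("POSIXct", "POSIXt"), tzone = "UTC"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage logging: terse messages, silenced unless option set.
pipeline_log <- function(...) {
  if (isTRUE(getOption("sepsiscreen.verbose", FALSE))) {
    message(sprintf(...))
  }
  invisible(NULL)
}
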