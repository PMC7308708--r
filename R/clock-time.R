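#' Clock-time helpers
#'
#' Clock times are carried through the package as minutes since midnight
#' (numeric, in `[0, 1440)`). `parse_hhmm()` and `format_hhmm()` convert to
#' and from `"hh:mm"` strings; `minute_of_day()` extracts the clock minute
#' from a POSIXct timestamp.
#'
#' @param x For `parse_hhmm()`, a character vector of `"hh:mm"` times; for
#'   `format_hhmm()` and `to_polar()`, minutes since midnight; for
#'   `minute_of_day()`, a POSIXct vector.
#' @return `parse_hhmm()` and `minute_of_day()` return numeric minutes since
#'   midnight; `format_hhmm()` returns `"hh:mm"` strings; `to_polar()`
#'   returns radians in `[0, 2*pi)`.
#' @examples
#' parse_hhmm("17:00")
#' format_hhmm(1020)
#' to_polar(360) # 06:00 -> pi/2
#' @name clock-time
NULL

#' @rdname clock-time
#' @export
parse_hhmm <- function(x) {
  m <- stringr::str_match(x, "^([0-2]?[0-9]):([0-5][0-9])$")
  bad <- !is.na(x) & is.na(m[, 1])
  if (any(bad)) {
    abort(paste0("invalid clock time(s): ", paste(x[bad], collapse = ", ")))
  }
  hh <- as.numeric(m[, 2])
  mm <- as.numeric(m[, 3])
  if (any(hh >= 24, na.rm = TRUE)) abort("hour component must be < 24")
  hh * 60 + mm
}

#' @rdname clock-time
#' @export
format_hhmm <- function(x) {
  x <- ((x %% 1440) + 1440) %% 1440
  sprintf("%02d:%02d", floor(x / 60), floor(x %% 60))
}

#' @rdname clock-time
#' @export
minute_of_day <- function(x) {
  lt <- as.POSIXlt(x, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' Map a clock time onto the 24 h circle
#'
#' Angle is `2*pi * minutes / 1440`, so midnight is 0 and the mapping
#' round-trips to the minute.
#'
#' @param minutes Minutes since midnight.
#' @return Radians in `[0, 2*pi)`.
#' @export
to_polar <- function(minutes) {
  (2 * pi * (((minutes %% 1440) + 1440) %% 1440) / 1440) %% (2 * pi)
}

#' @rdname to_polar
#' @param angle Radians.
#' @export
from_polar <- function(angle) {
  (((angle %% (2 * pi)) + 2 * pi) %% (2 * pi)) * 1440 / (2 * pi)
}

#' Significance ladder annotation
#'
#' Maps p-values to the conventional report annotations:
#' `***` < 0.001, `**` < 0.01, `*` < 0.05, `°` < 0.1, `-` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of annotations.
#' @export
sig_ladder <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.1 ~ "°",
    TRUE ~ "-"
  )
}
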