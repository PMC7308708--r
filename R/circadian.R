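#' Changepoint segmentation of a metabolic time series
#'
#' Optimal partition of a numeric series into mean-homogeneous segments
#' under a Gaussian change-in-mean cost with a linear penalty per
#' changepoint, solved exactly with the PELT pruned dynamic program. On
#' short series the result equals exhaustive search over all admissible
#' partitions.
#'
#' The cost of a segment is its residual sum of squares, optionally divided
#' by a variance estimate \eqn{\hat\sigma^2 = \mathrm{var}(\Delta x)/2}
#' (first-difference estimator, robust to mean shifts) so that the default
#' penalty `3 * log(n)` is on a comparable scale across series.
#'
#' @param x Numeric series (finite values).
#' @param penalty Positive penalty per changepoint; default `3 * log(n)`.
#' @param min_seg_len Minimum segment length (default 3 samples).
#' @param normalize Divide the cost by the estimated noise variance
#'   (default `TRUE`). Set `FALSE` to penalise raw RSS directly.
#' @return An object of class `segmented_series`: a list with `segments`
#'   (tibble of `start`, `end` half-open 1-based indices, `mean`, `n`),
#'   `penalty`, `min_seg_len`, `sigma2` and `n`.
#' @examples
#' seg <- segment_series(c(rep(0, 50), rep(10, 50)), penalty = 3 * log(100))
#' seg$segments
#' @export
segment_series <- function(x, penalty = NULL, min_seg_len = 3,
                           normalize = TRUE) {
  if (!all(is.finite(x))) abort("`x` must be finite")
  n <- length(x)
  min_seg_len <- as.integer(min_seg_len)
  if (min_seg_len < 1) abort("`min_seg_len` must be >= 1")
  penalty <- penalty %||% (3 * log(n))
  if (penalty <= 0) abort("`penalty` must be > 0")
  if (n < 2 * min_seg_len || var(x) == 0) {
    # too short to split, or exactly constant: one segment
    return(new_segmented_series(
      tibble::tibble(start = 1L, end = n + 1L, mean = mean(x), n = n),
      penalty, min_seg_len, sigma2 = if (n > 1) var(x) else 0, n = n
    ))
  }
  sigma2 <- 1
  if (normalize) {
    # robust first-difference estimator: immune to the few large diffs at
    # genuine level shifts, which would otherwise mask small plateaus
    sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
    if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1e-10 * var(x)
  }
  cps <- pelt_mean(x / sqrt(sigma2), penalty, min_seg_len)
  bounds <- c(0L, cps, n)
  segs <- tibble::tibble(
    start = head(bounds, -1) + 1L,
    end = tail(bounds, -1) + 1L
  ) |>
    dplyr::mutate(
      mean = purrr::map2_dbl(.data$start, .data$end - 1L, ~ mean(x[.x:.y])),
      n = .data$end - .data$start
    )
  new_segmented_series(segs, penalty, min_seg_len, sigma2, n)
}

new_segmented_series <- function(segments, penalty, min_seg_len, sigma2, n) {
  structure(
    list(
      segments = segments, penalty = penalty,
      min_seg_len = min_seg_len, sigma2 = sigma2, n = n
    ),
    class = "segmented_series"
  )
}

#' @export
print.segmented_series <- function(x, ...) {
  cat(
    "<segmented_series> ", nrow(x$segments), " segment(s) over ", x$n,
    " samples (penalty ", signif(x$penalty, 4), ")\n",
    sep = ""
  )
  print(x$segments)
  invisible(x)
}

# PELT dynamic program for change in mean, unit-variance Gaussian cost.
# Returns changepoint positions tau (last index of each left segment).
#
# With a minimum segment length, pruning must be delayed: a candidate
# dominated at time s is provably never optimal only for positions
# u >= s + min_seg_len (for closer u the dominating path would need an
# over-short segment), so it stays live for min_seg_len - 1 more steps.
pelt_mean <- function(x, penalty, min_seg_len) {
  n <- length(x)
  s1 <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  segcost <- function(a, b) {
    # cost of x[(a+1)..b]: RSS about the segment mean
    len <- b - a
    s2[b + 1] - s2[a + 1] - (s1[b + 1] - s1[a + 1])^2 / len
  }
  f <- rep(Inf, n + 1)
  f[1] <- -penalty
  last <- integer(n + 1)
  cand <- 0L
  dead_from <- Inf # per-candidate position from which it may be dropped
  for (t in seq_len(n)) {
    alive <- t < dead_from
    cand <- cand[alive]
    dead_from <- dead_from[alive]
    ok <- cand[t - cand >= min_seg_len]
    if (length(ok) > 0) {
      costs <- vapply(ok, function(a) f[a + 1] + segcost(a, t), numeric(1)) +
        penalty
      best <- which.min(costs)
      f[t + 1] <- costs[best]
      last[t + 1] <- ok[best]
      fail <- ok[(costs - penalty) > f[t + 1]] # f[a+1] + C(a+1,t) > f[t+1]
      idx <- match(fail, cand)
      newly <- idx[is.infinite(dead_from[idx])]
      dead_from[newly] <- t + min_seg_len
    }
    cand <- c(cand, t)
    dead_from <- c(dead_from, Inf)
  }
  cps <- integer(0)
  t <- n
  while (t > 0 && last[t + 1] > 0) {
    t <- last[t + 1]
    cps <- c(t, cps)
  }
  cps
}

#' Extrema of a segmented series within photoperiod windows
#'
#' The daily maximum (`Max`) is the highest segment mean among segments
#' overlapping the night window, and the minimum (`Min`) the lowest among
#' segments overlapping the day window, mirroring a night-active species
#' whose metabolic peak falls in the dark phase. `h_max`/`h_min` are the
#' clock times (minutes since midnight) of the first in-window sample of
#' the winning segment; equal-mean ties go to the earliest segment.
#'
#' @param seg A [segment_series()] result for one series.
#' @param minutes Clock minutes (since midnight) of each sample of the
#'   segmented series, same length as the series.
#' @param schedule A [photoperiod()].
#' @return A one-row tibble: `max_value`, `h_max`, `min_value`, `h_min`
#'   (`NA` markers where no segment overlaps a window).
#' @export
extract_extrema <- function(seg, minutes, schedule = photoperiod()) {
  stopifnot(inherits(seg, "segmented_series"))
  if (length(minutes) != seg$n) {
    abort("`minutes` must align with the segmented series")
  }
  phase <- assign_phase(minutes, schedule)
  pick <- function(target_phase, which_fun) {
    hits <- seg$segments |>
      dplyr::mutate(
        first_in = purrr::map2_dbl(.data$start, .data$end - 1L, function(a, b) {
          idx <- a:b
          inw <- idx[phase[idx] == target_phase]
          if (length(inw) == 0) NA_real_ else minutes[inw[1]]
        })
      ) |>
      dplyr::filter(!is.na(.data$first_in))
    if (nrow(hits) == 0) {
      return(tibble::tibble(value = NA_real_, at = NA_real_))
    }
    best <- if (identical(which_fun, "max")) max(hits$mean) else min(hits$mean)
    row <- hits |>
      dplyr::filter(.data$mean == best) |>
      dplyr::arrange(.data$start) |>
      dplyr::slice(1)
    tibble::tibble(value = row$mean, at = row$first_in)
  }
  mx <- pick("night", "max")
  mn <- pick("day", "min")
  tibble::tibble(
    max_value = mx$value, h_max = mx$at,
    min_value = mn$value, h_min = mn$at
  )
}

#' Per-cycle circadian extrema of a metabolic series
#'
#' Splits a multi-day series into 24 h cycles starting at lights-off,
#' segments each cycle with [segment_series()], extracts the windowed
#' extrema with [extract_extrema()], then averages values arithmetically
#' and clock times circularly across cycles, giving one `Max`/`hMax`/
#' `Min`/`hMin` summary per animal (and condition) per variable.
#'
#' @param series A metabolic-series tibble (see
#'   [derive_metabolic_series()]) with `animal_id`, `time` and the target
#'   variable; `sex`/`condition` columns are carried through.
#' @param var Name of the variable to analyse (e.g. `"vo2"`).
#' @param schedule A [photoperiod()].
#' @param penalty,min_seg_len Passed to [segment_series()]; the default
#'   penalty is `3 * log(n_cycle)` per cycle.
#' @return A tibble, one row per animal (x condition): `variable`,
#'   `max_value`, `h_max`, `min_value`, `h_min`, `n_cycles`.
#' @export
circadian_extrema <- function(series, var, schedule = photoperiod(),
                              penalty = NULL, min_seg_len = 3) {
  if (!var %in% names(series)) abort(paste0("no column `", var, "`"))
  keys <- intersect(c("animal_id", "sex", "condition"), names(series))
  series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$time)
      mins <- minute_of_day(df$time)
      # cycle index: 24 h blocks anchored at lights-off
      elapsed_h <- as.numeric(difftime(df$time, df$time[1], units = "hours"))
      offset_h <- ((mins[1] - schedule$lights_off) %% 1440) / 60
      cycle <- floor((elapsed_h + offset_h) / 24)
      per_cycle <- tibble::tibble(
        x = df[[var]], minutes = mins, cycle = cycle
      ) |>
        dplyr::filter(is.finite(.data$x)) |>
        dplyr::group_by(.data$cycle) |>
        dplyr::group_modify(function(cy, k) {
          seg <- segment_series(cy$x,
            penalty = penalty,
            min_seg_len = min_seg_len
          )
          extract_extrema(seg, cy$minutes, schedule)
        }) |>
        dplyr::ungroup()
      cm_max <- circular_mean(per_cycle$h_max[!is.na(per_cycle$h_max)])
      cm_min <- circular_mean(per_cycle$h_min[!is.na(per_cycle$h_min)])
      tibble::tibble(
        variable = var,
        max_value = mean(per_cycle$max_value, na.rm = TRUE),
        h_max = round(cm_max$mean_min) %% 1440, # clock times: minute resolution
        min_value = mean(per_cycle$min_value, na.rm = TRUE),
        h_min = round(cm_min$mean_min) %% 1440,
        n_cycles = nrow(per_cycle)
      )
    }) |>
    dplyr::ungroup()
}

#' Circular mean and SD of clock times
#'
#' Clock times are mapped to angles on the 24 h circle ([to_polar()]); the
#' mean is the direction of the resultant of unit vectors and the circular
#' SD is \eqn{\sqrt{-2 \ln \bar R}} converted back to minutes. When the
#' resultant length is ~0 (times spread uniformly) the mean is undefined
#' and reported as `NA`.
#'
#' @param minutes Clock times in minutes since midnight.
#' @return A one-row tibble: `mean_min`, `sd_min`, `r` (resultant length),
#'   `n`.
#' @examples
#' circular_mean(c(23 * 60, 1 * 60)) # wraps to midnight
#' @export
circular_mean <- function(minutes) {
  minutes <- minutes[!is.na(minutes)]
  n <- length(minutes)
  if (n == 0) {
    return(tibble::tibble(
      mean_min = NA_real_, sd_min = NA_real_, r = NA_real_, n = 0L
    ))
  }
  a <- to_polar(minutes)
  c_bar <- mean(cos(a))
  s_bar <- mean(sin(a))
  r <- sqrt(c_bar^2 + s_bar^2)
  if (r < 1e-8) {
    return(tibble::tibble(
      mean_min = NA_real_, sd_min = NA_real_, r = r, n = n
    ))
  }
  mean_min <- from_polar(atan2(s_bar, c_bar))
  sd_min <- sqrt(-2 * log(min(r, 1))) * 1440 / (2 * pi)
  tibble::tibble(mean_min = mean_min, sd_min = sd_min, r = r, n = n)
}

#' Signed circadian time shift
#'
#' Shortest signed arc from a pre-treatment to a post-treatment clock
#' time, in minutes within `(-720, 720]`. Negative values are phase
#' advances (the event happens earlier after treatment).
#'
#' @param pre_min,post_min Clock times, minutes since midnight.
#' @return Signed minutes.
#' @examples
#' time_shift(parse_hhmm("07:00"), parse_hhmm("03:53")) # -187
#' @export
time_shift <- function(pre_min, post_min) {
  d <- (post_min - pre_min) %% 1440
  ifelse(d > 720, d - 1440, d)
}

#' Polar-plot coordinates for event clock times
#'
#' Lays out per-individual event times for a 24 h circular diagram: each
#' group (e.g. sex x condition) sits on its own concentric circle and each
#' time becomes an angle on the clock face.
#'
#' @param times Tibble with a clock-time column (minutes) and a grouping
#'   column.
#' @param time_col,group_col Column names (strings).
#' @return The input with `angle_rad` and `radius_rank` (1-based ring
#'   index per group) added.
#' @export
polar_coordinates <- function(times, time_col = "h_min",
                              group_col = "group") {
  groups <- sort(unique(times[[group_col]]))
  times |>
    dplyr::mutate(
      angle_rad = to_polar(.data[[time_col]]),
      radius_rank = match(.data[[group_col]], groups)
    )
}
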