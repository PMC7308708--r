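#' Photoperiod schedule
#'
#' Describes the light/dark schedule used to label samples as `day` or
#' `night`. The default is a long-day (summer-like) 14 h photoperiod with
#' lights off at 17:00 and lights on at 03:00, so the dark (active) phase
#' runs 17:00--03:00.
#'
#' @param lights_off,lights_on Clock times (`"hh:mm"`) at which lights go
#'   off and on.
#' @return A list of class `photoperiod` with `lights_off`, `lights_on`
#'   (minutes since midnight) and `day_length_h`.
#' @examples
#' photoperiod()
#' photoperiod("18:00", "06:00") # 12 h light
#' @export
photoperiod <- function(lights_off = "17:00", lights_on = "03:00") {
  off <- parse_hhmm(lights_off)
  on <- parse_hhmm(lights_on)
  if (off == on) abort("lights_off and lights_on must differ")
  day_len <- ((off - on) %% 1440) / 60 # light runs lights_on -> lights_off
  structure(
    list(lights_off = off, lights_on = on, day_length_h = day_len),
    class = "photoperiod"
  )
}

#' @export
print.photoperiod <- function(x, ...) {
  cat(
    "<photoperiod> lights off ", format_hhmm(x$lights_off),
    ", lights on ", format_hhmm(x$lights_on),
    " (", x$day_length_h, " h light)\n",
    sep = ""
  )
  invisible(x)
}

#' Label clock minutes as day or night
#'
#' @param minutes Minutes since midnight.
#' @param schedule A [photoperiod()].
#' @return Character vector, `"day"` (lights on) or `"night"` (lights off).
#' @export
assign_phase <- function(minutes, schedule = photoperiod()) {
  m <- ((minutes %% 1440) + 1440) %% 1440
  since_on <- (m - schedule$lights_on) %% 1440
  ifelse(since_on < schedule$day_length_h * 60, "day", "night")
}

## ---- gas-exchange equations -------------------------------------------

#' Open-flow respirometry gas-exchange rates
#'
#' Mass-specific rates of oxygen consumption and carbon-dioxide production
#' from incurrent/excurrent fractional gas concentrations in a pull-mode,
#' water-vapour-scrubbed flow-through system:
#'
#' \deqn{VO_2 = \frac{FR_i\,[(F_iO_2 - F_e'O_2) - F_e'O_2 (F_e'CO_2 - F_iCO_2)]}{(1 - F_e'O_2)\,m}}
#' \deqn{VCO_2 = \frac{FR_i\,[(F_e'CO_2 - F_iCO_2) - F_e'CO_2 (F_iO_2 - F_e'O_2)]}{(1 - F_e'CO_2)\,m}}
#'
#' where \eqn{FR_i} is the incurrent flow rate (mL/h, STP-corrected
#' upstream) and \eqn{m} the body mass in kg, so both rates come out in
#' mL kg^-1 h^-1. The VCO2 expression uses the excurrent-minus-incurrent
#' orientation so that net CO2 production by the animal is positive.
#'
#' @param fr_i Incurrent flow rate, mL/h.
#' @param fi_o2,fe_o2 Incurrent and (scrubbed) excurrent fractional O2.
#' @param fi_co2,fe_co2 Incurrent and excurrent fractional CO2.
#' @param mass_kg Body mass, kg.
#' @return Numeric vector, mL kg^-1 h^-1.
#' @examples
#' vo2_rate(30000, 0.2095, 0.2000, 0.0004, 0.0100, 0.1) # 2842.5
#' @export
vo2_rate <- function(fr_i, fi_o2, fe_o2, fi_co2, fe_co2, mass_kg) {
  fr_i * ((fi_o2 - fe_o2) - fe_o2 * (fe_co2 - fi_co2)) /
    ((1 - fe_o2) * mass_kg)
}

#' @rdname vo2_rate
#' @export
vco2_rate <- function(fr_i, fi_o2, fe_o2, fi_co2, fe_co2, mass_kg) {
  fr_i * ((fe_co2 - fi_co2) - fe_co2 * (fi_o2 - fe_o2)) /
    ((1 - fe_co2) * mass_kg)
}

validate_gas_trace <- function(trace) {
  needed <- c(
    "animal_id", "time", "fi_o2", "fe_o2", "fi_co2", "fe_co2",
    "fr_i", "body_mass_kg"
  )
  missing_cols <- setdiff(needed, names(trace))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "gas trace is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  num <- c("fi_o2", "fe_o2", "fi_co2", "fe_co2", "fr_i", "body_mass_kg")
  for (col in num) {
    if (!all(is.finite(trace[[col]]))) {
      abort(paste0("non-finite values in `", col, "`"))
    }
  }
  frac <- c("fi_o2", "fe_o2", "fi_co2", "fe_co2")
  for (col in frac) {
    bad <- trace[[col]] <= 0 | trace[[col]] >= 1
    if (any(bad)) {
      abort(paste0(
        "`", col, "` outside (0, 1) at ",
        format(trace$time[which(bad)[1]], tz = "UTC", usetz = FALSE)
      ))
    }
  }
  if (any(trace$fr_i < 0)) abort("`fr_i` must be >= 0")
  if (any(trace$body_mass_kg <= 0)) abort("`body_mass_kg` must be > 0")
  ord <- trace |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      ok = all(diff(as.numeric(.data$time)) > 0),
      .groups = "drop"
    )
  if (!all(ord$ok)) {
    abort(paste0(
      "timestamps not strictly increasing for animal ",
      ord$animal_id[!ord$ok][1]
    ))
  }
  invisible(trace)
}

#' Derive VO2 from a gas trace
#'
#' Applies the open-flow [vo2_rate()] equation per timestamp and appends a
#' `vo2` column (mL kg^-1 h^-1).
#'
#' @param trace A gas-trace tibble with columns `animal_id`, `time`
#'   (POSIXct), `fi_o2`, `fe_o2`, `fi_co2`, `fe_co2`, `fr_i` (mL/h) and
#'   `body_mass_kg`.
#' @return The input tibble with a `vo2` column added.
#' @export
compute_vo2 <- function(trace) {
  validate_gas_trace(trace)
  dplyr::mutate(
    trace,
    vo2 = vo2_rate(
      .data$fr_i, .data$fi_o2, .data$fe_o2,
      .data$fi_co2, .data$fe_co2, .data$body_mass_kg
    )
  )
}

#' Derive VCO2 from a gas trace
#'
#' Applies [vco2_rate()] per timestamp and appends a `vco2` column
#' (mL kg^-1 h^-1), positive when the animal produces CO2.
#'
#' @inheritParams compute_vo2
#' @return The input tibble with a `vco2` column added.
#' @export
compute_vco2 <- function(trace) {
  validate_gas_trace(trace)
  dplyr::mutate(
    trace,
    vco2 = vco2_rate(
      .data$fr_i, .data$fi_o2, .data$fe_o2,
      .data$fi_co2, .data$fe_co2, .data$body_mass_kg
    )
  )
}

#' Respiratory exchange ratio
#'
#' Element-wise `vco2 / vo2`. Timestamps where `vo2 <= 0` get an explicit
#' undefined marker (`rer = NA`, `rer_defined = FALSE`) rather than a
#' silent NaN. Values outside the physiological range `[0.7, 1]`
#' (pure-lipid to pure-carbohydrate oxidation) are flagged, never clipped.
#'
#' @param vco2,vo2 Aligned numeric series (same units).
#' @return A tibble with columns `rer`, `rer_defined`, `rer_flagged`.
#' @examples
#' compute_rer(700, 1000) # rer 0.7, in range
#' @export
compute_rer <- function(vco2, vo2) {
  if (length(vco2) != length(vo2)) abort("`vco2` and `vo2` must be aligned")
  defined <- is.finite(vo2) & vo2 > 0 & is.finite(vco2)
  rer <- ifelse(defined, vco2 / vo2, NA_real_)
  tibble::tibble(
    rer = rer,
    rer_defined = defined,
    rer_flagged = defined & (rer < 0.7 | rer > 1.0)
  )
}

#' Energy expenditure from VO2 and RER
#'
#' Oxycaloric conversion `EE = (3.815 + 1.232 * RER) * VO2[L/kg/h] * BM[kg]`,
#' yielding kcal/h. `vo2` is supplied in mL kg^-1 h^-1 (the unit the rest of
#' the pipeline uses) and converted to L kg^-1 h^-1 internally; only that
#' unit pairing gives the ~1 kcal/h magnitudes expected for a 100 g animal.
#' Timestamps with `vo2 = 0` get `EE = 0`. For animals of 50--150 g, EE
#' values outside (0.01, 100) kcal/h trigger a unit-sanity warning.
#'
#' @param rer RER series (dimensionless); may be `NA` where `vo2` is 0.
#' @param vo2 VO2 series, mL kg^-1 h^-1.
#' @param body_mass_kg Body mass in kg (scalar or per-timestamp).
#' @return Numeric series, kcal/h.
#' @examples
#' compute_ee(1.0, 1000, 1) # 5.047
#' @export
compute_ee <- function(rer, vo2, body_mass_kg) {
  ee <- (3.815 + 1.232 * rer) * (vo2 / 1000) * body_mass_kg
  ee[is.finite(vo2) & vo2 == 0] <- 0
  small <- body_mass_kg >= 0.05 & body_mass_kg <= 0.15
  suspect <- small & is.finite(ee) & is.finite(vo2) & vo2 > 0 &
    (ee <= 0.01 | ee >= 100)
  if (any(suspect)) {
    warn(paste0(
      sum(suspect), " EE value(s) outside (0.01, 100) kcal/h for a ",
      "50-150 g animal; check VO2 and body-mass units"
    ))
  }
  ee
}

#' Full metabolic series from a gas trace
#'
#' Chains [compute_vo2()], [compute_vco2()], [compute_rer()] and
#' [compute_ee()] and labels each timestamp with its photoperiod phase.
#'
#' @inheritParams compute_vo2
#' @param schedule A [photoperiod()].
#' @return The trace tibble with `vo2`, `vco2`, `rer`, `rer_defined`,
#'   `rer_flagged`, `ee_kcal_h` and `phase` columns.
#' @export
derive_metabolic_series <- function(trace, schedule = photoperiod()) {
  out <- compute_vco2(compute_vo2(trace))
  rer <- compute_rer(out$vco2, out$vo2)
  out |>
    dplyr::bind_cols(rer) |>
    dplyr::mutate(
      ee_kcal_h = compute_ee(.data$rer, .data$vo2, .data$body_mass_kg),
      phase = assign_phase(minute_of_day(.data$time), schedule)
    )
}

#' Day/night phase means of a metabolic series
#'
#' Unweighted arithmetic means of each derived variable within each
#' photoperiod phase, per animal (and per `condition` when present).
#' Phases with no observations appear as explicit `NA` rows with `n = 0`
#' rather than being dropped.
#'
#' @param series Output of [derive_metabolic_series()] (or any tibble with
#'   `animal_id`, `phase` and numeric metric columns).
#' @param vars Metric columns to average.
#' @return A tibble with one row per animal (x condition) x phase, the
#'   per-phase means and the sample count `n`.
#' @export
aggregate_by_phase <- function(series,
                               vars = c("vo2", "vco2", "rer", "ee_kcal_h")) {
  vars <- intersect(vars, names(series))
  if (length(vars) == 0) abort("no metric columns found to aggregate")
  keys <- intersect(c("animal_id", "sex", "condition"), names(series))
  out <- series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "phase")))) |>
    dplyr::summarise(
      dplyr::across(
        dplyr::all_of(vars), ~ mean(.x, na.rm = TRUE)
      ),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(keys)),
      phase = c("day", "night"),
      fill = list(n = 0L)
    )
  out[vars] <- lapply(out[vars], function(x) ifelse(is.nan(x), NA_real_, x))
  out
}

#' Read a gas-trace CSV
#'
#' Expects one row per timestamp with columns `animal_id`, `datetime`
#' (ISO 8601), `fi_o2`, `fe_o2`, `fi_co2`, `fe_co2`, `fr_i_ml_per_h` and
#' `body_mass_g` (plus optional `sex`, `condition`). An `fr_e` column, if
#' present, is ignored with a notice: in a pull-mode system with a scrubbed
#' excurrent stream only the incurrent flow enters the equations.
#'
#' @param path CSV file path.
#' @return A gas-trace tibble (mass converted to kg) ready for
#'   [derive_metabolic_series()].
#' @export
read_gas_traces <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (any(grepl("^fr_e", names(raw)))) {
    inform("ignoring excurrent flow column(s); only `fr_i` enters the equations")
    raw <- raw[!grepl("^fr_e", names(raw))]
  }
  trace <- raw |>
    dplyr::rename(fr_i = "fr_i_ml_per_h") |>
    dplyr::mutate(
      time = as.POSIXct(.data$datetime, tz = "UTC"),
      body_mass_kg = .data$body_mass_g / 1000,
      .keep = "unused"
    )
  validate_gas_trace(trace)
  trace
}
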