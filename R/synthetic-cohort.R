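#' Group-level targets for the synthetic cohort
#'
#' Per-variable, per-sex, per-condition target means and SDs used by the
#' generator. They encode the group summaries of a paired
#' six-female/six-male, two-week 60% caloric-restriction experiment in a
#' ~100 g nocturnal primate: urinary and blood biomarkers, mito-stress
#' metrics, mtDNA/nuDNA ratios, body mass, and the day/night structure of
#' VO2 and RER (phase means, windowed extrema and their clock times).
#'
#' @return `biomarker_targets()`: tibble with `variable`, `sex`, `dist`
#'   and CTL/CR mean and SD columns. `calorimetry_targets()`: tibble with
#'   one row per sex x condition carrying VO2/RER profile parameters
#'   (means, extrema, clock times in minutes and their SDs).
#' @name synthetic-targets
#' @export
biomarker_targets <- function() {
  tribble_row <- function(variable, dist, f_ctl, f_ctl_sd, m_ctl, m_ctl_sd,
                          f_cr, f_cr_sd, m_cr, m_cr_sd) {
    tibble::tibble(
      variable = variable, dist = dist,
      sex = rep(c("F", "M"), 2),
      condition = rep(c("CTL", "CR"), each = 2),
      mean = c(f_ctl, m_ctl, f_cr, m_cr),
      sd = c(f_ctl_sd, m_ctl_sd, f_cr_sd, m_cr_sd)
    )
  }
  dplyr::bind_rows(
    tribble_row("cortisol", "lognormal", 603.4, 317.8, 403.2, 111.5, 992.3, 604.3, 596.4, 245.3),
    tribble_row("ohdg_8", "normal", 387.4, 93.0, 591.0, 262.4, 214.1, 36.3, 324.6, 110.8),
    tribble_row("thiols", "normal", 1.8, 0.5, 2.2, 0.3, 1.8, 0.6, 1.4, 0.2),
    tribble_row("gpx", "normal", 0.28, 0.10, 0.25, 0.17, 0.34, 0.06, 0.14, 0.04),
    tribble_row("t4", "normal", 30.6, 8.5, 32.4, 3.2, 25.8, 8.8, 21.3, 10.0),
    tribble_row("estradiol", "lognormal", 33558.8, 15819.7, 23364.4, 8297.4, 60086.8, 13681.9, 40180.7, 14563.2),
    tribble_row("testosterone", "lognormal", 2.8, 1.9, 64.1, 31.1, 12.9, 16.7, 94.4, 78.0),
    tribble_row("glycaemia", "normal", 95, 32, 65, 9, 84, 18, 72, 11),
    tribble_row("body_mass", "normal", 99.7, 3.8, 90.0, 6.6, 83.0, 5.1, 77.2, 5.4),
    tribble_row("oxcr", "normal", 60.96, 6.6, 72.59, 8.3, 69.49, 2.3, 67.54, 2.1),
    tribble_row("mtrc", "normal", 202.4, 45.9, 152.0, 21.8, 148.9, 33.0, 134.8, 41.8),
    tribble_row("glcp", "normal", 325.28, 27.37, 363.92, 203.20, 407.43, 128.65, 439.77, 35.41),
    tribble_row("mtnu_ratio", "lognormal", 1.78, 0.43, 3.01, 0.44, 2.56, 1.16, 3.30, 1.43)
  )
}

#' @rdname synthetic-targets
#' @export
calorimetry_targets <- function() {
  hm <- parse_hhmm
  tibble::tibble(
    sex = rep(c("F", "M"), 2),
    condition = rep(c("CTL", "CR"), each = 2),
    vo2_night = c(2147, 2192, 2260, 1882),
    vo2_night_sd = c(403, 510, 432, 473),
    vo2_day = c(1226, 1296, 1328, 1001),
    vo2_day_sd = c(406, 425, 598, 382),
    vo2_max = c(2343, 2287, 2301, 2228),
    vo2_max_sd = c(124, 266, 194, 344),
    vo2_min = c(1075, 1183, 1162, 758),
    vo2_min_sd = c(135, 162, 198, 233),
    h_max_vo2 = c(hm("19:36"), hm("19:01"), hm("18:55"), hm("17:39")),
    h_max_vo2_sd = c(184, 187, 236, 133),
    h_min_vo2 = c(hm("07:59"), hm("06:58"), hm("05:50"), hm("04:05")),
    h_min_vo2_sd = c(129, 272, 214, 68),
    rer_night = c(0.99, 0.96, 0.85, 0.90),
    rer_night_sd = c(0.077, 0.099, 0.076, 0.085),
    rer_day = c(0.77, 0.78, 0.76, 0.75),
    rer_day_sd = c(0.07, 0.07, 0.06, 0.07),
    rer_max = c(1.01, 0.97, 0.91, 0.95),
    rer_max_sd = c(0.04, 0.07, 0.04, 0.02),
    rer_min = c(0.74, 0.73, 0.75, 0.71),
    rer_min_sd = c(0.05, 0.02, 0.02, 0.06),
    h_max_rer = c(hm("18:23"), hm("17:44"), hm("17:30"), hm("17:17")),
    h_max_rer_sd = c(99, 94, 41, 41),
    h_min_rer = c(hm("07:00"), hm("10:43"), hm("03:53"), hm("04:58")),
    h_min_rer_sd = c(225, 192, 275, 238)
  )
}

#' Design of a synthetic paired caloric-restriction cohort
#'
#' Collects everything the generator needs: cohort size, photoperiod,
#' sampling cadence, gas/flow constants, noise levels and the group
#' target tables. The defaults reproduce the study conditions: 6 females
#' and 6 males, each its own control (paired CTL then CR), 4 recording
#' days per condition at a 10-minute cadence under a 14 h photoperiod.
#'
#' @param n_per_sex Animals per sex (default 6).
#' @param seed Integer seed; fully determines every generated output.
#' @param sampling_interval_min Calorimetry cadence, minutes (default 10).
#' @param n_days Recording days per condition (default 4).
#' @param schedule A [photoperiod()].
#' @param noise_scale Multiplier on every measurement-noise SD (0 gives a
#'   noise-free cohort; 1 the defaults).
#' @param ramp_samples Odd width (in samples) of the circular
#'   moving-average ramp smoothing the square-wave circadian profiles;
#'   1 leaves sharp steps.
#' @param vo2_cv,rer_cv Per-sample multiplicative measurement noise CVs.
#' @param flux_cv Per-cycle flux-plate jitter CV.
#' @param ct_sd qPCR replicate Ct jitter SD (cycles).
#' @param glyc_cv CV of repeated glycaemia readings.
#' @param well_dropout Probability a plate well is lost to culture
#'   contamination.
#' @param plateau_min Length of the programmed peak/trough plateaus,
#'   minutes.
#' @param fr_i Incurrent flow rate, mL/h.
#' @param fi_o2,fi_co2 Incurrent fractional gas concentrations.
#' @param rho_pair Latent correlation between an animal's CTL and CR
#'   values (paired design).
#' @param rho_track Latent correlation among an animal's calorimetry
#'   profile parameters within a condition.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_sex = 6, seed = 1,
                          sampling_interval_min = 10, n_days = 4,
                          schedule = photoperiod(),
                          noise_scale = 1, ramp_samples = 3,
                          vo2_cv = 0.05, rer_cv = 0.02,
                          flux_cv = 0.02, ct_sd = 0.1, glyc_cv = 0.03,
                          well_dropout = 0,
                          plateau_min = 120, fr_i = 30000,
                          fi_o2 = 0.2095, fi_co2 = 0.0004,
                          rho_pair = 0.7, rho_track = 0.8) {
  if (1440 %% sampling_interval_min != 0) {
    abort("`sampling_interval_min` must divide 1440")
  }
  structure(
    list(
      n_per_sex = n_per_sex, seed = as.integer(seed),
      sampling_interval_min = sampling_interval_min, n_days = n_days,
      schedule = schedule,
      vo2_cv = vo2_cv * noise_scale, rer_cv = rer_cv * noise_scale,
      flux_cv = flux_cv * noise_scale, ct_sd = ct_sd * noise_scale,
      glyc_cv = glyc_cv * noise_scale,
      well_dropout = well_dropout,
      ramp_samples = ramp_samples, plateau_min = plateau_min,
      fr_i = fr_i, fi_o2 = fi_o2, fi_co2 = fi_co2,
      rho_pair = rho_pair, rho_track = rho_track,
      biomarker_targets = biomarker_targets(),
      calorimetry_targets = calorimetry_targets()
    ),
    class = "cohort_design"
  )
}

# paired draws for one variable: CTL and CR values correlated rho across
# conditions; lognormal draws are moment-matched to the target mean/SD
draw_paired <- function(n, m_ctl, s_ctl, m_cr, s_cr, rho, dist = "normal") {
  z <- rnorm(n)
  u1 <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  u2 <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  one <- function(m, s, u) {
    if (dist == "lognormal") {
      sig2 <- log(1 + (s / m)^2)
      exp(log(m) - sig2 / 2 + sqrt(sig2) * u)
    } else {
      v <- m + s * u
      # strictly positive analytes: reflect the rare nonpositive draw
      ifelse(v <= 0, abs(v) + 0.05 * m, v)
    }
  }
  list(ctl = one(m_ctl, s_ctl, u1), cr = one(m_cr, s_cr, u2))
}

snap <- function(minutes, interval) round(minutes / interval) * interval

# per-animal programmed parameters for every generated quantity
draw_animal_params <- function(design) {
  set.seed(design$seed)
  n <- design$n_per_sex
  animals <- tibble::tibble(
    animal_id = c(sprintf("F%02d", seq_len(n)), sprintf("M%02d", seq_len(n))),
    sex = rep(c("F", "M"), each = n)
  )
  # scalar variables (biomarkers, flux metrics, ratio, body mass)
  scalars <- design$biomarker_targets |>
    dplyr::distinct(.data$variable, .data$dist) |>
    purrr::pmap(function(variable, dist) {
      purrr::map(c("F", "M"), function(sx) {
        tg <- design$biomarker_targets |>
          dplyr::filter(.data$variable == .env$variable, .data$sex == sx)
        ctl <- tg[tg$condition == "CTL", ]
        cr <- tg[tg$condition == "CR", ]
        d <- draw_paired(
          n, ctl$mean, ctl$sd, cr$mean, cr$sd, design$rho_pair, dist
        )
        tibble::tibble(
          animal_id = animals$animal_id[animals$sex == sx],
          sex = sx,
          variable = variable,
          CTL = d$ctl, CR = d$cr
        )
      }) |> purrr::list_rbind()
    }) |>
    purrr::list_rbind() |>
    tidyr::pivot_longer(c("CTL", "CR"),
      names_to = "condition", values_to = "value"
    )
  # calorimetry profile parameters, correlated within animal-condition
  calo <- purrr::pmap(
    animals,
    function(animal_id, sex) {
      z_animal <- rnorm(1)
      purrr::map(c("CTL", "CR"), function(cond) {
        tg <- design$calorimetry_targets |>
          dplyr::filter(.data$sex == .env$sex, .data$condition == cond)
        z <- design$rho_pair * z_animal +
          sqrt(1 - design$rho_pair^2) * rnorm(1)
        dr <- function(mu, sdv) {
          mu + sdv * (design$rho_track * z +
            sqrt(1 - design$rho_track^2) * rnorm(1))
        }
        # floors keep deep negative tails physiological (rates stay > 0)
        vo2_n <- max(dr(tg$vo2_night, tg$vo2_night_sd), 0.3 * tg$vo2_night)
        vo2_d <- max(dr(tg$vo2_day, tg$vo2_day_sd), 0.25 * tg$vo2_day)
        vo2_d <- min(vo2_d, 0.85 * vo2_n)
        vo2_pk <- max(dr(tg$vo2_max, tg$vo2_max_sd), 1.03 * vo2_n)
        vo2_tr <- min(dr(tg$vo2_min, tg$vo2_min_sd), 0.97 * vo2_d)
        vo2_tr <- max(vo2_tr, 0.2 * vo2_d)
        # ordering-coherent guards: trough < day mean < night mean < peak
        rer_n <- min(max(dr(tg$rer_night, tg$rer_night_sd), 0.76), 1.12)
        rer_d <- min(max(dr(tg$rer_day, tg$rer_day_sd), 0.71), rer_n - 0.05)
        rer_pk <- min(max(dr(tg$rer_max, tg$rer_max_sd), rer_n + 0.015), 1.15)
        rer_tr <- min(max(dr(tg$rer_min, tg$rer_min_sd), 0.68), rer_d - 0.015)
        iv <- design$sampling_interval_min
        night_len <- 1440 - design$schedule$day_length_h * 60
        day_len <- design$schedule$day_length_h * 60
        pl <- design$plateau_min
        clamp_time <- function(t, anchor, window_len) {
          # plateau sits >= 3 samples inside its window so the flanking
          # base segments stay detectable at the minimum segment length
          margin <- 3 * iv
          s <- (t - anchor) %% 1440
          s <- min(max(s, margin), window_len - pl - margin)
          (anchor + snap(s, iv)) %% 1440
        }
        off <- design$schedule$lights_off
        on <- design$schedule$lights_on
        tibble::tibble(
          animal_id = animal_id, sex = sex, condition = cond,
          vo2_night = vo2_n, vo2_day = vo2_d,
          vo2_max = vo2_pk, vo2_min = vo2_tr,
          rer_night = rer_n, rer_day = rer_d,
          rer_max = rer_pk, rer_min = rer_tr,
          h_max_vo2 = clamp_time(
            rnorm(1, tg$h_max_vo2, tg$h_max_vo2_sd), off, night_len
          ),
          h_min_vo2 = clamp_time(
            rnorm(1, tg$h_min_vo2, tg$h_min_vo2_sd), on, day_len
          ),
          h_max_rer = clamp_time(
            rnorm(1, tg$h_max_rer, tg$h_max_rer_sd), off, night_len
          ),
          h_min_rer = clamp_time(
            rnorm(1, tg$h_min_rer, tg$h_min_rer_sd), on, day_len
          )
        )
      }) |> purrr::list_rbind()
    }
  ) |> purrr::list_rbind()
  list(animals = animals, scalars = scalars, calorimetry = calo)
}

# one daily profile (values per sample, cycle anchored at lights-off)
daily_profile <- function(mins, schedule, level_night, level_day,
                          peak, trough, h_peak, h_trough, plateau_min,
                          ramp_samples) {
  phase <- assign_phase(mins, schedule)
  in_plateau <- function(m, start) ((m - start) %% 1440) < plateau_min
  night_n <- sum(phase == "night")
  day_n <- sum(phase == "day")
  pk_idx <- phase == "night" & in_plateau(mins, h_peak)
  tr_idx <- phase == "day" & in_plateau(mins, h_trough)
  pk_n <- sum(pk_idx)
  tr_n <- sum(tr_idx)
  # plateau bases chosen so the per-phase sample means equal the
  # programmed phase means exactly
  base_night <- (level_night * night_n - peak * pk_n) / (night_n - pk_n)
  base_day <- (level_day * day_n - trough * tr_n) / (day_n - tr_n)
  x <- ifelse(phase == "night", base_night, base_day)
  x[pk_idx] <- peak
  x[tr_idx] <- trough
  if (ramp_samples > 1) {
    w <- ramp_samples + (ramp_samples %% 2 == 0) # force odd
    k <- rep(1 / w, w)
    xx <- c(tail(x, (w - 1) / 2), x, head(x, (w - 1) / 2))
    x <- as.numeric(stats::filter(xx, k, sides = 2))[
      (w - 1) / 2 + seq_along(mins)
    ]
  }
  x
}

# invert the gas-exchange equations: excurrent fractions producing the
# target VO2/VCO2 at the design's flow, incurrent fractions and mass
invert_gas <- function(vo2, vco2, mass_kg, design) {
  v <- vo2 * mass_kg / design$fr_i
  cc <- vco2 * mass_kg / design$fr_i
  feo2 <- design$fi_o2 - v
  feco2 <- design$fi_co2 + cc
  for (i in 1:40) {
    feo2 <- (design$fi_o2 - v) / (1 + (feco2 - design$fi_co2) - v)
    feco2 <- (cc + design$fi_co2) / (1 + cc - (design$fi_o2 - feo2))
  }
  if (any(feo2 <= 0 | feo2 >= 1 | feco2 <= 0 | feco2 >= 1)) {
    abort("target profile yields excurrent fractions outside (0, 1)")
  }
  list(fe_o2 = feo2, fe_co2 = feco2)
}

#' Generate synthetic calorimetry gas traces
#'
#' Builds, for every animal and condition, an `n_days`-day gas trace by
#' inverting the open-flow gas-exchange equations: programmed circadian
#' VO2 and RER profiles (smoothed two-plateau square waves with a night
#' peak and a day trough) are converted to excurrent fractional gas
#' concentrations at fixed incurrent composition, flow and body mass,
#' with multiplicative per-sample measurement noise.
#'
#' @param design A [cohort_design()].
#' @param params Optional pre-drawn animal parameters (internal reuse by
#'   [gen_cohort()]).
#' @return A list: `traces` (gas-trace tibble for
#'   [derive_metabolic_series()]) and `truth` (programmed per-animal
#'   phase means, extrema values and clock times).
#' @export
gen_gas_traces <- function(design, params = NULL) {
  params <- params %||% draw_animal_params(design)
  set.seed(design$seed + 1L)
  iv <- design$sampling_interval_min
  per_day <- 1440 %/% iv
  day_mins <- (design$schedule$lights_off + iv * (seq_len(per_day) - 1)) %% 1440
  bm <- params$scalars |>
    dplyr::filter(.data$variable == "body_mass")
  start0 <- as.POSIXct("2024-06-01 17:00:00", tz = "UTC")
  traces <- purrr::pmap(
    params$calorimetry,
    function(animal_id, sex, condition, vo2_night, vo2_day, vo2_max,
             vo2_min, rer_night, rer_day, rer_max, rer_min,
             h_max_vo2, h_min_vo2, h_max_rer, h_min_rer) {
      vo2_prof <- daily_profile(
        day_mins, design$schedule, vo2_night, vo2_day, vo2_max, vo2_min,
        h_max_vo2, h_min_vo2, design$plateau_min, design$ramp_samples
      )
      rer_prof <- daily_profile(
        day_mins, design$schedule, rer_night, rer_day, rer_max, rer_min,
        h_max_rer, h_min_rer, design$plateau_min, design$ramp_samples
      )
      nall <- per_day * design$n_days
      vo2_t <- rep(vo2_prof, design$n_days)
      rer_t <- rep(rer_prof, design$n_days)
      if (design$vo2_cv > 0) {
        vo2_t <- vo2_t * exp(rnorm(nall, 0, design$vo2_cv))
      }
      if (design$rer_cv > 0) {
        rer_t <- rer_t * exp(rnorm(nall, 0, design$rer_cv))
      }
      mass_kg <- bm$value[
        bm$animal_id == animal_id & bm$condition == condition
      ] / 1000
      fe <- invert_gas(vo2_t, rer_t * vo2_t, mass_kg, design)
      start <- start0 + (condition == "CR") * 21 * 86400
      tibble::tibble(
        animal_id = animal_id, sex = sex, condition = condition,
        time = start + 60 * iv * (seq_len(nall) - 1),
        fi_o2 = design$fi_o2, fe_o2 = fe$fe_o2,
        fi_co2 = design$fi_co2, fe_co2 = fe$fe_co2,
        fr_i = design$fr_i, body_mass_kg = mass_kg
      )
    }
  ) |> purrr::list_rbind()
  list(traces = traces, truth = params$calorimetry)
}

#' Generate synthetic flux plates, qPCR records and biomarker panels
#'
#' `gen_flux_plates()` builds triplicate-well mito-stress plates whose
#' decisive statistics (baseline mean, post-oligomycin minimum, post-FCCP
#' maximum OCR and mean FCCP ECAR) encode each sample's programmed OxCR,
#' MtRC and GlcP exactly; cycle jitter and a per-well cell-count scale
#' factor (which the %-baseline metrics cancel by construction) provide
#' realistic scatter, and wells can drop out to emulate culture
#' contamination. `gen_qpcr()` emits two triplicate Ct runs per target
#' encoding the programmed mtDNA/nuDNA ratio; `gen_biomarkers()` emits a
#' long panel with creatinine for urinary analytes and repeat readings
#' for out-of-range glycaemia.
#'
#' @inheritParams gen_gas_traces
#' @return A list with the generated table (`plates`, `qpcr` or `panel`)
#'   and the programmed `truth`.
#' @name gen-assays
#' @export
gen_flux_plates <- function(design, params = NULL) {
  params <- params %||% draw_animal_params(design)
  set.seed(design$seed + 2L)
  truth <- params$scalars |>
    dplyr::filter(.data$variable %in% c("oxcr", "mtrc", "glcp")) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  base_ocr <- 150
  base_ecar <- 20
  cv <- design$flux_cv
  centred <- function(n, level) {
    e <- rnorm(n, 0, cv)
    level * (1 + e - mean(e))
  }
  plates <- purrr::pmap(truth, function(animal_id, sex, condition,
                                        oxcr, mtrc, glcp) {
    wells <- purrr::map(1:3, function(wi) {
      if (design$well_dropout > 0 && runif(1) < design$well_dropout) {
        return(NULL)
      }
      scale <- exp(rnorm(1, 0, 0.1)) # cell-count bias, cancelled by %
      away <- function(level, dir) {
        level * (1 + dir * abs(rnorm(2, 0, cv)))
      }
      oligo_min <- base_ocr * (1 - oxcr / 100)
      fccp_max <- base_ocr * (1 + mtrc / 100)
      ocr <- c(
        centred(3, base_ocr),
        sample(c(oligo_min, away(oligo_min, +1))),
        sample(c(fccp_max, away(fccp_max, -1))),
        abs(centred(3, base_ocr * 0.12))
      )
      ecar <- c(
        centred(3, base_ecar),
        centred(3, base_ecar * 1.3),
        centred(3, base_ecar * (1 + glcp / 100)),
        centred(3, base_ecar * 1.1)
      )
      tibble::tibble(
        sample_id = paste(animal_id, condition, sep = "_"),
        animal_id = animal_id, sex = sex, condition = condition,
        well = paste0("W", wi), cycle_index = 1:12,
        phase = rep(c("baseline", "oligomycin", "fccp", "rot_aa"), each = 3),
        ocr = ocr * scale, ecar = ecar * scale
      )
    })
    purrr::list_rbind(purrr::compact(wells))
  }) |> purrr::list_rbind()
  list(plates = plates, truth = truth)
}

#' @rdname gen-assays
#' @param efficiency qPCR amplification efficiency used to encode ratios.
#' @export
gen_qpcr <- function(design, params = NULL, efficiency = 2) {
  params <- params %||% draw_animal_params(design)
  set.seed(design$seed + 3L)
  truth <- params$scalars |>
    dplyr::filter(.data$variable == "mtnu_ratio") |>
    dplyr::rename(mtnu_ratio = "value") |>
    dplyr::select(-"variable")
  qpcr <- purrr::pmap(truth, function(animal_id, sex, condition,
                                      mtnu_ratio) {
    ct_nu <- 25 + rnorm(1, 0, 0.5)
    ct_mt <- ct_nu - log(mtnu_ratio, base = efficiency)
    jit <- function(m) {
      e <- rnorm(6, 0, design$ct_sd)
      m + e - mean(e) # replicate scatter, mean Ct preserved
    }
    tibble::tibble(
      sample_id = paste(animal_id, condition, sep = "_"),
      animal_id = animal_id, sex = sex, condition = condition,
      target = rep(c("mt", "nu"), each = 6),
      run = rep(rep(1:2, each = 3), 2),
      replicate = rep(1:3, 4),
      ct = c(jit(ct_mt), jit(ct_nu))
    )
  }) |> purrr::list_rbind()
  list(qpcr = qpcr, truth = truth)
}

#' @rdname gen-assays
#' @param glycaemia_range Normal range used to decide repeats.
#' @export
gen_biomarkers <- function(design, params = NULL,
                           glycaemia_range = c(50, 150)) {
  params <- params %||% draw_animal_params(design)
  set.seed(design$seed + 4L)
  urinary <- c("cortisol", "ohdg_8", "estradiol", "testosterone")
  blood <- c("thiols", "gpx", "t4")
  truth <- params$scalars |>
    dplyr::filter(.data$variable %in% c(urinary, blood, "glycaemia"))
  panel <- truth |>
    purrr::pmap(function(animal_id, sex, variable, condition, value) {
      if (variable == "glycaemia") {
        in_range <- value > glycaemia_range[1] & value < glycaemia_range[2]
        readings <- if (in_range) {
          value
        } else {
          c(value, value * (1 + rnorm(2, 0, design$glyc_cv)))
        }
        return(tibble::tibble(
          animal_id = animal_id, sex = sex, condition = condition,
          analyte = variable, reading_index = seq_along(readings),
          value = readings, creatinine = NA_real_
        ))
      }
      creat <- if (variable %in% urinary) exp(rnorm(1, log(0.8), 0.3)) else NA_real_
      tibble::tibble(
        animal_id = animal_id, sex = sex, condition = condition,
        analyte = variable, reading_index = 1L,
        value = if (variable %in% urinary) value * creat else value,
        creatinine = creat
      )
    }) |>
    purrr::list_rbind()
  list(panel = panel, truth = truth)
}

#' Generate a complete synthetic cohort
#'
#' Draws all per-animal programmed parameters once (paired across
#' conditions through a latent animal effect), then generates every data
#' family: gas traces, flux plates, qPCR records and biomarker panels.
#' The seed in the design fully determines all outputs.
#'
#' @param design A [cohort_design()].
#' @return A list of class `synthetic_cohort`: `design`, `gas_traces`,
#'   `flux_plates`, `qpcr`, `biomarkers` and `truth` (a list of
#'   programmed-value tables: `calorimetry`, `flux`, `mtnu`, `panel`,
#'   `scalars`).
#' @examples
#' \donttest{
#' cohort <- gen_cohort(cohort_design(seed = 42, n_days = 1))
#' dplyr::count(cohort$gas_traces, condition)
#' }
#' @export
gen_cohort <- function(design = cohort_design()) {
  params <- draw_animal_params(design)
  gas <- gen_gas_traces(design, params)
  flux <- gen_flux_plates(design, params)
  qpcr <- gen_qpcr(design, params)
  biom <- gen_biomarkers(design, params)
  structure(
    list(
      design = design,
      gas_traces = gas$traces,
      flux_plates = flux$plates,
      qpcr = qpcr$qpcr,
      biomarkers = biom$panel,
      truth = list(
        calorimetry = gas$truth, flux = flux$truth, mtnu = qpcr$truth,
        panel = biom$truth, scalars = params$scalars
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort> seed ", x$design$seed, ": ",
    nrow(x$truth$calorimetry) / 2, " animals x 2 conditions, ",
    nrow(x$gas_traces), " gas samples, ",
    nrow(x$flux_plates), " flux cycles\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic cohort to CSV fixtures
#'
#' Writes `gas_traces.csv`, `flux_plates.csv`, `qpcr.csv`,
#' `biomarkers.csv` and a `truth.json` ground-truth manifest. Identical
#' seeds produce byte-identical files.
#'
#' @param cohort A [gen_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gas <- cohort$gas_traces |>
    dplyr::mutate(
      datetime = format(.data$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      body_mass_g = .data$body_mass_kg * 1000,
      fr_i_ml_per_h = .data$fr_i
    ) |>
    dplyr::select(
      "animal_id", "sex", "condition", "datetime",
      "fi_o2", "fe_o2", "fi_co2", "fe_co2", "fr_i_ml_per_h", "body_mass_g"
    )
  readr::write_csv(gas, file.path(dir, "gas_traces.csv"))
  cohort$flux_plates |>
    dplyr::rename(ocr_pmol_min = "ocr", ecar_mpH_min = "ecar") |>
    readr::write_csv(file.path(dir, "flux_plates.csv"))
  readr::write_csv(cohort$qpcr, file.path(dir, "qpcr.csv"))
  readr::write_csv(cohort$biomarkers, file.path(dir, "biomarkers.csv"))
  jsonlite::write_json(
    cohort$truth,
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA
  )
  invisible(dir)
}
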