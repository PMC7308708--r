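#' Creatinine normalization of urinary analytes
#'
#' Urinary concentrations are divided by the sample's creatinine
#' concentration (mg/mL) to correct for urine dilution, giving values in
#' ng (or pg) per mg creatinine. Nonpositive or missing creatinine yields
#' an explicit `NA` (the reason is reported once as a message), never a
#' division artefact.
#'
#' @param raw Raw analyte concentration(s).
#' @param creatinine Creatinine concentration(s), mg/mL.
#' @return Numeric vector of normalized values.
#' @examples
#' normalize_urinary(100, 1) # 100
#' normalize_urinary(50, 0.5) # 100
#' @export
normalize_urinary <- function(raw, creatinine) {
  bad <- !is.finite(creatinine) | creatinine <= 0
  if (any(bad & is.finite(raw))) {
    inform(paste0(
      sum(bad & is.finite(raw)),
      " value(s) set to missing: creatinine absent or <= 0"
    ))
  }
  ifelse(bad, NA_real_, raw / creatinine)
}

#' mtDNA/nuDNA ratio from qPCR Ct values
#'
#' Relative mitochondrial genome copy number per cell from paired qPCR
#' targets (a mitochondrial amplicon, e.g. 12S, and a single-copy nuclear
#' amplicon, e.g. 36B4): `ratio = E^(mean Ct_nu - mean Ct_mt)` with
#' amplification efficiency `E` (2 = perfect doubling per cycle).
#' Replicate Cts (up to two triplicate runs per target) are averaged
#' before the difference is taken. Samples missing either target get an
#' explicit missing marker.
#'
#' @param qpcr Tibble with columns `sample_id`, `target` (`"mt"` or
#'   `"nu"`), `ct` (one row per replicate; extra metadata columns are
#'   carried through).
#' @param efficiency Amplification efficiency `E`, in `(1, 2]`.
#' @return A tibble, one row per sample: mean Cts per target, `n`
#'   replicates and `mtnu_ratio`.
#' @examples
#' qpcr <- tibble::tibble(
#'   sample_id = "s1",
#'   target = rep(c("mt", "nu"), each = 3),
#'   ct = c(23.4, 23.45, 23.4, 25.0, 25.0, 25.0)
#' )
#' mtnu_ratio(qpcr)
#' @export
mtnu_ratio <- function(qpcr, efficiency = 2) {
  if (efficiency <= 1 || efficiency > 2) {
    abort("`efficiency` must be in (1, 2]")
  }
  if (any(!is.finite(qpcr$ct) | qpcr$ct <= 0 | qpcr$ct >= 45)) {
    abort("Ct values must lie in (0, 45)")
  }
  if (!all(qpcr$target %in% c("mt", "nu"))) {
    abort("`target` must be \"mt\" or \"nu\"")
  }
  keys <- intersect(
    c("sample_id", "animal_id", "sex", "condition"), names(qpcr)
  )
  qpcr |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      ct_mt = mean(.data$ct[.data$target == "mt"]),
      ct_nu = mean(.data$ct[.data$target == "nu"]),
      n_mt = sum(.data$target == "mt"),
      n_nu = sum(.data$target == "nu"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mtnu_ratio = ifelse(
        .data$n_mt > 0 & .data$n_nu > 0,
        efficiency^(.data$ct_nu - .data$ct_mt),
        NA_real_
      )
    )
}

#' Resolve repeated glycaemia readings
#'
#' Bedside glucometer protocol: a reading within the configured normal
#' range stands as is; a first reading outside it triggers repeats, and
#' the reported value is then the mean of all readings, flagged
#' `repeated`.
#'
#' @param readings Numeric vector of readings (first reading first),
#'   mg/dL.
#' @param normal_range Length-2 numeric, the open interval considered
#'   normal (default `c(50, 150)` mg/dL).
#' @return A one-row tibble: `value`, `repeated`, `n_readings`.
#' @examples
#' resolve_glycaemia(80) # 80, unflagged
#' resolve_glycaemia(c(140, 95, 99), normal_range = c(60, 120)) # mean, flagged
#' @export
resolve_glycaemia <- function(readings, normal_range = c(50, 150)) {
  readings <- readings[!is.na(readings)]
  if (length(readings) == 0) abort("at least one reading required")
  in_range <- readings[1] > normal_range[1] & readings[1] < normal_range[2]
  tibble::tibble(
    value = if (in_range) readings[1] else mean(readings),
    repeated = !in_range && length(readings) > 1,
    n_readings = length(readings)
  )
}

#' Normalize a long-format biomarker panel
#'
#' Applies [normalize_urinary()] to the urinary analytes of a long panel
#' (rows = animal x condition x analyte) and resolves repeated glycaemia
#' readings with [resolve_glycaemia()]. Blood analytes pass through
#' unchanged (protein normalization is assumed done upstream).
#'
#' @param panel Tibble with columns `animal_id`, `condition`, `analyte`,
#'   `value`, `creatinine` (NA for blood analytes) and, for glycaemia,
#'   `reading_index`; extra columns (e.g. `sex`) are carried through.
#' @param urinary Analytes to normalise by creatinine.
#' @param glycaemia_range Normal range passed to [resolve_glycaemia()].
#' @return A tidy tibble, one row per animal x condition x analyte with
#'   the final `value` (normalized where urinary, resolved for
#'   glycaemia) and a `note` column (`"per_mg_creatinine"`, `"repeated"`
#'   or `NA`).
#' @export
normalize_panel <- function(panel,
                            urinary = c(
                              "cortisol", "ohdg_8", "estradiol",
                              "testosterone"
                            ),
                            glycaemia_range = c(50, 150)) {
  keys <- intersect(c("animal_id", "sex", "condition"), names(panel))
  panel |>
    dplyr::group_by(
      dplyr::across(dplyr::all_of(c(keys, "analyte")))
    ) |>
    dplyr::group_modify(function(df, key) {
      analyte <- key$analyte
      if (analyte == "glycaemia") {
        ord <- order(df$reading_index %||% seq_len(nrow(df)))
        res <- resolve_glycaemia(df$value[ord],
          normal_range = glycaemia_range
        )
        return(tibble::tibble(
          value = res$value,
          note = if (res$repeated) "repeated" else NA_character_
        ))
      }
      if (analyte %in% urinary) {
        return(tibble::tibble(
          value = normalize_urinary(df$value, df$creatinine),
          note = "per_mg_creatinine"
        ))
      }
      tibble::tibble(value = df$value, note = NA_character_)
    }) |>
    dplyr::ungroup()
}
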