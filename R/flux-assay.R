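#' Mito-stress-test metrics for a single well
#'
#' A well trace is a tibble of ordered measurement cycles with columns
#' `phase` (`baseline`, `oligomycin`, `fccp`, optionally `rot_aa`), `ocr`
#' (pmol O2/min) and `ecar` (mpH/min). All metrics are expressed as a
#' percentage of the well's own baseline to cancel cell-count bias, so
#' they are invariant to rescaling the whole well:
#'
#' * `compute_oxcr()` — oxidative coupling rate, the drop from the mean of
#'   the 3 baseline OCR measures to the minimum of the 3 post-oligomycin
#'   measures, as % of baseline OCR.
#' * `compute_mtrc()` — mitochondrial reserve capacity, the excess of the
#'   maximum post-FCCP OCR over baseline, as % of baseline OCR.
#' * `compute_glcp()` — glycolytic potential, the rise of mean post-FCCP
#'   ECAR over mean baseline ECAR, as % of baseline ECAR.
#' * `metabolic_potential()` — displacement from the basal phenotype
#'   (100, 100) to the stressed phenotype (stressed OCR %, stressed
#'   ECAR %), with its Euclidean magnitude.
#'
#' A `rot_aa` (rotenone/antimycin A) phase is accepted and ignored.
#'
#' @param well A well-trace tibble (see above).
#' @return `compute_oxcr()`, `compute_mtrc()`, `compute_glcp()` return a
#'   scalar; `metabolic_potential()` a one-row tibble
#'   (`delta_ocr_pct`, `delta_ecar_pct`, `magnitude`).
#' @examples
#' well <- tibble::tibble(
#'   phase = rep(c("baseline", "oligomycin", "fccp"), each = 3),
#'   ocr = c(100, 100, 100, 40, 35, 38, 290, 302.4, 295),
#'   ecar = c(10, 10, 10, 25, 25, 25, 45, 45, 45)
#' )
#' compute_oxcr(well) # 65
#' compute_mtrc(well) # 202.4
#' compute_glcp(well) # 350
#' @name flux-metrics
NULL

phase_vals <- function(well, ph, col) {
  v <- well[[col]][well$phase == ph]
  v[seq_len(min(length(v), 3))] # the protocol's 3 measures per phase
}

check_phases <- function(well, phases = c("baseline", "oligomycin", "fccp")) {
  for (ph in phases) {
    if (sum(well$phase == ph) < 3) {
      abort(paste0("well needs >= 3 `", ph, "` cycles"))
    }
  }
  invisible(well)
}

baseline_mean <- function(well, col = "ocr") {
  b <- mean(phase_vals(well, "baseline", col))
  if (!is.finite(b) || b <= 0) {
    abort(paste0("baseline ", toupper(col), " mean must be > 0"))
  }
  b
}

#' @rdname flux-metrics
#' @export
compute_oxcr <- function(well) {
  check_phases(well, c("baseline", "oligomycin"))
  b <- baseline_mean(well)
  100 * (b - min(phase_vals(well, "oligomycin", "ocr"))) / b
}

#' @rdname flux-metrics
#' @export
compute_mtrc <- function(well) {
  check_phases(well, c("baseline", "fccp"))
  b <- baseline_mean(well)
  100 * (max(phase_vals(well, "fccp", "ocr")) - b) / b
}

#' @rdname flux-metrics
#' @export
compute_glcp <- function(well) {
  check_phases(well, c("baseline", "fccp"))
  b <- baseline_mean(well, "ecar")
  100 * (mean(phase_vals(well, "fccp", "ecar")) - b) / b
}

#' @rdname flux-metrics
#' @export
metabolic_potential <- function(well) {
  check_phases(well, c("baseline", "fccp"))
  # stressed phenotype in % of own baseline: max-of-3 for OCR (as in MtRC),
  # mean-of-3 for ECAR (as in GlcP) -- the asymmetry is kept deliberately
  d_ocr <- compute_mtrc(well)
  d_ecar <- compute_glcp(well)
  tibble::tibble(
    delta_ocr_pct = d_ocr,
    delta_ecar_pct = d_ecar,
    magnitude = sqrt(d_ocr^2 + d_ecar^2)
  )
}

well_qc <- function(well) {
  for (ph in c("baseline", "oligomycin", "fccp")) {
    if (sum(well$phase == ph) < 3) {
      return(paste0("missing `", ph, "` cycles"))
    }
  }
  if (mean(phase_vals(well, "baseline", "ocr")) <= 0) {
    return("nonpositive baseline OCR")
  }
  if (mean(phase_vals(well, "baseline", "ecar")) <= 0) {
    return("nonpositive baseline ECAR")
  }
  NA_character_
}

#' Per-sample mito-stress metrics from a flux plate
#'
#' Normalises each well to its own baseline first, then averages the
#' per-well metrics across a sample's (nominally triplicate) wells. Wells
#' failing QC — a missing protocol phase or a nonpositive baseline — are
#' excluded with a logged reason (culture contamination attrition); a
#' sample with no valid well gets an explicit missing row, never a zero.
#'
#' @param plate Tibble with columns `sample_id`, `well`, `cycle_index`,
#'   `phase`, `ocr`, `ecar` (extra columns such as `sex`/`condition` are
#'   carried through).
#' @return A tibble, one row per sample: `oxcr`, `mtrc`, `glcp`,
#'   `delta_ocr_pct`, `delta_ecar_pct`, `mp_magnitude`, `n_wells`,
#'   `n_wells_excluded`.
#' @export
flux_metrics <- function(plate) {
  keys <- intersect(c("sample_id", "animal_id", "sex", "condition"), names(plate))
  plate |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(df, key) {
      wells <- split(df[order(df$cycle_index), ], df$well[order(df$cycle_index)])
      reasons <- purrr::map_chr(wells, well_qc)
      bad <- !is.na(reasons)
      if (any(bad)) {
        inform(paste0(
          "sample ", paste(unlist(key), collapse = "/"), ": excluded well(s) ",
          paste(names(wells)[bad], " (", reasons[bad], ")",
            sep = "", collapse = ", "
          )
        ))
      }
      valid <- wells[!bad]
      if (length(valid) == 0) {
        return(tibble::tibble(
          oxcr = NA_real_, mtrc = NA_real_, glcp = NA_real_,
          delta_ocr_pct = NA_real_, delta_ecar_pct = NA_real_,
          mp_magnitude = NA_real_,
          n_wells = 0L, n_wells_excluded = sum(bad)
        ))
      }
      per_well <- purrr::map(valid, function(w) {
        mp <- metabolic_potential(w)
        tibble::tibble(
          oxcr = compute_oxcr(w), mtrc = compute_mtrc(w),
          glcp = compute_glcp(w),
          delta_ocr_pct = mp$delta_ocr_pct,
          delta_ecar_pct = mp$delta_ecar_pct,
          mp_magnitude = mp$magnitude
        )
      }) |>
        purrr::list_rbind()
      dplyr::summarise(per_well, dplyr::across(dplyr::everything(), mean)) |>
        dplyr::mutate(
          n_wells = length(valid), n_wells_excluded = sum(bad)
        )
    }) |>
    dplyr::ungroup()
}

#' Read a flux-plate CSV
#'
#' Expects columns `sample_id`, `well`, `cycle_index`, `phase`,
#' `ocr_pmol_min`, `ecar_mpH_min` (plus optional metadata columns).
#'
#' @param path CSV file path.
#' @return A plate tibble ready for [flux_metrics()].
#' @export
read_flux_plates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(ocr = "ocr_pmol_min", ecar = "ecar_mpH_min")
}
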