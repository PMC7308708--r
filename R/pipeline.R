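#' Pipeline run configuration
#'
#' Collects every tunable of the full analysis in one flat list that can
#' be written to, and read back from, a YAML file, so a run is
#' reproducible from a single committed config.
#'
#' @param gas_csv,flux_csv,qpcr_csv,biomarkers_csv Input CSV paths (may
#'   be `NULL` when the pipeline is run on an in-memory cohort).
#' @param lights_off,lights_on Photoperiod clock times (`"hh:mm"`).
#' @param min_seg_len Minimum changepoint segment length (samples).
#' @param penalty Changepoint penalty; `NULL` for the `3 * log(n)`
#'   default.
#' @param qpcr_efficiency Amplification efficiency for mtDNA/nuDNA.
#' @param glycaemia_range Normal glycaemia range, mg/dL.
#' @param correlation_threshold Minimum `|r|` for a network edge.
#' @param seed Integer seed recorded in the run log.
#' @param out_dir Output directory (`NULL` = return results only).
#' @return A list of class `run_config`.
#' @export
run_config <- function(gas_csv = NULL, flux_csv = NULL, qpcr_csv = NULL,
                       biomarkers_csv = NULL,
                       lights_off = "17:00", lights_on = "03:00",
                       min_seg_len = 3, penalty = NULL,
                       qpcr_efficiency = 2,
                       glycaemia_range = c(50, 150),
                       correlation_threshold = 0.5,
                       seed = 1, out_dir = NULL) {
  structure(
    list(
      gas_csv = gas_csv, flux_csv = flux_csv, qpcr_csv = qpcr_csv,
      biomarkers_csv = biomarkers_csv,
      lights_off = lights_off, lights_on = lights_on,
      min_seg_len = min_seg_len, penalty = penalty,
      qpcr_efficiency = qpcr_efficiency,
      glycaemia_range = glycaemia_range,
      correlation_threshold = correlation_threshold,
      seed = seed, out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file to write to / read from.
#' @export
write_config_template <- function(path) {
  cfg <- unclass(run_config())
  cfg <- purrr::map(cfg, function(x) if (is.null(x)) "" else x)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw <- purrr::map(raw, function(x) {
    if (is.character(x) && length(x) == 1 && x == "") NULL else x
  })
  defaults <- unclass(run_config())
  merged <- utils::modifyList(defaults, raw[names(raw) %in% names(defaults)])
  structure(merged, class = "run_config")
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage `", name, "` failed: ", conditionMessage(e)))
  })
}

#' Run the full bioenergetics pipeline
#'
#' Orchestrates respirometry -> circadian -> flux assay -> biomarkers ->
#' cohort statistics, either from the CSV paths in `config` or from an
#' in-memory [gen_cohort()] result. Any stage failure aborts with the
#' stage name. With `out_dir` set, writes the report and all derived
#' tables as CSV plus a run log; outputs are byte-identical across reruns
#' with the same inputs and config.
#'
#' @param config A [run_config()].
#' @param cohort Optional [gen_cohort()] result used instead of the CSV
#'   inputs.
#' @return A list of class `pipeline_result` with elements
#'   `phase_means`, `extrema`, `shifts`, `polar`, `flux`, `panel`,
#'   `mtnu`, `metrics`, `response`, `report`, `outliers`, `network`,
#'   `pca`, `log`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  schedule <- photoperiod(config$lights_off, config$lights_on)
  log_lines <- c(
    paste0("calorest ", as.character(utils::packageVersion("calorest"))),
    paste0(R.version.string),
    paste0("seed: ", config$seed)
  )
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  traces <- stage_run("respirometry", {
    tr <- if (!is.null(cohort)) {
      cohort$gas_traces
    } else {
      if (is.null(config$gas_csv) || !file.exists(config$gas_csv %||% "")) {
        abort("gas-trace CSV not found")
      }
      read_gas_traces(config$gas_csv)
    }
    validate_gas_trace(tr)
  })
  series <- stage_run("respirometry", derive_metabolic_series(traces, schedule))
  phase_means <- stage_run("respirometry", aggregate_by_phase(series))
  note(
    "respirometry: ", dplyr::n_distinct(traces$animal_id), " animals, ",
    nrow(series), " samples"
  )

  circ <- stage_run("circadian", {
    purrr::map(
      c("vo2", "rer", "ee_kcal_h"),
      ~ circadian_extrema(series, .x,
        schedule = schedule,
        penalty = config$penalty, min_seg_len = config$min_seg_len
      )
    ) |> purrr::list_rbind()
  })
  shifts <- stage_run("circadian", {
    if (!"condition" %in% names(circ)) {
      tibble::tibble()
    } else {
      circ |>
        tidyr::pivot_wider(
          id_cols = dplyr::any_of(c("animal_id", "sex", "variable")),
          names_from = "condition",
          values_from = c("h_max", "h_min")
        ) |>
        dplyr::mutate(
          shift_max_min = time_shift(.data$h_max_CTL, .data$h_max_CR),
          shift_min_min = time_shift(.data$h_min_CTL, .data$h_min_CR)
        )
    }
  })
  polar <- stage_run("circadian", {
    dd <- circ |>
      tidyr::pivot_longer(c("h_max", "h_min"),
        names_to = "event", values_to = "minutes"
      ) |>
      dplyr::filter(!is.na(.data$minutes))
    if (!"sex" %in% names(dd)) dd$sex <- "all"
    if (!"condition" %in% names(dd)) dd$condition <- "all"
    dd |>
      dplyr::mutate(
        group = paste(.data$sex, .data$condition, sep = "_")
      ) |>
      polar_coordinates(time_col = "minutes", group_col = "group")
  })
  note("circadian: ", nrow(circ), " extrema rows")

  flux <- stage_run("flux_assay", {
    pl <- if (!is.null(cohort)) {
      cohort$flux_plates
    } else if (!is.null(config$flux_csv)) {
      if (!file.exists(config$flux_csv)) abort("flux-plate CSV not found")
      read_flux_plates(config$flux_csv)
    } else {
      NULL
    }
    if (is.null(pl)) NULL else flux_metrics(pl)
  })
  note("flux_assay: ", if (is.null(flux)) 0 else nrow(flux), " samples")

  biom <- stage_run("biomarkers", {
    panel <- if (!is.null(cohort)) {
      cohort$biomarkers
    } else if (!is.null(config$biomarkers_csv)) {
      if (!file.exists(config$biomarkers_csv)) {
        abort("biomarker CSV not found")
      }
      readr::read_csv(config$biomarkers_csv, show_col_types = FALSE)
    } else {
      NULL
    }
    qp <- if (!is.null(cohort)) {
      cohort$qpcr
    } else if (!is.null(config$qpcr_csv)) {
      if (!file.exists(config$qpcr_csv)) abort("qPCR CSV not found")
      readr::read_csv(config$qpcr_csv, show_col_types = FALSE)
    } else {
      NULL
    }
    list(
      panel = if (is.null(panel)) {
        NULL
      } else {
        normalize_panel(panel, glycaemia_range = config$glycaemia_range)
      },
      mtnu = if (is.null(qp)) {
        NULL
      } else {
        mtnu_ratio(qp, efficiency = config$qpcr_efficiency)
      }
    )
  })
  note(
    "biomarkers: ",
    if (is.null(biom$panel)) 0 else nrow(biom$panel), " panel rows, ",
    if (is.null(biom$mtnu)) 0 else nrow(biom$mtnu), " qPCR samples"
  )

  stats_out <- stage_run("cohort_stats", {
    metrics <- assemble_metrics(traces, phase_means, circ, flux, biom)
    resp <- response_table(metrics)
    report <- response_summary(resp)
    outliers <- metrics |>
      dplyr::group_by(.data$variable, .data$sex, .data$condition) |>
      dplyr::group_modify(function(df, key) {
        v <- df$value[is.finite(df$value)]
        if (length(v) < 3 || length(v) > 13) {
          return(tibble::tibble(
            n = length(v), variant = NA_character_, q = NA_real_,
            q_crit = NA_real_, outlier = FALSE, suspect = NA_real_
          ))
        }
        dixon_q(v)
      }) |>
      dplyr::ungroup()
    wide <- metrics |>
      tidyr::pivot_wider(
        id_cols = c("animal_id", "sex", "condition"),
        names_from = "variable", values_from = "value"
      )
    numeric_vars <- setdiff(names(wide), c("animal_id", "sex", "condition"))
    network <- correlation_network(
      wide,
      vars = numeric_vars, group_col = "sex",
      threshold = config$correlation_threshold
    )
    pca <- pca_describe(
      wide[numeric_vars],
      groups = paste(wide$sex, wide$condition, sep = "_"),
      n_components = 5
    )
    list(
      metrics = metrics, response = resp, report = report,
      outliers = outliers, network = network, pca = pca, wide = wide
    )
  })
  note(
    "cohort_stats: ", dplyr::n_distinct(stats_out$metrics$variable),
    " variables, ", nrow(stats_out$response), " response rows"
  )

  result <- structure(
    list(
      phase_means = phase_means, extrema = circ, shifts = shifts,
      polar = polar, flux = flux, panel = biom$panel, mtnu = biom$mtnu,
      metrics = stats_out$metrics, response = stats_out$response,
      report = stats_out$report, outliers = stats_out$outliers,
      network = stats_out$network, pca = stats_out$pca,
      wide = stats_out$wide, log = log_lines
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

# tidy long table of per-animal, per-condition scalar metrics
assemble_metrics <- function(traces, phase_means, circ, flux, biom) {
  keys <- c("animal_id", "sex", "condition")
  parts <- list()
  parts$phase <- phase_means |>
    tidyr::pivot_longer(dplyr::any_of(c("vo2", "vco2", "rer", "ee_kcal_h")),
      names_to = "var", values_to = "value"
    ) |>
    dplyr::mutate(variable = paste(.data$var, .data$phase, sep = "_")) |>
    dplyr::select(dplyr::any_of(keys), "variable", "value")
  parts$extrema <- circ |>
    tidyr::pivot_longer(c("max_value", "min_value"),
      names_to = "which", values_to = "value"
    ) |>
    dplyr::mutate(
      variable = paste0(
        .data$variable, ifelse(.data$which == "max_value", "_max", "_min")
      )
    ) |>
    dplyr::select(dplyr::any_of(keys), "variable", "value")
  parts$bm <- traces |>
    dplyr::distinct(dplyr::across(dplyr::any_of(keys)), .data$body_mass_kg) |>
    dplyr::mutate(variable = "body_mass", value = 1000 * .data$body_mass_kg) |>
    dplyr::select(dplyr::any_of(keys), "variable", "value")
  if (!is.null(flux)) {
    parts$flux <- flux |>
      tidyr::pivot_longer(
        dplyr::any_of(c("oxcr", "mtrc", "glcp", "mp_magnitude")),
        names_to = "variable", values_to = "value"
      ) |>
      dplyr::select(dplyr::any_of(keys), "variable", "value")
  }
  if (!is.null(biom$mtnu)) {
    parts$mtnu <- biom$mtnu |>
      dplyr::mutate(variable = "mtnu_ratio", value = .data$mtnu_ratio) |>
      dplyr::select(dplyr::any_of(keys), "variable", "value")
  }
  if (!is.null(biom$panel)) {
    parts$panel <- biom$panel |>
      dplyr::mutate(variable = .data$analyte) |>
      dplyr::select(dplyr::any_of(keys), "variable", "value")
  }
  purrr::list_rbind(unname(parts))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    if (!is.null(x) && nrow(x) > 0) {
      readr::write_csv(x, file.path(out_dir, name))
    }
  }
  wr(result$report, "report.csv")
  wr(result$response, "response_table.csv")
  wr(result$phase_means, "phase_means.csv")
  wr(result$extrema, "extrema.csv")
  wr(result$shifts, "time_shifts.csv")
  wr(result$polar, "polar_coordinates.csv")
  wr(result$flux, "flux_metrics.csv")
  wr(result$panel, "biomarkers_normalized.csv")
  wr(result$mtnu, "mtnu_ratio.csv")
  wr(result$outliers, "dixon_screen.csv")
  wr(result$network, "network_edges.csv")
  pca <- result$pca
  wr(
    tibble::as_tibble(pca$scores, rownames = "row"),
    "pca_scores.csv"
  )
  wr(
    tibble::as_tibble(pca$loadings, rownames = "variable"),
    "pca_loadings.csv"
  )
  wr(
    tibble::tibble(
      component = colnames(pca$loadings), pct_var = pca$pct_var
    ),
    "pca_variance.csv"
  )
  wr(pca$var_cor, "pca_dimension_description.csv")
  if (!is.null(pca$cat_v)) wr(pca$cat_v, "pca_category_vtest.csv")
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
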