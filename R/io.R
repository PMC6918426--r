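#' Read and write decay curves
#'
#' Decay curves are exchanged as plain CSV (columns `time_ms`, `amplitude`,
#' comma-separated, UTF-8, `.` decimal, mandatory header) with the protocol
#' carried in a YAML sidecar next to the data file (same path, `.yml`
#' extension). Everything a writer emits is accepted by the matching reader.
#'
#' @param curve A [decay_curve()].
#' @param path CSV path to write to / read from.
#' @param sidecar YAML sidecar path; defaults to `path` with a `.yml`
#'   extension. Pass `NULL` when reading to skip protocol metadata.
#' @return `write_decay_curve()` returns `path` invisibly;
#'   `read_decay_curve()` returns a [decay_curve()].
#' @name curve_io
NULL

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yml")
}

#' @rdname curve_io
#' @export
write_decay_curve <- function(curve, path, sidecar = sidecar_path(path)) {
  stopifnot(inherits(curve, "decay_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  if (!is.null(sidecar) && !is.null(curve$protocol)) {
    yaml::write_yaml(unclass(curve$protocol), sidecar)
  }
  invisible(path)
}

#' @rdname curve_io
#' @export
read_decay_curve <- function(path, sidecar = sidecar_path(path)) {
  df <- tryCatch(utils::read.csv(path), error = function(e) {
    stop("cannot parse decay-curve CSV `", path, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  if (!all(c("time_ms", "amplitude") %in% names(df))) {
    stop("`", path, "` lacks the required columns time_ms, amplitude",
         call. = FALSE)
  }
  df$time_ms <- suppressWarnings(as.numeric(df$time_ms))
  df$amplitude <- suppressWarnings(as.numeric(df$amplitude))
  if (anyNA(df$time_ms) || anyNA(df$amplitude)) {
    bad <- which(is.na(df$time_ms) | is.na(df$amplitude))[1]
    stop("`", path, "`: non-numeric value at data line ", bad, call. = FALSE)
  }
  protocol <- NULL
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    protocol <- if (identical(meta$sequence_kind, "inversion_recovery")) {
      ir_protocol(delays_ms = meta$delays_ms,
                  frequency_mhz = meta$frequency_mhz,
                  repetition_s = meta$repetition_s,
                  n_accumulations = meta$n_accumulations)
    } else if (identical(meta$sequence_kind, "cpmg")) {
      cpmg_protocol(te_ms = meta$te_ms, n_echoes = meta$n_echoes,
                    frequency_mhz = meta$frequency_mhz,
                    repetition_s = meta$repetition_s,
                    n_accumulations = meta$n_accumulations)
    } else {
      stop("unknown sequence kind in sidecar `", sidecar, "`", call. = FALSE)
    }
  }
  decay_curve(df$time_ms, df$amplitude, protocol = protocol)
}

#' Read and write tidy fit and correlation-time tables
#'
#' Tidy tables (one row per fitted component, or per recovered correlation
#' time) are exchanged as header-first CSV; the `"±"` glyph never appears in
#' machine-readable files — uncertainties travel in separate `*_sd` columns.
#' `write_fit_json()` additionally serializes a fit list with its goodness
#' diagnostics.
#'
#' @param df A tidy table ([fit_storage_series()] / [tauc_from_fits()]
#'   output).
#' @param path File path.
#' @param required Columns the reader insists on.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_fit_table <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_fit_table <- function(path,
                           required = c("starch", "hydrocolloid", "day",
                                        "kind", "component", "time_ms")) {
  df <- tryCatch(utils::read.csv(path), error = function(e) {
    stop("cannot parse fit CSV `", path, "`: ", conditionMessage(e),
         call. = FALSE)
  })
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("`", path, "` lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname table_io
#' @param fits A list of `relaxation_fit` objects (or a single one).
#' @export
write_fit_json <- function(fits, path) {
  if (inherits(fits, "relaxation_fit")) fits <- list(fits)
  payload <- lapply(fits, function(f) {
    list(kind = f$kind, m0 = f$m0, m0_sd = f$m0_sd,
         n_components = f$n_components,
         components = f$components,
         goodness = list(rss = f$rss, aicc = f$aicc,
                         n_points = f$n_points),
         converged = f$converged, diagnostics = f$diagnostics)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Run configuration
#'
#' A run configuration is a flat YAML map validated before any pipeline stage
#' executes; unknown keys are rejected outright so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file to read, or a named list of overrides for
#'   `run_config()`.
#' @param ... Named overrides of the defaults.
#' @return A named list of class `run_config`.
#' @name config
NULL

run_config_defaults <- function() {
  list(
    seed = 1L,
    snr = 200,
    m0 = 100,
    frequency_mhz = 15,
    delays_ms = seq(100, 1000, by = 100),
    te_ms = 2,
    n_echoes = 1024L,
    max_components = 2L,
    alpha = 0.05,
    factor = "day",
    n_replicates = 3L,
    hcs_fractions = c(0.3, 0.7),
    hydrocolloids = c("none", "AG", "GG", "XG"),
    out_dir = "results"
  )
}

#' @rdname config
#' @export
run_config <- function(...) {
  overrides <- list(...)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  validate_run_config(cfg)
}

#' @rdname config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(run_config, raw)
}

validate_run_config <- function(cfg) {
  stopifnot(cfg$snr > 0, cfg$m0 > 0, cfg$frequency_mhz > 0,
            cfg$te_ms > 0, cfg$n_echoes >= 2,
            cfg$max_components %in% 1:3,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$n_replicates >= 1,
            length(cfg$hcs_fractions) == 2,
            abs(sum(cfg$hcs_fractions) - 1) < 1e-9)
  if (!all(cfg$hydrocolloids %in% c("none", "AG", "GG", "XG"))) {
    stop("`hydrocolloids` must be a subset of none/AG/GG/XG", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write a JSON run report
#'
#' Records the configuration echo, the master seed, and per-stage diagnostics
#' (timings, convergence counts) for a pipeline run.
#'
#' @param path Output JSON path.
#' @param config The `run_config` used.
#' @param stages Named list of per-stage diagnostic lists.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(path, config, stages = list()) {
  report <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    stages = stages
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Plot storage trends of the mean correlation time
#'
#' Day-by-day trajectories of tau_c per sample and water-fraction track, the
#' figure style conventional for retrogradation storage studies.
#'
#' @param tauc A table from [tauc_from_fits()] (columns `starch`,
#'   `hydrocolloid`, `day`, `label`, `tau_c_s`).
#' @return A ggplot object.
#' @export
plot_storage_trends <- function(tauc) {
  tauc <- tibble::as_tibble(tauc)
  tauc$track <- paste(tauc$starch, tauc$hydrocolloid, tauc$label, sep = " / ")
  ggplot2::ggplot(tauc,
                  ggplot2::aes(x = .data$day, y = .data$tau_c_s,
                               colour = .data$track)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "storage day", y = "mean correlation time (s)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
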