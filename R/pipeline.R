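#' Default deflation protocol
#'
#' The standard decremental PEEP protocol: nominal steps 12, 9, 6, 3, 0
#' cmH2O, with typical measured-PEEP means and SDs at each step (measured
#' airway pressure always sits a little above nominal at the low steps).
#' [sample_measured_peep()] draws per-animal measured values from these.
#'
#' @return A tibble with `pressure_nominal`, `measured_mean`,
#'   `measured_sd`.
#' @export
default_protocol <- function() {
  tibble::tibble(
    pressure_nominal = c(12, 9, 6, 3, 0),
    measured_mean = c(12.3, 9.5, 6.9, 4.0, 1.2),
    measured_sd = c(0.5, 0.6, 0.8, 0.9, 0.4))
}

#' Sample measured PEEP values for one animal
#'
#' @param protocol A protocol tibble as from [default_protocol()].
#' @return Numeric vector of measured PEEP values (cmH2O), truncated at 0.
#' @export
sample_measured_peep <- function(protocol = default_protocol()) {
  pmax(0, rnorm(nrow(protocol), protocol$measured_mean,
                protocol$measured_sd))
}

#' Simulate a full multi-animal deflation experiment
#'
#' For each animal: draw an airspace population, render one phantom stack
#' per pressure step (driven by the animal's measured PEEP), run the
#' detection chain, partition into concentric ROIs and compute the per-ROI
#' metrics. The result is the tidy metrics table ready for
#' [summarize_run()].
#'
#' @param n_animals Number of simulated animals (default 7).
#' @param spec A [phantom_spec()] template; each animal gets a derived
#'   seed.
#' @param protocol Protocol tibble (see [default_protocol()]).
#' @param params A [detect_params()].
#' @param thresholds_mm Depth cuts for the concentric ROIs (mm).
#' @param seed Master seed; per-animal seeds are derived from it.
#' @param drive_with `"measured"` (default): phantom pressure dynamics are
#'   driven by the measured PEEP; `"nominal"` uses the nominal steps.
#' @return A tibble of per-ROI metrics (one row per animal x pressure x
#'   ROI), with a `truth_count` column of ground-truth open counts for
#'   validation.
#' @export
simulate_experiment <- function(n_animals = 7L,
                                spec = phantom_spec(),
                                protocol = default_protocol(),
                                params = detect_params(),
                                thresholds_mm = c(2, 4),
                                seed = 1L,
                                drive_with = c("measured", "nominal")) {
  drive_with <- match.arg(drive_with)
  out <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    aspec <- spec
    aspec$seed <- derive_seed(seed, 100L + a)
    set.seed(derive_seed(seed, 200L + a))
    measured <- sample_measured_peep(protocol)
    drive <- if (drive_with == "measured") measured
             else protocol$pressure_nominal
    series <- pressure_series(aspec, pressures = drive)
    partition <- partition_rois(
      boundary_depth(series[[1]]$truth$lung_mask, aspec$voxel_size_um),
      exclusion = series[[1]]$truth$exclusion_mask,
      thresholds_mm = thresholds_mm)
    rows <- vector("list", length(series))
    for (k in seq_along(series)) {
      det <- detect_stack(series[[k]]$stack,
                          masks = series[[k]]$truth$lung_mask,
                          exclusions = series[[k]]$truth$exclusion_mask,
                          params = params)
      m <- roi_metrics(det, partition,
                       pressure_nominal = protocol$pressure_nominal[k],
                       pressure_measured = measured[k],
                       animal = sprintf("animal_%02d", a))
      tc <- series[[k]]$truth$per_slice |>
        dplyr::group_by(roi = .data$roi) |>
        dplyr::summarise(truth_count = sum(.data$true_count),
                         .groups = "drop")
      tc <- dplyr::bind_rows(
        tibble::tibble(roi = "ALL", truth_count = sum(tc$truth_count)),
        tc)
      m$roi <- as.character(m$roi)
      m <- dplyr::left_join(m, tc, by = "roi")
      m$roi <- factor(m$roi, levels = ROI_LEVELS)
      m <- dplyr::mutate(m,
        truth_count = dplyr::coalesce(.data$truth_count, 0L))
      rows[[k]] <- m
    }
    out[[a]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(out)
}

#' Run configuration
#'
#' Assembles and validates the fully serializable configuration of a
#' pipeline run. All elements have defaults; the resolved configuration is
#' written back verbatim into the run directory so a run can be
#' reproduced from its own artifacts.
#'
#' @param out_dir Output directory for the run artifacts.
#' @param n_animals Number of simulated animals.
#' @param phantom Named list of [phantom_spec()] overrides.
#' @param detect Named list of [detect_params()] overrides.
#' @param thresholds_mm ROI depth cuts (mm).
#' @param regressor `"measured"` or `"nominal"`.
#' @param seed Master seed.
#' @param write_images Write label TIFFs and phantom stacks (default
#'   FALSE; CSV/JSON artifacts are always written).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(out_dir = tempfile("airspacer_run_"),
                       n_animals = 2L,
                       phantom = list(),
                       detect = list(),
                       thresholds_mm = c(2, 4),
                       regressor = c("measured", "nominal"),
                       seed = 17L,
                       write_images = FALSE) {
  cfg <- list(out_dir = out_dir,
              n_animals = as.integer(n_animals),
              phantom = phantom,
              detect = detect,
              thresholds_mm = thresholds_mm,
              regressor = match.arg(regressor),
              seed = as.integer(seed),
              write_images = isTRUE(write_images))
  # validate by constructing the component parameter objects
  do.call(phantom_spec, cfg$phantom)
  do.call(detect_params, cfg$detect)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Orchestrates phantom generation, detection, ROI partition, metrics and
#' the statistical report as one reproducible run: writes the per-ROI
#' metrics CSV, the report CSVs, a JSON manifest carrying the resolved
#' configuration and its hash, and (optionally) the image artifacts.
#' Identical configuration and seed reproduce byte-identical CSV outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `metrics`, `report` and the run
#'   directory `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(phantom_spec, config$phantom)
  params <- do.call(detect_params, config$detect)
  metrics <- simulate_experiment(
    n_animals = config$n_animals, spec = spec, params = params,
    thresholds_mm = config$thresholds_mm, seed = config$seed)
  report <- summarize_run(metrics, regressor = config$regressor)
  p <- function(...) file.path(config$out_dir, ...)
  readr::write_csv(metrics, p("metrics.csv"))
  readr::write_csv(report$summary, p("report_summary.csv"))
  readr::write_csv(report$regressions, p("report_regressions.csv"))
  readr::write_csv(report$f_tests, p("report_f_tests.csv"))
  readr::write_csv(report$wilcoxon, p("report_wilcoxon.csv"))
  cfg_path <- p("config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(
    package = "airspacer",
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n_rows_metrics = nrow(metrics),
    total_count = sum(metrics$count[metrics$roi == "ALL"]),
    files = c("metrics.csv", "report_summary.csv",
              "report_regressions.csv", "report_f_tests.csv",
              "report_wilcoxon.csv", "config.yaml"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(metrics = metrics, report = report,
                 out_dir = config$out_dir))
}
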