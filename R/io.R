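#' Read and write 1 Hz leaf traces
#'
#' The canonical interchange format is a tidy CSV, one row per second, with
#' mandatory columns `time_s` and at least one `chi_<compound>` channel, and
#' conventional environment columns `ppfd, t_leaf_c, co2_umol_mol,
#' q_flow_umol_s, a_net`.  Unknown extra columns are preserved.  A YAML
#' metadata sidecar (`<path>.meta.yml`) carries geometry and treatment
#' metadata.
#'
#' @param path CSV file path.
#' @return `read_trace()`: the trace tibble, with any sidecar metadata
#'   attached as attribute `meta`.  `write_trace()`: `path`, invisibly.
#' @export
read_trace <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_s" %in% names(tr)) abort(sprintf("%s: missing mandatory column time_s", path))
  if (!any(grepl("^chi_", names(tr)))) {
    abort(sprintf("%s: no chi_<compound> channel columns", path))
  }
  dup <- which(duplicated(tr$time_s))
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicated timestamp at data line %d (time_s = %g)",
                  path, dup[1], tr$time_s[dup[1]]))
  }
  if (is.unsorted(tr$time_s, strictly = TRUE)) {
    i <- which(diff(tr$time_s) <= 0)[1]
    abort(sprintf("%s: time_s not strictly increasing at data line %d", path, i + 1))
  }
  meta_path <- paste0(path, ".meta.yml")
  if (file.exists(meta_path)) {
    attr(tr, "meta") <- yaml::read_yaml(meta_path)
  }
  tr
}

#' @param trace Trace tibble.
#' @param meta Optional named list written to the YAML sidecar.
#' @rdname read_trace
#' @export
write_trace <- function(trace, path, meta = NULL) {
  readr::write_csv(trace, path)
  if (!is.null(meta)) {
    yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  }
  invisible(path)
}

#' Read and write simulator ground truth
#'
#' CSV keyed by `(t_leaf_c, co2, replicate)`, one row per simulated leaf.
#'
#' @param truth Truth tibble from [generate_experiment()].
#' @param path CSV file path.
#' @export
write_sim_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Per-leaf light-phase group emission means
#'
#' For each leaf, aggregates the blank-corrected compound fluxes into the six
#' VOC groups and averages each group over the light steady-state window
#' (the `ss_window` seconds before the dark transition) — the per-leaf
#' statistic the temperature-response figures and t-tests consume.
#'
#' @inheritParams analyze_experiment
#' @return Tibble: `trace_id, t_leaf_c, co2, replicate, group,
#'   flux_nmol_m2_s`.
#' @export
experiment_group_means <- function(traces, geom = chamber_geometry(),
                                   registry = default_channel_registry(),
                                   blanks = NULL, windows = decay_windows(),
                                   dynamic = FALSE) {
  rows <- purrr::map(seq_len(nrow(traces)), function(i) {
    tr <- traces$trace[[i]]
    blank <- NULL
    if (!is.null(blanks)) {
      j <- which(blanks$t_leaf_c == traces$t_leaf_c[i] &
                   blanks$co2 == traces$co2[i])
      if (length(j) >= 1) blank <- blanks$blank[[j[1]]]
    }
    fx <- compute_fluxes(tr, geom, registry, blank = blank, dynamic = dynamic,
                         trace_id = traces$trace_id[i])
    t_off <- detect_transition(tr)
    gx <- aggregate_groups(
      dplyr::filter(fx, .data$time_s >= t_off - windows$ss_window,
                    .data$time_s < t_off),
      registry
    )
    gx |>
      dplyr::summarise(flux_nmol_m2_s = mean(.data$flux_nmol_m2_s),
                       .by = c("trace_id", "group")) |>
      dplyr::mutate(t_leaf_c = traces$t_leaf_c[i], co2 = traces$co2[i],
                    replicate = traces$replicate[i], .after = "trace_id")
  })
  purrr::list_rbind(rows)
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run (simulate -> quantify -> decay
#' -> respond -> report) into a serializable list.  The effective
#' configuration of a run is written next to its outputs as YAML.
#'
#' @param out_dir Output directory for all artifact files.
#' @param seed Integer seed for the simulation stage.
#' @param sim A [sim_config()] (used when `traces_dir` is `NULL`).
#' @param traces_dir Optional directory of measured trace CSVs; when given,
#'   the simulation stage is skipped and traces are read from disk.
#' @param windows A [decay_windows()].
#' @param exclude_temps Temperatures excluded from substrate-control fits.
#' @param dynamic Use the dynamic mass balance (chamber storage term).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("vocflux_run_"), seed = 1,
                            sim = sim_config(), traces_dir = NULL,
                            windows = decay_windows(), exclude_temps = 40,
                            dynamic = NULL) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
         traces_dir = traces_dir, windows = windows,
         exclude_temps = exclude_temps,
         dynamic = dynamic %||% (sim$geometry$n_chamber > 0)),
    class = "pipeline_config"
  )
}

serialize_config <- function(config) {
  geom <- config$sim$geometry
  list(
    out_dir = config$out_dir, seed = config$seed,
    traces_dir = config$traces_dir,
    geometry = list(q_flow_umol_s = geom$q_flow, a_leaf_m2 = geom$a_leaf,
                    n_chamber_umol = geom$n_chamber),
    protocol = list(light_s = config$sim$light_s,
                    dark_s = config$sim$dark_s, dt = config$sim$dt),
    noise = list(cv_mult = config$sim$cv_mult, sd_add = config$sim$sd_add,
                 chi_bg = config$sim$chi_bg),
    windows = unclass(config$windows),
    exclude_temps = config$exclude_temps,
    dynamic = config$dynamic
  )
}

#' Run the full pipeline
#'
#' Orchestrates simulate -> flux quantification -> decay analysis ->
#' response statistics -> report tables, writing every artifact as CSV under
#' `config$out_dir` together with the resolved configuration
#' (`config.yml`).  Per-trace failures are isolated and logged in the decay
#' result table; the run continues.  Reruns with the same configuration and
#' seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory results: `decays`,
#'   `group_means`, `report`, `truth` (when simulated) and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  truth <- NULL
  if (is.null(config$traces_dir)) {
    say("simulate: %d traces (seed %d)", nrow(config$sim$grid), config$seed)
    exp <- generate_experiment(config$sim, seed = config$seed)
    traces <- exp$traces
    blanks <- exp$blanks
    truth <- exp$truth
    write_sim_truth(truth, file.path(config$out_dir, "sim_truth.csv"))
  } else {
    files <- sort(list.files(config$traces_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    files <- files[!grepl("blank|truth", basename(files))]
    if (length(files) == 0) abort("empty input set: no trace CSVs found")
    say("read: %d traces from %s", length(files), config$traces_dir)
    parsed <- purrr::map(files, function(f) {
      tryCatch(read_trace(f), error = function(e) {
        warn(sprintf("skipping %s: %s", basename(f), conditionMessage(e)))
        NULL
      })
    })
    keep <- !purrr::map_lgl(parsed, is.null)
    parsed <- parsed[keep]
    if (length(parsed) == 0) abort("empty input set: no readable trace CSVs")
    traces <- tibble::tibble(
      trace_id = sub("\\.csv$", "", basename(files[keep])),
      t_leaf_c = purrr::map_dbl(parsed, ~ .x$t_leaf_c[1]),
      co2 = purrr::map_dbl(parsed, ~ .x$co2_umol_mol[1]),
      replicate = seq_along(parsed),
      trace = parsed
    )
    blanks <- NULL
  }

  geom <- config$sim$geometry
  registry <- config$sim$registry

  say("decay: analyzing %d traces", nrow(traces))
  decays <- analyze_experiment(traces, geom, registry, blanks,
                               config$windows, dynamic = config$dynamic)
  readr::write_csv(decays, file.path(config$out_dir, "decay_results.csv"))
  n_fail <- sum(!is.na(decays$error))
  if (n_fail > 0) say("decay: %d trace(s) failed and were logged", n_fail)

  say("flux: per-leaf group emission means")
  group_means <- experiment_group_means(traces, geom, registry, blanks,
                                        config$windows,
                                        dynamic = config$dynamic)
  readr::write_csv(group_means, file.path(config$out_dir, "group_fluxes.csv"))

  say("respond: fits and treatment comparisons")
  a_net <- purrr::list_rbind(purrr::map(seq_len(nrow(traces)), function(i) {
    tibble::tibble(t_leaf_c = traces$t_leaf_c[i], co2 = traces$co2[i],
                   a_net = mean(traces$trace[[i]]$a_net))
  }))
  report <- build_report(decays, group_means = group_means, a_net = a_net,
                         exclude_temps = config$exclude_temps)

  files <- c(assimilation = "report_fig1.csv", dmadp_pool = "report_fig2.csv",
             substrate_control = "report_fig3.csv",
             group_response = "report_fig4.csv",
             ttests = "ttests.csv", sigmoid_params = "sigmoid_params.csv")
  for (nm in names(files)) {
    if (!is.null(report[[nm]])) {
      readr::write_csv(report[[nm]], file.path(config$out_dir, files[[nm]]))
    }
  }
  yaml::write_yaml(serialize_config(config),
                   file.path(config$out_dir, "config.yml"))
  say("done: artifacts in %s", config$out_dir)
  invisible(list(decays = decays, group_means = group_means, report = report,
                 truth = truth, out_dir = config$out_dir))
}

#' Write all simulated traces of an experiment to disk
#'
#' One CSV per leaf (plus YAML sidecar with treatment and geometry metadata)
#' and one per-cell blank CSV, in the interchange schema of [read_trace()].
#'
#' @param exp Result of [generate_experiment()].
#' @param dir Output directory.
#' @param geom The [chamber_geometry()] used (stored in the sidecars).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir, geom = chamber_geometry()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(exp$traces))) {
    id <- exp$traces$trace_id[i]
    write_trace(
      exp$traces$trace[[i]], file.path(dir, paste0(id, ".csv")),
      meta = list(trace_id = id,
                  t_leaf_c = exp$traces$t_leaf_c[i],
                  co2_umol_mol = exp$traces$co2[i],
                  replicate = exp$traces$replicate[i],
                  a_leaf_m2 = geom$a_leaf,
                  n_chamber_umol = geom$n_chamber)
    )
  }
  for (i in seq_len(nrow(exp$blanks))) {
    id <- sprintf("blank_T%02d_C%03d", exp$blanks$t_leaf_c[i], exp$blanks$co2[i])
    write_trace(exp$blanks$blank[[i]], file.path(dir, paste0(id, ".csv")))
  }
  write_sim_truth(exp$truth, file.path(dir, "sim_truth.csv"))
  invisible(dir)
}
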