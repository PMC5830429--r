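#' Read and write pipeline stage files
#'
#' Stage products are plain delimited text or JSON so every stage can be
#' audited and re-run from its stored inputs. Traces: columns time_s,
#' cell_id, ratio. Peak tables: cell_id, concentration_nM, replicate,
#' pulse_index, peak_log_response, qc_flag. Noise parameters and run reports
#' are JSON.
#'
#' @param path file path.
#' @param x object to write.
#' @name stage_io
NULL

#' @rdname stage_io
#' @export
read_trace_set <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "cell_id", "ratio")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0) {
    stop("trace file ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  tr
}

#' @rdname stage_io
#' @export
write_trace_set <- function(x, path) {
  utils::write.csv(x[, c("time_s", "cell_id", "ratio")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stage_io
#' @export
read_peak_table <- function(path) {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "concentration_nM", "replicate", "pulse_index",
            "peak_log_response")
  miss <- setdiff(need, names(pk))
  if (length(miss) > 0) {
    stop("peak table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(pk$qc_flag)) pk$qc_flag <- "ok"
  pk
}

#' @rdname stage_io
#' @export
write_peak_table <- function(x, path) {
  cols <- c("cell_id", "concentration_nM", "replicate", "pulse_index",
            "peak_log_response", "qc_flag")
  utils::write.csv(x[, intersect(cols, names(x))], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname stage_io
#' @export
read_noise_params <- function(path) {
  as.data.frame(jsonlite::fromJSON(path))
}

#' @rdname stage_io
#' @export
write_noise_params <- function(x, path) {
  jsonlite::write_json(x, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run configuration for the full analysis pipeline
#'
#' Exactly one entry point must be given: a \code{simulation_config} (the
#' run starts by generating synthetic data), a trace file, or a peak table
#' file.
#'
#' @param out_dir output directory (created if needed).
#' @param design a \code{stimulus_design}.
#' @param simulate optional \code{simulation_config}.
#' @param traces_file optional path to a trace CSV.
#' @param peaks_file optional path to a peak table CSV.
#' @param adaptation_correct apply the median-residual correction and
#'   re-estimate capacities on the corrected table.
#' @param grid_M interpolated-support size.
#' @param min_n_noise minimum pooled residuals per concentration for the
#'   noise fit.
#' @param with_traces when simulating, also render and process raw traces
#'   (slower); otherwise the generated peak table is used directly.
#' @param seed integer seed for the run.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(out_dir,
                       design = stimulus_design(),
                       simulate = NULL,
                       traces_file = NULL,
                       peaks_file = NULL,
                       adaptation_correct = TRUE,
                       grid_M = 101,
                       min_n_noise = 50,
                       with_traces = FALSE,
                       seed = 1L) {
  entries <- c(!is.null(simulate), !is.null(traces_file), !is.null(peaks_file))
  if (sum(entries) != 1) {
    stop("run_config: exactly one of simulate, traces_file, peaks_file")
  }
  structure(list(out_dir = out_dir, design = design, simulate = simulate,
                 traces_file = traces_file, peaks_file = peaks_file,
                 adaptation_correct = adaptation_correct, grid_M = grid_M,
                 min_n_noise = min_n_noise, with_traces = with_traces,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full channel-capacity pipeline
#'
#' Orchestrates simulate -> peak extraction -> residuals and noise fit ->
#' per-cell capacity (lower bound and interpolated) -> adaptation analysis,
#' writing every intermediate product under \code{config$out_dir} and a
#' machine-readable JSON report. Identical config and seed reproduce the
#' report byte for byte.
#'
#' @param config a \code{run_config}.
#' @param quiet suppress progress messages.
#' @return the run report (list), invisibly written to
#'   \code{out_dir/run_report.json}.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage_counts <- list()
  design <- config$design
  truth <- NULL

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$simulate)) {
    say("stage simulate")
    sim <- run_stage("simulate", {
      generate_peak_table(config$simulate, compute_truth = FALSE)
    })
    truth <- sim$truth
    if (config$with_traces) {
      traces <- run_stage("simulate", generate_traces(config$simulate,
                                                      sim$peaks))
      write_trace_set(traces, file.path(config$out_dir, "traces.csv"))
      say("stage peaks")
      peaks <- run_stage("peaks", extract_peak_table(traces, design))
    } else {
      peaks <- sim$peaks
    }
    write_peak_table(sim$peaks, file.path(config$out_dir,
                                          "peaks_generated.csv"))
  } else if (!is.null(config$traces_file)) {
    traces <- run_stage("peaks", read_trace_set(config$traces_file))
    say("stage peaks")
    peaks <- run_stage("peaks", extract_peak_table(traces, design))
  } else {
    peaks <- run_stage("peaks", read_peak_table(config$peaks_file))
  }
  write_peak_table(peaks, file.path(config$out_dir, "peaks.csv"))
  stage_counts$peaks <- nrow(peaks)

  say("stage residuals")
  residuals <- run_stage("residuals", compute_residuals(peaks))
  stage_counts$residuals <- nrow(residuals)

  say("stage fit-noise")
  noise <- run_stage("fit-noise", {
    fit_noise_model(residuals, min_n = config$min_n_noise)
  })
  write_noise_params(noise, file.path(config$out_dir, "noise_params.json"))
  stage_counts$noise_concentrations <- nrow(noise)

  say("stage capacity")
  caps <- run_stage("capacity", {
    estimate_population_capacity(peaks, noise, design, mode = "both",
                                 M = config$grid_M)
  })
  utils::write.csv(caps, file.path(config$out_dir, "capacity.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- summarize_population(caps)
  stage_counts$cells_estimated <- nrow(caps)

  say("stage adaptation")
  adapt <- run_stage("adaptation", {
    list(correlation = tryCatch(consecutive_correlation(peaks),
                                error = function(e) NULL),
         decay = tryCatch(fit_decay(peaks),
                          error = function(e) NULL))
  })
  corrected_summary <- NULL
  if (isTRUE(config$adaptation_correct)) {
    corrected <- run_stage("adaptation", adaptation_correct(peaks))
    write_peak_table(corrected, file.path(config$out_dir,
                                          "peaks_corrected.csv"))
    # the correction preserves group means; its benefit is the tightened
    # residuals, so the noise model is refit on the corrected table
    noise2 <- run_stage("adaptation", {
      fit_noise_model(corrected, min_n = config$min_n_noise)
    })
    write_noise_params(noise2, file.path(config$out_dir,
                                         "noise_params_corrected.json"))
    caps2 <- run_stage("adaptation", {
      estimate_population_capacity(corrected, noise2, design, mode = "both",
                                   M = config$grid_M)
    })
    utils::write.csv(caps2, file.path(config$out_dir,
                                      "capacity_corrected.csv"),
                     row.names = FALSE, quote = FALSE)
    corrected_summary <- summarize_population(caps2)
  }
  stage_counts$adaptation <- 1L

  report <- list(
    seed = config$seed,
    design = list(concentrations_nM = design$concentrations_nM,
                  n_replicates = design$n_replicates,
                  pulse_duration_s = design$pulse_duration_s,
                  gap_s = design$gap_s),
    settings = list(grid_M = config$grid_M,
                    min_n_noise = config$min_n_noise,
                    adaptation_correct = config$adaptation_correct,
                    with_traces = config$with_traces,
                    entry = if (!is.null(config$simulate)) "simulate"
                            else if (!is.null(config$traces_file)) "traces"
                            else "peaks"),
    stage_counts = stage_counts,
    noise_params = noise,
    capacity = list(
      lower_bound_mean_bits = summ$lower_bound$mean,
      lower_bound_sd_bits = summ$lower_bound$sd,
      interpolated_mean_bits = summ$interpolated$mean,
      interpolated_sd_bits = summ$interpolated$sd,
      n_cells = summ$n_cells),
    capacity_corrected = if (!is.null(corrected_summary)) list(
      lower_bound_mean_bits = corrected_summary$lower_bound$mean,
      interpolated_mean_bits = corrected_summary$interpolated$mean,
      n_cells = corrected_summary$n_cells) else NULL,
    adaptation = list(
      consecutive_r = if (!is.null(adapt$correlation))
        adapt$correlation$r else NULL,
      slope = if (!is.null(adapt$correlation))
        adapt$correlation$slope else NULL,
      decay_percent = if (!is.null(adapt$decay))
        adapt$decay$decay_percent else NULL,
      decay_ci_percent = if (!is.null(adapt$decay))
        adapt$decay$decay_ci_percent else NULL,
      drop_20_pulses_percent = if (!is.null(adapt$decay))
        adapt$decay$drop_20_pulses_percent else NULL))
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(report = report, capacity = caps, noise = noise,
                 peaks = peaks, truth = truth,
                 capacity_corrected = if (exists("caps2", inherits = FALSE))
                   caps2 else NULL))
}

#' Load a run configuration from a YAML file
#'
#' Flat key-value file mirroring the \code{run_config} arguments; the
#' optional \code{simulate:} block mirrors \code{simulation_config}
#' (n_cells, desensitization_d, seed, noise as parallel lists
#' concentration_nM / sigma / nu) and the \code{design:} block mirrors
#' \code{stimulus_design}.
#'
#' @param path YAML file.
#' @param out_dir output directory (overrides the file if given).
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  design <- if (is.null(y$design)) stimulus_design() else {
    do.call(stimulus_design, y$design)
  }
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    noise <- if (!is.null(s$noise)) as.data.frame(s$noise) else NULL
    sim <- simulation_config(
      n_cells = if (is.null(s$n_cells)) 100 else s$n_cells,
      design = design,
      noise = noise,
      desensitization_d = if (is.null(s$desensitization_d)) 0.99
                          else s$desensitization_d,
      seed = if (is.null(s$seed)) y$seed %||% 1L else s$seed)
  }
  run_config(out_dir = out_dir %||% y$out_dir %||% "chancap_run",
             design = design,
             simulate = sim,
             traces_file = y$traces_file,
             peaks_file = y$peaks_file,
             adaptation_correct = isTRUE(y$adaptation_correct %||% TRUE),
             grid_M = y$grid_M %||% 101,
             min_n_noise = y$min_n_noise %||% 50,
             with_traces = isTRUE(y$with_traces),
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
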