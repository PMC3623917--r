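#' Assemble and validate an analysis configuration
#'
#' A configuration fully describes one run: where the energy series come
#' from (files on disk, or a [synthetic_model()] to simulate), the time
#' scales to analyse, the window exponents, and the output options.
#'
#' @param input Either a list `list(paths =, dialect =, delta =, p_columns =,
#'   pw_columns =)` describing files to read, or `NULL` when `model` is
#'   given.
#' @param model A [synthetic_model()] to simulate instead of reading files.
#' @param n_traj Number of replicate trajectories to simulate from `model`.
#' @param scales Numeric vector of time scales tau (each an integer
#'   multiple of the sampling interval; strictly increasing). Defaults to
#'   8 logarithmic decades `delta * 10^(0:7)` at run time — the analysis's
#'   analogue of a 10 fs to 100 ns grid — of which infeasible scales are
#'   skipped with a warning.
#' @param m Window exponents; each window has `2^m` points. Default
#'   `c(5, 6)` so the robustness of conclusions to `m` is visible in every
#'   report.
#' @param max_windows Cap on windows per scale.
#' @param hist_bins Histogram bins per statistic per scale.
#' @param placement Window placement, `"even"` or `"random"`.
#' @param seed Integer seed governing simulation and random placement.
#' @param output_dir Where [run_analysis()] writes tables; `NULL` for none.
#' @param plots Whether [run_analysis()] also saves figures.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, model = NULL, n_traj = 1L,
                            scales = NULL, m = c(5L, 6L),
                            max_windows = 1000L, hist_bins = 50L,
                            placement = c("even", "random"), seed = 1L,
                            output_dir = NULL, plots = FALSE) {
  placement <- match.arg(placement)
  bad <- character(0)
  if (is.null(input) == is.null(model)) {
    stop_validation("exactly one of `input` or `model` must be given.")
  }
  if (!is.null(input)) {
    if (!is.list(input) || is.null(input$paths) || is.null(input$delta)) {
      bad <- c(bad, "input (needs $paths and $delta)")
    }
    if (is.null(input$dialect)) input$dialect <- "plain2col"
  }
  if (!is.null(model) && !inherits(model, "synthetic_model")) {
    bad <- c(bad, "model (not a synthetic_model)")
  }
  if (!is.null(scales)) {
    if (!is.numeric(scales) || length(scales) < 1L || any(scales <= 0) ||
        (length(scales) > 1L && any(diff(scales) <= 0))) {
      bad <- c(bad, "scales (must be positive and strictly increasing)")
    }
  }
  if (!is.numeric(m) || length(m) < 1L || any(m < 1)) bad <- c(bad, "m")
  if (!is.numeric(max_windows) || max_windows < 1) bad <- c(bad, "max_windows")
  if (!is.numeric(hist_bins) || hist_bins < 1) bad <- c(bad, "hist_bins")
  if (length(bad) > 0L) {
    stop_validation(paste0(
      "invalid configuration key(s): ", paste(bad, collapse = "; "), "."
    ))
  }
  structure(
    list(
      input = input, model = model, n_traj = as.integer(n_traj),
      scales = scales, m = as.integer(m),
      max_windows = as.integer(max_windows), hist_bins = as.integer(hist_bins),
      placement = placement, seed = as.integer(seed),
      output_dir = output_dir, plots = isTRUE(plots)
    ),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the arguments of [analysis_config()]; a `model` block holds
#' `components` (list of `theta`/`a`/`b`/`rho` maps), `mu_p`, `mu_w`,
#' `delta`, `n_steps` and `seed`.
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: '%s'", path))
  y <- yaml::read_yaml(path)
  model <- NULL
  if (!is.null(y$model)) {
    comps <- bind_rows(lapply(y$model$components, as_tibble))
    model <- synthetic_model(
      comps,
      mu_p = y$model$mu_p %||% 0, mu_w = y$model$mu_w %||% 0,
      delta = y$model$delta %||% 1,
      n_steps = y$model$n_steps,
      seed = y$model$seed %||% (y$seed %||% 1L)
    )
  }
  analysis_config(
    input = y$input, model = model, n_traj = y$n_traj %||% 1L,
    scales = if (!is.null(y$scales)) as.numeric(y$scales) else NULL,
    m = if (!is.null(y$m)) as.integer(y$m) else c(5L, 6L),
    max_windows = y$max_windows %||% 1000L,
    hist_bins = y$hist_bins %||% 50L,
    placement = y$placement %||% "even",
    seed = y$seed %||% 1L,
    output_dir = y$output_dir, plots = isTRUE(y$plots)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_scale_grid <- function(delta) delta * 10^(0:7)

#' Multi-scale correlation and roughness analysis of an energy series
#'
#' The core pipeline: for every window exponent `m` and every feasible time
#' scale tau, plan windows ([plan_windows()]), compute per-window
#' statistics ([window_stats()]) and aggregate them ([summarize_scale()]).
#' Scales the data cannot support (no trajectory admits a single window)
#' are skipped with a warning rather than failing the run; if no scale is
#' feasible a capacity error is raised.
#'
#' @param series An [energy_series()] tibble (one or many trajectories).
#' @param scales Time scales tau to analyse; defaults to the 8-decade grid
#'   `delta * 10^(0:7)` clipped to feasibility.
#' @param m Window exponents (windows of `2^m` points each).
#' @param max_windows,hist_bins,placement,seed See [analysis_config()].
#' @param keep_windows Keep the per-window tibbles in the report (needed
#'   for quadrant scatter plots and window dumps).
#' @return A `roughness_report`: list with `summaries` (tibble, one row per
#'   m and scale), `windows` (nested list of per-window tibbles),
#'   `skipped` (tibble of skipped scales), `delta`, `seed`.
#' @export
analyze_landscape <- function(series, scales = NULL, m = c(5L, 6L),
                              max_windows = 1000L, hist_bins = 50L,
                              placement = "even", seed = 1L,
                              keep_windows = TRUE) {
  delta <- sampling_interval(series)
  if (is.null(scales)) scales <- default_scale_grid(delta)
  summaries <- list()
  windows <- list()
  skipped <- list()
  for (mm in m) {
    mkey <- sprintf("m%d", mm)
    windows[[mkey]] <- list()
    for (tau in scales) {
      plan <- tryCatch(
        plan_windows(series, tau, m = mm, max_windows = max_windows,
                     placement = placement, seed = seed),
        roughscape_capacity_error = function(e) e
      )
      if (inherits(plan, "error")) {
        warn(sprintf("skipping infeasible scale tau = %g at m = %d: %s",
                     tau, mm, conditionMessage(plan)))
        skipped[[length(skipped) + 1L]] <- tibble(
          m = as.integer(mm), tau = tau, reason = conditionMessage(plan)
        )
        next
      }
      ws <- window_stats(series, plan)
      summaries[[length(summaries) + 1L]] <-
        summarize_scale(ws, tau = tau, m = mm, hist_bins = hist_bins)
      if (keep_windows) windows[[mkey]][[sprintf("tau%g", tau)]] <- ws
    }
  }
  if (length(summaries) == 0L) {
    stop_capacity("no requested scale is feasible for the supplied trajectories.")
  }
  structure(
    list(
      summaries = bind_rows(summaries),
      windows = windows,
      skipped = if (length(skipped)) bind_rows(skipped) else
        tibble(m = integer(0), tau = numeric(0), reason = character(0)),
      delta = delta,
      seed = as.integer(seed)
    ),
    class = "roughness_report"
  )
}

#' Run a configured analysis end to end
#'
#' Loads or simulates the trajectories described by the configuration,
#' runs [analyze_landscape()], and (when `output_dir` is set) writes the
#' report tables with [write_report()]. Re-running an identical
#' configuration reproduces identical output bytes.
#'
#' @param config An [analysis_config()].
#' @return The `roughness_report`, invisibly augmented with the config.
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "analysis_config")) {
    stop_validation("`config` must be an `analysis_config`.")
  }
  series <- if (!is.null(config$model)) {
    simulate_trajectory_set(config$model, config$n_traj, seed = config$seed)
  } else {
    parts <- lapply(config$input$paths, function(p) {
      read_energy_series(p, delta = config$input$delta,
                         dialect = config$input$dialect,
                         p_columns = config$input$p_columns,
                         pw_columns = config$input$pw_columns)
    })
    trajectory_set(parts)
  }
  report <- analyze_landscape(
    series,
    scales = config$scales, m = config$m,
    max_windows = config$max_windows, hist_bins = config$hist_bins,
    placement = config$placement, seed = config$seed
  )
  report$config <- config
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir, plots = config$plots)
  }
  report
}

#' Write a report's tables (and optional figures) to disk
#'
#' Per exponent `m`, a subdirectory `m<exponent>/` receives `summary.tsv`
#' (one row per scale), `histograms.json`, and one `windows_tau<tau>.tsv`
#' scatter dump per scale. A `manifest.json` at the top level records the
#' configuration hash, seed and versions. All tables are written
#' deterministically: identical reports give byte-identical files.
#'
#' @param report A `roughness_report`.
#' @param dir Output directory (created if needed).
#' @param plots Also save the standard figures as PDF.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mm in unique(report$summaries$m)) {
    mdir <- file.path(dir, sprintf("m%d", mm))
    dir.create(mdir, showWarnings = FALSE)
    sub <- report$summaries[report$summaries$m == mm, ]
    readr::write_tsv(sub[setdiff(names(sub), "histograms")],
                     file.path(mdir, "summary.tsv"))
    hists <- stats::setNames(sub$histograms, sprintf("tau%g", sub$tau))
    jsonlite::write_json(hists, file.path(mdir, "histograms.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    for (key in names(report$windows[[sprintf("m%d", mm)]])) {
      ws <- report$windows[[sprintf("m%d", mm)]][[key]]
      readr::write_tsv(ws, file.path(mdir, sprintf("windows_%s.tsv", key)))
    }
  }
  manifest <- list(
    package = "roughscape",
    version = as.character(utils::packageVersion("roughscape")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = report$seed,
    config_hash = if (!is.null(report$config)) {
      # hash only the analytical content: where the report is written must
      # not change what it contains
      rlang::hash(report$config[setdiff(names(report$config),
                                        c("output_dir", "plots"))])
    } else NA,
    scales = sort(unique(report$summaries$tau)),
    exponents = sort(unique(report$summaries$m))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (isTRUE(plots)) {
    save_plot <- function(p, name) {
      grDevices::pdf(file.path(dir, name), width = 7, height = 5)
      print(p)
      grDevices::dev.off()
    }
    save_plot(plot_correlation(report), "correlation.pdf")
    save_plot(plot_roughness(report), "roughness.pdf")
    save_plot(plot_probabilities(report), "probabilities.pdf")
    save_plot(plot_quadrants(report), "quadrants.pdf")
  }
  invisible(dir)
}

#' Compare summaries across window exponents
#'
#' Robustness check: conclusions should not depend on the window exponent
#' `m`. Produces a side-by-side table of `mean_r` and `mean_sigma_tot` per
#' scale and exponent, plus the maximum absolute discrepancy across
#' exponents per scale.
#'
#' @param reports A single `roughness_report` computed at two or more
#'   exponents, or a list of reports on the same data and scale grid.
#' @return A tibble with one row per scale: `mean_r_m<..>` and
#'   `mean_sigma_tot_m<..>` columns plus `max_abs_diff_r` and
#'   `max_abs_diff_sigma_tot`.
#' @export
compare_exponents <- function(reports) {
  summaries <- if (inherits(reports, "roughness_report")) {
    reports$summaries
  } else {
    if (!is.list(reports) || length(reports) < 2L) {
      stop_validation("supply one multi-exponent report or a list of >= 2 reports.")
    }
    grids <- lapply(reports, function(r) sort(unique(r$summaries$tau)))
    if (!all(vapply(grids[-1], identical, logical(1), grids[[1]]))) {
      stop_validation("reports use mismatched scale grids.")
    }
    bind_rows(lapply(reports, function(r) r$summaries))
  }
  ms <- sort(unique(summaries$m))
  if (length(ms) < 2L) {
    stop_validation("need summaries at two or more exponents to compare.")
  }
  wide <- summaries |>
    select("tau", "m", "mean_r", "mean_sigma_tot") |>
    tidyr::pivot_wider(
      names_from = "m",
      values_from = c("mean_r", "mean_sigma_tot"),
      names_glue = "{.value}_m{m}"
    ) |>
    arrange(.data$tau)
  rng <- function(row, prefix) {
    v <- as.numeric(row[startsWith(names(wide), prefix)])
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else max(v) - min(v)
  }
  wide$max_abs_diff_r <-
    apply(wide, 1L, rng, prefix = "mean_r_m")
  wide$max_abs_diff_sigma_tot <-
    apply(wide, 1L, rng, prefix = "mean_sigma_tot_m")
  wide
}

#' @export
print.roughness_report <- function(x, ...) {
  cat(sprintf(
    "<roughness_report> %d scale(s) x exponent(s) {%s}, delta = %g, seed = %d\n",
    length(unique(x$summaries$tau)),
    paste(sort(unique(x$summaries$m)), collapse = ", "),
    x$delta, x$seed
  ))
  print(select(x$summaries, -"histograms"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-scale summaries of a report
#'
#' @param x A `roughness_report`.
#' @param ... Unused.
#' @return The summaries tibble (one row per exponent and scale), without
#'   the histogram list-column.
#' @export
tidy.roughness_report <- function(x, ...) {
  as_tibble(select(x$summaries, -"histograms"))
}

#' One-row overview of a report
#'
#' @param x A `roughness_report`.
#' @param ... Unused.
#' @return A one-row tibble: scale and window counts, scale range, and the
#'   mean correlation at the smallest and largest analysed scale (largest
#'   exponent).
#' @export
glance.roughness_report <- function(x, ...) {
  s <- x$summaries
  mtop <- max(s$m)
  stop_ <- s[s$m == mtop, ]
  tibble(
    n_scales = length(unique(s$tau)),
    n_exponents = length(unique(s$m)),
    n_windows = sum(s$window_count),
    tau_min = min(s$tau),
    tau_max = max(s$tau),
    mean_r_smallest_scale = stop_$mean_r[which.min(stop_$tau)],
    mean_r_largest_scale = stop_$mean_r[which.max(stop_$tau)]
  )
}
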