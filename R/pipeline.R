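#' Assemble a full analysis configuration
#'
#' A run configuration names the bound and viscous replica sets (each either
#' a synthetic [pull_config()] or a directory of XVG pairs), the cutoff
#' policy, estimator settings, and optional experimental affinity inputs.
#'
#' @param bound,viscous one of: a [pull_config()] (synthetic generation), a
#'   string path to a directory of `pullf_*/pullx_*.xvg` pairs, or `NULL`
#'   (viscous only: the correction stage is skipped with a warning).
#' @param cutoff either `"auto"` (production cutoff from the error-bar
#'   crossing criterion, doubled) or a fixed pull-coordinate value.
#' @param convention work convention, see [accumulate_work()].
#' @param bin_width force-profile bin width; default total travel / 100.
#' @param boundary_coordinate pocket-threshold coordinate for the region
#'   partition; `NULL` places it at 29.4% of the total travel (1.47 for the
#'   reference travel of 5).
#' @param B,seed bootstrap settings.
#' @param n_bins work-histogram bins.
#' @param Ka,Ka_temperature optional experimental affinity constant (1/M) and
#'   its temperature (K) for the free-energy comparison.
#' @param output_dir optional directory; when set, [run_pipeline()] writes
#'   CSV/JSON outputs and a run manifest there.
#' @return a list of class `run_config`.
#' @export
run_config <- function(bound = pull_config(),
                       viscous = NULL,
                       cutoff = "auto",
                       convention = c("control_parameter", "com_path"),
                       bin_width = NULL,
                       boundary_coordinate = NULL,
                       B = 1000L, seed = 1L, n_bins = 20L,
                       Ka = NULL, Ka_temperature = 300,
                       output_dir = NULL) {
  convention <- match.arg(convention)
  check_source <- function(x, what) {
    ok <- is.null(x) || inherits(x, "pull_config") ||
      (is.character(x) && length(x) == 1)
    if (!ok) stop(what, " must be a pull_config, a directory path, or NULL",
                  call. = FALSE)
  }
  check_source(bound, "bound")
  check_source(viscous, "viscous")
  if (is.null(bound)) stop("a bound replica set is required", call. = FALSE)
  if (is.null(viscous) && inherits(bound, "pull_config")) {
    viscous <- viscous_control(bound)
  }
  if (!(identical(cutoff, "auto") ||
        (is.numeric(cutoff) && is.finite(cutoff) && cutoff > 0))) {
    stop("cutoff must be \"auto\" or a positive number", call. = FALSE)
  }
  structure(list(bound = bound, viscous = viscous, cutoff = cutoff,
                 convention = convention, bin_width = bin_width,
                 boundary_coordinate = boundary_coordinate,
                 B = as.integer(B), seed = as.integer(seed),
                 n_bins = as.integer(n_bins),
                 Ka = Ka, Ka_temperature = Ka_temperature,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' The file mirrors [run_config()]'s arguments; `bound`/`viscous` entries are
#' either a string (XVG directory) or an object of [pull_config()] fields,
#' with the potential spelled as `{form, depth, width, center}`. All unit
#' fields are explicit — the config declares its `units` per replica set.
#'
#' @param path a `.json`, `.yml` or `.yaml` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  parse_source <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) return(x)
    pot <- if (!is.null(x$potential)) {
      binding_potential(form = x$potential$form,
                        depth = x$potential$depth %||% numeric(),
                        width = x$potential$width %||% numeric(),
                        center = x$potential$center %||% numeric())
    } else binding_potential("flat")
    args <- x[setdiff(names(x), "potential")]
    do.call(pull_config, c(args, list(potential = pot)))
  }
  args <- raw[setdiff(names(raw), c("bound", "viscous"))]
  do.call(run_config, c(list(bound = parse_source(raw$bound),
                             viscous = parse_source(raw$viscous)), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run one pipeline stage with error context
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pulling analysis
#'
#' Orchestrates simulate/ingest -> work integration -> force profiles and
#' error-bar-crossing cutoff -> work samples -> estimators -> viscous
#' correction -> ordering checks -> region partition -> histogram summary,
#' deterministically under the configured seeds. When `output_dir` is set,
#' work series, profiles and samples are written as CSV, estimates and
#' reports as JSON, and a manifest records the config hash, seeds and package
#' version; identical config and seeds reproduce identical outputs.
#'
#' @param config a [run_config()] or a path to a JSON/YAML config file.
#' @return a list of class `pull_report` with every stage's results.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  get_set <- function(src, what) {
    stage(paste0("ingest ", what), {
      if (inherits(src, "pull_config")) simulate_replicas(src)
      else read_replica_set(src)
    })
  }
  bound_set <- get_set(config$bound, "bound")
  viscous_set <- if (!is.null(config$viscous))
    get_set(config$viscous, "viscous") else NULL

  conv <- config$convention
  bound_series <- stage("work integration (bound)",
    lapply(bound_set$trajectories, accumulate_work, convention = conv))
  viscous_series <- if (!is.null(viscous_set)) {
    stage("work integration (viscous)",
      lapply(viscous_set$trajectories, accumulate_work, convention = conv))
  }

  travel <- max(bound_series[[1]]$pull_coordinate)
  bin_width <- config$bin_width %||% (travel / 100)

  profile_bound <- stage("force profile (bound)",
    mean_force_profile(bound_set, bin_width))
  profile_viscous <- if (!is.null(viscous_set)) {
    stage("force profile (viscous)",
      mean_force_profile(viscous_set, bin_width))
  }

  crossing <- NULL
  if (identical(config$cutoff, "auto")) {
    if (is.null(profile_viscous)) {
      stop("pipeline stage 'cutoff': auto cutoff needs a viscous control set",
           call. = FALSE)
    }
    crossing <- stage("cutoff", errorbar_crossing(profile_bound,
                                                  profile_viscous))
    cutoff <- min(crossing$cutoff, travel)
  } else {
    cutoff <- config$cutoff
  }

  sample_bound <- stage("work sample (bound)",
    collect_work_sample(bound_series, cutoff))
  est_bound <- stage("estimate (bound)",
    estimate_work(sample_bound, B = config$B, seed = config$seed,
                  label = "bound"))

  sample_viscous <- est_viscous <- corrected <- NULL
  if (!is.null(viscous_series)) {
    sample_viscous <- stage("work sample (viscous)",
      collect_work_sample(viscous_series, cutoff))
    est_viscous <- stage("estimate (viscous)",
      estimate_work(sample_viscous, B = config$B, seed = config$seed + 1L,
                    label = "viscous"))
    corrected <- stage("viscous correction",
      viscous_correction(est_bound, est_viscous))
  } else {
    warning("no viscous control set: corrected result omitted", call. = FALSE)
  }

  # exact free-energy oracle, available in synthetic mode only
  delta_g <- ordering <- NULL
  if (inherits(config$bound, "pull_config") && config$bound$spring_k > 0) {
    cfg <- config$bound
    delta_g <- stage("analytic free energy",
      analytic_delta_g_spring(cfg$potential, cfg$spring_k, cfg$z0,
                              cfg$z0 + cutoff, cfg$temperature_T, cfg$units))
    ordering <- ordering_check(delta_g, est_bound)
  }

  delta_g_experimental <- if (!is.null(config$Ka)) {
    stage("affinity free energy",
      delta_g_from_ka(config$Ka, config$Ka_temperature))
  }

  boundary <- config$boundary_coordinate %||% (0.294 * travel)
  partition <- stage("region partition",
    partition_work(bound_series, boundary, travel))

  histogram <- if (!is.null(sample_viscous)) {
    stage("work histograms",
      work_histogram_summary(sample_bound, sample_viscous, config$n_bins))
  }

  report <- structure(
    list(config = config,
         cutoff = cutoff, crossing = crossing,
         profile_bound = profile_bound, profile_viscous = profile_viscous,
         work_series_bound = bound_series,
         work_series_viscous = viscous_series,
         sample_bound = sample_bound, sample_viscous = sample_viscous,
         estimate_bound = est_bound, estimate_viscous = est_viscous,
         corrected = corrected,
         delta_g_analytic = delta_g, ordering = ordering,
         delta_g_experimental = delta_g_experimental,
         partition = partition, histogram = histogram),
    class = "pull_report")

  if (!is.null(config$output_dir)) {
    stage("write outputs", write_report(report, config$output_dir))
  }
  report
}

# CSV/JSON outputs plus a deterministic run manifest
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  units <- report$sample_bound$units

  series_df <- function(series, label) {
    do.call(rbind, lapply(series, function(s) {
      data.frame(set = label, replica = s$replica_id,
                 pull_coordinate = s$pull_coordinate,
                 cumulative_work = s$cumulative_work)
    }))
  }
  ws <- series_df(report$work_series_bound, "bound")
  if (!is.null(report$work_series_viscous)) {
    ws <- rbind(ws, series_df(report$work_series_viscous, "viscous"))
  }
  utils::write.csv(ws, file.path(dir, "work_series.csv"), row.names = FALSE)

  prof_df <- function(p, label) {
    data.frame(set = label, bin_center = p$bin_centers,
               mean_force = p$mean_force_magnitude, sd_force = p$sd_force,
               n = p$n_per_bin)
  }
  pf <- prof_df(report$profile_bound, "bound")
  if (!is.null(report$profile_viscous)) {
    pf <- rbind(pf, prof_df(report$profile_viscous, "viscous"))
  }
  utils::write.csv(pf, file.path(dir, "force_profile.csv"), row.names = FALSE)

  samples <- data.frame(set = "bound", work = report$sample_bound$works)
  if (!is.null(report$sample_viscous)) {
    samples <- rbind(samples, data.frame(set = "viscous",
                                         work = report$sample_viscous$works))
  }
  utils::write.csv(samples, file.path(dir, "work_samples.csv"),
                   row.names = FALSE)

  est_list <- function(e) if (is.null(e)) NULL else
    e[c("Wa", "Wx", "se_Wa", "se_Wx", "N_s", "temperature_T", "units",
        "convention", "label")]
  out <- list(
    units = units,
    cutoff = report$cutoff,
    crossing = report$crossing,
    estimates = list(bound = est_list(report$estimate_bound),
                     viscous = est_list(report$estimate_viscous),
                     corrected = est_list(report$corrected)),
    delta_g_analytic = report$delta_g_analytic,
    ordering = if (!is.null(report$ordering)) unclass(report$ordering),
    delta_g_experimental_J = report$delta_g_experimental,
    partition = unclass(report$partition),
    histogram_separation = if (!is.null(report$histogram)) list(
      standardized_mean_difference =
        report$histogram$standardized_mean_difference,
      overlap_coefficient = report$histogram$overlap_coefficient)
  )
  jsonlite::write_json(out, file.path(dir, "estimates.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  cfg_echo <- report$config
  cfg_echo$output_dir <- NULL # implicit: it is the directory itself
  cfg_json <- jsonlite::serializeJSON(cfg_echo)
  tmp <- file.path(dir, "config_echo.json")
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "pullwork",
    version = as.character(utils::packageVersion("pullwork")),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = report$config$seed,
    base_seed_bound = if (inherits(report$config$bound, "pull_config"))
      report$config$bound$seed,
    base_seed_viscous = if (inherits(report$config$viscous, "pull_config"))
      report$config$viscous$seed,
    files = c("work_series.csv", "force_profile.csv", "work_samples.csv",
              "estimates.json", "config_echo.json")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(dir)
}

#' @export
print.pull_report <- function(x, ...) {
  kbt <- x$sample_bound$kbt
  cat("<pull_report>\n")
  cat(sprintf("  production cutoff: %.4g%s\n", x$cutoff,
              if (!is.null(x$crossing))
                sprintf(" (error-bar crossing at %.4g, doubled)",
                        x$crossing$crossing) else " (fixed)"))
  print(x$estimate_bound)
  if (!is.null(x$estimate_viscous)) print(x$estimate_viscous)
  if (!is.null(x$corrected)) {
    cat(sprintf("  corrected Wx = %.4g +/- %.3g (display: %g +/- %g)\n",
                x$corrected$Wx, x$corrected$se_Wx,
                x$corrected$display_Wx, x$corrected$display_se_Wx))
  }
  if (!is.null(x$delta_g_analytic)) {
    cat(sprintf("  analytic dG (0 -> cutoff): %.4g (%.4g kBT)\n",
                x$delta_g_analytic, x$delta_g_analytic / kbt))
  }
  if (!is.null(x$ordering)) print(x$ordering)
  if (!is.null(x$delta_g_experimental)) {
    cat(sprintf("  experimental dG from Ka: %.4g J\n",
                x$delta_g_experimental))
  }
  print(x$partition)
  if (!is.null(x$histogram)) print(x$histogram)
  invisible(x)
}
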