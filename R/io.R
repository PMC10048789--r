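#' Serialise model parameters to / from YAML
#'
#' The YAML layout uses `weights.{a..h}`, either a scalar `av_all` or a
#' per-element `av` map, `hv`, a `constants` block (gain, sat_denominator,
#' time_halflife, act_feedback_divisor, upstream_divisor), a `delays`
#' block and an `options` block. Round-trips are lossless.
#'
#' @param params A `model_parameters`.
#' @param path File path.
#' @export
write_parameters_yaml <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  av <- if (length(unique(params$av)) == 1)
    list(av_all = unname(params$av[[1]]))
  else list(av = as.list(params$av))
  obj <- c(list(weights = lapply(params$weights, function(w)
                  as.list(unname(w)))),
           av,
           list(hv = params$hv,
                constants = list(gain = params$gain,
                                 sat_denominator = params$sat_denominator,
                                 time_halflife = params$time_halflife,
                                 act_feedback_divisor =
                                   params$act_feedback_divisor,
                                 upstream_divisor = params$upstream_divisor),
                delays = as.list(params$delay_times),
                options = params$options))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_parameters_yaml
#' @param taxonomy A `cause_taxonomy`.
#' @export
read_parameters_yaml <- function(path, taxonomy = default_taxonomy()) {
  y <- yaml::read_yaml(path)
  known <- c("weights", "av", "av_all", "hv", "constants", "delays",
             "options")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown parameter keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  w <- if (is.null(y$weights)) default_weights(taxonomy)
       else weight_table(lapply(y$weights, unlist), taxonomy = taxonomy)
  av <- if (!is.null(y$av)) unlist(y$av) else if (!is.null(y$av_all))
    y$av_all else 60
  cst <- y$constants %||% list()
  model_parameters(
    weights = w, av = av, hv = y$hv %||% 0,
    gain = cst$gain %||% 1.5,
    sat_denominator = cst$sat_denominator %||% 80,
    time_halflife = cst$time_halflife %||% 6,
    act_feedback_divisor = cst$act_feedback_divisor %||% 4,
    upstream_divisor = cst$upstream_divisor %||% 2,
    delay_times = if (is.null(y$delays))
      c(SC_down = 1, SM_up = 0.25, SM_down = 0.5, SA_up = 0.25,
        SA_down = 0.25) else unlist(y$delays),
    options = y$options %||% list(),
    taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a run configuration
#'
#' A run configuration is a YAML file with up to five blocks:
#'
#' * `paths`: `params` (parameter YAML), `cause_records` (CSV),
#'   `out_dir`;
#' * `scenario`: `label`, `hv`, `av`, `overrides` (map), or grids
#'   `hv_set` / `av_set`;
#' * `engine`: `t0`, `t_end`, `dt` and option flags `sm1`, `sa_damping`,
#'   `ua_outflow`, `delay_init`;
#' * `seed`: integer seed for synthetic generation;
#' * `log_level`: `"quiet"` or `"info"`.
#'
#' Defaults are filled (t0 = 0, t_end = 24, dt = 0.25, hv = 0, av = 60),
#' unknown keys are rejected, and the time grid is validated to close
#' exactly.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list with components `paths`,
#'   `scenario`, `engine` (including a ready [sim_config()] as
#'   `engine$config`), `options`, `seed`, `log_level`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  y <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config parse error: ", conditionMessage(e), call. = FALSE))
  if (!is.list(y)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("paths", "scenario", "engine", "seed", "log_level")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)

  paths <- y$paths %||% list()
  bad <- setdiff(names(paths), c("params", "cause_records", "out_dir"))
  if (length(bad))
    stop("unknown `paths` keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (k in c("params", "cause_records"))
    if (!is.null(paths[[k]]) && !file.exists(paths[[k]]))
      stop(sprintf("`paths.%s` does not exist: %s", k, paths[[k]]),
           call. = FALSE)

  sc <- y$scenario %||% list()
  bad <- setdiff(names(sc),
                 c("label", "hv", "av", "overrides", "hv_set", "av_set"))
  if (length(bad))
    stop("unknown `scenario` keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sc$label <- sc$label %||% "run"
  sc$hv <- sc$hv %||% 0
  sc$av <- sc$av %||% 60
  if (sc$hv < 0 || sc$hv > 1)
    stop("`scenario.hv` must lie in [0, 1]", call. = FALSE)
  if (sc$av < 0 || sc$av > 100)
    stop("`scenario.av` must lie in [0, 100]", call. = FALSE)

  en <- y$engine %||% list()
  opt_keys <- c("sm1", "sa_damping", "ua_outflow", "delay_init")
  bad <- setdiff(names(en), c("t0", "t_end", "dt", opt_keys))
  if (length(bad))
    stop("unknown `engine` keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  config <- sim_config(en$t0 %||% 0, en$t_end %||% 24, en$dt %||% 0.25)
  options <- en[intersect(opt_keys, names(en))]

  seed <- y$seed %||% NULL
  if (!is.null(seed) && (length(seed) != 1 || seed != round(seed)))
    stop("`seed` must be a single integer", call. = FALSE)
  log_level <- y$log_level %||% "info"
  if (!log_level %in% c("quiet", "info"))
    stop("`log_level` must be 'quiet' or 'info'", call. = FALSE)

  structure(list(paths = paths, scenario = sc,
                 engine = c(en[setdiff(names(en), opt_keys)],
                            list(config = config)),
                 options = options, seed = seed, log_level = log_level),
            class = "run_config")
}

#' Save a run configuration
#' @param config A `run_config`.
#' @param path File path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  en <- config$engine$config
  y <- list(paths = config$paths,
            scenario = config$scenario,
            engine = c(list(t0 = en$t0, t_end = en$t_end, dt = en$dt),
                       config$options),
            seed = config$seed, log_level = config$log_level)
  y <- y[!vapply(y, function(x) is.null(x) || length(x) == 0, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write scenario summaries as CSV
#'
#' Tidy CSV `scenario,hv,av,stock,peak_value,peak_time,trough_time,
#' final_value`.
#'
#' @param summaries Data frame as returned by [grid_run()].
#' @param path File path.
#' @export
write_summary_csv <- function(summaries, path) {
  need <- c("scenario", "hv", "av", "stock", "peak_value", "peak_time",
            "trough_time", "final_value")
  stopifnot(is.data.frame(summaries), all(need %in% names(summaries)))
  utils::write.csv(summaries[, need, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a bundle of run outputs plus a manifest
#'
#' Writes trajectory CSVs, summary CSVs and ranking JSONs into `out_dir`
#' and a `manifest.json` recording the files, the package version, the
#' seed and an optional config echo. File contents are deterministic for
#' deterministic inputs.
#'
#' @param trajectories Named list of `sd_trajectory` objects (may be
#'   empty).
#' @param summaries Named list of summary data frames.
#' @param rankings Named list of `influence_ranking` objects.
#' @param out_dir Output directory (created if needed).
#' @param config_echo Optional list echoed into the manifest.
#' @param seed Optional seed echoed into the manifest.
#' @return The manifest, invisibly (also written as JSON).
#' @export
write_outputs <- function(trajectories = list(), summaries = list(),
                          rankings = list(), out_dir,
                          config_echo = NULL, seed = NULL) {
  if (length(trajectories) + length(summaries) + length(rankings) == 0)
    stop("nothing to write: all output collections are empty",
         call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character(0)
  emit <- function(obj, nm, suffix, writer) {
    fn <- file.path(out_dir, paste0(nm, suffix))
    writer(obj, fn)
    files <<- c(files, basename(fn))
  }
  for (nm in names(trajectories))
    emit(trajectories[[nm]], nm, "_trajectory.csv", write_trajectory_csv)
  for (nm in names(summaries))
    emit(summaries[[nm]], nm, "_summary.csv", write_summary_csv)
  for (nm in names(rankings))
    emit(rankings[[nm]], nm, "_ranking.json", write_ranking_json)
  manifest <- list(
    package = "safetysd",
    version = as.character(utils::packageVersion("safetysd")),
    seed = seed, files = as.list(files), config = config_echo)
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, "manifest.json")
  manifest$files <- as.list(files)
  invisible(manifest)
}
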