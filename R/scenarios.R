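#' Define a simulation scenario
#'
#' A scenario fixes the initial safety level `hv` (0 for a new mine,
#' 0.25/0.5/0.75 for production mines), a baseline construction standard
#' `av` applied to every element, optional AV overrides for single
#' elements, whole weight groups or whole layers, and optional model
#' option flags.
#'
#' Override names may be AV element codes (e.g. `"SM1"`, `"SC4"`), weight
#' group ids (`"a"`, `"b"`, `"c"`, `"e"`, `"f"`, `"g"`), or layer ids
#' (`"sc"`, `"sm"`, `"sa"`), each mapped to the set of elements feeding
#' that unit.
#'
#' @param label Scenario label.
#' @param hv Initial safety level in `[0, 1]`.
#' @param av Baseline construction standard in `[0, 100]`.
#' @param overrides Named numeric vector/list of AV overrides (may be
#'   `NULL`).
#' @param options Model option flags passed through to
#'   [model_parameters()].
#' @return An object of class `scenario`.
#' @export
scenario <- function(label = "scenario", hv = 0, av = 60, overrides = NULL,
                     options = list()) {
  if (hv < 0 || hv > 1) stop("`hv` must lie in [0, 1]", call. = FALSE)
  if (av < 0 || av > 100) stop("`av` must lie in [0, 100]", call. = FALSE)
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    if (is.null(names(overrides)))
      stop("`overrides` must be named", call. = FALSE)
    if (any(overrides < 0 | overrides > 100))
      stop("override AVs must lie in [0, 100]", call. = FALSE)
  }
  structure(list(label = label, hv = hv, av = av, overrides = overrides,
                 options = options), class = "scenario")
}

#' Elements feeding each layer
#'
#' The construction standard of a layer is carried by the AV elements that
#' feed it: the culture categories for SC; the policy standard plus the
#' structure and procedure sub-elements for SM; the knowledge, awareness
#' and psychology sub-elements plus the habit element for SA.
#'
#' @param layer One of `"sc"`, `"sm"`, `"sa"`.
#' @param taxonomy A `cause_taxonomy`.
#' @return Character vector of AV element codes.
#' @export
layer_elements <- function(layer, taxonomy = default_taxonomy()) {
  switch(match.arg(layer, c("sc", "sm", "sa")),
    sc = taxonomy$a$elements,
    sm = c("SM1", taxonomy$b$elements, taxonomy$c$elements),
    sa = c(taxonomy$e$elements, taxonomy$f$elements, "SA31",
           taxonomy$g$elements))
}

#' Resolve scenario override names to AV element codes
#' @keywords internal
resolve_override_codes <- function(name, taxonomy) {
  codes <- av_elements(taxonomy)
  if (name %in% codes) return(name)
  if (name %in% c("a", "b", "c", "e", "f", "g"))
    return(taxonomy[[name]]$elements)
  if (name %in% c("sc", "sm", "sa"))
    return(layer_elements(name, taxonomy))
  stop("unknown AV override target: ", name, call. = FALSE)
}

#' Run one scenario
#'
#' Builds the parameterisation (baseline AV, overrides, initial level,
#' option flags layered over `params`) and integrates the model.
#'
#' @param scen A [scenario()].
#' @param params Base `model_parameters` supplying weights, constants,
#'   delays and default options.
#' @param config A [sim_config()].
#' @return An `sd_trajectory`.
#' @examples
#' traj <- run_scenario(scenario(hv = 0, av = 80))
#' all(diff(traj$UA) >= 0)   # new-mine safe acts keep increasing
#' @export
run_scenario <- function(scen, params = default_parameters(),
                         config = sim_config()) {
  stopifnot(inherits(scen, "scenario"), inherits(params, "model_parameters"))
  tax <- params$taxonomy
  codes <- av_elements(tax)
  av <- stats::setNames(rep(scen$av, length(codes)), codes)
  for (nm in names(scen$overrides))
    av[resolve_override_codes(nm, tax)] <- scen$overrides[[nm]]
  p <- model_parameters(
    weights = params$weights, av = av, hv = scen$hv,
    gain = params$gain, sat_denominator = params$sat_denominator,
    time_halflife = params$time_halflife,
    act_feedback_divisor = params$act_feedback_divisor,
    upstream_divisor = params$upstream_divisor,
    delay_times = params$delay_times,
    options = utils::modifyList(params$options, scen$options),
    taxonomy = tax)
  run_model(p, config)
}

#' Summarise a trajectory
#'
#' Per stock: the peak value, peak time (earliest grid time attaining the
#' maximum), the trough time after the peak (earliest grid time attaining
#' the post-peak minimum, reported only when that minimum lies strictly
#' below the peak value; `NA` otherwise) and the final value.
#'
#' @param traj An `sd_trajectory` (or any data frame with a `time` column
#'   and one column per series).
#' @return A data frame with columns `stock`, `peak_value`, `peak_time`,
#'   `trough_time`, `final_value`.
#' @export
summarize_trajectory <- function(traj) {
  stopifnot(is.data.frame(traj), "time" %in% names(traj), nrow(traj) > 0)
  stocks <- setdiff(names(traj), "time")
  rows <- lapply(stocks, function(s) {
    v <- traj[[s]]
    ip <- which.max(v)                       # earliest tie by which.max
    trough <- NA_real_
    if (ip < length(v)) {
      after <- v[(ip + 1):length(v)]
      it <- which.min(after)
      if (after[it] < v[ip])
        trough <- traj$time[ip + it]
    }
    data.frame(stock = s, peak_value = v[ip], peak_time = traj$time[ip],
               trough_time = trough, final_value = v[length(v)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build an influence ranking from named effects
#' @keywords internal
as_influence_ranking <- function(effects) {
  ord <- order(-unlist(effects))
  out <- data.frame(factor = names(effects)[ord],
                    effect = unname(unlist(effects))[ord],
                    rank = seq_along(effects), stringsAsFactors = FALSE)
  class(out) <- c("influence_ranking", "data.frame")
  out
}

#' Mean response difference between an experiment and a baseline run
#' @keywords internal
mean_effect <- function(traj_exp, traj_base, stock, window = NULL) {
  keep <- rep(TRUE, nrow(traj_base))
  if (!is.null(window))
    keep <- traj_base$time >= window[1] & traj_base$time <= window[2]
  mean(traj_exp[[stock]][keep] - traj_base[[stock]][keep])
}

#' Layer influence on safe acts
#'
#' For each layer (safety culture, safety management system, safety
#' ability), runs the model with only that layer's element AVs raised from
#' `baseline_av` to `raised_av` and measures the effect as the
#' time-averaged difference in the safe-acts stock UA against the
#' unraised baseline, optionally over a time window (the published
#' contrast is clearest in months 10–18).
#'
#' @param hv Initial safety level.
#' @param baseline_av Baseline construction standard.
#' @param raised_av Raised standard, `>= baseline_av`.
#' @param params Base `model_parameters`.
#' @param config A [sim_config()].
#' @param window Optional `c(from, to)` months restricting the average.
#' @return An `influence_ranking` data frame (`factor`, `effect`, `rank`),
#'   sorted by effect descending.
#' @export
layer_influence_experiment <- function(hv, baseline_av, raised_av,
                                       params = default_parameters(),
                                       config = sim_config(),
                                       window = NULL) {
  if (raised_av < baseline_av)
    stop("`raised_av` must be >= `baseline_av`", call. = FALSE)
  base <- run_scenario(scenario("baseline", hv, baseline_av),
                       params, config)
  layers <- c("safety culture" = "sc",
              "safety management system" = "sm",
              "safety ability" = "sa")
  effects <- lapply(layers, function(ly) {
    ov <- stats::setNames(list(raised_av), ly)
    exp_traj <- run_scenario(scenario(ly, hv, baseline_av, overrides = ov),
                             params, config)
    mean_effect(exp_traj, base, "UA", window)
  })
  as_influence_ranking(effects)
}

#' Element categories within a weight group
#'
#' Maps each category of a group to the AV element codes it raises and to
#' the parent stock whose response is measured. Groups `a`, `d` and `h`
#' have composite categories (e.g. the `d`-group "organisational
#' structure" category raises all `b`-group sub-element AVs); in the
#' remaining groups every element is its own category.
#'
#' @param group_id A weight-group id.
#' @param taxonomy A `cause_taxonomy`.
#' @return List with `response_stock` and `categories` (a named list of
#'   element-code vectors).
#' @export
group_categories <- function(group_id, taxonomy = default_taxonomy()) {
  per_element <- function(g, stock) {
    list(response_stock = stock,
         categories = stats::setNames(as.list(g$elements),
                                      unname(g$labels[g$elements])))
  }
  switch(group_id,
    a = per_element(taxonomy$a, "SC"),
    b = per_element(taxonomy$b, "SM2"),
    c = per_element(taxonomy$c, "SM3"),
    d = list(response_stock = "SM",
             categories = list(
               "safety policy" = "SM1",
               "safety management organisational structure" =
                 taxonomy$b$elements,
               "safety management procedures" = taxonomy$c$elements)),
    e = per_element(taxonomy$e, "SA1"),
    f = per_element(taxonomy$f, "SA2"),
    g = per_element(taxonomy$g, "SA4"),
    h = list(response_stock = "SA",
             categories = list(
               "safety knowledge" = taxonomy$e$elements,
               "safety awareness" = taxonomy$f$elements,
               "safety habits" = "SA31",
               "safety psychology" = taxonomy$g$elements)),
    stop("unknown weight group: ", group_id, call. = FALSE))
}

#' Element influence within a layer
#'
#' For each element category of a weight group, runs the model with only
#' that category's AVs raised and measures the time-averaged difference
#' of the group's parent stock (SC for group `a`, SM for `d`, SA for `h`)
#' against the baseline.
#'
#' @inheritParams layer_influence_experiment
#' @param group_id Weight group id (see [group_categories()]).
#' @param response_stock Stock whose response is averaged; defaults to the
#'   group's parent stock.
#' @return An `influence_ranking` data frame.
#' @export
element_influence_experiment <- function(group_id, hv, baseline_av,
                                         raised_av,
                                         params = default_parameters(),
                                         config = sim_config(),
                                         response_stock = NULL,
                                         window = NULL) {
  if (raised_av < baseline_av)
    stop("`raised_av` must be >= `baseline_av`", call. = FALSE)
  gc <- group_categories(group_id, params$taxonomy)
  stock <- if (is.null(response_stock)) gc$response_stock else response_stock
  base <- run_scenario(scenario("baseline", hv, baseline_av),
                       params, config)
  effects <- lapply(gc$categories, function(codes) {
    ov <- stats::setNames(rep(list(raised_av), length(codes)), codes)
    exp_traj <- run_scenario(
      scenario("experiment", hv, baseline_av, overrides = ov),
      params, config)
    mean_effect(exp_traj, base, stock, window)
  })
  as_influence_ranking(effects)
}

#' Factorial HV x AV scenario batch
#'
#' Runs every combination of initial safety level and construction
#' standard and stacks the per-stock trajectory summaries into one tidy
#' table.
#'
#' @param hv_set Numeric vector of initial safety levels.
#' @param av_set Numeric vector of construction standards.
#' @param params Base `model_parameters`.
#' @param config A [sim_config()].
#' @return Data frame with columns `scenario`, `hv`, `av`, `stock`,
#'   `peak_value`, `peak_time`, `trough_time`, `final_value`.
#' @export
grid_run <- function(hv_set, av_set, params = default_parameters(),
                     config = sim_config()) {
  stopifnot(length(hv_set) > 0, length(av_set) > 0)
  rows <- list()
  for (hv in hv_set) for (av in av_set) {
    lab <- sprintf("hv%03.0f_av%02.0f", 100 * hv, av)
    traj <- run_scenario(scenario(lab, hv, av), params, config)
    s <- summarize_trajectory(traj)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(scenario = lab, hv = hv, av = av,
                       stringsAsFactors = FALSE), s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an influence ranking as JSON
#'
#' A JSON array of `{factor, effect, rank}` records.
#'
#' @param ranking An `influence_ranking`.
#' @param path File path.
#' @export
write_ranking_json <- function(ranking, path) {
  stopifnot(is.data.frame(ranking),
            all(c("factor", "effect", "rank") %in% names(ranking)))
  jsonlite::write_json(ranking[, c("factor", "effect", "rank")], path,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
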