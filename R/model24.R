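#' Rate-equation building blocks
#'
#' The model's rates are built from four saturating cores, all written with
#' base-2 exponentials so that each "half" constant has a direct reading:
#'
#' * `element_uptake(S, t)` `= (1 - 2^(-S/80)) * 2^(-t/6)`: uptake of a
#'   stock from its weighted element construction standards
#'   `S = sum(w_i * AV_i)` (0–100 scale). At `S = 80` the saturation factor
#'   is exactly 0.5; the time factor halves every 6 months, representing
#'   the fading novelty of a fixed construction program.
#' * `layer_uptake_core(up, W, n, self)`
#'   `= 1.5 * (1 - 2^(-up/2)) * (1 - 2^(-W/n)) * 2^(-self)`: transfer from
#'   an upstream layer at level `up`, gated by the weighted sub-stock sum
#'   `W` (group size `n`), and damped by the receiving level `self`.
#' * `feedback_decay_core(UA)` `= 1 - 2^(-UA/4)`: the negative behavioural
#'   feedback of established safe acts on the upstream layers (fed through
#'   DELAY1s).
#' * `acts_uptake(SA, UA)` `= (1 - 2^(-SA/2)) * 2^(-UA)`: formation of safe
#'   acts from current safety ability, damped by the acts level already
#'   attained.
#'
#' @param weighted_av_sum Weighted element construction standard `S >= 0`
#'   (0–100 scale).
#' @param time Simulation time in months.
#' @param sat Saturation denominator for element uptake (default 80).
#' @param halflife Half-life of the time damping in months (default 6).
#' @return A nonnegative rate per month.
#' @export
element_uptake <- function(weighted_av_sum, time, sat = 80, halflife = 6) {
  if (any(weighted_av_sum < 0))
    stop("`weighted_av_sum` must be nonnegative", call. = FALSE)
  (1 - 2^(-weighted_av_sum / sat)) * 2^(-time / halflife)
}

#' @rdname element_uptake
#' @param upstream Upstream layer level in `[0, 1]`.
#' @param weighted_substock_sum Weighted sum `W` of the receiving layer's
#'   sub-stocks, in `[0, n]`.
#' @param n Group size (number of sub-stocks), `> 0`.
#' @param self_level Receiving layer level in `[0, 1]`.
#' @param gain Layer-uptake gain (default 1.5).
#' @param upstream_divisor Divisor applied to the upstream level (default 2).
#' @export
layer_uptake_core <- function(upstream, weighted_substock_sum, n, self_level,
                              gain = 1.5, upstream_divisor = 2) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  if (any(upstream < 0 | upstream > 1) || any(self_level < 0 | self_level > 1))
    stop("layer levels must lie in [0, 1]", call. = FALSE)
  if (any(weighted_substock_sum < 0))
    stop("`weighted_substock_sum` must be nonnegative", call. = FALSE)
  gain * (1 - 2^(-upstream / upstream_divisor)) *
    (1 - 2^(-weighted_substock_sum / n)) * 2^(-self_level)
}

#' @rdname element_uptake
#' @param ua_level Safe-acts level in `[0, 1]`.
#' @param divisor Feedback divisor (default 4).
#' @export
feedback_decay_core <- function(ua_level, divisor = 4) {
  if (any(ua_level < 0 | ua_level > 1))
    stop("`ua_level` must lie in [0, 1]", call. = FALSE)
  1 - 2^(-ua_level / divisor)
}

#' @rdname element_uptake
#' @param sa_level Safety-ability level in `[0, 1]`.
#' @export
acts_uptake <- function(sa_level, ua_level) {
  if (any(sa_level < 0 | sa_level > 1) || any(ua_level < 0 | ua_level > 1))
    stop("levels must lie in [0, 1]", call. = FALSE)
  (1 - 2^(-sa_level / 2)) * 2^(-ua_level)
}

#' Elements carrying a construction standard (AV)
#'
#' All elements whose construction standard enters an element-uptake sum:
#' the culture categories (group a), the SM2/SM3 sub-elements (b, c), the
#' SA1/SA2/SA4 sub-elements (e, f, g), the single SA3 habit element
#' `SA31`, and the safety-policy standard `SM1`.
#'
#' @param taxonomy A `cause_taxonomy`.
#' @return Character vector of AV element codes.
#' @export
av_elements <- function(taxonomy = default_taxonomy()) {
  c(taxonomy$a$elements, "SM1", taxonomy$b$elements, taxonomy$c$elements,
    taxonomy$e$elements, taxonomy$f$elements, "SA31", taxonomy$g$elements)
}

#' Model parameters
#'
#' Bundles everything the rate equations need: the layer weight table, the
#' per-element construction standards `AV` (0–100), the initial safety
#' level `HV` (0–1 ratio applied to every stock), the saturation/gain
#' constants, the five material-delay times, and the option flags that
#' record how ambiguities in the published equation list are resolved.
#'
#' Option flags:
#' * `sm1`: `"exogenous"` (default) holds the safety-policy sub-stock SM1
#'   constant at `AV_SM1 / 100`; `"stock"` lets SM1 evolve with the same
#'   element-uptake form as the single-element SA3 stock.
#' * `sa_damping`: self-damping of the SA layer uptake; `"sm"` (default,
#'   as published) uses `2^(-SM)`, `"sa"` the symmetric `2^(-SA)` reading.
#' * `ua_outflow`: `"none"` (default; no outflow of safe acts is
#'   published) or `"feedback"` (an exploratory `1 - 2^(-UA/4)` decay).
#' * `delay_init`: `"steady"` or `"empty"` delay initialisation.
#'
#' @param weights A `weight_table`.
#' @param av Scalar construction standard applied to all elements, or a
#'   named vector over (a subset of) [av_elements()] merged onto
#'   `av_baseline`.
#' @param av_baseline Fill value for elements not named in `av`.
#' @param hv Initial safety level in `[0, 1]` for every stock.
#' @param gain,sat_denominator,time_halflife,act_feedback_divisor,upstream_divisor
#'   Model constants (defaults 1.5, 80, 6, 4, 2).
#' @param delay_times Named delay times in months for the five DELAY1s
#'   `SC_down`, `SM_up`, `SM_down`, `SA_up`, `SA_down` (defaults 1, 0.25,
#'   0.5, 0.25, 0.25).
#' @param options List of option flags, see Details.
#' @param taxonomy A `cause_taxonomy`.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(weights = default_weights(taxonomy),
                             av = 60, av_baseline = 60, hv = 0,
                             gain = 1.5, sat_denominator = 80,
                             time_halflife = 6, act_feedback_divisor = 4,
                             upstream_divisor = 2,
                             delay_times = c(SC_down = 1, SM_up = 0.25,
                                             SM_down = 0.5, SA_up = 0.25,
                                             SA_down = 0.25),
                             options = list(),
                             taxonomy = default_taxonomy()) {
  validate_taxonomy(taxonomy)
  stopifnot(inherits(weights, "weight_table"))
  codes <- av_elements(taxonomy)
  if (length(av) == 1 && is.null(names(av))) {
    av_vec <- stats::setNames(rep(as.numeric(av), length(codes)), codes)
  } else {
    if (is.null(names(av)))
      stop("`av` must be a scalar or a named vector", call. = FALSE)
    bad <- setdiff(names(av), codes)
    if (length(bad))
      stop("unknown AV elements: ", paste(bad, collapse = ", "),
           call. = FALSE)
    av_vec <- stats::setNames(rep(as.numeric(av_baseline), length(codes)),
                              codes)
    av_vec[names(av)] <- as.numeric(av)
  }
  if (any(av_vec < 0 | av_vec > 100))
    stop("AV construction standards must lie in [0, 100]", call. = FALSE)
  if (hv < 0 || hv > 1)
    stop("`hv` must lie in [0, 1]", call. = FALSE)
  need_delays <- c("SC_down", "SM_up", "SM_down", "SA_up", "SA_down")
  if (!setequal(names(delay_times), need_delays) || any(delay_times <= 0))
    stop("`delay_times` must name ", paste(need_delays, collapse = ", "),
         " with positive values", call. = FALSE)
  if (gain <= 0 || sat_denominator <= 0 || time_halflife <= 0 ||
      act_feedback_divisor <= 0 || upstream_divisor <= 0)
    stop("model constants must be positive", call. = FALSE)

  defaults <- list(sm1 = "exogenous", sa_damping = "sm",
                   ua_outflow = "none", delay_init = "steady")
  bad <- setdiff(names(options), names(defaults))
  if (length(bad))
    stop("unknown options: ", paste(bad, collapse = ", "), call. = FALSE)
  opts <- utils::modifyList(defaults, options)
  opts$sm1 <- match.arg(opts$sm1, c("exogenous", "stock"))
  opts$sa_damping <- match.arg(opts$sa_damping, c("sm", "sa"))
  opts$ua_outflow <- match.arg(opts$ua_outflow, c("none", "feedback"))
  opts$delay_init <- match.arg(opts$delay_init, c("steady", "empty"))

  structure(list(weights = weights, av = av_vec, hv = hv, gain = gain,
                 sat_denominator = sat_denominator,
                 time_halflife = time_halflife,
                 act_feedback_divisor = act_feedback_divisor,
                 upstream_divisor = upstream_divisor,
                 delay_times = delay_times[need_delays],
                 options = opts, taxonomy = taxonomy),
            class = "model_parameters")
}

#' Default model parameterisation
#'
#' The default weight table, constants 80/6/4/2 and gain 1.5, the delay
#' times (SC feedback 1 month, SM uptake 0.25, SM feedback 0.5, SA uptake
#' 0.25, SA feedback 0.25), all construction standards at AV = 60 and a
#' new-mine initial level HV = 0.
#'
#' @return A `model_parameters` object.
#' @examples
#' p <- default_parameters()
#' p$weights$d    # 0.2 0.5 0.3
#' @export
default_parameters <- function() model_parameters()

#' Weighted AV sum for one element group
#' @param params A `model_parameters`.
#' @param group_id One of `"a"`, `"b"`, `"c"`, `"e"`, `"f"`, `"g"`.
#' @return `sum(w_i * AV_i)` over the group, a 0–100 scale value.
#' @export
weighted_av <- function(params, group_id) {
  g <- params$taxonomy[[group_id]]
  sum(params$weights[[group_id]] * params$av[g$elements])
}

#' Net rates of the safety-system model
#'
#' Assembles the full rate list of the
#' safety culture–safety management system–safety ability–safety acts
#' model at one instant:
#'
#' * `SC` gains the culture element uptake (group `a`) and loses the
#'   delayed acts feedback (delay 1 month);
#' * `SM` gains the delayed layer uptake from SC gated by
#'   `d1*SM1 + d2*SM2 + d3*SM3` (delay 0.25) and loses the delayed acts
#'   feedback (delay 0.5);
#' * `SM2`, `SM3`, `SA2`, `SA3`, `SA4` gain their element uptakes (groups
#'   `b`, `c`, `f`, the single `SA31` element, `g`) with time damping and
#'   have no outflow;
#' * `SA1` (knowledge) gains the `e`-group uptake damped by `2^(-SA1)`
#'   instead of time;
#' * `SA` gains the delayed layer uptake from SM gated by the `h`-weighted
#'   ability components (delay 0.25) and loses the delayed acts feedback
#'   (delay 0.25);
#' * `UA` gains the acts uptake from SA, with no outflow by default;
#' * `SM1` is exogenous (rate 0) by default.
#'
#' @param stocks Named numeric vector of the eleven stocks.
#' @param delay_out Named numeric vector of current delay outputs
#'   (`SC_down`, `SM_up`, `SM_down`, `SA_up`, `SA_down`).
#' @param params A `model_parameters`.
#' @param time Months.
#' @return `list(rates = <named net rates>, delay_inputs = <named
#'   pre-delay inflows>)`.
#' @export
compute_rates <- function(stocks, delay_out, params, time) {
  w <- params$weights
  av <- params$av
  opt <- params$options
  sat <- params$sat_denominator
  hl <- params$time_halflife
  fb_div <- params$act_feedback_divisor
  up_div <- params$upstream_divisor

  up_a <- element_uptake(weighted_av(params, "a"), time, sat, hl)
  up_b <- element_uptake(weighted_av(params, "b"), time, sat, hl)
  up_c <- element_uptake(weighted_av(params, "c"), time, sat, hl)
  up_f <- element_uptake(weighted_av(params, "f"), time, sat, hl)
  up_sa3 <- element_uptake(av[["SA31"]], time, sat, hl)
  up_g <- element_uptake(weighted_av(params, "g"), time, sat, hl)
  # knowledge uptake is damped by its own level, not by time
  up_e <- (1 - 2^(-weighted_av(params, "e") / sat)) * 2^(-stocks[["SA1"]])

  w_sm <- sum(w$d * stocks[c("SM1", "SM2", "SM3")])
  sm_up_in <- layer_uptake_core(stocks[["SC"]], w_sm, 3, stocks[["SM"]],
                                params$gain, up_div)
  sa_self <- if (opt$sa_damping == "sm") stocks[["SM"]] else stocks[["SA"]]
  w_sa <- sum(w$h * stocks[c("SA1", "SA2", "SA3", "SA4")])
  sa_up_in <- layer_uptake_core(stocks[["SM"]], w_sa, 4, sa_self,
                                params$gain, up_div)
  fb <- feedback_decay_core(stocks[["UA"]], fb_div)

  sm1_rate <- switch(opt$sm1,
    exogenous = 0,
    stock = element_uptake(av[["SM1"]], time, sat, hl))
  ua_rate <- acts_uptake(stocks[["SA"]], stocks[["UA"]])
  if (opt$ua_outflow == "feedback")
    ua_rate <- ua_rate - feedback_decay_core(stocks[["UA"]], fb_div)

  rates <- c(
    SC = up_a - delay_out[["SC_down"]],
    SM = delay_out[["SM_up"]] - delay_out[["SM_down"]],
    SM1 = sm1_rate,
    SM2 = up_b,
    SM3 = up_c,
    SA = delay_out[["SA_up"]] - delay_out[["SA_down"]],
    SA1 = unname(up_e),
    SA2 = up_f,
    SA3 = up_sa3,
    SA4 = up_g,
    UA = unname(ua_rate)
  )
  inputs <- c(SC_down = fb, SM_up = unname(sm_up_in), SM_down = fb,
              SA_up = unname(sa_up_in), SA_down = fb)
  list(rates = rates, delay_inputs = inputs)
}

#' Initial stock vector for a parameterisation
#'
#' Every stock starts at the safety level `hv`; under the default
#' exogenous-policy option, SM1 instead sits at its construction standard
#' `AV_SM1 / 100` throughout.
#'
#' @param params A `model_parameters`.
#' @return Named numeric vector over the eleven stocks.
#' @export
initial_stocks <- function(params) {
  s <- stats::setNames(rep(params$hv, length(.stock_order)), .stock_order)
  if (params$options$sm1 == "exogenous")
    s[["SM1"]] <- params$av[["SM1"]] / 100
  s
}

#' Simulate the safety-system model
#'
#' Runs the full model under a parameterisation on a time grid, returning
#' the sampled trajectory of all eleven stocks.
#'
#' @param params A `model_parameters`.
#' @param config A [sim_config()].
#' @return An `sd_trajectory` data frame.
#' @examples
#' traj <- run_model(model_parameters(av = 80, hv = 0))
#' tail(traj[, c("time", "SC", "SM", "SA", "UA")], 3)
#' @export
run_model <- function(params, config = sim_config()) {
  stopifnot(inherits(params, "model_parameters"))
  sd_integrate(
    stocks = initial_stocks(params),
    rate_fn = function(stocks, delay_out, time)
      compute_rates(stocks, delay_out, params, time),
    delays = params$delay_times,
    config = config,
    delay_init = params$options$delay_init
  )
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Safety-system model parameters\n")
  cat(sprintf("  hv: %.2f; av: %s\n", x$hv,
              if (length(unique(x$av)) == 1)
                sprintf("all %.0f", x$av[[1]])
              else sprintf("%d per-element values", length(x$av))))
  cat(sprintf("  constants: gain %.2f, sat %g, halflife %g, feedback /%g, upstream /%g\n",
              x$gain, x$sat_denominator, x$time_halflife,
              x$act_feedback_divisor, x$upstream_divisor))
  cat("  delays:", paste(sprintf("%s=%g", names(x$delay_times),
                                 x$delay_times), collapse = ", "), "\n")
  cat("  options:", paste(sprintf("%s=%s", names(x$options), unlist(x$options)),
                          collapse = ", "), "\n")
  invisible(x)
}
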