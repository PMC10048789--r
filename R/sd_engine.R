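#' Simulation time grid
#'
#' Fixed-step time grid in months. The default horizon matches the study
#' conditions: start 0, end 24, step 0.25 months. The grid must close
#' exactly, i.e. `(t_end - t0) / dt` must be a positive integer.
#'
#' @param t0 Start time (months).
#' @param t_end End time (months).
#' @param dt Step (months), `> 0`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t0 = 0, t_end = 24, dt = 0.25) {
  stopifnot(is.numeric(t0), is.numeric(t_end), is.numeric(dt))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  n <- (t_end - t0) / dt
  if (n <= 0 || abs(n - round(n)) > 1e-8)
    stop(sprintf(
      "time grid does not close: (t_end - t0)/dt = %g is not a positive integer",
      n), call. = FALSE)
  structure(list(t0 = t0, t_end = t_end, dt = dt, n_steps = as.integer(round(n))),
            class = "sim_config")
}

#' First-order material delay (DELAY1)
#'
#' A DELAY1 holds an in-transit level `L` with outflow `L / T` for delay
#' time `T`; the level obeys `dL/dt = input - L/T`, so the output is an
#' exponentially smoothed copy of the input with time constant `T`.
#'
#' `delay1_init()` initialises the level. With `init = "steady"` the level
#' is `input0 * T`, so the initial output equals the initial input (the
#' delay starts in equilibrium); with `init = "empty"` the level is 0.
#'
#' @param input0 Inflow rate at the initial time.
#' @param delay_time Delay time `T` in months, `> 0`.
#' @param init `"steady"` or `"empty"`.
#' @return A `delay1_state` with fields `level` and `delay_time`.
#' @examples
#' s <- delay1_init(0.4, 1)
#' delay1_output(s)          # 0.4: starts at steady state
#' @export
delay1_init <- function(input0, delay_time, init = c("steady", "empty")) {
  init <- match.arg(init)
  if (!is.numeric(delay_time) || delay_time <= 0)
    stop("invalid delay: `delay_time` must be positive", call. = FALSE)
  level <- if (init == "steady") input0 * delay_time else 0
  structure(list(level = level, delay_time = delay_time),
            class = "delay1_state")
}

#' @rdname delay1_init
#' @param state A `delay1_state`.
#' @return `delay1_output()` returns the current outflow `level / delay_time`.
#' @export
delay1_output <- function(state) state$level / state$delay_time

#' @rdname delay1_init
#' @param input Current inflow rate.
#' @param dt Euler step (months), `> 0`.
#' @return `delay1_step()` returns the updated `delay1_state` after one
#'   explicit Euler step `level <- level + dt * (input - level/T)`.
#' @export
delay1_step <- function(state, input, dt) {
  stopifnot(inherits(state, "delay1_state"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  state$level <- state$level + dt * (input - state$level / state$delay_time)
  state
}

#' Integrate a clamped stock-and-flow system
#'
#' Explicit fixed-step Euler integration of a set of named stocks coupled
#' to named first-order material delays. At each grid point the rate
#' function receives the current stock values, the current delay outputs
#' and the time, and must return
#' `list(rates = <named net rate per stock>, delay_inputs = <named inflow
#' per delay>)`. Stocks are then advanced and clamped to `[0, 1]` (stocks
#' are safety-level ratios), and each delay level is advanced with its
#' instantaneous pre-delay input.
#'
#' Delay levels are initialised from the rate function evaluated at the
#' initial state (with all delay outputs read as zero for that one
#' bootstrap call, which is exact here because pre-delay inflows never
#' depend on delay outputs).
#'
#' @param stocks Named numeric vector of initial stock values in `[0, 1]`.
#' @param rate_fn Function `(stocks, delay_out, time) -> list(rates,
#'   delay_inputs)`.
#' @param delays Named numeric vector of delay times (months); may be
#'   empty.
#' @param config A [sim_config()].
#' @param delay_init `"steady"` or `"empty"` (see [delay1_init()]).
#' @return An object of classes `sd_trajectory` and `data.frame`: column
#'   `time` plus one column per stock, one row per grid point including
#'   both endpoints.
#' @export
sd_integrate <- function(stocks, rate_fn, delays = numeric(0),
                         config = sim_config(),
                         delay_init = c("steady", "empty")) {
  delay_init <- match.arg(delay_init)
  stopifnot(inherits(config, "sim_config"), is.function(rate_fn))
  if (is.null(names(stocks)) || anyNA(stocks))
    stop("`stocks` must be a named numeric vector without NA", call. = FALSE)
  if (length(delays) && is.null(names(delays)))
    stop("`delays` must be named", call. = FALSE)

  n <- config$n_steps
  dt <- config$dt
  times <- config$t0 + dt * (0:n)
  zero_out <- stats::setNames(numeric(length(delays)), names(delays))

  # bootstrap delay levels from the initial pre-delay inflows
  states <- list()
  if (length(delays)) {
    r0 <- rate_fn(stocks, zero_out, config$t0)
    for (nm in names(delays))
      states[[nm]] <- delay1_init(r0$delay_inputs[[nm]], delays[[nm]],
                                  init = delay_init)
  }

  traj <- matrix(NA_real_, nrow = n + 1L, ncol = length(stocks),
                 dimnames = list(NULL, names(stocks)))
  traj[1L, ] <- stocks
  for (k in seq_len(n)) {
    t_k <- times[k]
    out <- if (length(states))
      vapply(states, delay1_output, numeric(1)) else zero_out
    r <- rate_fn(stocks, out, t_k)
    rates <- r$rates[names(stocks)]
    bad <- which(!is.finite(unlist(rates)))
    if (length(bad))
      stop(sprintf("non-finite net rate for stock '%s' at time %g",
                   names(stocks)[bad[1]], t_k), call. = FALSE)
    stocks <- pmin(pmax(stocks + dt * unlist(rates), 0), 1)
    for (nm in names(states))
      states[[nm]] <- delay1_step(states[[nm]], r$delay_inputs[[nm]], dt)
    traj[k + 1L, ] <- stocks
  }
  res <- data.frame(time = times, traj, check.names = FALSE)
  class(res) <- c("sd_trajectory", "data.frame")
  attr(res, "dt") <- dt
  res
}

#' Fixed stock column order for trajectory files
#' @keywords internal
.stock_order <- c("SC", "SM", "SM1", "SM2", "SM3",
                  "SA", "SA1", "SA2", "SA3", "SA4", "UA")

#' Write / read a trajectory as CSV
#'
#' First column `time`, then one column per stock in the fixed order
#' `SC,SM,SM1,SM2,SM3,SA,SA1,SA2,SA3,SA4,UA` (any additional stocks follow
#' in their trajectory order), values in 6-decimal fixed point.
#'
#' @param traj An `sd_trajectory`.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "sd_trajectory") || is.data.frame(traj))
  cols <- setdiff(names(traj), "time")
  cols <- c(intersect(.stock_order, cols), setdiff(cols, .stock_order))
  df <- traj[, c("time", cols), drop = FALSE]
  for (cc in names(df)) df[[cc]] <- formatC(df[[cc]], format = "f", digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8", check.names = FALSE)
  class(df) <- c("sd_trajectory", "data.frame")
  if (nrow(df) > 1) attr(df, "dt") <- df$time[2] - df$time[1]
  df
}
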