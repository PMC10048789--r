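test_that("element uptake has the half-saturation / half-life structure", {
  expect_equal(element_uptake(80, 0), 0.5)
  expect_equal(element_uptake(0, 3), 0)
  expect_equal(element_uptake(80, 6), 0.25)   # one half-life later
  expect_equal(element_uptake(80, 12), 0.125)
  # strictly increasing in the weighted standard
  s <- seq(0, 100, by = 5)
  expect_true(all(diff(element_uptake(s, 2)) > 0))
  expect_error(element_uptake(-1, 0), "nonnegative")
})

test_that("layer uptake core matches its closed form and vanishes correctly", {
  expect_equal(layer_uptake_core(0, 1, 3, 0.5), 0)
  expect_equal(layer_uptake_core(1, 0, 3, 0.5), 0)
  expect_equal(layer_uptake_core(1, 4, 4, 0),
               1.5 * (1 - 1 / sqrt(2)) * 0.5)
  # decreasing in the receiving level
  lv <- seq(0, 1, by = 0.1)
  expect_true(all(diff(layer_uptake_core(0.8, 2, 3, lv)) < 0))
  expect_error(layer_uptake_core(0.5, 1, 0, 0.5), "positive")
  expect_error(layer_uptake_core(1.5, 1, 3, 0.5), "\\[0, 1\\]")
})

test_that("feedback decay and acts uptake match closed-form values", {
  expect_equal(feedback_decay_core(0), 0)
  expect_equal(feedback_decay_core(1), 1 - 2^(-1 / 4))
  expect_equal(feedback_decay_core(0.5), 1 - 2^(-1 / 8))
  expect_error(feedback_decay_core(1.2), "\\[0, 1\\]")

  expect_equal(acts_uptake(0, 0.3), 0)
  expect_equal(acts_uptake(1, 0), 1 - 1 / sqrt(2))
  expect_equal(acts_uptake(1, 1), (1 - 1 / sqrt(2)) / 2)
  expect_error(acts_uptake(0.5, -0.1), "\\[0, 1\\]")
})

test_that("rate cores stay inside their ranges on random inputs", {
  set.seed(23)
  for (i in 1:200) {
    expect_true(element_uptake(stats::runif(1, 0, 100),
                               stats::runif(1, 0, 24)) >= 0)
    lu <- layer_uptake_core(stats::runif(1), stats::runif(1, 0, 4),
                            sample(3:4, 1), stats::runif(1))
    expect_true(lu >= 0 && lu <= 1.5)
    fd <- feedback_decay_core(stats::runif(1))
    expect_true(fd >= 0 && fd < 1)
  }
})

test_that("default parameters carry the published weights and constants", {
  p <- default_parameters()
  expect_equal(unname(p$weights$h), c(0.5, 0.1, 0.2, 0.2))
  expect_equal(unname(p$weights$d), c(0.2, 0.5, 0.3))
  expect_equal(unname(p$weights$g), c(0.4085, 0.2022, 0.2336, 0.1557))
  expect_equal(p$sat_denominator, 80)
  expect_equal(p$time_halflife, 6)
  expect_equal(p$act_feedback_divisor, 4)
  expect_equal(p$upstream_divisor, 2)
  expect_equal(p$gain, 1.5)
  expect_equal(p$delay_times,
               c(SC_down = 1, SM_up = 0.25, SM_down = 0.5,
                 SA_up = 0.25, SA_down = 0.25))
  expect_true(all(p$av == 60))
  expect_equal(p$hv, 0)
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(model_parameters(av = 120), "\\[0, 100\\]")
  expect_error(model_parameters(hv = 1.2), "\\[0, 1\\]")
  expect_error(model_parameters(av = c(BAD = 50)), "unknown AV")
  expect_error(model_parameters(options = list(nope = 1)),
               "unknown options")
  expect_error(model_parameters(delay_times = c(SC_down = 1)),
               "delay_times")
  # named partial AV overrides merge onto the baseline
  p <- model_parameters(av = c(SM1 = 90), av_baseline = 60)
  expect_equal(unname(p$av[["SM1"]]), 90)
  expect_true(all(p$av[setdiff(names(p$av), "SM1")] == 60))
})

test_that("all-zero construction and level is an exact fixed point", {
  p <- model_parameters(av = 0, hv = 0)
  zero <- stats::setNames(rep(0, 11), names(initial_stocks(p)))
  dout <- stats::setNames(rep(0, 5), names(p$delay_times))
  r <- compute_rates(zero, dout, p, 0)
  expect_true(all(r$rates == 0))
  expect_true(all(r$delay_inputs == 0))
  tr <- run_model(p)
  expect_true(all(as.matrix(tr[, -1]) == 0))
})

test_that("at AV = 80 and empty stocks the culture inflow is exactly 0.5", {
  p <- model_parameters(av = 80, hv = 0,
                        options = list(sm1 = "stock"))
  zero <- stats::setNames(rep(0, 11), names(initial_stocks(p)))
  dout <- stats::setNames(rep(0, 5), names(p$delay_times))
  r <- compute_rates(zero, dout, p, 0)
  expect_equal(unname(r$rates[["SC"]]), 0.5)
})

test_that("compute_rates matches the independent transcription oracle", {
  set.seed(31)
  opts <- expand.grid(sa_damping = c("sm", "sa"),
                      ua_outflow = c("none", "feedback"),
                      sm1 = c("exogenous", "stock"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(opts))) {
    p <- model_parameters(
      av = stats::setNames(stats::runif(30, 0, 100),
                           av_elements(default_taxonomy())),
      options = as.list(opts[i, ]))
    reps <- if (i == 1) 1000 else 50
    for (j in seq_len(reps)) {
      st <- random_state()
      got <- compute_rates(st$stocks, st$delay_out, p, st$time)
      want <- oracle_rates(st$stocks, st$delay_out, p, st$time)
      expect_equal(got$rates, want$rates, tolerance = 1e-12)
      expect_equal(got$delay_inputs, want$delay_inputs,
                   tolerance = 1e-12)
    }
  }
})

test_that("outflow-free sub-stocks are monotone in time and in their AVs", {
  p60 <- model_parameters(av = 60, hv = 0)
  p80 <- model_parameters(av = 80, hv = 0)
  t60 <- run_model(p60)
  t80 <- run_model(p80)
  for (s in c("SM2", "SM3", "SA2", "SA3", "SA4")) {
    expect_true(all(diff(t60[[s]]) >= -1e-12),
                label = paste(s, "nondecreasing in time"))
    expect_true(all(t80[[s]] - t60[[s]] >= -1e-12),
                label = paste(s, "nondecreasing in AV"))
  }
})

test_that("new-mine run shows rising safe acts and unimodal layers", {
  tr <- run_model(model_parameters(av = 80, hv = 0))
  expect_true(all(diff(tr$UA) >= -1e-12))
  for (s in c("SC", "SM", "SA")) {
    expect_unimodal(tr[[s]])
    ip <- which.max(tr[[s]])
    expect_gt(tr$time[ip], 0)                  # interior peak: rises first
    expect_lt(tr[[s]][nrow(tr)], max(tr[[s]])) # then falls
  }
})
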