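# Independent straight-line transcription of the model's rate equations,
# written term by term with exp()/log(2) and no reuse of the package's
# rate cores. Used to cross-check compute_rates().
oracle_rates <- function(st, dout, p, t) {
  ln2 <- log(2)
  w <- p$weights
  av <- p$av

  S_a <- w$a[[1]] * av[["SC1"]] + w$a[[2]] * av[["SC2"]] +
         w$a[[3]] * av[["SC3"]] + w$a[[4]] * av[["SC4"]]
  S_b <- w$b[[1]] * av[["SM21"]] + w$b[[2]] * av[["SM22"]] +
         w$b[[3]] * av[["SM23"]]
  S_c <- w$c[[1]] * av[["SM31"]] + w$c[[2]] * av[["SM32"]] +
         w$c[[3]] * av[["SM33"]] + w$c[[4]] * av[["SM34"]] +
         w$c[[5]] * av[["SM35"]] + w$c[[6]] * av[["SM36"]] +
         w$c[[7]] * av[["SM37"]]
  S_e <- w$e[[1]] * av[["SA11"]] + w$e[[2]] * av[["SA12"]] +
         w$e[[3]] * av[["SA13"]] + w$e[[4]] * av[["SA14"]] +
         w$e[[5]] * av[["SA15"]] + w$e[[6]] * av[["SA16"]] +
         w$e[[7]] * av[["SA17"]]
  S_f <- w$f[[1]] * av[["SA21"]] + w$f[[2]] * av[["SA22"]] +
         w$f[[3]] * av[["SA23"]]
  S_g <- w$g[[1]] * av[["SA41"]] + w$g[[2]] * av[["SA42"]] +
         w$g[[3]] * av[["SA43"]] + w$g[[4]] * av[["SA44"]]

  time_damp <- exp(-t * ln2 / 6)
  sc_up  <- (1 - exp(-ln2 * S_a / 80)) * time_damp
  sm2_up <- (1 - exp(-ln2 * S_b / 80)) * time_damp
  sm3_up <- (1 - exp(-ln2 * S_c / 80)) * time_damp
  sa1_up <- (1 - exp(-ln2 * S_e / 80)) * exp(-st[["SA1"]] * ln2)
  sa2_up <- (1 - exp(-ln2 * S_f / 80)) * time_damp
  sa3_up <- (1 - exp(-ln2 * av[["SA31"]] / 80)) * time_damp
  sa4_up <- (1 - exp(-ln2 * S_g / 80)) * time_damp

  w_d <- w$d[[1]] * st[["SM1"]] + w$d[[2]] * st[["SM2"]] +
         w$d[[3]] * st[["SM3"]]
  sm_up_in <- 1.5 * (1 - exp(-ln2 * st[["SC"]] / 2)) *
    (1 - exp(-ln2 * w_d / 3)) * exp(-st[["SM"]] * ln2)
  w_h <- w$h[[1]] * st[["SA1"]] + w$h[[2]] * st[["SA2"]] +
         w$h[[3]] * st[["SA3"]] + w$h[[4]] * st[["SA4"]]
  sa_self <- if (p$options$sa_damping == "sm") st[["SM"]] else st[["SA"]]
  sa_up_in <- 1.5 * (1 - exp(-ln2 * st[["SM"]] / 2)) *
    (1 - exp(-ln2 * w_h / 4)) * exp(-sa_self * ln2)
  fb <- 1 - exp(-st[["UA"]] * ln2 / 4)

  ua <- (1 - exp(-ln2 * st[["SA"]] / 2)) * exp(-st[["UA"]] * ln2)
  if (p$options$ua_outflow == "feedback")
    ua <- ua - (1 - exp(-st[["UA"]] * ln2 / 4))
  sm1 <- if (p$options$sm1 == "stock")
    (1 - exp(-ln2 * av[["SM1"]] / 80)) * time_damp else 0

  list(
    rates = c(SC = sc_up - dout[["SC_down"]],
              SM = dout[["SM_up"]] - dout[["SM_down"]],
              SM1 = sm1, SM2 = sm2_up, SM3 = sm3_up,
              SA = dout[["SA_up"]] - dout[["SA_down"]],
              SA1 = sa1_up, SA2 = sa2_up, SA3 = sa3_up, SA4 = sa4_up,
              UA = ua),
    delay_inputs = c(SC_down = fb, SM_up = sm_up_in, SM_down = fb,
                     SA_up = sa_up_in, SA_down = fb))
}

# random valid model state for property tests
random_state <- function() {
  stocks <- stats::setNames(stats::runif(11),
                            c("SC", "SM", "SM1", "SM2", "SM3",
                              "SA", "SA1", "SA2", "SA3", "SA4", "UA"))
  dout <- stats::setNames(stats::runif(5, 0, 0.5),
                          c("SC_down", "SM_up", "SM_down", "SA_up",
                            "SA_down"))
  list(stocks = stocks, delay_out = dout, time = stats::runif(1, 0, 24))
}

# unimodality allowing a flat stretch at the maximum: nondecreasing up to
# the first maximum, equal to the max on the plateau, nonincreasing after
# the last maximum
expect_unimodal <- function(v, tol = 1e-12) {
  i1 <- which.max(v)
  i2 <- max(which(v >= max(v) - tol))
  expect_true(all(diff(v[1:i1]) >= -tol))
  expect_true(all(abs(v[i1:i2] - max(v)) <= tol))
  expect_true(all(diff(v[i2:length(v)]) <= tol))
}
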