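test_that("scenario construction validates its ranges", {
  expect_error(scenario(hv = 1.5), "\\[0, 1\\]")
  expect_error(scenario(av = 150), "\\[0, 100\\]")
  expect_error(scenario(overrides = c(a = 150)), "\\[0, 100\\]")
  expect_error(run_scenario(scenario(overrides = c(zzz = 50))),
               "unknown AV override")
})

test_that("zero construction at zero level stays at the fixed point", {
  tr <- run_scenario(scenario(hv = 0, av = 0))
  expect_true(all(as.matrix(tr[, -1]) == 0))
})

test_that("identical scenarios write identical trajectory files", {
  scen <- scenario("rep", hv = 0.25, av = 70)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(run_scenario(scen), f1)
  write_trajectory_csv(run_scenario(scen), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("trajectory summaries follow the earliest-tie peak/trough rules", {
  tr <- data.frame(time = 0:4, X = c(0, 1, 2, 3, 4))
  s <- summarize_trajectory(tr)
  expect_equal(s$peak_time, 4)
  expect_true(is.na(s$trough_time))
  expect_equal(s$final_value, 4)

  s <- summarize_trajectory(data.frame(time = 0:2, X = c(1, 3, 2)))
  expect_equal(s$peak_time, 1)
  expect_equal(s$peak_value, 3)
  expect_equal(s$trough_time, 2)

  s <- summarize_trajectory(data.frame(time = 0:2, X = c(1, 3, 3)))
  expect_equal(s$peak_time, 1)        # earliest tie
  expect_true(is.na(s$trough_time))   # flat tail is not a trough

  s <- summarize_trajectory(data.frame(time = 0:4,
                                       X = c(0, 5, 1, 4, 4)))
  expect_equal(s$peak_time, 1)
  expect_equal(s$trough_time, 2)      # earliest post-peak minimum
})

test_that("null influence experiments give exactly zero effects", {
  rk <- layer_influence_experiment(0.25, 60, 60)
  expect_equal(rk$effect, rep(0, 3))
  rk <- element_influence_experiment("a", 0.25, 60, 60)
  expect_equal(rk$effect, rep(0, 4))
  expect_error(layer_influence_experiment(0.25, 80, 60), ">=")
})

test_that("raising a zero-weight category has zero effect", {
  w <- unclass(default_weights())
  w$a <- c(0, w$a[-1] / sum(w$a[-1]))
  p <- model_parameters(weights = weight_table(w))
  rk <- element_influence_experiment("a", 0.25, 60, 80, p)
  zero_cat <- rk$effect[rk$factor == "safety concept elements"]
  expect_equal(zero_cat, 0)
  expect_equal(rk$factor[4], "safety concept elements")
})

test_that("relabelling culture categories permutes the ranking identically", {
  tax1 <- default_taxonomy()
  tax2 <- default_taxonomy(c(SC1 = "safety measures elements",
                             SC2 = "safety responsibility elements",
                             SC3 = "safety discipline elements",
                             SC4 = "safety concept elements"))
  p1 <- model_parameters(taxonomy = tax1)
  p2 <- model_parameters(taxonomy = tax2)
  r1 <- layer_influence_experiment(0.25, 60, 80, p1)
  r2 <- layer_influence_experiment(0.25, 60, 80, p2)
  expect_equal(r1, r2)   # labels of a-categories do not enter layer runs

  e1 <- element_influence_experiment("a", 0.25, 60, 80, p1)
  e2 <- element_influence_experiment("a", 0.25, 60, 80, p2)
  # same multiset of effects, names permuted with the relabelling
  expect_equal(sort(e1$effect), sort(e2$effect))
  eff_by_code <- function(rk, tax) {
    code <- vapply(rk$factor, function(lb)
      names(which(tax$a$labels == lb)), character(1))
    stats::setNames(rk$effect, code)
  }
  c1 <- eff_by_code(e1, tax1)
  c2 <- eff_by_code(e2, tax2)
  expect_equal(c1[sort(names(c1))], c2[sort(names(c2))])
})

test_that("culture and ability element orderings match the published ranking", {
  rk <- element_influence_experiment("a", 0.25, 60, 80)
  expect_equal(rk$factor[4], "safety concept elements")  # weakest
  rk0 <- element_influence_experiment("a", 0, 60, 80)
  expect_equal(rk0$factor[4], "safety concept elements")

  for (hv in c(0.25, 0.5, 0.75)) {
    rk <- element_influence_experiment("h", hv, 60, 80)
    expect_equal(rk$factor[1], "safety knowledge")
    # habits and psychology perturb the ability uptake identically
    # (equal h-weights, identical uptake forms): an exact tie
    expect_equal(rk$effect[rk$factor == "safety habits"],
                 rk$effect[rk$factor == "safety psychology"])
  }
})

test_that("in a new mine the safety policy leads the management elements", {
  rk <- element_influence_experiment("d", 0, 60, 80, window = c(0, 18))
  expect_equal(rk$factor[1], "safety policy")
})

test_that("grid_run enumerates the factorial and is repeatable", {
  cfg <- sim_config(0, 6, 0.25)   # short horizon keeps the batch quick
  tab <- grid_run(c(0.25, 0.5, 0.75), c(70, 80, 90), config = cfg)
  expect_equal(length(unique(tab$scenario)), 9L)
  expect_equal(nrow(tab), 9L * 11L)   # one row per run and stock
  tab2 <- grid_run(c(0.25, 0.5, 0.75), c(70, 80, 90), config = cfg)
  expect_identical(tab, tab2)
  # higher construction standard -> safety-culture peak no lower
  for (hv in c(0.25, 0.5, 0.75)) {
    pk <- tab$peak_value[tab$hv == hv & tab$stock == "SC"]
    expect_true(all(diff(pk[order(tab$av[tab$hv == hv &
                                          tab$stock == "SC"])]) >= 0))
  }
})

test_that("rankings serialise to factor/effect/rank JSON records", {
  rk <- layer_influence_experiment(0.25, 60, 80)
  f <- withr::local_tempfile(fileext = ".json")
  write_ranking_json(rk, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(names(back), c("factor", "effect", "rank"))
  expect_equal(back$rank, 1:3)
  expect_equal(back$effect, rk$effect)
})
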