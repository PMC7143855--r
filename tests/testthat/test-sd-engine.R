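test_that("validate_model reports each violation and accepts valid models", {
  expect_length(validate_model(one_stock_model()), 0L)

  bad_ref <- sd_model(
    constants = list(sd_constant("dust", 3310)),
    rates = list(sd_rate("prod", "dustt + 1", "inflow", "s")),
    stocks = list(sd_stock("s", 0)))
  d <- validate_model(bad_ref)
  expect_true(any(grepl("dustt", d)))

  cyclic <- sd_model(
    auxiliaries = list(sd_aux("a", "b + 1"), sd_aux("b", "a + 1")))
  d <- validate_model(cyclic)
  expect_length(grep("circular", d), 1L)
  expect_match(d[grepl("circular", d)], "a")
  expect_match(d[grepl("circular", d)], "b")

  dup <- sd_model(constants = list(sd_constant("x", 1)),
                  stocks = list(sd_stock("x", 0)))
  expect_true(any(grepl("duplicate name 'x'", validate_model(dup))))

  missing_stock <- sd_model(
    rates = list(sd_rate("r", "1 + 1", "inflow", "ghost")))
  expect_true(any(grepl("ghost", validate_model(missing_stock))))

  malformed <- sd_model(auxiliaries = list(sd_aux("a", "min(1, 2)")))
  expect_true(any(grepl("disallowed", validate_model(malformed))))
  unparseable <- sd_model(auxiliaries = list(sd_aux("a", "1 +")))
  expect_true(any(grepl("parse", validate_model(unparseable))))
})

test_that("evaluate_step_values computes auxiliaries then rates in order", {
  air <- build_air_subsystem(mine_config(), allocation_policy(air = 0.4))
  vals <- evaluate_step_values(air, c(air_pollution = 300))
  # production = dust + waste gas = 3310 + 1514
  expect_equal(vals[["air_pollution_production"]], 4824)
  # control = stock x technical factor = 300 x 0.4
  expect_equal(vals[["air_pollution_control"]], 120)
  expect_setequal(names(vals),
                  c("investment_air", "tech_factor_air",
                    "air_pollution_production", "air_pollution_control"))

  empty <- sd_model(stocks = list(sd_stock("s", 1)))
  expect_length(evaluate_step_values(empty, c(s = 1)), 0L)
})

test_that("evaluation errors name the offending variable", {
  m <- sd_model(constants = list(sd_constant("zero", 0)),
                auxiliaries = list(sd_aux("ratio", "1 / zero")))
  expect_error(evaluate_step_values(m, numeric()), "ratio")
  expect_error(simulate_sd(m, sim_config(0, 2, 1)), "time 0")
})

test_that("euler_step applies the level equation stock + dt*(in - out)", {
  still <- sd_model(stocks = list(sd_stock("s", 300)))
  expect_equal(euler_step(still, c(s = 300), 1), c(s = 300))

  air <- build_air_subsystem(mine_config(), allocation_policy(air = 0.4))
  nxt <- euler_step(air, c(air_pollution = 300), 1)
  expect_equal(nxt[["air_pollution"]], 300 + (4824 - 120))  # = 5004

  balanced <- sd_model(
    constants = list(sd_constant("k", 5)),
    rates = list(sd_rate("rin", "k", "inflow", "s"),
                 sd_rate("rout", "k", "outflow", "s")),
    stocks = list(sd_stock("s", 10)))
  expect_equal(euler_step(balanced, c(s = 10), 1), c(s = 10))
})

test_that("simulate_sd matches the linear-stock closed form at every grid point", {
  cases <- list(c(X0 = 300, P = 4824, p = 0.4),
                c(X0 = 35, P = 0, p = 0.15),
                c(X0 = 25.6, P = 9048, p = 0.05),
                c(X0 = 1000, P = 10, p = 0.9))
  for (cs in cases) {
    traj <- simulate_sd(one_stock_model(cs["X0"], cs["P"], cs["p"]),
                        sim_config(0, 24, 1))
    expected <- linear_stock_closed_form(cs["X0"], cs["P"], cs["p"], 0:24)
    expect_equal(traj$pollution, unname(expected), tolerance = 1e-9)
  }
})

test_that("full removal each step leaves exactly the fresh production", {
  traj <- simulate_sd(one_stock_model(X0 = 300, P = 4824, p = 1),
                      sim_config(0, 24, 1))
  expect_equal(traj$pollution[-1L], rep(4824, 24))
})

test_that("zero flows conserve stocks and constant-only models stay flat", {
  m <- sd_model(constants = list(sd_constant("c1", 7)),
                stocks = list(sd_stock("a", 2), sd_stock("b", -3)))
  traj <- simulate_sd(m, sim_config(0, 24, 1))
  expect_equal(traj$a, rep(2, 25))
  expect_equal(traj$b, rep(-3, 25))
})

test_that("linear models scale: trajectories are homogeneous in (X0, P)", {
  for (c_scale in c(0.5, 3, 100)) {
    base <- simulate_sd(one_stock_model(300, 4824, 0.4), sim_config(0, 24, 1))
    scaled <- simulate_sd(one_stock_model(300 * c_scale, 4824 * c_scale, 0.4),
                          sim_config(0, 24, 1))
    expect_equal(scaled$pollution, base$pollution * c_scale, tolerance = 1e-9)
  }
})

test_that("trajectory grid contract: length, strictly increasing times, finite", {
  for (cfg in list(sim_config(0, 24, 1), sim_config(0, 12, 0.5),
                   sim_config(3, 9, 2))) {
    traj <- simulate_sd(one_stock_model(), cfg)
    n_expected <- (cfg$final_time - cfg$initial_time) / cfg$dt + 1
    expect_identical(nrow(traj), as.integer(n_expected))
    expect_true(all(diff(traj$time) > 0))
    expect_true(all(is.finite(as.matrix(traj))))
  }
})

test_that("simulation is deterministic: identical runs are bit-identical", {
  m <- assemble_mine_model(mine_config(),
                           allocation_policy(0.4, 0.15, 0.15, 0.15, 0.15))
  expect_identical(simulate_sd(m), simulate_sd(m))
})

test_that("sim_config rejects degenerate grids", {
  expect_error(sim_config(0, 0, 1), "greater")
  expect_error(sim_config(0, 24, -1), "positive")
  expect_error(sim_config(0, 10, 3), "whole number")
})
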