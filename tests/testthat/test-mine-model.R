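test_that("technical factor: chained and simplified forms cancel exactly", {
  expect_identical(technical_factor(0.4, 50), 0.4)
  expect_identical(technical_factor(0, 50), 0)
  expect_identical(technical_factor(0.2, 50), 0.2)
  set.seed(1)
  p <- stats::runif(200)
  E <- stats::runif(200, 1e-3, 1e6)
  for (i in seq_along(p))
    expect_lt(abs(technical_factor(p[i], E[i]) - p[i]), 1e-12)
  expect_error(technical_factor(0.4, 0), "> 0")
  expect_error(technical_factor(0.4, -5), "> 0")
  expect_error(technical_factor(1.5, 50), "\\[0, 1\\]")
})

test_that("subsystem production flows equal the summed constants", {
  cfg <- mine_config()
  pol <- allocation_policy(0.15, 0.15, 0.15, 0.15, 0.15)
  state <- c(air_pollution = 300, solid_waste_pollution = 25.6,
             water_pollution = 35, vegetation_destruction_area = 275,
             land_damage_area = 450)
  get_rate <- function(frag, nm, stocks) {
    evaluate_step_values(frag, stocks)[[nm]]
  }
  expect_equal(get_rate(build_air_subsystem(cfg, pol),
                        "air_pollution_production", state["air_pollution"]),
               3310 + 1514)                        # = 4824
  expect_equal(get_rate(build_solid_subsystem(cfg, pol),
                        "solid_waste_production",
                        state["solid_waste_pollution"]),
               8750 + 0 + 298)                     # = 9048, garbage defaults 0
  expect_equal(get_rate(build_water_subsystem(cfg, pol),
                        "water_pollution_production",
                        state["water_pollution"]),
               8750 + 980 + 5392 + 73)             # = 15195
  expect_equal(get_rate(build_vegetation_subsystem(cfg, pol),
                        "vegetation_destruction",
                        state["vegetation_destruction_area"]),
               (30000 + 9833 + 1500 + 80) / 1e4)   # = 4.1413 harmonized
  expect_equal(get_rate(build_land_subsystem(cfg, pol),
                        "land_damage_production", state["land_damage_area"]),
               (4400 + 8800) / 1e4)                # = 1.32 harmonized
})

test_that("unit harmonization switch restores raw printed magnitudes", {
  cfg_raw <- mine_config(unit_harmonization = FALSE)
  pol <- allocation_policy()
  v <- evaluate_step_values(build_vegetation_subsystem(cfg_raw, pol),
                            c(vegetation_destruction_area = 275))
  expect_equal(v[["vegetation_destruction"]], 41413)
  l <- evaluate_step_values(build_land_subsystem(cfg_raw, pol),
                            c(land_damage_area = 450))
  expect_equal(l[["land_damage_production"]], 13200)
})

test_that("waste gas components replace the aggregate when all are given", {
  cfg <- mine_config(mine_params(no2 = 800, so2 = 500, co = 214))
  frag <- build_air_subsystem(cfg, allocation_policy())
  vals <- evaluate_step_values(frag, c(air_pollution = 300))
  expect_equal(vals[["waste_gas"]], 1514)
  expect_equal(vals[["air_pollution_production"]], 4824)
  # partial components fall back to the aggregate constant
  cfg2 <- mine_config(mine_params(no2 = 800))
  frag2 <- build_air_subsystem(cfg2, allocation_policy())
  expect_true("waste_gas" %in% frag2$constants$name)
})

test_that("greening rate is the intact fraction of total vegetation", {
  frag <- build_vegetation_subsystem(mine_config(), allocation_policy())
  rate_at <- function(s)
    evaluate_step_values(frag, c(vegetation_destruction_area = s))[["vegetation_greening_rate"]]
  expect_equal(rate_at(0), 1)
  expect_equal(rate_at(275), 1 - 275 / 2645.2)  # ~ 0.8960
})

test_that("untreated stocks accumulate production linearly", {
  cfg <- mine_config()
  zero <- allocation_policy()
  water <- simulate_sd(build_water_subsystem(cfg, zero), sim_config(0, 24, 1))
  expect_equal(water$water_pollution[25], 35 + 24 * 15195)
  land <- simulate_sd(build_land_subsystem(cfg, zero), sim_config(0, 24, 1))
  expect_equal(land$land_damage_area[25], 450 + 24 * 1.32)  # = 481.68
})

test_that("removal bases: stock saturates, literal leaves a constant net inflow", {
  pol <- allocation_policy(solid = 1)
  stock_cfg <- mine_config(removal_basis = "stock")
  traj <- simulate_sd(build_solid_subsystem(stock_cfg, pol),
                      sim_config(0, 24, 1))
  # full stock removal each step leaves exactly the fresh production
  expect_equal(traj$solid_waste_pollution[-1L], rep(9048, 24))

  lit_cfg <- mine_config(removal_basis = "literal")
  pol2 <- allocation_policy(solid = 0.4, water = 0.4)
  solid <- simulate_sd(build_solid_subsystem(lit_cfg, pol2),
                       sim_config(0, 24, 1))
  expect_equal(diff(solid$solid_waste_pollution), rep(0.6 * 9048, 24))
  water <- simulate_sd(build_water_subsystem(lit_cfg, pol2),
                       sim_config(0, 24, 1))
  expect_equal(diff(water$water_pollution), rep(0.6 * 15195, 24))
})

test_that("pure decay without production follows the geometric closed form", {
  p0 <- mine_params(coal_gangue = 0, life_wastewater = 0, mine_water = 0,
                    gangue_leaching = 0)
  frag <- build_water_subsystem(mine_config(p0),
                                allocation_policy(water = 0.15))
  traj <- simulate_sd(frag, sim_config(0, 24, 1))
  expect_equal(traj$water_pollution, 35 * 0.85^(0:24), tolerance = 1e-12)
})

test_that("assembled model has five stocks, validates, and equals its fragments", {
  cfg <- mine_config()
  pol <- allocation_policy(0.2, 0.2, 0.2, 0.2, 0.2)
  full <- assemble_mine_model(cfg, pol)
  expect_identical(nrow(full$stocks), 5L)
  expect_length(validate_model(full), 0L)

  sim <- sim_config(0, 24, 1)
  whole <- simulate_sd(full, sim)
  frags <- list(build_air_subsystem(cfg, pol), build_solid_subsystem(cfg, pol),
                build_water_subsystem(cfg, pol),
                build_vegetation_subsystem(cfg, pol),
                build_land_subsystem(cfg, pol))
  for (frag in frags) {
    alone <- simulate_sd(frag, sim)
    stock <- attr(alone, "stocks")
    expect_identical(whole[[stock]], alone[[stock]])
  }
})

test_that("subsystems are cross-independent in the allocation", {
  cfg <- mine_config()
  sim <- sim_config(0, 24, 1)
  base <- simulate_sd(assemble_mine_model(
    cfg, allocation_policy(0.15, 0.15, 0.15, 0.15, 0.15)), sim)
  bumped <- simulate_sd(assemble_mine_model(
    cfg, allocation_policy(0.40, 0.15, 0.15, 0.15, 0.15)), sim)
  others <- setdiff(unname(mine_stock_names()), "air_pollution")
  for (s in others) expect_identical(bumped[[s]], base[[s]])
  expect_false(identical(bumped$air_pollution, base$air_pollution))
})

test_that("quality assessment: zero policy scores 0, overall is the mean, bounds hold", {
  cfg <- mine_config()
  sim <- sim_config(0, 24, 1)
  baseline <- simulate_sd(assemble_mine_model(cfg, allocation_policy()), sim)
  q0 <- quality_assessment(baseline, baseline)
  expect_true(all(as.matrix(q0$per_subsystem) == 0))
  expect_true(all(q0$overall == 0))

  for (pol in list(allocation_policy(0.4, 0.15, 0.15, 0.15, 0.15),
                   allocation_policy(0.2, 0.2, 0.2, 0.2, 0.2),
                   allocation_policy(1, 0, 0, 0, 0))) {
    traj <- simulate_sd(assemble_mine_model(cfg, pol), sim)
    q <- quality_assessment(traj, baseline)
    m <- as.matrix(q$per_subsystem)
    expect_true(all(m >= 0 & m <= 1))
    expect_true(all(q$overall >= 0 & q$overall <= 1))
    expect_equal(q$overall, rowMeans(m))
  }
})

test_that("air quality at month 24 under a 0.4 share matches hand arithmetic", {
  cfg <- mine_config()
  sim <- sim_config(0, 24, 1)
  baseline <- simulate_sd(assemble_mine_model(cfg, allocation_policy()), sim)
  traj <- simulate_sd(assemble_mine_model(
    cfg, allocation_policy(0.4, 0.15, 0.15, 0.15, 0.15)), sim)
  q <- quality_assessment(traj, baseline)
  expect_equal(q$per_subsystem$air_pollution[25],
               1 - 12059.944 / (300 + 24 * 4824), tolerance = 1e-5)
})

test_that("each subsystem's final stock falls and quality rises in its own share", {
  cfg <- mine_config()
  sim <- sim_config(0, 24, 1)
  baseline <- simulate_sd(assemble_mine_model(cfg, allocation_policy()), sim)
  slots <- c(air = "air", solid = "solid", water = "water",
             vegetation = "green", land = "land")
  for (sub in names(slots)) {
    stocks <- numeric(); quals <- numeric()
    for (g in c(0.1, 0.25, 0.4)) {
      props <- as.list(stats::setNames(rep(0.15, 5),
                                       c("air", "solid", "water", "green", "land")))
      props[[slots[[sub]]]] <- g
      traj <- simulate_sd(assemble_mine_model(cfg, do.call(allocation_policy, props)),
                          sim)
      s <- mine_stock_names()[[sub]]
      stocks <- c(stocks, traj[[s]][25])
      quals <- c(quals, quality_assessment(traj, baseline)$per_subsystem[[s]][25])
    }
    expect_true(all(diff(stocks) < 0))
    expect_true(all(diff(quals) > 0))
  }
})

test_that("allocation and parameter validation reject out-of-range inputs", {
  expect_error(allocation_policy(air = 1.5), "\\[0, 1\\]")
  expect_error(allocation_policy(0.4, 0.4, 0.4, 0.4, 0.4), "sum")
  expect_silent(allocation_policy(0.4, 0.4, 0.4, 0.4, 0.4,
                                  enforce_budget = FALSE))
  expect_error(mine_params(dust = -1), "dust")
  expect_error(mine_params(environmental_investment = 0), "> 0")
})
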