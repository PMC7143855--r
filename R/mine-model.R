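#' @title Five-subsystem coal-mining-area environmental model
#' @description Builders that assemble the stock-flow model of a coal mining
#'   area — atmospheric, solid waste, water, vegetation cover and land
#'   reclamation subsystems — from the published parameter set, under an
#'   investment allocation policy, plus the environmental quality assessment
#'   computed against the zero-investment baseline.
#' @name mine_model
NULL

#' Model parameters for the coal-mining-area case study
#'
#' Defaults are the Shanxi coal-mining-area parameter set: monthly pollution
#' production constants (in square metres), the monthly environmental
#' investment budget (ten thousand yuan), the total vegetation area and the
#' initial pollution stocks. `living_garbage` feeds solid-waste production but
#' has no published value; it defaults to 0 and can be overridden. The waste
#' gas aggregate can alternatively be supplied as its `no2`, `so2`, `co`
#' components: when all three are given they replace `waste_gas`.
#'
#' @param environmental_investment Monthly budget, ten thousand yuan (> 0).
#' @param dust,waste_gas Monthly air pollution production, m^2.
#' @param no2,so2,co Optional components of the waste gas aggregate, m^2.
#' @param coal_gangue,living_garbage,boiler_ash Monthly solid waste
#'   production, m^2. Coal gangue also leaches into the water subsystem.
#' @param life_wastewater,mine_water,gangue_leaching Monthly water pollution
#'   production, m^2.
#' @param construction_square,waste_rock_pile,open_pit,road Monthly vegetation
#'   destruction, m^2.
#' @param land_subsidence,land_to_dig Monthly land damage, m^2.
#' @param total_vegetation_area Total vegetation area, 10,000 m^2.
#' @param initial_air_pollution,initial_solid_waste,initial_water_pollution
#'   Initial pollution stocks, m^2.
#' @param initial_vegetation_destruction,initial_land_damage Initial damaged
#'   areas, 10,000 m^2. `land_area` is accepted as a config-file alias for the
#'   initial land damage.
#' @return A `mine_params` object (named list).
#' @export
mine_params <- function(environmental_investment = 50,
                        dust = 3310, waste_gas = 1514,
                        no2 = NULL, so2 = NULL, co = NULL,
                        coal_gangue = 8750, living_garbage = 0,
                        boiler_ash = 298,
                        life_wastewater = 980, mine_water = 5392,
                        gangue_leaching = 73,
                        construction_square = 30000, waste_rock_pile = 9833,
                        open_pit = 1500, road = 80,
                        land_subsidence = 4400, land_to_dig = 8800,
                        total_vegetation_area = 2645.2,
                        initial_air_pollution = 300,
                        initial_solid_waste = 25.6,
                        initial_water_pollution = 35,
                        initial_vegetation_destruction = 275,
                        initial_land_damage = 450) {
  p <- list(environmental_investment = environmental_investment,
            dust = dust, waste_gas = waste_gas, no2 = no2, so2 = so2, co = co,
            coal_gangue = coal_gangue, living_garbage = living_garbage,
            boiler_ash = boiler_ash, life_wastewater = life_wastewater,
            mine_water = mine_water, gangue_leaching = gangue_leaching,
            construction_square = construction_square,
            waste_rock_pile = waste_rock_pile, open_pit = open_pit,
            road = road, land_subsidence = land_subsidence,
            land_to_dig = land_to_dig,
            total_vegetation_area = total_vegetation_area,
            initial_air_pollution = initial_air_pollution,
            initial_solid_waste = initial_solid_waste,
            initial_water_pollution = initial_water_pollution,
            initial_vegetation_destruction = initial_vegetation_destruction,
            initial_land_damage = initial_land_damage)
  bad <- character()
  for (nm in names(p)) {
    v <- p[[nm]]
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      bad <- c(bad, sprintf("'%s' must be a single finite nonnegative number", nm))
  }
  if (is.numeric(p$environmental_investment) &&
      length(p$environmental_investment) == 1L &&
      is.finite(p$environmental_investment) &&
      p$environmental_investment <= 0)
    bad <- c(bad, "'environmental_investment' must be > 0")
  if (length(bad))
    stop(paste(c("invalid parameters:", bad), collapse = "\n  "),
         call. = FALSE)
  structure(p, class = "mine_params")
}

#' Investment allocation policy
#'
#' The five proportions splitting the fixed monthly environmental investment
#' among air pollution control, solid waste treatment, water pollution
#' control, green vegetation and land reclamation.
#'
#' @param air,solid,water,green,land Proportions in \[0, 1\].
#' @param enforce_budget When `TRUE` (default) the proportions must sum to at
#'   most 1 (within 1e-9): they share one budget. Sensitivity scans that vary
#'   a single proportion independently may disable the check, since the five
#'   subsystems are dynamically independent.
#' @return An `allocation_policy` object.
#' @export
allocation_policy <- function(air = 0, solid = 0, water = 0, green = 0,
                              land = 0, enforce_budget = TRUE) {
  p <- c(air = air, solid = solid, water = water, green = green, land = land)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  if (enforce_budget && sum(p) > 1 + 1e-9)
    stop(sprintf("allocation proportions sum to %.4f > 1", sum(p)),
         call. = FALSE)
  structure(as.list(p), class = "allocation_policy")
}

#' Mine model configuration
#'
#' @param params A [mine_params()] object.
#' @param removal_basis `"stock"` (default): every treatment flow drains its
#'   stock in proportion to the current stock, the uniform reading under which
#'   all five subsystems saturate. `"literal"`: solid-waste and water
#'   treatment flows are instead proportional to the current production (their
#'   printed rate equations), leaving a constant net inflow.
#' @param unit_harmonization When `TRUE` (default), the vegetation and land
#'   production constants (printed in m^2) are converted to the 10,000 m^2
#'   unit of their stocks; `FALSE` keeps the raw magnitudes.
#' @return A `mine_config` object.
#' @export
mine_config <- function(params = mine_params(),
                        removal_basis = c("stock", "literal"),
                        unit_harmonization = TRUE) {
  stopifnot(inherits(params, "mine_params"),
            isTRUE(unit_harmonization) || isFALSE(unit_harmonization))
  structure(list(params = params,
                 removal_basis = match.arg(removal_basis),
                 unit_harmonization = unit_harmonization),
            class = "mine_config")
}

#' Treatment technical factor
#'
#' The technical factor of a subsystem's treatment is its investment share:
#' investment = proportion x budget, factor = investment / budget. Both the
#' chained and the algebraically simplified forms are computed and checked
#' equal before the value is returned.
#'
#' @param proportion Investment proportion in \[0, 1\].
#' @param env_investment Environmental investment budget (> 0).
#' @return The technical factor (equals `proportion`).
#' @export
technical_factor <- function(proportion, env_investment) {
  if (!is.numeric(env_investment) || length(env_investment) != 1L ||
      !is.finite(env_investment) || env_investment <= 0)
    stop("env_investment must be a single finite number > 0", call. = FALSE)
  if (!is.numeric(proportion) || anyNA(proportion) ||
      any(proportion < 0) || any(proportion > 1))
    stop("proportion must lie in [0, 1]", call. = FALSE)
  investment <- proportion * env_investment
  chained <- investment / env_investment
  stopifnot(all(abs(chained - proportion) <= 1e-12))
  chained
}

# shared constants every fragment carries; deduplicated on assembly
shared_constants <- function(params) {
  list(sd_constant("environmental_investment", params$environmental_investment,
                   "ten thousand yuan"))
}

investment_chain <- function(tag, proportion) {
  # proportion constant -> investment auxiliary -> technical factor auxiliary
  list(
    constants = list(sd_constant(paste0("prop_", tag), proportion, "fraction")),
    auxiliaries = list(
      sd_aux(paste0("investment_", tag),
             sprintf("prop_%s * environmental_investment", tag)),
      sd_aux(paste0("tech_factor_", tag),
             sprintf("investment_%s / environmental_investment", tag))))
}

#' Build the atmospheric subsystem
#'
#' One stock, air pollution, fed by dust plus waste gas each month and drained
#' by treatment proportional to the current stock times the air technical
#' factor.
#'
#' @param config A [mine_config()].
#' @param policy An [allocation_policy()].
#' @return An [sd_model()] fragment.
#' @export
build_air_subsystem <- function(config = mine_config(),
                                policy = allocation_policy()) {
  stopifnot(inherits(config, "mine_config"),
            inherits(policy, "allocation_policy"))
  p <- config$params
  chain <- investment_chain("air", policy$air)
  use_components <- !is.null(p$no2) && !is.null(p$so2) && !is.null(p$co)
  gas_constants <- if (use_components)
    list(sd_constant("no2", p$no2, "m^2"), sd_constant("so2", p$so2, "m^2"),
         sd_constant("co", p$co, "m^2"))
  else list(sd_constant("waste_gas", p$waste_gas, "m^2"))
  gas_aux <- if (use_components)
    list(sd_aux("waste_gas", "no2 + so2 + co")) else list()
  sd_model(
    constants = c(shared_constants(p), chain$constants,
                  list(sd_constant("dust", p$dust, "m^2")), gas_constants),
    auxiliaries = c(gas_aux, chain$auxiliaries),
    rates = list(
      sd_rate("air_pollution_production", "dust + waste_gas",
              "inflow", "air_pollution"),
      sd_rate("air_pollution_control", "air_pollution * tech_factor_air",
              "outflow", "air_pollution")),
    stocks = list(sd_stock("air_pollution", p$initial_air_pollution, "m^2")))
}

#' Build the solid waste subsystem
#'
#' Solid waste pollution accumulates coal gangue, living garbage and boiler
#' ash. Under the default stock removal basis the treatment flow is
#' proportional to the pollution stock; under the literal basis it is
#' proportional to current production.
#'
#' @inheritParams build_air_subsystem
#' @return An [sd_model()] fragment.
#' @export
build_solid_subsystem <- function(config = mine_config(),
                                  policy = allocation_policy()) {
  stopifnot(inherits(config, "mine_config"),
            inherits(policy, "allocation_policy"))
  p <- config$params
  chain <- investment_chain("solid", policy$solid)
  treat_expr <- if (config$removal_basis == "stock")
    "solid_waste_pollution * tech_factor_solid"
  else "solid_waste_sources * tech_factor_solid"
  sd_model(
    constants = c(shared_constants(p), chain$constants, list(
      sd_constant("coal_gangue", p$coal_gangue, "m^2"),
      sd_constant("living_garbage", p$living_garbage, "m^2"),
      sd_constant("boiler_ash", p$boiler_ash, "m^2"))),
    auxiliaries = c(list(
      sd_aux("solid_waste_sources",
             "coal_gangue + living_garbage + boiler_ash")),
      chain$auxiliaries),
    rates = list(
      sd_rate("solid_waste_production", "solid_waste_sources",
              "inflow", "solid_waste_pollution"),
      sd_rate("solid_waste_treatment", treat_expr,
              "outflow", "solid_waste_pollution")),
    stocks = list(sd_stock("solid_waste_pollution", p$initial_solid_waste,
                           "m^2")))
}

#' Build the water resource subsystem
#'
#' Water pollution accumulates coal gangue leachate sources, life wastewater,
#' mine water and gangue leaching; treatment follows the configured removal
#' basis, as in [build_solid_subsystem()].
#'
#' @inheritParams build_air_subsystem
#' @return An [sd_model()] fragment.
#' @export
build_water_subsystem <- function(config = mine_config(),
                                  policy = allocation_policy()) {
  stopifnot(inherits(config, "mine_config"),
            inherits(policy, "allocation_policy"))
  p <- config$params
  chain <- investment_chain("water", policy$water)
  treat_expr <- if (config$removal_basis == "stock")
    "water_pollution * tech_factor_water"
  else "water_pollution_sources * tech_factor_water"
  sd_model(
    constants = c(shared_constants(p), chain$constants, list(
      sd_constant("coal_gangue", p$coal_gangue, "m^2"),
      sd_constant("life_wastewater", p$life_wastewater, "m^2"),
      sd_constant("mine_water", p$mine_water, "m^2"),
      sd_constant("gangue_leaching", p$gangue_leaching, "m^2"))),
    auxiliaries = c(list(
      sd_aux("water_pollution_sources",
             "coal_gangue + life_wastewater + mine_water + gangue_leaching")),
      chain$auxiliaries),
    rates = list(
      sd_rate("water_pollution_production", "water_pollution_sources",
              "inflow", "water_pollution"),
      sd_rate("water_pollution_control", treat_expr,
              "outflow", "water_pollution")),
    stocks = list(sd_stock("water_pollution", p$initial_water_pollution,
                           "m^2")))
}

harmonize <- function(config, value) {
  if (config$unit_harmonization) value / 1e4 else value
}

#' Build the vegetation cover subsystem
#'
#' The vegetation destruction area grows with mining construction, waste rock
#' piling, open-pit mining and roads, and is restored in proportion to the
#' destroyed area times the greening technical factor. The greening rate
#' auxiliary is the intact fraction of the total vegetation area. With unit
#' harmonization on (default), the m^2 production constants are converted to
#' the 10,000 m^2 unit of the stock.
#'
#' @inheritParams build_air_subsystem
#' @return An [sd_model()] fragment.
#' @export
build_vegetation_subsystem <- function(config = mine_config(),
                                       policy = allocation_policy()) {
  stopifnot(inherits(config, "mine_config"),
            inherits(policy, "allocation_policy"))
  p <- config$params
  chain <- investment_chain("green", policy$green)
  u <- if (config$unit_harmonization) "10,000 m^2" else "m^2"
  sd_model(
    constants = c(shared_constants(p), chain$constants, list(
      sd_constant("construction_square", harmonize(config, p$construction_square), u),
      sd_constant("waste_rock_pile", harmonize(config, p$waste_rock_pile), u),
      sd_constant("open_pit", harmonize(config, p$open_pit), u),
      sd_constant("road", harmonize(config, p$road), u),
      sd_constant("total_vegetation_area", p$total_vegetation_area,
                  "10,000 m^2"))),
    auxiliaries = c(list(
      sd_aux("vegetation_damage_sources",
             "construction_square + waste_rock_pile + open_pit + road"),
      sd_aux("vegetation_greening_rate",
             paste("(total_vegetation_area - vegetation_destruction_area)",
                   "/ total_vegetation_area"))),
      chain$auxiliaries),
    rates = list(
      sd_rate("vegetation_destruction", "vegetation_damage_sources",
              "inflow", "vegetation_destruction_area"),
      sd_rate("vegetation_restoration",
              "vegetation_destruction_area * tech_factor_green",
              "outflow", "vegetation_destruction_area")),
    stocks = list(sd_stock("vegetation_destruction_area",
                           p$initial_vegetation_destruction, "10,000 m^2")))
}

#' Build the land reclamation subsystem
#'
#' The land damage area grows with subsidence and excavation and is reclaimed
#' in proportion to the damaged area times the land technical factor.
#'
#' @inheritParams build_air_subsystem
#' @return An [sd_model()] fragment.
#' @export
build_land_subsystem <- function(config = mine_config(),
                                 policy = allocation_policy()) {
  stopifnot(inherits(config, "mine_config"),
            inherits(policy, "allocation_policy"))
  p <- config$params
  chain <- investment_chain("land", policy$land)
  u <- if (config$unit_harmonization) "10,000 m^2" else "m^2"
  sd_model(
    constants = c(shared_constants(p), chain$constants, list(
      sd_constant("land_subsidence", harmonize(config, p$land_subsidence), u),
      sd_constant("land_to_dig", harmonize(config, p$land_to_dig), u))),
    auxiliaries = c(list(
      sd_aux("land_damage_sources", "land_subsidence + land_to_dig")),
      chain$auxiliaries),
    rates = list(
      sd_rate("land_damage_production", "land_damage_sources",
              "inflow", "land_damage_area"),
      sd_rate("land_reclamation", "land_damage_area * tech_factor_land",
              "outflow", "land_damage_area")),
    stocks = list(sd_stock("land_damage_area", p$initial_land_damage,
                           "10,000 m^2")))
}

#' Names of the five pollution stocks
#' @return Character vector in subsystem order: air, solid, water, vegetation,
#'   land.
#' @export
mine_stock_names <- function() {
  c(air = "air_pollution", solid = "solid_waste_pollution",
    water = "water_pollution", vegetation = "vegetation_destruction_area",
    land = "land_damage_area")
}

#' Assemble the full five-subsystem model
#'
#' Merges the five subsystem fragments into one model sharing the
#' environmental-investment constant. The subsystems are dynamically
#' independent by assumption: no variable of one subsystem appears in
#' another's equations, so the assembled model's per-subsystem trajectories
#' equal those of the fragments simulated alone.
#'
#' @inheritParams build_air_subsystem
#' @return A validated [sd_model()] with five stocks.
#' @export
assemble_mine_model <- function(config = mine_config(),
                                policy = allocation_policy()) {
  frags <- list(build_air_subsystem(config, policy),
                build_solid_subsystem(config, policy),
                build_water_subsystem(config, policy),
                build_vegetation_subsystem(config, policy),
                build_land_subsystem(config, policy))
  constants <- do.call(rbind, lapply(frags, `[[`, "constants"))
  # shared constants (budget, coal gangue) appear in several fragments:
  # deduplicate identical rows, refuse conflicting redefinitions
  constants <- unique(constants)
  dup <- constants$name[duplicated(constants$name)]
  if (length(dup))
    stop(sprintf("conflicting definitions of constant(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  spec <- structure(list(
    constants = constants,
    auxiliaries = do.call(rbind, lapply(frags, `[[`, "auxiliaries")),
    rates = do.call(rbind, lapply(frags, `[[`, "rates")),
    stocks = do.call(rbind, lapply(frags, `[[`, "stocks"))
  ), class = "sd_model")
  diags <- validate_model(spec)
  if (length(diags))
    stop(paste(c("assembled model is invalid:", diags), collapse = "\n  "),
         call. = FALSE)
  spec
}

#' Environmental quality assessment
#'
#' Per-subsystem quality at each time is the relative reduction of the
#' pollution stock against the zero-allocation baseline: `q_i(t) = (B_i(t) -
#' S_i(t)) / B_i(t)`, where `S_i` is the treated stock and `B_i` the baseline
#' stock. It is 0 with no treatment, approaches 1 under complete removal, and
#' is scale-invariant, so subsystems with very different magnitudes and units
#' are comparable. The overall environmental quality assessment is the
#' arithmetic mean of the five subsystem qualities.
#'
#' @param treated Trajectory of the model under some allocation.
#' @param baseline Trajectory of the same configuration under the all-zero
#'   allocation, on the same time grid.
#' @return A `quality_series` object: `time`, `per_subsystem` (data frame, one
#'   column per stock) and `overall` (numeric vector).
#' @export
quality_assessment <- function(treated, baseline) {
  stopifnot(inherits(treated, "sd_trajectory"),
            inherits(baseline, "sd_trajectory"))
  if (!isTRUE(all.equal(treated$time, baseline$time)))
    stop("treated and baseline must share the same time grid", call. = FALSE)
  stocks <- attr(treated, "stocks")
  if (!all(stocks %in% names(baseline)))
    stop("baseline lacks the treated model's stocks", call. = FALSE)
  S <- as.matrix(as.data.frame(treated)[, stocks, drop = FALSE])
  B <- as.matrix(as.data.frame(baseline)[, stocks, drop = FALSE])
  if (any(B == 0))
    stop("baseline stock reaches zero; quality undefined", call. = FALSE)
  q <- (B - S) / B
  structure(list(time = treated$time,
                 per_subsystem = as.data.frame(q),
                 overall = rowMeans(q)),
            class = "quality_series")
}

#' @export
print.quality_series <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("<quality_series> %d time points; final overall quality %.4f\n",
              n, x$overall[n]))
  cat("  final per-subsystem quality:\n")
  print(round(unlist(x$per_subsystem[n, ]), 4))
  invisible(x)
}
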