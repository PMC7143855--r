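#' @title Allocation scenario experiments
#' @description The six published investment-allocation cases, the scenario
#'   runner with its shared zero-allocation baseline, the ranking report and
#'   one-at-a-time sensitivity analysis.
#' @name experiments
NULL

#' The six default allocation scenarios
#'
#' Cases 1-5 each boost one subsystem to a 0.4 share with the other four at
#' 0.15; case 6 splits the budget evenly at 0.2. Every case sums to 1.
#'
#' @return A `scenario_table`: list with `case_id` (integer vector) and
#'   `policies` (list of [allocation_policy()]).
#' @export
default_scenarios <- function() {
  rows <- list(
    allocation_policy(0.40, 0.15, 0.15, 0.15, 0.15),
    allocation_policy(0.15, 0.40, 0.15, 0.15, 0.15),
    allocation_policy(0.15, 0.15, 0.40, 0.15, 0.15),
    allocation_policy(0.15, 0.15, 0.15, 0.40, 0.15),
    allocation_policy(0.15, 0.15, 0.15, 0.15, 0.40),
    allocation_policy(0.20, 0.20, 0.20, 0.20, 0.20))
  scenario_table(seq_along(rows), rows)
}

#' Construct a scenario table
#'
#' @param case_id Unique case identifiers (coerced to integer).
#' @param policies List of [allocation_policy()] objects, one per case.
#' @return A `scenario_table` object.
#' @export
scenario_table <- function(case_id, policies) {
  case_id <- as.integer(case_id)
  if (anyDuplicated(case_id)) stop("case ids must be unique", call. = FALSE)
  if (length(case_id) != length(policies))
    stop("one policy per case id required", call. = FALSE)
  stopifnot(all(vapply(policies, inherits, logical(1), "allocation_policy")))
  structure(list(case_id = case_id, policies = policies),
            class = "scenario_table")
}

#' Run the allocation scenarios
#'
#' Simulates the assembled five-subsystem model once per case plus the shared
#' all-zero baseline, and computes each case's quality series against that
#' baseline. Fully deterministic.
#'
#' @param config A [mine_config()].
#' @param table A `scenario_table`; defaults to the six published cases.
#' @param sim A [sim_config()]; defaults to 24 months at a one-month step.
#' @return A `scenario_results` object: `baseline` trajectory, `results` (one
#'   element per case with `case_id`, `policy`, `trajectory`, `quality`),
#'   plus the active `config` and `sim`.
#' @export
run_scenarios <- function(config = mine_config(), table = default_scenarios(),
                          sim = sim_config()) {
  stopifnot(inherits(config, "mine_config"), inherits(table, "scenario_table"),
            inherits(sim, "sim_config"))
  baseline <- simulate_sd(assemble_mine_model(config, allocation_policy()), sim)
  results <- lapply(seq_along(table$case_id), function(i) {
    traj <- simulate_sd(assemble_mine_model(config, table$policies[[i]]), sim)
    list(case_id = table$case_id[i], policy = table$policies[[i]],
         trajectory = traj, quality = quality_assessment(traj, baseline))
  })
  structure(list(baseline = baseline, results = results,
                 config = config, sim = sim),
            class = "scenario_results")
}

#' Rank scenarios by overall environmental quality
#'
#' Orders the cases by the overall quality assessment, either read at a
#' single month (default: the final one) or averaged over the whole horizon,
#' ties broken by the lower case id. Also reports, per subsystem, the case
#' with the minimal final pollution stock. The report carries the active
#' model options so an ordering is always read together with the assumptions
#' that produced it.
#'
#' @param results A `scenario_results` object.
#' @param at_time Month at which quality is read; must lie on the simulation
#'   grid. Default: the final time.
#' @param aggregate `"at_time"` (default) or `"mean"` over the horizon.
#' @return A `ranking_report`: `ordering` (case ids, best first), `quality`
#'   (named by case id), `per_subsystem_best`, `at_time`, `aggregate`,
#'   `options`.
#' @export
rank_scenarios <- function(results, at_time = NULL,
                           aggregate = c("at_time", "mean")) {
  stopifnot(inherits(results, "scenario_results"))
  aggregate <- match.arg(aggregate)
  times <- results$baseline$time
  if (is.null(at_time)) at_time <- times[length(times)]
  idx <- which(abs(times - at_time) < 1e-9)
  if (length(idx) != 1L)
    stop(sprintf("at_time %s is not on the simulation grid", format(at_time)),
         call. = FALSE)
  ids <- vapply(results$results, `[[`, integer(1), "case_id")
  score <- vapply(results$results, function(r)
    if (aggregate == "mean") mean(r$quality$overall)
    else r$quality$overall[idx], numeric(1))
  ord <- order(-score, ids)
  stocks <- mine_stock_names()
  n <- length(times)
  finals <- vapply(results$results, function(r)
    unlist(as.data.frame(r$trajectory)[n, stocks]), numeric(length(stocks)))
  rownames(finals) <- names(stocks)
  best <- apply(finals, 1L, function(v) ids[order(v, ids)[1L]])
  structure(list(ordering = ids[ord],
                 quality = stats::setNames(score, ids),
                 per_subsystem_best = best,
                 final_stocks = finals,
                 at_time = at_time, aggregate = aggregate,
                 options = list(
                   removal_basis = results$config$removal_basis,
                   unit_harmonization = results$config$unit_harmonization)),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("<ranking_report> overall quality %s (removal_basis=%s, unit_harmonization=%s)\n",
              if (x$aggregate == "mean") "averaged over the horizon"
              else sprintf("at month %s", format(x$at_time)),
              x$options$removal_basis, x$options$unit_harmonization))
  for (i in seq_along(x$ordering)) {
    id <- x$ordering[i]
    cat(sprintf("  rank %d: case %d (overall quality %.4f)\n", i, id,
                x$quality[[as.character(id)]]))
  }
  cat("  best case per subsystem (minimal final stock):\n")
  for (s in names(x$per_subsystem_best))
    cat(sprintf("    %-10s case %d\n", s, x$per_subsystem_best[[s]]))
  invisible(x)
}

#' One-at-a-time sensitivity analysis
#'
#' Varies a single subsystem's investment proportion over a grid while the
#' other four stay at a reference value, and records that subsystem's final
#' stock and final quality for each grid point. The grid may exceed the joint
#' budget: because the subsystems are independent, each point is a
#' well-defined single-subsystem experiment.
#'
#' @param config A [mine_config()].
#' @param subsystem One of `"air"`, `"solid"`, `"water"`, `"vegetation"`,
#'   `"land"`.
#' @param proportion_grid Numeric vector of proportions in \[0, 1\].
#' @param sim A [sim_config()].
#' @param reference Proportion held by the other four subsystems (default
#'   0.15).
#' @return Data frame with columns `proportion`, `final_stock`,
#'   `final_quality`.
#' @export
oat_sensitivity <- function(config = mine_config(), subsystem,
                            proportion_grid, sim = sim_config(),
                            reference = 0.15) {
  stopifnot(inherits(config, "mine_config"), inherits(sim, "sim_config"))
  slots <- c(air = "air", solid = "solid", water = "water",
             vegetation = "green", land = "land")
  if (length(subsystem) != 1L || !subsystem %in% names(slots))
    stop(sprintf("subsystem must be one of: %s",
                 paste(names(slots), collapse = ", ")), call. = FALSE)
  if (!is.numeric(proportion_grid) || any(proportion_grid < 0) ||
      any(proportion_grid > 1))
    stop("proportion_grid values must lie in [0, 1]", call. = FALSE)
  stock <- mine_stock_names()[[subsystem]]
  baseline <- simulate_sd(assemble_mine_model(config, allocation_policy()), sim)
  n <- nrow(baseline)
  rows <- lapply(proportion_grid, function(g) {
    props <- stats::setNames(rep(reference, 5L),
                             c("air", "solid", "water", "green", "land"))
    props[[slots[[subsystem]]]] <- g
    pol <- allocation_policy(props[["air"]], props[["solid"]],
                             props[["water"]], props[["green"]],
                             props[["land"]], enforce_budget = FALSE)
    traj <- simulate_sd(assemble_mine_model(config, pol), sim)
    q <- quality_assessment(traj, baseline)
    data.frame(proportion = g,
               final_stock = traj[[stock]][n],
               final_quality = q$per_subsystem[[stock]][n])
  })
  do.call(rbind, rows)
}
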