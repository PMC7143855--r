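#' @title Discrete-time stock-flow system dynamics engine
#' @description Declarative stock-flow models (constants, auxiliaries, rates,
#'   stocks) integrated with fixed-step explicit Euler, the classic
#'   DYNAMO/Vensim level-rate scheme: `stock.K = stock.J + DT * (inflow.JK -
#'   outflow.JK)`, with all rates and auxiliaries evaluated from the state at
#'   the start of the step.
#' @name sd_engine
NULL

#' Define a model constant
#'
#' @param name Identifier (letters, digits, underscore, dot; must start with a
#'   letter). Unique within a model.
#' @param value Finite numeric value.
#' @param unit Free-text unit label, carried as an inert annotation; no
#'   dimensional analysis is performed.
#' @return A constant definition usable in [sd_model()].
#' @export
sd_constant <- function(name, value, unit = "") {
  list(kind = "constant", name = as.character(name),
       value = as.numeric(value), unit = as.character(unit))
}

#' Define an auxiliary variable
#'
#' An auxiliary is recomputed algebraically each time step from constants,
#' stocks and other auxiliaries. The expression language is arithmetic only:
#' `+ - * /`, parentheses, numeric literals and variable names.
#'
#' @param name Identifier.
#' @param expression Expression text, e.g. `"dust + waste_gas"`.
#' @return An auxiliary definition usable in [sd_model()].
#' @export
sd_aux <- function(name, expression) {
  list(kind = "auxiliary", name = as.character(name),
       expression = as.character(expression))
}

#' Define a rate (flow)
#'
#' @param name Identifier.
#' @param expression Expression text over constants, stocks and auxiliaries.
#' @param direction `"inflow"` (adds to the stock) or `"outflow"` (drains it).
#' @param stock Name of the stock this rate feeds or drains.
#' @return A rate definition usable in [sd_model()].
#' @export
sd_rate <- function(name, expression, direction = c("inflow", "outflow"),
                    stock) {
  direction <- match.arg(direction)
  list(kind = "rate", name = as.character(name),
       expression = as.character(expression), direction = direction,
       stock = as.character(stock))
}

#' Define a stock (level)
#'
#' @param name Identifier.
#' @param initial Finite initial value.
#' @param unit Free-text unit label.
#' @return A stock definition usable in [sd_model()].
#' @export
sd_stock <- function(name, initial, unit = "") {
  list(kind = "stock", name = as.character(name),
       initial = as.numeric(initial), unit = as.character(unit))
}

defs_to_df <- function(defs, kind, fields) {
  if (length(defs) == 0L) {
    out <- lapply(fields, function(f) if (f %in% c("value", "initial")) numeric() else character())
    names(out) <- fields
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  if (is.data.frame(defs)) return(defs[, fields, drop = FALSE])
  if (!is.null(defs$kind)) defs <- list(defs)  # a single bare definition
  rows <- lapply(defs, function(d) {
    stopifnot(identical(d$kind, kind))
    as.data.frame(d[fields], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Construct a stock-flow model specification
#'
#' @param constants,auxiliaries,rates,stocks Lists of definitions created with
#'   [sd_constant()], [sd_aux()], [sd_rate()], [sd_stock()].
#' @return An object of class `sd_model`. Use [validate_model()] to check it;
#'   [simulate_sd()] validates before running.
#' @seealso [simulate_sd()], [euler_step()], [evaluate_step_values()]
#' @export
sd_model <- function(constants = list(), auxiliaries = list(),
                     rates = list(), stocks = list()) {
  m <- structure(list(
    constants   = defs_to_df(constants, "constant", c("name", "value", "unit")),
    auxiliaries = defs_to_df(auxiliaries, "auxiliary", c("name", "expression")),
    rates       = defs_to_df(rates, "rate", c("name", "expression", "direction", "stock")),
    stocks      = defs_to_df(stocks, "stock", c("name", "initial", "unit"))
  ), class = "sd_model")
  m
}

#' @export
print.sd_model <- function(x, ...) {
  cat(sprintf("<sd_model> %d stock(s), %d rate(s), %d auxiliar%s, %d constant(s)\n",
              nrow(x$stocks), nrow(x$rates), nrow(x$auxiliaries),
              if (nrow(x$auxiliaries) == 1L) "y" else "ies", nrow(x$constants)))
  if (nrow(x$stocks)) cat("  stocks:", paste(x$stocks$name, collapse = ", "), "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Fixed-step explicit Euler on a regular grid. The model's native settings
#' are a 24-month horizon at a one-month step.
#'
#' @param initial_time Start time (months).
#' @param final_time End time (months); must exceed `initial_time`.
#' @param dt Positive step (months); `(final_time - initial_time) / dt` must be
#'   a whole number.
#' @return A `sim_config` object.
#' @export
sim_config <- function(initial_time = 0, final_time = 24, dt = 1) {
  if (!is.finite(initial_time) || !is.finite(final_time) || !is.finite(dt))
    stop("sim_config values must be finite", call. = FALSE)
  if (final_time <= initial_time)
    stop("final_time must be greater than initial_time", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  n <- (final_time - initial_time) / dt
  if (abs(n - round(n)) > 1e-8)
    stop("(final_time - initial_time) / dt must be a whole number of steps",
         call. = FALSE)
  structure(list(initial_time = initial_time, final_time = final_time,
                 dt = dt, method = "euler"), class = "sim_config")
}

# Parse an expression and restrict it to arithmetic: + - * / ( ), names,
# numeric literals. Returns list(ok, expr, vars) or list(ok = FALSE, msg).
sd_parse <- function(text) {
  expr <- tryCatch(str2lang(text), error = function(e) NULL)
  if (is.null(expr) || !(is.call(expr) || is.name(expr) || is.numeric(expr)))
    return(list(ok = FALSE, msg = "cannot be parsed as an expression"))
  allowed <- c("+", "-", "*", "/", "(")
  bad <- character()
  walk <- function(e) {
    if (is.name(e) || is.numeric(e)) return(invisible(NULL))
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% allowed) bad <<- c(bad, op)
      for (i in seq_along(e)[-1L]) walk(e[[i]])
      return(invisible(NULL))
    }
    bad <<- c(bad, class(e)[1L])
  }
  walk(expr)
  if (length(bad))
    return(list(ok = FALSE,
                msg = sprintf("uses disallowed operator(s): %s",
                              paste(unique(bad), collapse = ", "))))
  list(ok = TRUE, expr = expr, vars = all.vars(expr))
}

valid_identifier <- function(x) grepl("^[A-Za-z][A-Za-z0-9_.]*$", x)

# Topological order of auxiliaries by Kahn's algorithm.
# Returns list(order = character, cycle = character) — cycle non-empty on failure.
aux_topo_order <- function(aux_names, deps) {
  remaining <- aux_names
  order <- character()
  repeat {
    ready <- remaining[vapply(remaining, function(a)
      !any(deps[[a]] %in% remaining), logical(1))]
    if (!length(ready)) break
    order <- c(order, sort(ready))
    remaining <- setdiff(remaining, ready)
  }
  list(order = order, cycle = sort(remaining))
}

#' Validate a model specification
#'
#' Collects one diagnostic per violation: malformed or non-arithmetic
#' expressions, duplicate or invalid names, references to undefined names,
#' circular auxiliary definitions, rates attached to missing stocks,
#' non-finite constants or initial values. Never raises.
#'
#' @param spec An [sd_model()].
#' @return Character vector of diagnostics; `character(0)` when the model is
#'   valid.
#' @export
validate_model <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  d <- character()
  all_names <- c(spec$constants$name, spec$auxiliaries$name,
                 spec$rates$name, spec$stocks$name)
  dup <- unique(all_names[duplicated(all_names)])
  for (nm in dup) d <- c(d, sprintf("duplicate name '%s'", nm))
  bad_id <- unique(all_names[!valid_identifier(all_names)])
  for (nm in bad_id) d <- c(d, sprintf("invalid identifier '%s'", nm))

  if (nrow(spec$constants) && any(!is.finite(spec$constants$value)))
    for (nm in spec$constants$name[!is.finite(spec$constants$value)])
      d <- c(d, sprintf("constant '%s' has a non-finite value", nm))
  if (nrow(spec$stocks) && any(!is.finite(spec$stocks$initial)))
    for (nm in spec$stocks$name[!is.finite(spec$stocks$initial)])
      d <- c(d, sprintf("stock '%s' has a non-finite initial value", nm))

  referable <- c(spec$constants$name, spec$auxiliaries$name, spec$stocks$name)
  deps <- list()
  check_expr <- function(kind, nm, text) {
    p <- sd_parse(text)
    if (!p$ok) {
      d <<- c(d, sprintf("%s '%s': expression %s", kind, nm, p$msg))
      return(character())
    }
    unknown <- setdiff(p$vars, referable)
    for (u in unknown)
      d <<- c(d, sprintf("%s '%s' references undefined name '%s'", kind, nm, u))
    p$vars
  }
  if (nrow(spec$auxiliaries))
    for (i in seq_len(nrow(spec$auxiliaries))) {
      nm <- spec$auxiliaries$name[i]
      vars <- check_expr("auxiliary", nm, spec$auxiliaries$expression[i])
      deps[[nm]] <- intersect(vars, spec$auxiliaries$name)
    }
  if (nrow(spec$rates))
    for (i in seq_len(nrow(spec$rates))) {
      nm <- spec$rates$name[i]
      check_expr("rate", nm, spec$rates$expression[i])
      if (!spec$rates$stock[i] %in% spec$stocks$name)
        d <- c(d, sprintf("rate '%s' refers to undefined stock '%s'",
                          nm, spec$rates$stock[i]))
      if (!spec$rates$direction[i] %in% c("inflow", "outflow"))
        d <- c(d, sprintf("rate '%s' has invalid direction '%s'",
                          nm, spec$rates$direction[i]))
    }
  if (length(deps)) {
    topo <- aux_topo_order(names(deps), deps)
    if (length(topo$cycle))
      d <- c(d, sprintf("circular auxiliary definitions: %s",
                        paste(topo$cycle, collapse = ", ")))
  }
  d
}

# Pre-parse expressions and fix evaluation order. Assumes a valid spec.
sd_plan <- function(spec) {
  deps <- list()
  aux_exprs <- list()
  if (nrow(spec$auxiliaries))
    for (i in seq_len(nrow(spec$auxiliaries))) {
      nm <- spec$auxiliaries$name[i]
      p <- sd_parse(spec$auxiliaries$expression[i])
      aux_exprs[[nm]] <- p$expr
      deps[[nm]] <- intersect(p$vars, spec$auxiliaries$name)
    }
  order <- if (length(deps)) aux_topo_order(names(deps), deps)$order else character()
  rate_exprs <- list()
  if (nrow(spec$rates))
    for (i in seq_len(nrow(spec$rates)))
      rate_exprs[[spec$rates$name[i]]] <- sd_parse(spec$rates$expression[i])$expr
  list(aux_order = order, aux_exprs = aux_exprs, rate_exprs = rate_exprs)
}

eval_plan <- function(spec, plan, stock_values) {
  env <- new.env(parent = baseenv())
  for (i in seq_len(nrow(spec$constants)))
    assign(spec$constants$name[i], spec$constants$value[i], envir = env)
  for (nm in names(stock_values)) assign(nm, stock_values[[nm]], envir = env)
  out <- numeric(0)
  for (nm in plan$aux_order) {
    v <- eval(plan$aux_exprs[[nm]], envir = env)
    if (!is.finite(v))
      stop(sprintf("evaluation of auxiliary '%s' is non-finite (division by zero?)",
                   nm), call. = FALSE)
    assign(nm, v, envir = env)
    out[nm] <- v
  }
  for (nm in names(plan$rate_exprs)) {
    v <- eval(plan$rate_exprs[[nm]], envir = env)
    if (!is.finite(v))
      stop(sprintf("evaluation of rate '%s' is non-finite (division by zero?)",
                   nm), call. = FALSE)
    out[nm] <- v
  }
  out
}

#' Evaluate auxiliaries and rates at a given stock state
#'
#' Auxiliaries are evaluated in dependency order, then rates; the result holds
#' every auxiliary and rate exactly once. This is the per-step evaluation the
#' integrator performs at the start of each interval.
#'
#' @param spec A valid [sd_model()].
#' @param stock_values Named numeric vector or list covering every stock.
#' @return Named numeric vector of auxiliary and rate values.
#' @export
evaluate_step_values <- function(spec, stock_values) {
  diags <- validate_model(spec)
  if (length(diags))
    stop(paste(c("invalid model:", diags), collapse = "\n  "), call. = FALSE)
  stock_values <- unlist(stock_values)
  missing <- setdiff(spec$stocks$name, names(stock_values))
  if (length(missing))
    stop(sprintf("stock_values missing: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  eval_plan(spec, sd_plan(spec), stock_values[spec$stocks$name])
}

#' Advance every stock by one Euler step
#'
#' Implements the level equation `stock.K = stock.J + dt * (sum of inflows -
#' sum of outflows)`, with rates taken from [evaluate_step_values()] at the
#' current state (explicit Euler).
#'
#' @param spec A valid [sd_model()].
#' @param stock_values Named numeric vector covering every stock.
#' @param dt Positive step.
#' @return Named numeric vector of next stock values.
#' @export
euler_step <- function(spec, stock_values, dt = 1) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
  vals <- evaluate_step_values(spec, stock_values)
  advance_stocks(spec, unlist(stock_values), vals, dt)
}

advance_stocks <- function(spec, state, vals, dt) {
  out <- state[spec$stocks$name]
  if (nrow(spec$rates))
    for (i in seq_len(nrow(spec$rates))) {
      sgn <- if (spec$rates$direction[i] == "inflow") 1 else -1
      s <- spec$rates$stock[i]
      out[s] <- out[s] + dt * sgn * vals[[spec$rates$name[i]]]
    }
  out
}

#' Simulate a stock-flow model
#'
#' Iterates [euler_step()] over the whole grid. Every model variable is
#' recorded at every grid point: stocks as integrated, auxiliaries and rates
#' as evaluated at the state holding at that time. The engine is fully
#' deterministic.
#'
#' @param spec A valid [sd_model()].
#' @param config A [sim_config()].
#' @return A data frame of class `sd_trajectory`: column `time`, then stocks,
#'   auxiliaries and rates in declaration order. Attributes `stocks`,
#'   `auxiliaries` and `rates` carry the variable names by role.
#' @examples
#' m <- sd_model(
#'   constants = list(sd_constant("production", 4824)),
#'   auxiliaries = list(sd_aux("removal_fraction", "0.4")),
#'   rates = list(
#'     sd_rate("inflow_rate", "production", "inflow", "pollution"),
#'     sd_rate("treatment", "pollution * removal_fraction", "outflow", "pollution")),
#'   stocks = list(sd_stock("pollution", 300)))
#' traj <- simulate_sd(m, sim_config(0, 24, 1))
#' tail(traj$pollution, 1)
#' @export
simulate_sd <- function(spec, config = sim_config()) {
  diags <- validate_model(spec)
  if (length(diags))
    stop(paste(c("invalid model:", diags), collapse = "\n  "), call. = FALSE)
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(round((config$final_time - config$initial_time) / config$dt))
  times <- config$initial_time + (0:n) * config$dt
  plan <- sd_plan(spec)
  state <- stats::setNames(spec$stocks$initial, spec$stocks$name)
  var_names <- c(spec$stocks$name, plan$aux_order, names(plan$rate_exprs))
  out <- matrix(NA_real_, nrow = n + 1L, ncol = length(var_names),
                dimnames = list(NULL, var_names))
  for (k in 0:n) {
    vals <- tryCatch(eval_plan(spec, plan, state), error = function(e)
      stop(sprintf("at time %s: %s", format(times[k + 1L]),
                   conditionMessage(e)), call. = FALSE))
    out[k + 1L, ] <- c(state, vals)[var_names]
    if (k < n) state <- advance_stocks(spec, state, vals, config$dt)
  }
  traj <- data.frame(time = times, out, check.names = FALSE)
  # re-order value columns to declaration order: stocks, auxiliaries, rates
  decl <- c("time", spec$stocks$name, spec$auxiliaries$name, spec$rates$name)
  traj <- traj[, decl, drop = FALSE]
  structure(traj,
            class = c("sd_trajectory", "data.frame"),
            stocks = spec$stocks$name,
            auxiliaries = spec$auxiliaries$name,
            rates = spec$rates$name,
            sim = config)
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat(sprintf("<sd_trajectory> %d time points (%s to %s), %d variable(s)\n",
              nrow(x), format(x$time[1L]), format(x$time[nrow(x)]),
              ncol(x) - 1L))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
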