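#' @title Configuration files, serialization and run manifests
#' @description Plain-text I/O: YAML/JSON model configuration with all
#'   published defaults embedded (an empty file reproduces the published
#'   model), CSV trajectory round-tripping, and a JSON run manifest recording
#'   the active options for reproducibility.
#' @name io_interface
NULL

mine_validation_error <- function(msg) {
  structure(class = c("minesd_validation", "error", "condition"),
            list(message = msg, call = NULL))
}

norm_key <- function(x) gsub("[ \\-]+", "_", tolower(trimws(x)))

PARAM_ALIASES <- c(land_area = "initial_land_damage",
                   air_pollution = "initial_air_pollution",
                   solid_waste_pollution = "initial_solid_waste",
                   water_pollution = "initial_water_pollution",
                   vegetation_destruction_area = "initial_vegetation_destruction")

ALLOC_ALIASES <- c(p_air = "air", p_solid = "solid", p_water = "water",
                   p_green = "green", p_land = "land",
                   vegetation = "green")

#' Load a model configuration file
#'
#' Reads a YAML (or JSON, by file extension) configuration with optional
#' sections `params`, `allocation`, `options`, `simulation` and `scenarios`.
#' Every missing field falls back to the published defaults, so an empty file
#' yields the default model (budget 50, 24 months, dt 1). Unknown keys
#' produce a warning naming them; invalid values produce one error listing
#' every violation.
#'
#' Accepted aliases: `land_area` for the initial land damage stock (and the
#' other state-variable names for their `initial_*` parameters); `p_air` ...
#' `p_land` for the allocation proportions.
#'
#' @param path Path to the configuration file.
#' @return List with `config` ([mine_config()]), `policy` (an
#'   [allocation_policy()] or `NULL` when no `allocation` section is given),
#'   `scenarios` (a [scenario_table()] or `NULL`) and `sim` ([sim_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(mine_validation_error(sprintf("config file not found: %s", path)))
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }, error = function(e)
    stop(mine_validation_error(sprintf("cannot parse config '%s': %s", path,
                                       conditionMessage(e)))))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop(mine_validation_error("config must be a mapping of sections"))
  known_sections <- c("params", "allocation", "options", "simulation",
                      "scenarios")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown))
    warning(sprintf("ignoring unknown config section(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  problems <- character()

  # --- params ---------------------------------------------------------------
  pr <- as.list(raw$params)
  names(pr) <- norm_key(names(pr))
  hit <- names(pr) %in% names(PARAM_ALIASES)
  names(pr)[hit] <- PARAM_ALIASES[names(pr)[hit]]
  valid_params <- names(formals(mine_params))
  unknown <- setdiff(names(pr), valid_params)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown parameter(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
    pr <- pr[setdiff(names(pr), unknown)]
  }
  params <- tryCatch(do.call(mine_params, pr), error = function(e) {
    problems <<- c(problems, conditionMessage(e)); NULL
  })

  # --- options --------------------------------------------------------------
  op <- as.list(raw$options)
  names(op) <- norm_key(names(op))
  unknown <- setdiff(names(op), c("removal_basis", "unit_harmonization"))
  if (length(unknown))
    warning(sprintf("ignoring unknown option(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  removal_basis <- op$removal_basis %||% "stock"
  if (!removal_basis %in% c("stock", "literal"))
    problems <- c(problems,
                  sprintf("options$removal_basis must be 'stock' or 'literal', got '%s'",
                          removal_basis))
  unit_harmonization <- op$unit_harmonization %||% TRUE
  if (!is.logical(unit_harmonization) || length(unit_harmonization) != 1L)
    problems <- c(problems, "options$unit_harmonization must be true or false")

  # --- allocation -----------------------------------------------------------
  policy <- NULL
  if (!is.null(raw$allocation)) {
    al <- as.list(raw$allocation)
    orig <- names(al)
    names(al) <- norm_key(names(al))
    hit <- names(al) %in% names(ALLOC_ALIASES)
    names(al)[hit] <- ALLOC_ALIASES[names(al)[hit]]
    slots <- c("air", "solid", "water", "green", "land")
    unknown <- setdiff(names(al), slots)
    if (length(unknown))
      warning(sprintf("ignoring unknown allocation key(s): %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    al <- al[intersect(names(al), slots)]
    vals <- stats::setNames(rep(0, 5L), slots)
    for (k in names(al)) {
      v <- al[[k]]
      shown <- orig[which(norm_key(orig) == k |
                            ALLOC_ALIASES[norm_key(orig)] == k)][1L]
      if (is.na(shown)) shown <- k
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
          v < 0 || v > 1)
        problems <- c(problems,
                      sprintf("allocation '%s' must lie in [0, 1], got %s",
                              shown, format(v)))
      else vals[[k]] <- v
    }
    if (!length(problems))
      policy <- tryCatch(do.call(allocation_policy, as.list(vals)),
                         error = function(e) {
                           problems <<- c(problems, conditionMessage(e)); NULL
                         })
  }

  # --- simulation -----------------------------------------------------------
  si <- as.list(raw$simulation)
  names(si) <- norm_key(names(si))
  unknown <- setdiff(names(si), c("initial_time", "final_time", "dt"))
  if (length(unknown))
    warning(sprintf("ignoring unknown simulation key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  sim <- tryCatch(sim_config(si$initial_time %||% 0, si$final_time %||% 24,
                             si$dt %||% 1),
                  error = function(e) {
                    problems <<- c(problems, conditionMessage(e)); NULL
                  })

  # --- scenarios ------------------------------------------------------------
  scen <- NULL
  if (!is.null(raw$scenarios)) {
    sc <- raw$scenarios
    if (is.data.frame(sc)) sc <- split(sc, seq_len(nrow(sc)))
    pols <- list(); ids <- integer()
    for (i in seq_along(sc)) {
      row <- as.list(sc[[i]])
      names(row) <- norm_key(names(row))
      hit <- names(row) %in% names(ALLOC_ALIASES)
      names(row)[hit] <- ALLOC_ALIASES[names(row)[hit]]
      ids[i] <- as.integer(row$case_id %||% i)
      pol <- tryCatch(
        allocation_policy(row$air %||% 0, row$solid %||% 0, row$water %||% 0,
                          row$green %||% 0, row$land %||% 0),
        error = function(e) {
          problems <<- c(problems,
                         sprintf("scenario %d: %s", i, conditionMessage(e)))
          NULL
        })
      pols[[i]] <- pol
    }
    if (!length(problems)) scen <- scenario_table(ids, pols)
  }

  if (length(problems))
    stop(mine_validation_error(
      paste(c("invalid configuration:", problems), collapse = "\n  ")))
  list(config = mine_config(params, removal_basis, unit_harmonization),
       policy = policy, scenarios = scen, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory as CSV
#'
#' Column order is `time` followed by the model variables in declaration
#' order; values round-trip at full double precision. `read_trajectory()`
#' restores the `sd_trajectory` class but not the variable-role attributes
#' (they live in the model, not the file).
#'
#' @param traj An `sd_trajectory`.
#' @param path Output file (`""` writes to standard output).
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns a data frame of class `sd_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "data.frame"))
  df <- as.data.frame(traj)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 17,
                                                format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  class(df) <- c("sd_trajectory", "data.frame")
  df
}

#' Build a run manifest
#'
#' A small record serialized next to every scenario-run output so a result
#' can be traced back to the options that produced it.
#'
#' @param config A [mine_config()].
#' @param sim A [sim_config()].
#' @param source Config source path, or `"builtin"` for the embedded defaults.
#' @param extra Named list merged into the manifest (e.g. the ranking time).
#' @param timestamp Include the creation time? Disable for byte-identical
#'   reruns.
#' @return Named list.
#' @export
run_manifest <- function(config, sim, source = "builtin", extra = list(),
                         timestamp = TRUE) {
  m <- c(list(package = "minesd",
              version = as.character(utils::packageVersion("minesd")),
              source = source,
              removal_basis = config$removal_basis,
              unit_harmonization = config$unit_harmonization,
              initial_time = sim$initial_time, final_time = sim$final_time,
              dt = sim$dt, method = sim$method),
         extra)
  if (timestamp) m$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  m
}

#' Write a manifest as JSON
#' @param manifest A list from [run_manifest()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
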