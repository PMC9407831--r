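# JSON configuration reading/writing and time-series serialisation.

.config_fields <- list(
  chemical = c("name", "Ds", "Koa", "Ksa", "Kls"),
  surface = c("Ls", "A", "Cs0", "n_layers"),
  room = c("V", "Q", "Cout", "Ca0", "h"),
  liquid = c("Cl", "m0"),
  simulation = c("mode", "t_end", "output_interval"),
  numerics = c("n_layers", "dt_init", "convergence_rtol", "theta",
               "max_refinements")
)

#' Load a scenario (and optional numerics) from a JSON configuration
#'
#' The configuration is a JSON object with sections `chemical`, `surface`,
#' `room`, `liquid` (omitted in stage-2-only mode), `simulation` and
#' optionally `numerics`; field names mirror the constructor arguments and
#' all values are in internal SI units (ug, m, s).  Unknown sections or
#' keys are rejected with a listing; validation problems are aggregated
#' into a single error report.  A missing `Kls` is filled as `Koa/Ksa`.
#'
#' @param path Path to the JSON file.
#' @return List with elements `scenario` and `numerics` (the latter `NULL`
#'   when no `numerics` section is present).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(sprintf("config parse failure in '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  problems <- character()
  unknown_sections <- setdiff(names(cfg), names(.config_fields))
  if (length(unknown_sections) > 0L)
    problems <- c(problems, sprintf("unknown section(s): %s",
                                    paste(unknown_sections, collapse = ", ")))
  for (sec in intersect(names(cfg), names(.config_fields))) {
    unknown <- setdiff(names(cfg[[sec]]), .config_fields[[sec]])
    if (length(unknown) > 0L)
      problems <- c(problems, sprintf("unknown key(s) in [%s]: %s", sec,
                                      paste(unknown, collapse = ", ")))
  }
  for (sec in c("chemical", "surface", "room", "simulation"))
    if (is.null(cfg[[sec]]))
      problems <- c(problems, sprintf("missing section [%s]", sec))
  if (length(problems) > 0L)
    stop("invalid configuration:\n",
         paste0("  - ", problems, collapse = "\n"), call. = FALSE)

  grab <- function(sec, key, default = NULL) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) default else v
  }
  build <- function() {
    mode <- grab("simulation", "mode", "full")
    liquid <- if (!is.null(cfg$liquid))
      liquid_application(Cl = grab("liquid", "Cl"), m0 = grab("liquid", "m0"))
    if (mode == "full" && is.null(liquid))
      stop("mode 'full' requires a [liquid] section", call. = FALSE)
    scenario(
      chemical = chemical_props(
        name = grab("chemical", "name", "unnamed"),
        Ds = grab("chemical", "Ds"), Koa = grab("chemical", "Koa"),
        Ksa = grab("chemical", "Ksa"), Kls = grab("chemical", "Kls")),
      surface = surface_spec(
        Ls = grab("surface", "Ls"), A = grab("surface", "A"),
        Cs0 = grab("surface", "Cs0", 0),
        n_layers = grab("surface", "n_layers", 10L)),
      room = room_spec(
        V = grab("room", "V"), Q = grab("room", "Q"),
        h = grab("room", "h"), Cout = grab("room", "Cout", 0),
        Ca0 = grab("room", "Ca0", 0)),
      liquid = liquid,
      mode = mode,
      t_end = grab("simulation", "t_end"),
      output_interval = grab("simulation", "output_interval"))
  }
  s <- tryCatch(build(), error = function(e)
    stop(sprintf("configuration '%s' failed validation:\n  %s", path,
                 conditionMessage(e)), call. = FALSE))
  numerics <- if (!is.null(cfg$numerics)) {
    nn <- cfg$numerics
    numerics_config(
      n_layers = nn$n_layers, dt_init = nn$dt_init,
      convergence_rtol = if (is.null(nn$convergence_rtol)) 1e-3
                         else nn$convergence_rtol,
      theta = if (is.null(nn$theta)) 0.5 else nn$theta,
      max_refinements = if (is.null(nn$max_refinements)) 18L
                        else nn$max_refinements)
  }
  list(scenario = s, numerics = numerics)
}

#' Write a scenario to a JSON configuration file
#'
#' Produces a configuration that [load_config()] reads back into an
#' identical scenario (field-for-field, to the precision of the textual
#' representation, which is full double precision).
#'
#' @param s A [scenario()].
#' @param path Output file path.
#' @param numerics Optional [numerics_config()] written as a `numerics`
#'   section.
#' @return `path`, invisibly.
#' @export
write_config <- function(s, path, numerics = NULL) {
  stopifnot(inherits(s, "scenario"))
  cfg <- list(
    chemical = list(name = s$chemical$name, Ds = s$chemical$Ds,
                    Koa = s$chemical$Koa, Ksa = s$chemical$Ksa,
                    Kls = s$chemical$Kls),
    surface = list(Ls = s$surface$Ls, A = s$surface$A, Cs0 = s$surface$Cs0,
                   n_layers = s$surface$n_layers),
    room = list(V = s$room$V, Q = s$room$Q, Cout = s$room$Cout,
                Ca0 = s$room$Ca0, h = s$room$h),
    simulation = list(mode = s$mode, t_end = s$t_end,
                      output_interval = s$output_interval)
  )
  if (!is.null(s$liquid))
    cfg$liquid <- list(Cl = s$liquid$Cl, m0 = s$liquid$m0)
  if (!is.null(numerics)) {
    stopifnot(inherits(numerics, "numerics_config"))
    cfg$numerics <- Filter(Negate(is.null), unclass(numerics))
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the simulation time series to CSV
#'
#' Columns: `time_s`, `Ca_ug_m3`, `ml_ug`, `substrate_mass_ug`,
#' `exhaust_cumulative_ug`, `stage`; one row per reported time; numbers in
#' full-precision scientific notation.  Identical inputs and numerics give
#' byte-identical files.
#'
#' @param result An `emission_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  stopifnot(inherits(result, "emission_sim"))
  df <- data.frame(
    time_s = sprintf("%.15e", result$times),
    Ca_ug_m3 = sprintf("%.15e", result$Ca),
    ml_ug = sprintf("%.15e", result$ml),
    substrate_mass_ug = sprintf("%.15e", result$substrate_mass),
    exhaust_cumulative_ug = sprintf("%.15e", result$exhaust_cumulative),
    stage = result$stage,
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a time-series CSV written by [write_timeseries()]
#'
#' @param path Path to the CSV file.
#' @return Data frame with numeric columns and integer `stage`.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), "stage")) df[[nm]] <- as.numeric(df[[nm]])
  df$stage <- as.integer(df$stage)
  df
}
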