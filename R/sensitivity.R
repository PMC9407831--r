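# One-at-a-time parameter sweep engine.

.sweep_paths <- c("chemical.Ds", "chemical.Koa", "chemical.Ksa",
                  "chemical.Kls", "surface.Ls", "surface.A", "surface.Cs0",
                  "room.V", "room.Q", "room.h", "liquid.Cl", "liquid.m0",
                  "koa_ksa_fixed_ratio")

#' Decade-spaced parameter grid
#'
#' Generates a grid with one value per decade, inclusive of both endpoints,
#' which must be an exact number of decades apart.  Descending grids are
#' allowed.
#'
#' @param from,to Positive endpoints.
#' @return Numeric vector from `from` to `to`.
#' @examples
#' decade_grid(5.05e-7, 5.05e-16)  # 10 values
#' @export
decade_grid <- function(from, to) {
  stopifnot(from > 0, to > 0)
  k <- log10(to / from)
  if (abs(k - round(k)) > 1e-6)
    stop("endpoints must be an integer number of decades apart", call. = FALSE)
  k <- round(k)
  out <- from * 10^(seq(0, k, by = sign(k + (k == 0))))
  out[length(out)] <- to
  out
}

#' Specification of a one-parameter sensitivity sweep
#'
#' @param base Base [scenario()]; each sweep row re-runs it with one
#'   parameter replaced.
#' @param parameter Dotted path into the scenario (for example
#'   `"chemical.Ds"` or `"room.Q"`), or `"koa_ksa_fixed_ratio"` to vary the
#'   octanol/gas and substrate/gas partition coefficients together at a
#'   constant ratio so the liquid/substrate coefficient is unchanged.
#' @param values For a scalar parameter, a non-empty vector of positive
#'   values; for the coupled pair, a two-column matrix (or list of pairs)
#'   of `(Koa, Ksa)` values whose ratio is constant.
#' @param numerics A [numerics_config()] applied to every row.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(base, parameter, values,
                       numerics = numerics_config()) {
  stopifnot(inherits(base, "scenario"))
  if (!parameter %in% .sweep_paths)
    stop(sprintf("unknown parameter path '%s'; available: %s", parameter,
                 paste(.sweep_paths, collapse = ", ")), call. = FALSE)
  if (parameter == "koa_ksa_fixed_ratio") {
    if (is.list(values)) values <- do.call(rbind, lapply(values, as.numeric))
    values <- as.matrix(values)
    if (ncol(values) != 2L || nrow(values) == 0L)
      stop("coupled sweep needs a non-empty two-column (Koa, Ksa) matrix",
           call. = FALSE)
    if (any(!is.finite(values)) || any(values <= 0))
      stop("sweep values must be positive and finite", call. = FALSE)
    ratio <- values[, 1L] / values[, 2L]
    if (diff(range(ratio)) > 1e-9 * max(ratio))
      stop("Koa/Ksa ratio must be constant across the coupled sweep",
           call. = FALSE)
  } else {
    values <- as.numeric(values)
    if (length(values) == 0L || any(!is.finite(values)) || any(values <= 0))
      stop("sweep values must be a non-empty vector of positive numbers",
           call. = FALSE)
  }
  structure(list(base = base, parameter = parameter, values = values,
                 numerics = numerics), class = "sweep_spec")
}

# Replace one parameter in a scenario, rebuilding it so validation runs.
apply_sweep_value <- function(base, parameter, value) {
  ch <- base$chemical; su <- base$surface; ro <- base$room; lq <- base$liquid
  if (parameter == "koa_ksa_fixed_ratio") {
    ch$Koa <- value[1L]; ch$Ksa <- value[2L]
  } else {
    parts <- strsplit(parameter, ".", fixed = TRUE)[[1L]]
    obj <- parts[1L]; fld <- parts[2L]
    switch(obj,
           chemical = { ch[[fld]] <- value },
           surface = { su[[fld]] <- value },
           room = { ro[[fld]] <- value },
           liquid = { lq[[fld]] <- value })
  }
  scenario(chemical = chemical_props(ch$name, ch$Ds, ch$Koa, ch$Ksa, ch$Kls),
           surface = surface_spec(su$Ls, su$A, su$Cs0, su$n_layers),
           room = room_spec(ro$V, ro$Q, ro$h, ro$Cout, ro$Ca0),
           liquid = if (!is.null(lq)) liquid_application(lq$Cl, lq$m0),
           mode = base$mode, t_end = base$t_end,
           output_interval = base$output_interval)
}

#' Run a sensitivity sweep
#'
#' Each row is an independent [simulate_scenario()] run (with its own
#' time-step convergence loop) followed by [emission_metrics()].  A row
#' that fails is recorded with its error message and does not abort the
#' sweep.  Rows preserve the requested order.
#'
#' @param spec A [sweep_spec()].
#' @param quiet Suppress per-row progress messages (default `TRUE`).
#' @return An object of class `emission_sweep`: a data frame with the
#'   parameter value(s), the emission metrics, and a `status` column,
#'   carrying the spec as an attribute.
#' @export
run_sweep <- function(spec, quiet = TRUE) {
  stopifnot(inherits(spec, "sweep_spec"))
  coupled <- spec$parameter == "koa_ksa_fixed_ratio"
  nrows <- if (coupled) nrow(spec$values) else length(spec$values)
  rows <- vector("list", nrows)
  for (i in seq_len(nrows)) {
    val <- if (coupled) spec$values[i, ] else spec$values[i]
    if (!quiet)
      message(sprintf("sweep row %d/%d: %s = %s", i, nrows, spec$parameter,
                      paste(signif(val, 4), collapse = ", ")))
    row <- tryCatch({
      s <- apply_sweep_value(spec$base, spec$parameter, val)
      res <- simulate_scenario(s, spec$numerics)
      mt <- emission_metrics(res)
      data.frame(
        t_peak_s = mt$t_peak, C_peak = mt$C_peak,
        f_liquid_to_air = mt$f_liquid_to_air,
        f_liquid_to_substrate = mt$f_liquid_to_substrate,
        f_substrate_to_air = mt$f_substrate_to_air,
        depletion_time_s = if (is.na(mt$depletion_time)) NA_real_
                           else mt$depletion_time,
        stage2_duration_s = if (is.na(mt$stage2_duration)) NA_real_
                            else mt$stage2_duration,
        status = "ok", message = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(t_peak_s = NA_real_, C_peak = NA_real_,
                 f_liquid_to_air = NA_real_,
                 f_liquid_to_substrate = NA_real_,
                 f_substrate_to_air = NA_real_,
                 depletion_time_s = NA_real_, stage2_duration_s = NA_real_,
                 status = "error", message = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    pv <- if (coupled) data.frame(Koa = val[1L], Ksa = val[2L])
          else stats::setNames(data.frame(val), spec$parameter)
    rows[[i]] <- cbind(pv, row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("emission_sweep", "data.frame"),
            parameter = spec$parameter,
            numerics = spec$numerics)
}

#' Extreme values of a sweep metric
#'
#' @param result An `emission_sweep` from [run_sweep()].
#' @param metric Metric column name, e.g. `"f_liquid_to_air"`,
#'   `"t_peak_s"`, `"C_peak"`.
#' @return List with `min` and `max`, each a one-row data frame (parameter
#'   value(s) plus the metric); ties are broken by first occurrence.
#' @export
summarize_extremes <- function(result, metric) {
  stopifnot(inherits(result, "emission_sweep"))
  if (!metric %in% names(result))
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE)
  ok <- result[result$status == "ok" & !is.na(result[[metric]]), ,
               drop = FALSE]
  if (nrow(ok) == 0L)
    stop("no successful sweep rows to summarise", call. = FALSE)
  pcols <- setdiff(names(ok), c("t_peak_s", "C_peak", "f_liquid_to_air",
                                "f_liquid_to_substrate", "f_substrate_to_air",
                                "depletion_time_s", "stage2_duration_s",
                                "status", "message"))
  keep <- c(pcols, metric)
  list(min = ok[which.min(ok[[metric]]), keep, drop = FALSE],
       max = ok[which.max(ok[[metric]]), keep, drop = FALSE])
}

#' Write a sweep table to CSV
#'
#' One row per parameter value with all metrics, in full-precision
#' scientific notation.
#'
#' @param result An `emission_sweep`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path) {
  stopifnot(inherits(result, "emission_sweep"))
  df <- as.data.frame(result)
  for (nm in names(df))
    if (is.numeric(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), "", sprintf("%.15e", df[[nm]]))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.emission_sweep <- function(x, ...) {
  cat(sprintf("<emission_sweep: %s, %d rows (%d ok)>\n",
              attr(x, "parameter"), nrow(x), sum(x$status == "ok")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
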