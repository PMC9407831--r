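# Emission/exposure summary metrics derived from a simulation result.

#' Peak air concentration and its time
#'
#' Returns the maximum of the air concentration series and the first time
#' at which it is attained (ties broken by first occurrence).  Real solver
#' results carry a step-level peak cache, which is used when present; a
#' result lacking the cache falls back to the reported series.
#'
#' @param result An `emission_sim` object (or any list with `times` and
#'   `Ca`).
#' @param use_cache Use the solver's step-level peak cache when available
#'   (default `TRUE`).
#' @return A list with `t_peak` (s) and `C_peak` (ug/m^3).  An all-zero
#'   series yields `(0, 0)` with a warning.
#' @export
peak_concentration <- function(result, use_cache = TRUE) {
  if (use_cache && !is.null(result$peak) &&
      is.finite(result$peak$C_peak) && result$peak$C_peak > 0)
    return(list(t_peak = result$peak$t_peak, C_peak = result$peak$C_peak))
  Ca <- result$Ca
  if (length(Ca) == 0L) stop("empty concentration series", call. = FALSE)
  if (all(Ca == 0)) {
    warning("air concentration series is identically zero", call. = FALSE)
    return(list(t_peak = 0, C_peak = 0))
  }
  i <- which.max(Ca)                    # which.max is first-attainment
  list(t_peak = result$times[i], C_peak = Ca[i])
}

#' Emission metrics of a simulation
#'
#' Derives the summary quantities of the two-stage emission profile:
#'
#' * `t_peak`, `C_peak`: time and value of the maximum air concentration;
#' * `f_liquid_to_air`: fraction of the applied chemical mass `m0`
#'   volatilised directly from the liquid during stage 1 (the cumulative
#'   convective transfer at depletion over `m0`);
#' * `f_liquid_to_substrate`: fraction of `m0` absorbed into the substrate
#'   by depletion (substrate mass gain over stage 1 divided by `m0`);
#' * `f_substrate_to_air`: fraction of `m0` re-emitted from the substrate
#'   during stage 2 up to `t_end`, computed from the decrease of the
#'   substrate inventory (unambiguous, unlike splitting the exhaust
#'   integral by provenance);
#' * `stage2_duration`: time from depletion until the air concentration
#'   first falls below 1 % of `C_peak` after the peak (`NA` if the band is
#'   not reached within the horizon).
#'
#' For `mode = "stage2_only"` only `f_substrate_to_air` is defined, relative
#' to the initial substrate mass.
#'
#' @param result An `emission_sim` object.
#' @return An object of class `emission_metrics`.
#' @export
emission_metrics <- function(result) {
  stopifnot(inherits(result, "emission_sim"))
  s <- result$scenario
  pk <- peak_concentration(result)
  full <- s$mode == "full"
  if (full) {
    if (is.na(result$depletion_time))
      stop("mode 'full' result has no depletion event: cannot compute mass fractions",
           call. = FALSE)
    m0 <- s$liquid$m0
    f_l2a <- result$l2a_dep / m0
    f_l2s <- (result$M_dep - result$M0) / m0
    f_s2a <- (result$M_dep - result$M_final) / m0
    t0 <- result$depletion_time
  } else {
    M0 <- max(result$M0, .Machine$double.xmin)
    f_l2a <- NA_real_
    f_l2s <- NA_real_
    f_s2a <- (result$M0 - result$M_final) / M0
    t0 <- 0
  }
  band <- 0.01 * pk$C_peak
  after <- result$times > pk$t_peak & result$Ca < band
  stage2_duration <- if (pk$C_peak > 0 && any(after))
    result$times[which(after)[1L]] - t0 else NA_real_
  structure(list(
    t_peak = pk$t_peak, C_peak = pk$C_peak,
    f_liquid_to_air = f_l2a,
    f_liquid_to_substrate = f_l2s,
    f_substrate_to_air = f_s2a,
    stage2_duration = stage2_duration,
    depletion_time = result$depletion_time,
    mode = s$mode
  ), class = "emission_metrics")
}

#' Stage-1 mass fractions of a simulation
#'
#' Convenience accessor returning only the mass-fraction fields of
#' [emission_metrics()].
#'
#' @param result An `emission_sim` object.
#' @param s Scenario override (defaults to the one stored in `result`).
#' @return Named numeric vector with `f_liquid_to_air`,
#'   `f_liquid_to_substrate` and `f_substrate_to_air`.
#' @export
mass_fractions <- function(result, s = result$scenario) {
  m <- emission_metrics(result)
  c(f_liquid_to_air = m$f_liquid_to_air,
    f_liquid_to_substrate = m$f_liquid_to_substrate,
    f_substrate_to_air = m$f_substrate_to_air)
}

#' @export
print.emission_metrics <- function(x, ...) {
  cat("<emission_metrics>\n")
  cat(sprintf("  C_peak            : %.4g ug/m^3 at t = %.4g h\n",
              x$C_peak, x$t_peak / 3600))
  if (x$mode == "full") {
    cat(sprintf("  liquid -> air     : %.1f %%\n", 100 * x$f_liquid_to_air))
    cat(sprintf("  liquid -> substrate: %.1f %%\n",
                100 * x$f_liquid_to_substrate))
    cat(sprintf("  substrate -> air  : %.1f %% (by t_end)\n",
                100 * x$f_substrate_to_air))
  } else {
    cat(sprintf("  substrate -> air  : %.1f %% of initial substrate mass\n",
                100 * x$f_substrate_to_air))
  }
  if (!is.na(x$stage2_duration))
    cat(sprintf("  stage-2 duration  : %.4g h (to 1%% of peak)\n",
                x$stage2_duration / 3600))
  invisible(x)
}

#' Serialise metrics to a flat JSON file
#'
#' @param metrics An [emission_metrics()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "emission_metrics"))
  x <- unclass(metrics)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
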