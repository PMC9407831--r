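# Domain types and validation.  All quantities are kept in fixed internal
# units: micrograms, metres, seconds (concentrations in ug/m^3).

.chk_num <- function(x, field, positive = TRUE, zero_ok = !positive) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("validation error: '%s' must be a single finite number", field),
         call. = FALSE)
  if (positive && !zero_ok && x <= 0)
    stop(sprintf("validation error: '%s' must be > 0", field), call. = FALSE)
  if (zero_ok && x < 0)
    stop(sprintf("validation error: '%s' must be >= 0", field), call. = FALSE)
  as.numeric(x)
}

#' Transport and partitioning properties of a target chemical
#'
#' Bundles the four coefficients that control chemical transport in the
#' two-stage emission model: the diffusion coefficient in the substrate and
#' three dimensionless equilibrium partition coefficients.  Octanol serves
#' as the surrogate phase for the product liquid, so `Cl/Koa` is the
#' gas-phase concentration in equilibrium with the liquid and governs
#' volatilisation, while `Ksa` governs re-emission from the substrate.
#'
#' @param name Character label for the chemical.
#' @param Ds Diffusion coefficient of the chemical in the substrate (m^2/s).
#' @param Koa Octanol/gas partition coefficient (dimensionless).
#' @param Ksa Substrate (material or skin)/gas partition coefficient
#'   (dimensionless).
#' @param Kls Liquid/substrate partition coefficient (dimensionless), fixing
#'   the substrate surface concentration `Cl/Kls` under the liquid.  When
#'   `NULL` it is derived as `Koa/Ksa` by [resolve_chemical()]; an explicit
#'   value is never overwritten.
#' @return An object of class `chemical_props`.
#' @seealso [resolve_chemical()]
#' @examples
#' acetic <- chemical_props("acetic acid", Ds = 5.05e-10,
#'                          Koa = 1.66e5, Ksa = 6.27e2)
#' resolve_chemical(acetic)$Kls  # Koa/Ksa
#' @export
chemical_props <- function(name, Ds, Koa, Ksa, Kls = NULL) {
  out <- list(
    name = as.character(name)[1L],
    Ds  = .chk_num(Ds, "Ds"),
    Koa = .chk_num(Koa, "Koa"),
    Ksa = .chk_num(Ksa, "Ksa"),
    Kls = if (!is.null(Kls)) .chk_num(Kls, "Kls") else NULL
  )
  structure(out, class = "chemical_props")
}

#' Fill in derivable chemical coefficients
#'
#' Resolves the liquid/substrate partition coefficient: when `Kls` is absent
#' it is estimated as `Koa/Ksa`; a user-supplied `Kls` is kept unchanged.
#' The operation is idempotent.
#'
#' @param props A [chemical_props()] object.
#' @return The same object with `Kls` guaranteed non-`NULL`.
#' @export
resolve_chemical <- function(props) {
  stopifnot(inherits(props, "chemical_props"))
  if (is.null(props$Kls)) props$Kls <- props$Koa / props$Ksa
  props
}

#' Substrate geometry and initial loading
#'
#' @param Ls Substrate thickness (m).
#' @param A Applied surface area (m^2).
#' @param Cs0 Initial chemical concentration in the substrate (ug/m^3),
#'   uniform over the thickness.  Zero for a clean substrate.
#' @param n_layers Number of discretisation layers across the thickness
#'   (default 10).
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(Ls, A, Cs0 = 0, n_layers = 10L) {
  if (length(n_layers) != 1L || !is.finite(n_layers) ||
      n_layers != round(n_layers) || n_layers < 2)
    stop("validation error: 'n_layers' must be an integer >= 2", call. = FALSE)
  structure(list(
    Ls = .chk_num(Ls, "Ls"),
    A = .chk_num(A, "A"),
    Cs0 = .chk_num(Cs0, "Cs0", positive = FALSE, zero_ok = TRUE),
    n_layers = as.integer(n_layers)
  ), class = "surface_spec")
}

#' Well-mixed room air specification
#'
#' @param V Room air volume (m^3).
#' @param Q Ventilation air flow rate (m^3/s); `Q/V` is the air change rate.
#' @param h Convective mass-transfer coefficient at the emitting surface
#'   (m/s).
#' @param Cout Chemical concentration in outdoor (supply) air (ug/m^3).
#' @param Ca0 Initial indoor air concentration (ug/m^3).
#' @return An object of class `room_spec`.
#' @export
room_spec <- function(V, Q, h, Cout = 0, Ca0 = 0) {
  structure(list(
    V = .chk_num(V, "V"),
    Q = .chk_num(Q, "Q", positive = FALSE, zero_ok = TRUE),
    Cout = .chk_num(Cout, "Cout", positive = FALSE, zero_ok = TRUE),
    Ca0 = .chk_num(Ca0, "Ca0", positive = FALSE, zero_ok = TRUE),
    h = .chk_num(h, "h", positive = FALSE, zero_ok = TRUE)
  ), class = "room_spec")
}

#' Applied liquid product
#'
#' The target chemical's concentration in the liquid is held constant while
#' the liquid exists (constant mass-percentage assumption), so `m0/Cl` is
#' the applied liquid volume.
#'
#' @param Cl Chemical concentration in the liquid product (ug/m^3).
#' @param m0 Initial chemical mass in the applied liquid (ug).
#' @return An object of class `liquid_application`.
#' @export
liquid_application <- function(Cl, m0) {
  structure(list(
    Cl = .chk_num(Cl, "Cl"),
    m0 = .chk_num(m0, "m0")
  ), class = "liquid_application")
}

#' A complete simulation scenario
#'
#' @param chemical A [chemical_props()] object (its `Kls` is resolved on
#'   construction).
#' @param surface A [surface_spec()] object.
#' @param room A [room_spec()] object.
#' @param liquid A [liquid_application()] object, required for
#'   `mode = "full"` and forbidden for `mode = "stage2_only"`.
#' @param mode `"full"` simulates stage 1 (liquid present) followed by
#'   stage 2 (substrate re-emission after depletion); `"stage2_only"` starts
#'   from a loaded substrate with no liquid, as when the initial substrate
#'   concentration was measured after the product had already dried.
#' @param t_end Simulation horizon (s).
#' @param output_interval Reporting interval of the result series (s).
#' @return An object of class `scenario`.
#' @export
scenario <- function(chemical, surface, room, liquid = NULL,
                     mode = c("full", "stage2_only"),
                     t_end, output_interval) {
  mode <- match.arg(mode)
  stopifnot(inherits(chemical, "chemical_props"),
            inherits(surface, "surface_spec"),
            inherits(room, "room_spec"))
  if (!is.null(liquid)) stopifnot(inherits(liquid, "liquid_application"))
  s <- structure(list(
    chemical = resolve_chemical(chemical),
    surface = surface,
    room = room,
    liquid = liquid,
    mode = mode,
    t_end = .chk_num(t_end, "t_end"),
    output_interval = .chk_num(output_interval, "output_interval")
  ), class = "scenario")
  errs <- scenario_errors(s)
  if (nrow(errs) > 0L)
    stop("invalid scenario:\n", paste0("  - [", errs$field, "] ",
                                       errs$message, collapse = "\n"),
         call. = FALSE)
  s
}

.finding <- function(severity, field, message) {
  data.frame(severity = severity, field = field, message = message,
             stringsAsFactors = FALSE)
}

.no_findings <- function() {
  data.frame(severity = character(), field = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Check a scenario for consistency
#'
#' Returns a data frame of findings with columns `severity` (`"error"` or
#' `"warning"`), `field` and `message`.  Errors block simulation; warnings
#' (for example a ventilation rate implying an air change rate outside
#' 0.01--100 per hour) do not.  An empty data frame means the scenario is
#' consistent.
#'
#' @param s A [scenario()] object.
#' @return A data frame of findings (possibly empty).
#' @export
validate_scenario <- function(s) {
  f <- .no_findings()
  if (!inherits(s, "scenario")) {
    return(.finding("error", "scenario", "not a 'scenario' object"))
  }
  add <- function(sev, field, msg) f <<- rbind(f, .finding(sev, field, msg))
  ch <- s$chemical; su <- s$surface; ro <- s$room
  for (fd in c("Ds", "Koa", "Ksa", "Kls"))
    if (is.null(ch[[fd]]) || !is.finite(ch[[fd]]) || ch[[fd]] <= 0)
      add("error", fd, "must be a positive finite number")
  if (!is.finite(su$Ls) || su$Ls <= 0) add("error", "Ls", "must be > 0")
  if (!is.finite(su$A) || su$A <= 0) add("error", "A", "must be > 0")
  if (!is.finite(su$Cs0) || su$Cs0 < 0) add("error", "Cs0", "must be >= 0")
  if (su$n_layers < 2) add("error", "n_layers",
                           "spatial grid needs at least 2 layers")
  if (!is.finite(ro$V) || ro$V <= 0) add("error", "V", "must be > 0")
  if (!is.finite(ro$Q) || ro$Q < 0) add("error", "Q", "must be >= 0")
  if (!is.finite(ro$h) || ro$h < 0) add("error", "h", "must be >= 0")
  if (s$mode == "full") {
    if (is.null(s$liquid))
      add("error", "liquid", "mode 'full' requires an applied liquid")
  } else {
    if (!is.null(s$liquid))
      add("error", "liquid",
          "mode 'stage2_only' must not have an applied liquid")
    if (su$Cs0 <= 0)
      add("error", "Cs0",
          "mode 'stage2_only' needs Cs0 > 0: no emission source exists")
  }
  if (!is.finite(s$t_end) || s$t_end <= 0) add("error", "t_end", "must be > 0")
  if (!is.finite(s$output_interval) || s$output_interval <= 0 ||
      s$output_interval > s$t_end)
    add("error", "output_interval", "must satisfy 0 < output_interval <= t_end")
  ach <- ro$Q / ro$V * 3600
  if (is.finite(ach) && (ach < 0.01 || ach > 100))
    add("warning", "Q",
        sprintf("air change rate %.3g / h is outside the typical 0.01-100 / h range", ach))
  f
}

# Findings of severity "error" only (empty data frame when clean).
scenario_errors <- function(s) {
  f <- validate_scenario(s)
  f[f$severity == "error", , drop = FALSE]
}

#' Instantaneous state of the two-stage system
#'
#' @param t Elapsed time (s).
#' @param Cs Substrate concentration per layer (ug/m^3), ordered from the
#'   surface layer downwards.
#' @param Ca Indoor air concentration (ug/m^3).
#' @param ml Chemical mass remaining in the liquid (ug); 0 in stage 2.
#' @param stage Integer stage indicator, 1 or 2.
#' @return An object of class `sim_state`.
#' @export
sim_state <- function(t, Cs, Ca, ml = 0, stage = 1L) {
  stopifnot(is.numeric(Cs), length(Cs) >= 2, all(is.finite(Cs)),
            stage %in% c(1L, 2L))
  structure(list(
    t = .chk_num(t, "t", positive = FALSE, zero_ok = TRUE),
    Cs = as.numeric(Cs),
    Ca = .chk_num(Ca, "Ca", positive = FALSE, zero_ok = TRUE),
    ml = .chk_num(ml, "ml", positive = FALSE, zero_ok = TRUE),
    stage = as.integer(stage)
  ), class = "sim_state")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario: %s, mode = %s>\n", x$chemical$name, x$mode))
  cat(sprintf("  chemical : Ds = %.3g m^2/s, Koa = %.3g, Ksa = %.3g, Kls = %.3g\n",
              x$chemical$Ds, x$chemical$Koa, x$chemical$Ksa, x$chemical$Kls))
  cat(sprintf("  surface  : Ls = %.3g m, A = %.3g m^2, Cs0 = %.3g ug/m^3, %d layers\n",
              x$surface$Ls, x$surface$A, x$surface$Cs0, x$surface$n_layers))
  cat(sprintf("  room     : V = %.3g m^3, Q = %.3g m^3/s (%.3g ACH), h = %.3g m/s\n",
              x$room$V, x$room$Q, x$room$Q / x$room$V * 3600, x$room$h))
  if (!is.null(x$liquid))
    cat(sprintf("  liquid   : Cl = %.3g ug/m^3, m0 = %.3g ug (%.3g mL)\n",
                x$liquid$Cl, x$liquid$m0, x$liquid$m0 / x$liquid$Cl * 1e6))
  cat(sprintf("  horizon  : t_end = %.4g h, reported every %.3g s\n",
              x$t_end / 3600, x$output_interval))
  invisible(x)
}
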