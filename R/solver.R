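# Finite-volume integration of the coupled substrate-diffusion / liquid /
# room-air system.
#
# The substrate of thickness Ls is divided into n_layers equal cells
# (cell-centred finite volume); unknowns are the cell-average substrate
# concentrations plus the room air concentration, advanced jointly by a
# theta-weighted (Crank-Nicolson by default) linear step.  The scheme is
# exactly mass-conservative: the discrete change of substrate mass equals
# the discrete boundary flux at every step, so the global audit residual is
# at round-off level regardless of step size.

#' Numerical settings for the finite-volume solver
#'
#' @param n_layers Optional override of the number of substrate layers;
#'   `NULL` uses the value carried by the surface specification (default 10).
#' @param dt_init Initial time step (s).  `NULL` chooses a step from the
#'   scenario scales (reporting interval, horizon and an estimate of the
#'   stage-1 depletion time); the refinement loop then halves it until the
#'   results converge.
#' @param convergence_rtol Relative tolerance on the change of the peak air
#'   concentration and of the final mass fractions between successive
#'   step-halvings (default `1e-3`).
#' @param theta Implicitness weight of the time scheme in `[0, 1]`:
#'   0.5 is Crank-Nicolson (default), 1 is backward Euler for stiff cases.
#' @param max_refinements Maximum number of step halvings (default 18).
#' @return An object of class `numerics_config`.
#' @export
numerics_config <- function(n_layers = NULL, dt_init = NULL,
                            convergence_rtol = 1e-3, theta = 0.5,
                            max_refinements = 18L) {
  if (!is.null(n_layers)) {
    if (length(n_layers) != 1L || !is.finite(n_layers) ||
        n_layers != round(n_layers) || n_layers < 2)
      stop("validation error: 'n_layers' must be an integer >= 2", call. = FALSE)
    n_layers <- as.integer(n_layers)
  }
  if (!is.null(dt_init)) dt_init <- .chk_num(dt_init, "dt_init")
  theta <- .chk_num(theta, "theta", positive = FALSE, zero_ok = TRUE)
  if (theta > 1) stop("validation error: 'theta' must lie in [0, 1]",
                      call. = FALSE)
  structure(list(
    n_layers = n_layers,
    dt_init = dt_init,
    convergence_rtol = .chk_num(convergence_rtol, "convergence_rtol"),
    theta = theta,
    max_refinements = as.integer(max_refinements)
  ), class = "numerics_config")
}

#' Build the spatial grid over the substrate thickness
#'
#' The substrate is divided into `n_layers` equal layers, so the spacing is
#' `Ls/n_layers` exactly.  `x_nodes` are the `n_layers + 1` layer interfaces
#' running from the surface in contact with the liquid or air (`x = 0`) to
#' the backed, impermeable side (`x = Ls`); `x_centers` are the layer
#' mid-points at which the concentrations are carried.
#'
#' @param surface A [surface_spec()] object.
#' @param numerics Optional [numerics_config()]; its `n_layers` overrides
#'   the surface value.
#' @return An object of class `fd_grid` with fields `n_layers`, `dx`,
#'   `x_nodes` and `x_centers`.
#' @export
build_grid <- function(surface, numerics = NULL) {
  stopifnot(inherits(surface, "surface_spec"))
  n <- surface$n_layers
  if (!is.null(numerics) && !is.null(numerics$n_layers))
    n <- numerics$n_layers
  dx <- surface$Ls / n
  structure(list(
    n_layers = as.integer(n),
    dx = dx,
    x_nodes = (0:n) * dx,
    x_centers = (seq_len(n) - 0.5) * dx
  ), class = "fd_grid")
}

# Linear system dy/dt = J y + b for the state y = (Cs[1..n], Ca).
# Stage 1: Dirichlet surface value Cl/Kls at the top interface (the liquid
# shields the substrate from the air), zero flux at the bottom; the air
# balance sees only the liquid source.  Stage 2: conjugate
# diffusion/convection (Robin) exchange between the surface layer and the
# air through the series conductance of the half-cell diffusion path and
# the boundary layer.
assemble_system <- function(stage, s, grid) {
  n <- grid$n_layers; dx <- grid$dx
  ch <- s$chemical; su <- s$surface; ro <- s$room
  r <- ch$Ds / dx^2
  m <- n + 1L
  J <- matrix(0, m, m)
  b <- numeric(m)
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      J[i, i - 1L] <- r; J[i, i] <- -2 * r; J[i, i + 1L] <- r
    }
  }
  J[n, n - 1L] <- J[n, n - 1L] + r
  J[n, n] <- J[n, n] - r
  hA <- ro$h * su$A
  if (stage == 1L) {
    Csurf <- s$liquid$Cl / ch$Kls
    J[1L, 1L] <- J[1L, 1L] - 3 * r
    J[1L, 2L] <- J[1L, 2L] + r
    b[1L] <- b[1L] + 2 * r * Csurf
    J[m, m] <- -(ro$Q + hA) / ro$V
    b[m] <- (ro$Q * ro$Cout + hA * s$liquid$Cl / ch$Koa) / ro$V
  } else {
    beta <- 2 * ch$Ds / dx            # half-cell diffusive conductance
    g <- if (ro$h <= 0 || beta <= 0) 0
         else ro$h * beta * ch$Ksa / (beta * ch$Ksa + ro$h)
    J[1L, 1L] <- J[1L, 1L] - r - g / (ch$Ksa * dx)
    J[1L, 2L] <- J[1L, 2L] + r
    J[1L, m] <- J[1L, m] + g / dx
    J[m, 1L] <- su$A * g / (ch$Ksa * ro$V)
    J[m, m] <- -(ro$Q + su$A * g) / ro$V
    b[m] <- ro$Q * ro$Cout / ro$V
  }
  list(J = J, b = b)
}

# Pre-factorised theta-weighted step: y_new = P2 %*% y + cvec.
make_stepper <- function(J, b, dt, theta) {
  m <- nrow(J)
  I <- diag(m)
  A1 <- I - theta * dt * J
  list(P2 = solve(A1, I + (1 - theta) * dt * J),
       cvec = solve(A1, dt * b),
       dt = dt)
}

# Default initial time step from the scenario scales.
default_dt <- function(s) {
  cand <- c(s$output_interval, s$t_end / 200)
  if (s$mode == "full") {
    hA <- s$room$h * s$surface$A
    if (hA > 0) {
      est <- s$liquid$m0 * s$chemical$Koa / (hA * s$liquid$Cl)
      if (is.finite(est)) cand <- c(cand, est / 20)
    }
  }
  max(min(cand), s$t_end / 2e5)
}

# One run of the two-stage integration at fixed dt.  Returns the reported
# series plus step-level caches (peak, depletion state, extrema, audit).
integrate_run <- function(s, grid, numerics, dt) {
  n <- grid$n_layers
  ch <- s$chemical; su <- s$surface; ro <- s$room
  A <- su$A; V <- ro$V; Q <- ro$Q; Cout <- ro$Cout
  th <- numerics$theta
  full <- s$mode == "full"
  hA <- ro$h * A
  ClKoa <- if (full) s$liquid$Cl / ch$Koa else 0
  mw <- A * grid$dx                      # mass per unit concentration per cell
  m <- n + 1L

  y <- c(rep(su$Cs0, n), ro$Ca0)
  M <- mw * sum(y[1:n])
  ml <- if (full) s$liquid$m0 else 0
  exhaust <- 0; intake <- 0; l2a <- 0
  total0 <- ml + M + V * ro$Ca0
  t <- 0
  stage <- if (full) 1L else 2L
  dep_time <- NA_real_; M_dep <- NA_real_; l2a_dep <- NA_real_
  Cs_dep <- NULL

  rep_t <- seq(0, s$t_end, by = s$output_interval)
  if (rep_t[length(rep_t)] < s$t_end - 1e-9 * s$t_end)
    rep_t <- c(rep_t, s$t_end)
  nr <- length(rep_t)
  R_Ca <- R_ml <- R_M <- R_ex <- R_in <- R_l2a <- numeric(nr)
  R_Ca[1L] <- y[m]; R_ml[1L] <- ml; R_M[1L] <- M
  ri <- 2L

  peak_C <- y[m]; peak_t <- 0
  min_Ca <- y[m]; min_Cs <- min(y[1:n]); max_Cs <- max(y[1:n])
  max_resid <- 0

  sys <- assemble_system(stage, s, grid)
  st_main <- make_stepper(sys$J, sys$b, dt, th)
  eps_t <- 1e-9 * s$t_end
  n_steps <- 0L

  while (t < s$t_end - eps_t) {
    dtt <- min(dt, s$t_end - t)
    stp <- if (abs(dtt - st_main$dt) <= 1e-12 * dt) st_main
           else make_stepper(sys$J, sys$b, dtt, th)
    y_new <- drop(stp$P2 %*% y) + stp$cvec
    Ca_old <- y[m]; Ca_new <- y_new[m]
    Ca_th <- th * Ca_new + (1 - th) * Ca_old
    M_new <- mw * sum(y_new[1:n])
    ex_step <- Q * Ca_th * dtt
    in_step <- Q * Cout * dtt
    if (stage == 1L) {
      l2a_step <- hA * (ClKoa - Ca_th) * dtt
      ml_new <- ml - l2a_step - (M_new - M)
    } else {
      l2a_step <- 0
      ml_new <- ml
    }
    if (stage == 1L && ml_new < 0) {
      # liquid depletes within this step: truncate it by linear
      # interpolation to the depletion instant
      frac <- if (ml_new < ml) ml / (ml - ml_new) else 0
      y_new <- y + frac * (y_new - y)
      Ca_new <- y_new[m]
      M_new <- M + frac * (M_new - M)
      l2a_step <- frac * l2a_step
      ex_step <- frac * ex_step
      in_step <- frac * in_step
      ml_new <- 0
      dtt <- frac * dtt
    }
    t_new <- t + dtt

    while (ri <= nr && rep_t[ri] <= t_new + eps_t) {
      w <- if (dtt > 0) (rep_t[ri] - t) / dtt else 1
      w <- min(max(w, 0), 1)
      R_Ca[ri] <- Ca_old + w * (Ca_new - Ca_old)
      R_ml[ri] <- ml + w * (ml_new - ml)
      R_M[ri] <- M + w * (M_new - M)
      R_ex[ri] <- exhaust + w * ex_step
      R_in[ri] <- intake + w * in_step
      R_l2a[ri] <- l2a + w * l2a_step
      ri <- ri + 1L
    }

    y <- y_new; M <- M_new; ml <- ml_new
    exhaust <- exhaust + ex_step; intake <- intake + in_step
    l2a <- l2a + l2a_step
    t <- t_new
    n_steps <- n_steps + 1L

    if (Ca_new > peak_C) { peak_C <- Ca_new; peak_t <- t }
    min_Ca <- min(min_Ca, Ca_new)
    cs_rng <- range(y[1:n])
    min_Cs <- min(min_Cs, cs_rng[1L]); max_Cs <- max(max_Cs, cs_rng[2L])
    if (total0 > 0) {
      resid <- (ml + M + V * y[m] + exhaust - intake - total0) / total0
      max_resid <- max(max_resid, abs(resid))
    }

    if (stage == 1L && ml <= 0 && is.na(dep_time)) {
      dep_time <- t; M_dep <- M; l2a_dep <- l2a
      Cs_dep <- y[1:n]
      stage <- 2L
      sys <- assemble_system(2L, s, grid)
      st_main <- make_stepper(sys$J, sys$b, dt, th)
    }
  }

  R_stage <- if (!full) rep(2L, nr)
             else if (is.na(dep_time)) rep(1L, nr)
             else ifelse(rep_t >= dep_time - eps_t, 2L, 1L)

  list(times = rep_t, Ca = R_Ca, ml = R_ml, substrate_mass = R_M,
       exhaust_cumulative = R_ex, intake_cumulative = R_in,
       l2a_cumulative = R_l2a, stage = R_stage,
       depletion_time = dep_time, M_dep = M_dep, l2a_dep = l2a_dep,
       Cs_at_transition = Cs_dep, Cs_final = y[1:n],
       M0 = mw * n * su$Cs0, M_final = M,
       peak = list(t_peak = peak_t, C_peak = peak_C),
       audit = list(max_residual = max_resid, total0 = total0,
                    min_Ca = min_Ca, min_Cs = min_Cs, max_Cs = max_Cs),
       dt = dt, n_steps = n_steps)
}

# Convergence metrics compared between successive step halvings.
run_metrics <- function(run, s) {
  if (s$mode == "full") {
    m0 <- s$liquid$m0
    if (!is.na(run$depletion_time)) {
      f_l2a <- run$l2a_dep / m0
      f_l2s <- (run$M_dep - run$M0) / m0
      f_s2a <- (run$M_dep - run$M_final) / m0
    } else {
      f_l2a <- run$l2a_cumulative[length(run$l2a_cumulative)] / m0
      f_l2s <- (run$M_final - run$M0) / m0
      f_s2a <- 0
    }
    c(peak = run$peak$C_peak, f_l2a = f_l2a, f_l2s = f_l2s, f_s2a = f_s2a)
  } else {
    M0 <- max(run$M0, .Machine$double.xmin)
    c(peak = run$peak$C_peak, f_s2a = (run$M0 - run$M_final) / M0)
  }
}

conv_deltas <- function(m_prev, m_cur) {
  d <- numeric(length(m_cur))
  names(d) <- names(m_cur)
  for (i in seq_along(m_cur)) {
    if (names(m_cur)[i] == "peak") {
      sc <- max(abs(m_prev[i]), abs(m_cur[i]))
      d[i] <- if (sc > 0) abs(m_cur[i] - m_prev[i]) / sc else 0
    } else {
      d[i] <- abs(m_cur[i] - m_prev[i])   # fractions are O(1): absolute
    }
  }
  d
}

#' Simulate a scenario with time-step refinement
#'
#' Integrates the two-stage system.  In `mode = "full"`, stage 1 (liquid
#' source, Dirichlet surface condition, air balance fed by liquid
#' volatilisation) runs from `t = 0` until the liquid chemical mass reaches
#' zero -- the step in which it crosses zero is truncated by linear
#' interpolation to the depletion instant -- and stage 2 (substrate
#' re-emission through a flux-matching surface condition) continues to
#' `t_end`.  In `mode = "stage2_only"` stage 2 runs from a uniformly loaded
#' substrate.  The time step starts at `dt_init` and is halved, rerunning
#' the integration, until the peak air concentration and the final mass
#' fractions change by less than `convergence_rtol` between refinements.
#'
#' @param s A [scenario()] that passes [validate_scenario()] without errors.
#' @param numerics A [numerics_config()].
#' @return An object of class `emission_sim` carrying the reported series
#'   (`times`, `Ca`, `ml`, `substrate_mass`, `exhaust_cumulative`,
#'   `intake_cumulative`, `l2a_cumulative`, `stage`), the depletion time,
#'   the step-level peak cache, the final and transition substrate
#'   profiles, the mass-balance audit, and the numerics actually used.
#' @examples
#' \donttest{
#' res <- simulate_scenario(acetic_acid_floor())
#' res$depletion_time / 3600   # hours of liquid emission
#' }
#' @export
simulate_scenario <- function(s, numerics = numerics_config()) {
  errs <- scenario_errors(s)
  if (nrow(errs) > 0L)
    stop("scenario fails validation:\n",
         paste0("  - [", errs$field, "] ", errs$message, collapse = "\n"),
         call. = FALSE)
  stopifnot(inherits(numerics, "numerics_config"))
  grid <- build_grid(s$surface, numerics)
  dt <- if (!is.null(numerics$dt_init)) numerics$dt_init else default_dt(s)
  dt <- min(dt, s$t_end)
  prev <- integrate_run(s, grid, numerics, dt)
  mp <- run_metrics(prev, s)
  refinements <- NA_integer_
  deltas <- NULL
  for (k in seq_len(numerics$max_refinements)) {
    dt <- dt / 2
    cur <- integrate_run(s, grid, numerics, dt)
    mc <- run_metrics(cur, s)
    deltas <- conv_deltas(mp, mc)
    if (max(deltas) < numerics$convergence_rtol) {
      refinements <- k
      prev <- cur
      break
    }
    prev <- cur; mp <- mc
  }
  if (is.na(refinements))
    stop(sprintf(paste0("time-step refinement did not converge within %d ",
                        "halvings; last deltas: %s"),
                 numerics$max_refinements,
                 paste(sprintf("%s = %.3g", names(deltas), deltas),
                       collapse = ", ")), call. = FALSE)
  finalize_result(prev, s, grid, numerics, refinements, deltas)
}

finalize_result <- function(run, s, grid, numerics, refinements, deltas) {
  rtol <- numerics$convergence_rtol
  neg_scale_Cs <- rtol * max(run$audit$max_Cs, 0)
  neg_scale_Ca <- rtol * max(run$peak$C_peak, 0)
  if (run$audit$min_Cs < -max(neg_scale_Cs, .Machine$double.eps) ||
      run$audit$min_Ca < -max(neg_scale_Ca, .Machine$double.eps))
    stop(sprintf(paste0("persistent negative concentrations beyond tolerance ",
                        "(min Cs = %.3g, min Ca = %.3g): the integration is ",
                        "unstable at the converged step"),
                 run$audit$min_Cs, run$audit$min_Ca), call. = FALSE)
  run$Ca <- pmax(run$Ca, 0)
  run$ml <- pmax(run$ml, 0)
  run$substrate_mass <- pmax(run$substrate_mass, 0)
  structure(c(run, list(
    scenario = s, grid = grid, numerics = numerics,
    refinements = refinements, conv_deltas = deltas
  )), class = "emission_sim")
}

#' @export
print.emission_sim <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("<emission_sim: %s, mode = %s>\n", s$chemical$name, s$mode))
  cat(sprintf("  horizon      : %.4g h, %d reported times\n",
              s$t_end / 3600, length(x$times)))
  if (!is.na(x$depletion_time))
    cat(sprintf("  depletion    : %.4g h (stage 1 -> 2)\n",
                x$depletion_time / 3600))
  cat(sprintf("  peak         : Ca = %.4g ug/m^3 at t = %.4g h\n",
              x$peak$C_peak, x$peak$t_peak / 3600))
  cat(sprintf("  numerics     : dt = %.4g s after %d refinement(s), %d steps\n",
              x$dt, x$refinements, x$n_steps))
  cat(sprintf("  mass audit   : max |residual| = %.3g (relative)\n",
              x$audit$max_residual))
  invisible(x)
}

#' Relative mass-balance residual of a simulation result
#'
#' At each reported time the chemical inventory (liquid mass + substrate
#' mass + air mass `V*Ca` + cumulative exhaust - cumulative intake) is
#' compared with the initial inventory; the signed difference is returned
#' relative to the initial inventory.
#'
#' @param result An `emission_sim` object.
#' @return Numeric vector of signed relative residuals, one per reported
#'   time.
#' @export
mass_balance_residual <- function(result) {
  stopifnot(inherits(result, "emission_sim"))
  V <- result$scenario$room$V
  total0 <- result$audit$total0
  (result$ml + result$substrate_mass + V * result$Ca +
     result$exhaust_cumulative - result$intake_cumulative - total0) /
    max(total0, .Machine$double.xmin)
}

# ---- single-step operations -------------------------------------------------

.advance_state <- function(state, s, grid, numerics, dt) {
  n <- grid$n_layers; m <- n + 1L
  th <- numerics$theta
  mw <- s$surface$A * grid$dx
  sys <- assemble_system(state$stage, s, grid)
  stp <- make_stepper(sys$J, sys$b, dt, th)
  y <- c(state$Cs, state$Ca)
  y_new <- drop(stp$P2 %*% y) + stp$cvec
  Ca_th <- th * y_new[m] + (1 - th) * y[m]
  M_old <- mw * sum(y[1:n]); M_new <- mw * sum(y_new[1:n])
  out <- state
  if (state$stage == 1L) {
    hA <- s$room$h * s$surface$A
    l2a_step <- hA * (s$liquid$Cl / s$chemical$Koa - Ca_th) * dt
    ml_new <- state$ml - l2a_step - (M_new - M_old)
    if (ml_new < 0) {
      frac <- if (ml_new < state$ml) state$ml / (state$ml - ml_new) else 0
      y_new <- y + frac * (y_new - y)
      ml_new <- 0
      dt <- frac * dt
      out$stage <- 2L
      attr(out, "transition") <- state$t + dt
    }
    out$ml <- ml_new
  }
  out$t <- state$t + dt
  out$Cs <- y_new[1:n]
  out$Ca <- y_new[m]
  out
}

#' Advance the system by one step while the liquid layer exists
#'
#' One theta-weighted step of stage 1: the substrate diffuses under the
#' fixed surface concentration `Cl/Kls`, the air balance gains the
#' convective flux `h*A*(Cl/Koa - Ca)` from the liquid, and the liquid
#' chemical mass is decremented by that flux plus the change of the
#' substrate inventory.  If the liquid would cross zero within the step,
#' the step is truncated by linear interpolation to the depletion instant,
#' and the returned state is flagged with a `"transition"` attribute and
#' `stage = 2`.
#'
#' @param state A [sim_state()] with `stage = 1` and `ml > 0`.
#' @param s The [scenario()] (must be `mode = "full"`).
#' @param grid The [build_grid()] grid matching `length(state$Cs)`.
#' @param numerics A [numerics_config()].
#' @param dt Step size (s), `> 0`.
#' @return The advanced `sim_state`.
#' @export
step_stage1 <- function(state, s, grid, numerics = numerics_config(), dt) {
  stopifnot(inherits(state, "sim_state"), inherits(s, "scenario"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (state$stage != 1L) stop("state is not in stage 1", call. = FALSE)
  if (state$ml <= 0) stop("stage 1 requires liquid mass ml > 0", call. = FALSE)
  if (is.null(s$liquid)) stop("scenario has no applied liquid", call. = FALSE)
  stopifnot(length(state$Cs) == grid$n_layers)
  .advance_state(state, s, grid, numerics, dt)
}

#' Advance the system by one step after liquid depletion
#'
#' One theta-weighted step of stage 2: the substrate surface exchanges with
#' the air through the flux-matching condition `Ds dCs/dx = h (Cs/Ksa - Ca)`
#' at `x = 0` (implemented as the series conductance of the half-cell
#' diffusion path and the air boundary layer), with zero flux at the backed
#' side, and the air balance gains the same surface flux.
#'
#' @inheritParams step_stage1
#' @param state A [sim_state()] with `stage = 2`.
#' @return The advanced `sim_state`.
#' @export
step_stage2 <- function(state, s, grid, numerics = numerics_config(), dt) {
  stopifnot(inherits(state, "sim_state"), inherits(s, "scenario"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (state$stage != 2L) stop("state is not in stage 2", call. = FALSE)
  stopifnot(length(state$Cs) == grid$n_layers)
  .advance_state(state, s, grid, numerics, dt)
}

#' Substrate surface concentration implied by a state
#'
#' In stage 1 the surface of the substrate is pinned at `Cl/Kls` by the
#' liquid above it; in stage 2 the surface value is reconstructed from the
#' flux balance between half-cell diffusion and boundary-layer convection.
#'
#' @param state A [sim_state()].
#' @param s The [scenario()].
#' @param grid The matching [build_grid()] grid.
#' @return Surface concentration (ug/m^3).
#' @export
surface_concentration <- function(state, s, grid) {
  if (state$stage == 1L) {
    if (is.null(s$liquid)) stop("stage 1 needs an applied liquid", call. = FALSE)
    return(s$liquid$Cl / s$chemical$Kls)
  }
  beta <- 2 * s$chemical$Ds / grid$dx
  h <- s$room$h
  if (beta <= 0 && h <= 0) return(state$Cs[1L])
  (beta * state$Cs[1L] + h * state$Ca) / (beta + h / s$chemical$Ksa)
}

# ---- closed-form oracles ----------------------------------------------------

#' Closed-form stage-1 air concentration for an impermeable substrate
#'
#' With no diffusion into the substrate, a constant liquid concentration,
#' clean outdoor air and clean initial air, the air balance is a linear
#' first-order ODE with solution
#' `Ca(t) = hACl/Koa / (Q + hA) * (1 - exp(-(Q + hA) t / V))`.
#' This is an independent oracle for testing; it is never used by the
#' solver.
#'
#' @param s A `mode = "full"` [scenario()] with `Cout = 0`, `Ca0 = 0`.
#' @param t Time or vector of times (s).
#' @return Air concentration(s) (ug/m^3).
#' @export
analytic_stage1_impermeable <- function(s, t) {
  stopifnot(inherits(s, "scenario"), s$mode == "full")
  hA <- s$room$h * s$surface$A
  E <- hA * s$liquid$Cl / s$chemical$Koa
  k <- (s$room$Q + hA)
  if (k <= 0) return(E * t / s$room$V)
  E / k * (1 - exp(-k * t / s$room$V))
}

#' Closed-form ventilation decay of the air concentration
#'
#' With no surface exchange (`h = 0`) and clean outdoor air, the room
#' concentration decays as `Ca0 * exp(-Q t / V)`.  Independent oracle for
#' testing.
#'
#' @param Ca0 Initial air concentration (ug/m^3).
#' @param room A [room_spec()].
#' @param t Time or vector of times (s).
#' @return Air concentration(s) (ug/m^3).
#' @export
analytic_ventilation_decay <- function(Ca0, room, t) {
  stopifnot(inherits(room, "room_spec"))
  Ca0 * exp(-room$Q * t / room$V)
}
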