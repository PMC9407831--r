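# Independent naive oracle: fully explicit forward-Euler finite-volume
# integration of the two-stage system.  Deliberately written as a plain
# loop, sharing no stepping code with the package solver.
explicit_oracle <- function(s, n = 40L, dt) {
  dx <- s$surface$Ls / n
  r <- s$chemical$Ds / dx^2
  Cs <- rep(s$surface$Cs0, n)
  Ca <- s$room$Ca0
  A <- s$surface$A; V <- s$room$V; Q <- s$room$Q
  hA <- s$room$h * A; mw <- A * dx
  full <- s$mode == "full"
  ml <- if (full) s$liquid$m0 else 0
  Csurf <- if (full) s$liquid$Cl / s$chemical$Kls else NA_real_
  ClKoa <- if (full) s$liquid$Cl / s$chemical$Koa else NA_real_
  Ksa <- s$chemical$Ksa
  beta <- 2 * s$chemical$Ds / dx
  g <- if (s$room$h <= 0 || beta <= 0) 0 else
    s$room$h * beta * Ksa / (beta * Ksa + s$room$h)
  stage <- if (full) 1L else 2L
  t <- 0; l2a <- 0; dep <- NA_real_
  M0 <- mw * sum(Cs); M_dep <- NA_real_; l2a_dep <- NA_real_
  peak <- Ca
  while (t < s$t_end - 1e-9 * s$t_end) {
    dtt <- min(dt, s$t_end - t)
    dCs <- numeric(n)
    if (n > 2) dCs[2:(n - 1)] <- r * (Cs[1:(n - 2)] - 2 * Cs[2:(n - 1)] + Cs[3:n])
    dCs[n] <- r * (Cs[n - 1] - Cs[n])
    if (stage == 1L) {
      dCs[1] <- r * (2 * Csurf - 3 * Cs[1] + Cs[2])
      flux <- hA * (ClKoa - Ca)
      dCa <- (Q * (s$room$Cout - Ca) + flux) / V
    } else {
      q <- g * (Cs[1] / Ksa - Ca)
      dCs[1] <- r * (Cs[2] - Cs[1]) - q / dx
      dCa <- (Q * (s$room$Cout - Ca) + A * q) / V
    }
    Cs_n <- Cs + dtt * dCs
    Ca_n <- Ca + dtt * dCa
    if (stage == 1L) {
      dM <- mw * (sum(Cs_n) - sum(Cs))
      l2a_step <- flux * dtt
      ml_n <- ml - l2a_step - dM
      if (ml_n < 0) {
        frac <- ml / (ml - ml_n)
        Cs_n <- Cs + frac * (Cs_n - Cs)
        Ca_n <- Ca + frac * (Ca_n - Ca)
        l2a_step <- frac * l2a_step
        dtt <- frac * dtt
        ml_n <- 0
      }
      ml <- ml_n
      l2a <- l2a + l2a_step
    }
    Cs <- Cs_n; Ca <- Ca_n; t <- t + dtt
    peak <- max(peak, Ca)
    if (stage == 1L && ml <= 0) {
      dep <- t; M_dep <- mw * sum(Cs); l2a_dep <- l2a; stage <- 2L
    }
  }
  list(peak = peak, dep = dep,
       f_l2a = if (full) l2a_dep / s$liquid$m0 else NA_real_,
       f_l2s = if (full) (M_dep - M0) / s$liquid$m0 else NA_real_,
       f_s2a = if (full) (M_dep - mw * sum(Cs)) / s$liquid$m0
               else (M0 - mw * sum(Cs)) / M0)
}

# A fast-depleting variant of the floor-cleaning scenario (1/10 of the
# chemical mass, 2 h horizon) used where a short two-stage run suffices.
small_scenario <- function() {
  s <- acetic_acid_floor(t_end = 2 * 3600, output_interval = 30)
  s$liquid$m0 <- 2.52e5
  s
}

# Minimal stand-in for a simulation result: just enough structure for the
# series-based peak search.
fake_series_result <- function(times, Ca) list(times = times, Ca = Ca)
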