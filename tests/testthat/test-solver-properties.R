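test_that("chemical mass is conserved on the packaged scenarios", {
  for (res in list(acetic_result(), d5_result())) {
    rtol <- res$numerics$convergence_rtol
    expect_lt(max(abs(mass_balance_residual(res))), 10 * rtol)
    expect_lt(res$audit$max_residual, 10 * rtol)
  }
})

test_that("chemical mass is conserved on randomly generated scenarios", {
  for (seed in 1:10) {
    res <- simulate_scenario(synthetic_scenario(seed))
    expect_lt(max(abs(mass_balance_residual(res))),
              10 * res$numerics$convergence_rtol)
  }
})

test_that("reported series are well-formed and physically admissible", {
  res <- acetic_result()
  n <- length(res$times)
  expect_identical(res$times[1], 0)
  expect_true(all(diff(res$times) > 0))
  for (nm in c("Ca", "ml", "substrate_mass", "exhaust_cumulative",
               "intake_cumulative", "stage"))
    expect_length(res[[nm]], n)
  expect_true(all(res$Ca >= 0))
  expect_true(all(res$ml >= 0))
  expect_true(all(res$substrate_mass >= 0))
  # stage 1: the liquid only loses mass; exhaust only accumulates
  expect_true(all(diff(res$ml) <= 1e-9 * res$scenario$liquid$m0))
  expect_true(all(diff(res$exhaust_cumulative) >= 0))
})

test_that("the stage switches 1 -> 2 exactly once and the state is continuous", {
  res <- acetic_result()
  expect_identical(sort(unique(res$stage)), c(1L, 2L))
  expect_identical(sum(diff(res$stage) != 0L), 1L)
  expect_true(all(diff(res$stage) >= 0L))
  # the air concentration is continuous across the transition: extrapolating
  # the last stage-1 and first stage-2 reporting intervals to the depletion
  # instant must meet (the slope changes there, the value does not)
  i <- which(diff(res$stage) == 1L)[1L]
  td <- res$depletion_time
  left <- res$Ca[i] + (td - res$times[i]) *
    (res$Ca[i] - res$Ca[i - 1L]) / (res$times[i] - res$times[i - 1L])
  right <- res$Ca[i + 1L] - (res$times[i + 1L] - td) *
    (res$Ca[i + 2L] - res$Ca[i + 1L]) / (res$times[i + 2L] - res$times[i + 1L])
  expect_lt(abs(left - right), 0.001 * res$peak$C_peak)
  expect_identical(res$ml[i + 1L], 0)
})

test_that("doubling the spatial resolution barely changes the headline outputs", {
  for (make in list(acetic_acid_floor, d5_skin)) {
    r10 <- simulate_scenario(make(), numerics_config(n_layers = 10L))
    r20 <- simulate_scenario(make(), numerics_config(n_layers = 20L))
    m10 <- emission_metrics(r10); m20 <- emission_metrics(r20)
    expect_lt(abs(m20$C_peak - m10$C_peak) / m10$C_peak, 0.02)
    expect_lt(abs(m20$t_peak - m10$t_peak) / m10$t_peak, 0.02)
    if (!is.na(r10$depletion_time))
      expect_lt(abs(r20$depletion_time - r10$depletion_time) /
                  r10$depletion_time, 0.02)
    for (f in c("f_liquid_to_air", "f_liquid_to_substrate",
                "f_substrate_to_air"))
      if (!is.na(m10[[f]]))
        expect_lt(abs(m20[[f]] - m10[[f]]), 0.02)
  }
})

test_that("the solver is exactly deterministic for fixed inputs", {
  s <- small_scenario()
  r1 <- simulate_scenario(s)
  r2 <- simulate_scenario(s)
  expect_identical(r1$Ca, r2$Ca)
  expect_identical(r1$depletion_time, r2$depletion_time)
  expect_identical(r1$peak, r2$peak)
})

test_that("an unconvergeable refinement budget raises an informative error", {
  s <- small_scenario()
  expect_error(
    simulate_scenario(s, numerics_config(dt_init = 1800,
                                         convergence_rtol = 1e-12,
                                         max_refinements = 1L)),
    "did not converge")
})

test_that("simulation refuses a scenario with validation errors", {
  s <- acetic_acid_floor()
  s$surface$n_layers <- 1L
  expect_error(simulate_scenario(s), "n_layers")
})
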