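test_that("the grid divides the thickness into equal layers", {
  g <- build_grid(surface_spec(Ls = 1.9e-2, A = 0.56, n_layers = 10L))
  expect_identical(g$dx, 1.9e-3)
  expect_length(g$x_nodes, 11L)
  g2 <- build_grid(surface_spec(Ls = 1e-6, A = 2.28, n_layers = 10L))
  expect_identical(g2$dx, 1e-7)
  g3 <- build_grid(surface_spec(Ls = 1, A = 1, n_layers = 2L))
  expect_identical(g3$x_nodes, c(0, 0.5, 1))
  expect_identical(g3$x_centers, c(0.25, 0.75))
  # numerics override wins over the surface value
  g4 <- build_grid(surface_spec(Ls = 1, A = 1, n_layers = 10L),
                   numerics_config(n_layers = 4L))
  expect_identical(g4$n_layers, 4L)
})

test_that("stage-1 equilibrium is a fixed point of the step", {
  s <- acetic_acid_floor()
  Ceq <- s$liquid$Cl / s$chemical$Koa
  s$room$Cout <- Ceq        # ventilation supplies air at the liquid equilibrium
  grid <- build_grid(s$surface)
  st <- sim_state(t = 0, Cs = rep(s$liquid$Cl / s$chemical$Kls, 10),
                  Ca = Ceq, ml = s$liquid$m0, stage = 1L)
  out <- step_stage1(st, s, grid, dt = 60)
  expect_equal(out$Cs, st$Cs, tolerance = 1e-12)
  expect_equal(out$Ca, st$Ca, tolerance = 1e-12)
  expect_equal(out$ml, st$ml, tolerance = 1e-12)
  expect_identical(out$stage, 1L)
})

test_that("with no surface transfer the liquid mass is conserved and the air only ventilates", {
  s <- acetic_acid_floor()
  s$room$h <- 0
  s$chemical$Ds <- 1e-30
  grid <- build_grid(s$surface)
  st <- sim_state(t = 0, Cs = rep(0, 10), Ca = 100, ml = s$liquid$m0,
                  stage = 1L)
  out <- step_stage1(st, s, grid, dt = 60)
  expect_equal(out$ml, s$liquid$m0, tolerance = 1e-12)
  expect_equal(max(abs(out$Cs)), 0)
  # air follows the scalar theta-weighted ventilation update
  k <- s$room$Q / s$room$V
  expect_equal(out$Ca, 100 * (1 - 0.5 * 60 * k) / (1 + 0.5 * 60 * k),
               tolerance = 1e-12)
})

test_that("the stage-1 surface is pinned at the liquid/substrate equilibrium", {
  s <- acetic_acid_floor()
  grid <- build_grid(s$surface)
  st <- sim_state(t = 0, Cs = rep(0, 10), Ca = 0, ml = s$liquid$m0, 1L)
  expect_equal(surface_concentration(st, s, grid), 4.2e10 / 2.65e2)
  expect_equal(surface_concentration(st, s, grid), 1.585e8,
               tolerance = 1e-3)
  # first step from a clean start: air rises, liquid shrinks, top cell loads
  out <- step_stage1(st, s, grid, dt = 60)
  expect_gt(out$Ca, 0)
  expect_lt(out$ml, s$liquid$m0)
  expect_gt(out$Cs[1], 0)
})

test_that("stage-2 equilibrium with the air is a no-flux state", {
  s <- d5_skin()
  s$room$Q <- 0             # remove ventilation so the state is stationary
  grid <- build_grid(s$surface)
  Ca <- s$surface$Cs0 / s$chemical$Ksa
  st <- sim_state(t = 0, Cs = rep(s$surface$Cs0, 10), Ca = Ca, stage = 2L)
  out <- step_stage2(st, s, grid, dt = 10)
  expect_equal(out$Cs, st$Cs, tolerance = 1e-12)
  expect_equal(out$Ca, Ca, tolerance = 1e-12)
})

test_that("the loaded skin initially emits: surface flux is into the air", {
  s <- d5_skin()
  grid <- build_grid(s$surface)
  st <- sim_state(t = 0, Cs = rep(8.80e10, 10), Ca = 0, stage = 2L)
  expect_equal(st$Cs[1] / s$chemical$Ksa, 2.69e6, tolerance = 1e-2)
  out <- step_stage2(st, s, grid, dt = 1)
  expect_gt(out$Ca, 0)
  expect_lt(out$Cs[1], st$Cs[1])
})

test_that("step preconditions are enforced", {
  s <- acetic_acid_floor()
  grid <- build_grid(s$surface)
  st1 <- sim_state(0, rep(0, 10), 0, ml = 1, stage = 1L)
  st2 <- sim_state(0, rep(1, 10), 0, stage = 2L)
  expect_error(step_stage1(st1, s, grid, dt = 0), "dt")
  expect_error(step_stage2(st2, s, grid, dt = -1), "dt")
  expect_error(step_stage1(st2, s, grid, dt = 1), "stage")
  expect_error(step_stage2(st1, s, grid, dt = 1), "stage")
  st0 <- sim_state(0, rep(0, 10), 0, ml = 0, stage = 1L)
  expect_error(step_stage1(st0, s, grid, dt = 1), "ml")
})

test_that("a step that would overdraw the liquid truncates at depletion", {
  s <- acetic_acid_floor()
  grid <- build_grid(s$surface)
  st <- sim_state(0, rep(0, 10), 0, ml = 1, stage = 1L)  # 1 ug left
  out <- step_stage1(st, s, grid, dt = 600)
  expect_identical(out$stage, 2L)
  expect_identical(out$ml, 0)
  trans <- attr(out, "transition")
  expect_true(is.numeric(trans) && trans > 0 && trans < 600)
  expect_equal(out$t, trans)
})
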