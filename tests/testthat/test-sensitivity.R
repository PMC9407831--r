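test_that("decade grids include both endpoints exactly, either direction", {
  g <- decade_grid(5.05e-7, 5.05e-16)
  expect_length(g, 10L)
  expect_identical(g[1], 5.05e-7)
  expect_identical(g[10], 5.05e-16)
  expect_true(all(diff(log10(g)) < 0))
  up <- decade_grid(6.27, 6.27e4)
  expect_length(up, 5L)
  expect_identical(up[5], 6.27e4)
  expect_error(decade_grid(1, 30), "decades")
})

test_that("sweep specs validate the parameter path and values up front", {
  base <- acetic_acid_floor()
  expect_error(sweep_spec(base, "chemical.nope", 1:3), "unknown parameter")
  expect_error(sweep_spec(base, "chemical.Ds", numeric(0)), "non-empty")
  expect_error(sweep_spec(base, "chemical.Ds", c(1e-10, -1)), "positive")
  # coupled pair must keep the Koa/Ksa ratio constant
  expect_error(sweep_spec(base, "koa_ksa_fixed_ratio",
                          rbind(c(1e4, 10), c(1e5, 99))), "ratio")
  ok <- sweep_spec(base, "koa_ksa_fixed_ratio",
                   rbind(c(1.66e4, 62.7), c(1.66e5, 627)))
  expect_s3_class(ok, "sweep_spec")
})

test_that("a single-value sweep equals a direct simulation", {
  s <- small_scenario()
  sw <- run_sweep(sweep_spec(s, "chemical.Ds", s$chemical$Ds))
  m <- emission_metrics(simulate_scenario(s))
  expect_identical(nrow(sw), 1L)
  expect_identical(sw$status, "ok")
  expect_equal(sw$C_peak, m$C_peak)
  expect_equal(sw$f_liquid_to_air, m$f_liquid_to_air)
  expect_equal(sw$t_peak_s, m$t_peak)
})

test_that("rows preserve request order and failures do not abort the sweep", {
  s <- small_scenario()
  vals <- c(5.05e-10, 5.05e-12, 5.05e-11)
  sw <- run_sweep(sweep_spec(s, "chemical.Ds", vals,
                             numerics_config(dt_init = 900,
                                             convergence_rtol = 1e-12,
                                             max_refinements = 1L)))
  expect_identical(sw$chemical.Ds, vals)        # order as requested
  expect_identical(sw$status, rep("error", 3))  # refinement budget too small
  expect_match(sw$message[1], "converge")
  expect_error(summarize_extremes(sw, "C_peak"), "no successful")
})

test_that("liquid-to-air transfer falls as the substrate gets more permeable", {
  s <- small_scenario()
  sw <- run_sweep(sweep_spec(s, "chemical.Ds",
                             c(5.05e-9, 5.05e-11, 5.05e-13)))
  expect_identical(sw$status, rep("ok", 3))
  # values are ordered from large to small Ds: fraction must rise
  expect_true(all(diff(sw$f_liquid_to_air) > 0))
  ex <- summarize_extremes(sw, "f_liquid_to_air")
  expect_identical(ex$min$chemical.Ds, 5.05e-9)
  expect_identical(ex$max$chemical.Ds, 5.05e-13)
})

test_that("extremes break ties by first occurrence", {
  sw <- structure(
    data.frame(chemical.Ds = c(1e-10, 1e-11, 1e-12),
               t_peak_s = c(5, 5, 5), C_peak = c(2, 1, 2),
               f_liquid_to_air = c(0.5, 0.6, 0.7),
               f_liquid_to_substrate = c(0.5, 0.4, 0.3),
               f_substrate_to_air = c(0, 0, 0),
               depletion_time_s = c(1, 1, 1),
               stage2_duration_s = c(NA, NA, NA),
               status = "ok", message = "", stringsAsFactors = FALSE),
    class = c("emission_sweep", "data.frame"), parameter = "chemical.Ds")
  ex <- summarize_extremes(sw, "C_peak")
  expect_identical(ex$max$chemical.Ds, 1e-10)   # first of the tied rows
  ex2 <- summarize_extremes(sw, "t_peak_s")
  expect_identical(ex2$min$chemical.Ds, 1e-10)
})

test_that("sweep tables round-trip through CSV", {
  s <- small_scenario()
  sw <- run_sweep(sweep_spec(s, "chemical.Ds", c(5.05e-10, 5.05e-11)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sweep(sw, path)
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 2L)
  expect_equal(as.numeric(back$f_liquid_to_air), sw$f_liquid_to_air,
               tolerance = 1e-12)
})
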