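test_that("transient solver relaxes to the independent steady Ohmic solution", {
  # near-zero density so inertial history cannot mask the steady balance
  net <- build_default_network(fluid = fluid_properties(density = 1e-6))
  tg <- default_targets()
  p <- initial_params_from_shares(tg, net)
  p <- wk_table(p$outlet, p$Rp, C = p$C / 100, Rd = p$Rd, Pv = p$Pv) # fast tau
  wf <- constant_waveform(lpm(5), period = 0.5)
  res <- run_simulation(net, wf, p, settings = solver_settings(n_cycles = 2),
                        init_state = setNames(rep(0, 15), outlet_names(net)))
  oracle <- oracle_steady_state(net, p, q_in = lpm(5))
  last <- ncol(res$P)
  expect_equal(res$P[names(oracle$P), last], oracle$P, tolerance = 1e-4)
  expect_equal(res$Q[names(oracle$Q), last], oracle$Q, tolerance = 1e-4)
})

test_that("steady Ohmic agreement also holds with an LVAD source", {
  net <- build_default_network(fluid = fluid_properties(density = 1e-6))
  tg <- default_targets()
  p0 <- initial_params_from_shares(tg, net)
  p <- wk_table(p0$outlet, p0$Rp, C = p0$C / 100, Rd = p0$Rd, Pv = p0$Pv)
  g <- lvad_graft("right_axillary", lpm(3))
  res <- run_simulation(net, constant_waveform(lpm(2), period = 0.5), p,
                        lvad = g, settings = solver_settings(n_cycles = 2))
  oracle <- oracle_steady_state(res$network, p, q_in = lpm(2), q_lvad = lpm(3))
  last <- ncol(res$P)
  expect_equal(res$P[names(oracle$P), last], oracle$P, tolerance = 1e-4)
})

test_that("quiescent network stays exactly at rest", {
  net <- build_default_network()
  p <- wk_table(outlet_names(net), Rp = 1e7, C = 1e-9, Rd = 1e8, Pv = 0)
  res <- run_simulation(net, inlet_waveform(0),
                        p, settings = solver_settings(n_cycles = 1))
  expect_true(all(res$Q == 0))
  expect_true(all(res$P == 0))
})

test_that("three-cycle run flags a final-cycle window of T/dt steps", {
  res <- cached_study()$results$baseline
  expect_identical(res$n_per_cycle, 800)
  w <- res$final_window
  expect_length(w, 801L)
  expect_equal(res$time[w[length(w)]] - res$time[w[1]], 0.8, tolerance = 1e-12)
  expect_equal(res$time[length(res$time)], 3 * 0.8, tolerance = 1e-12)
})

test_that("cycle averaging: constants pass through, full-period sines vanish", {
  res <- cached_study()$results$baseline
  n <- length(res$time)
  fake <- res
  tt <- res$time
  fake$Q_out <- rbind(const = rep(3.5, n),
                      sine = sin(2 * pi * tt / 0.8))
  m <- cycle_average(fake, "outlet_flow")
  expect_equal(m[["const"]], 3.5, tolerance = 1e-12)
  expect_lt(abs(m[["sine"]]), 1e-6)
  # generated inlet waveform recovers its declared mean
  wf <- res$inlet
  w <- res$final_window
  expect_equal(num_trapz(tt[w], res$Q_in[w]) / 0.8, wf$mean_flow,
               tolerance = 1e-3)
})

test_that("periodicity residual shrinks with more cycles and gates the baseline", {
  net <- build_default_network()
  p <- cached_params()
  wf <- inlet_waveform(lpm(5))
  vals <- vapply(c(2L, 3L, 5L), function(nc)
    periodicity_check(run_simulation(net, wf, p,
                                     settings = solver_settings(n_cycles = nc))),
    numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[2], 0.01)                 # 3-cycle run-quality gate
  # constant inflow converges towards a steady (trivially periodic) state
  resc <- run_simulation(net, constant_waveform(lpm(5)), p,
                         settings = solver_settings(n_cycles = 3))
  expect_lt(periodicity_check(resc), 1e-3)
})

test_that("inlet plus LVAD volume balances outlet volume within 0.5% per cycle", {
  st <- cached_study()
  for (nm in names(st$results))
    expect_lt(conservation_check(st$results[[nm]]), 5e-3)
})

test_that("halving the time step moves cycle-averaged outlet flows by < 0.5%", {
  net <- build_default_network()
  p <- cached_params()
  wf <- inlet_waveform(lpm(5))
  q1 <- cycle_average(run_simulation(net, wf, p), "outlet_flow")
  q2 <- cycle_average(run_simulation(net, wf, p,
                                     settings = solver_settings(dt = 5e-4)),
                      "outlet_flow")
  expect_lt(max(abs(q2 - q1) / q1), 5e-3)
})

test_that("with negligible inertia and stiff chambers the system superposes", {
  net <- build_default_network(fluid = fluid_properties(density = 1e-6))
  p0 <- initial_params_from_shares(default_targets(), net)
  stiff <- wk_table(p0$outlet, p0$Rp, C = p0$C * 1e6, Rd = p0$Rd, Pv = 0)
  zero_pc <- setNames(rep(0, 15), outlet_names(net))
  s <- solver_settings(n_cycles = 1)
  run1 <- function(heart, pump) {
    run_simulation(net, inlet_waveform(heart), stiff,
                   lvad = lvad_graft("right_femoral", pump),
                   settings = s, init_state = zero_pc)
  }
  r_heart <- run1(lpm(3), 0)
  r_pump <- run1(0, lpm(2))
  r_both <- run1(lpm(3), lpm(2))
  scale <- max(abs(r_both$Q))
  expect_lt(max(abs(r_both$Q - (r_heart$Q + r_pump$Q))) / scale, 1e-6)
})

test_that("femoral perfusion at 3 L/min reverses flow in the thoraco-abdominal trunk", {
  res <- cached_study()$results$FA60
  w <- res$final_window
  tr <- trunk_segments(res$network, include_ascending = FALSE)
  mins <- apply(res$Q[tr, w], 1L, min)
  expect_true(any(mins < 0))
})

test_that("loose-coupling sub-iteration reproduces the monolithic solution", {
  net <- build_default_network()
  p <- cached_params()
  wf <- inlet_waveform(lpm(5))
  s_mono <- solver_settings(n_cycles = 1)
  s_sub <- solver_settings(n_cycles = 1, coupling = "subiteration",
                           coupling_tolerance = 1e-6)
  r1 <- run_simulation(net, wf, p, settings = s_mono)
  r2 <- run_simulation(net, wf, p, settings = s_sub)
  expect_lt(max(abs(r1$P - r2$P)) / max(abs(r1$P)), 1e-4)
  expect_lt(max(abs(r1$Q_out - r2$Q_out)) / max(abs(r1$Q_out)), 1e-3)
})

test_that("missing Windkessel coverage is a hard error", {
  net <- build_default_network()
  p <- cached_params()
  expect_error(run_simulation(net, inlet_waveform(lpm(5)), p[-3, ]),
               "coverage error")
})
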