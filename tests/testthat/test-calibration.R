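test_that("Ohmic initial sizing: larger target shares get smaller Rd", {
  tg <- default_targets()
  net <- build_default_network()
  p <- initial_params_from_shares(tg, net)
  expect_identical(nrow(p), 15L)
  s <- tg$shares[p$outlet]
  # strict inverse ordering wherever shares differ
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(p))) {
    if (s[i] > s[j]) expect_lt(p$Rd[i], p$Rd[j])
  }
  # proximal:distal split and compliance time constant
  expect_equal(p$Rp / (p$Rp + p$Rd), rep(0.06, 15), tolerance = 1e-10)
  expect_equal(p$Rd * p$C, rep(1.5, 15), tolerance = 1e-10)
})

test_that("symmetric two-outlet targets give identical parameter triples", {
  net <- toy_two()
  tg <- calibration_targets(c(left = 50, right = 50))
  p <- initial_params_from_shares(tg, net)
  expect_equal(p$Rp[1], p$Rp[2])
  expect_equal(p$Rd[1], p$Rd[2])
  expect_equal(p$C[1], p$C[2])
})

test_that("single-outlet sizing satisfies the Ohmic identity MAP/CO", {
  net <- toy_single()
  tg <- calibration_targets(c(only = 100), p_sys = mmhg(120),
                            p_dia = mmhg(80), co = lpm(5))
  p <- initial_params_from_shares(tg, net)
  map <- mmhg(80) + (mmhg(120) - mmhg(80)) / 3
  r_up <- oracle_path_resistance(net, "out")
  expect_equal(p$Rp + p$Rd + r_up, map / lpm(5), tolerance = 1e-10)
})

test_that("missing outlet coverage and bad share sums are rejected", {
  net <- toy_two()
  expect_error(calibration_targets(c(left = 50, right = 49)), "sum to 100")
  expect_error(calibration_targets(c(50, 50)), "named")
  tg <- calibration_targets(c(left = 60, wrong_name = 40))
  expect_error(initial_params_from_shares(tg, net), "coverage error")
})

test_that("calibration loop contracts the share error on a mis-split toy", {
  net <- toy_two()
  tg <- calibration_targets(c(left = 50, right = 50))
  p0 <- initial_params_from_shares(tg, net)
  # deliberately mis-split distal resistances (keeps total roughly right)
  bad <- wk_table(p0$outlet, Rp = p0$Rp,
                  C = p0$C, Rd = p0$Rd * c(1.8, 0.6), Pv = p0$Pv)
  cal <- calibrate_windkessel(net, tg, params = bad, max_iter = 6L)
  h <- cal$report$error_history
  expect_gte(length(h), 3L)
  expect_lt(h[2], h[1])
  expect_lt(h[3], h[2])
})

test_that("already-calibrated parameters exit after one evaluation unchanged", {
  st <- cached_study()
  net <- st$config$network
  tg <- st$config$targets
  good <- wk_table(st$params$outlet, st$params$Rp, st$params$C,
                   st$params$Rd, st$params$Pv)
  cal <- calibrate_windkessel(net, tg, params = good)
  expect_true(cal$report$converged)
  expect_identical(cal$report$iterations, 1L)
  expect_identical(cal$params$Rd, good$Rd)   # no update applied
})

test_that("calibrating against shares from a known forward run recovers them", {
  net <- toy_two()
  wf <- inlet_waveform(lpm(4))
  known <- wk_table(c("left", "right"), Rp = c(8e6, 1.2e7), C = c(9e-9, 6e-9),
                    Rd = c(1.2e8, 2.4e8), Pv = 0)
  res <- run_simulation(net, wf, known)
  q <- cycle_average(res, "outlet_flow")
  target_shares <- 100 * q / sum(q)
  pr <- inlet_pressures(res)
  tg <- calibration_targets(target_shares, p_sys = pr[["systolic"]],
                            p_dia = pr[["diastolic"]], co = lpm(4))
  cal <- calibrate_windkessel(net, tg, waveform = wf)
  expect_true(cal$report$converged)
  expect_lt(cal$report$max_share_error, 0.1)
})

test_that("raising one outlet's Rd strictly lowers its achieved share", {
  net <- toy_two()
  tg <- calibration_targets(c(left = 50, right = 50))
  p <- initial_params_from_shares(tg, net)
  wf <- inlet_waveform(lpm(4))
  s0 <- flow_shares(run_simulation(net, wf, p))
  p2 <- wk_table(p$outlet, p$Rp, p$C, p$Rd * c(1.5, 1), p$Pv)
  s1 <- flow_shares(run_simulation(net, wf, p2))
  expect_lt(s1[["left"]], s0[["left"]])
  expect_gt(s1[["right"]], s0[["right"]])
})

test_that("achieved shares always sum to 100 within 0.1 pp", {
  st <- cached_study()
  for (nm in names(st$shares))
    expect_equal(sum(st$shares[[nm]]), 100, tolerance = 1e-3)
})

test_that("calibration report serialises to a readable log", {
  st <- cached_study()
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration_report(st$calibration$report, path)
  txt <- readLines(path)
  expect_true(any(grepl("converged", txt)))
  expect_true(any(grepl("Celiac trunk", txt)))
})
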