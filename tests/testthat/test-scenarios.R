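test_that("flow shares: single outlet takes 100%, symmetric pair splits 50/50", {
  net1 <- toy_single()
  tg1 <- calibration_targets(c(only = 100))
  p1 <- initial_params_from_shares(tg1, net1)
  s1 <- flow_shares(run_simulation(net1, inlet_waveform(lpm(5)), p1))
  expect_equal(s1[["only"]], 100, tolerance = 1e-9)

  net2 <- toy_two()
  tg2 <- calibration_targets(c(left = 50, right = 50))
  p2 <- initial_params_from_shares(tg2, net2)
  s2 <- flow_shares(run_simulation(net2, inlet_waveform(lpm(5)), p2))
  expect_equal(s2[["left"]], 50, tolerance = 1e-6)
  expect_equal(s2[["right"]], 50, tolerance = 1e-6)
})

test_that("variation arithmetic reproduces the reference-table cells", {
  base <- reference_shares("baseline")
  expect_equal(round_half_up(variation_pp(reference_shares("fa40"), base), 1)[["Right femoral artery"]],
               3.5)
  expect_equal(round_half_up(variation_pp(reference_shares("fa60"), base), 1)[["Right femoral artery"]],
               9.2)
  expect_true(all(variation_pp(base, base) == 0))
  expect_error(variation_pp(c(a = 1), c(b = 1)), "outlet mismatch")
})

test_that("relative-change arithmetic follows the narrative convention", {
  expect_equal(relative_change_pct(0.5, 0.9), -44.4)
  expect_equal(relative_change_pct(10.3, 9.3), 10.8)
  expect_equal(relative_change_pct(7, 7), 0)
  expect_error(relative_change_pct(1, 0), "zero baseline")
  # half-away-from-zero rendering at one decimal
  expect_equal(round_half_up(c(-0.45, 0.45, 2.349), 1), c(-0.5, 0.5, 2.3))
})

test_that("instantaneous perfusion split behaves at the extremes", {
  st <- cached_study()
  # no LVAD: all perfusion is cardiac at any instant with forward flow
  expect_equal(end_systolic_split(st$results$baseline, t_es = 0.1),
               c(cardiac = 100, lvad = 0), tolerance = 1e-12)
  # constant inlet 3 L/min + pump 2 L/min -> 60/40 at any instant
  net <- build_default_network()
  res <- run_simulation(net, constant_waveform(lpm(3)), cached_params(),
                        lvad = lvad_graft("right_femoral", lpm(2)),
                        settings = solver_settings(n_cycles = 1))
  expect_equal(end_systolic_split(res, t_es = 0.3),
               c(cardiac = 60, lvad = 40), tolerance = 1e-9)
  # zero total inflow is undefined
  expect_error(end_systolic_split(st$results$baseline, t_es = 0.6),
               "undefined split")
})

test_that("the study produces all five scenarios with frozen boundaries", {
  st <- cached_study()
  expect_setequal(names(st$results),
                  c("baseline", "FA40", "FA60", "AA40", "AA60"))
  # LVAD rates: 40% support = 2 L/min, 60% = 3 L/min of a 5 L/min total
  expect_equal(st$results$FA40$lvad_flow, lpm(2), tolerance = 1e-12)
  expect_equal(st$results$AA60$lvad_flow, lpm(3), tolerance = 1e-12)
  expect_equal(st$results$FA60$inlet$mean_flow, lpm(2), tolerance = 1e-12)
  # bitwise-identical Windkessel tables across every scenario run
  ser <- lapply(st$results, function(r) serialize(r$wk, NULL, version = 3))
  for (k in 2:length(ser)) expect_identical(ser[[k]], ser[[1]])
  expect_s3_class(st$params, "frozen_wk_table")
})

test_that("rendered shares per scenario sum to 100.0 within 0.1", {
  st <- cached_study()
  tab <- st$perfusion
  for (col in c("baseline", "fa40", "fa60", "aa40", "aa60"))
    expect_lt(abs(sum(tab[[col]]) - 100), 0.1 + 1e-9)
})

test_that("axillary perfusion perturbs most non-cannulated outlets less than femoral", {
  st <- cached_study()
  base <- st$shares$baseline
  non_can <- setdiff(names(base),
                     c("Right femoral artery", "Right subclavian artery"))
  for (lvl in c("40", "60")) {
    v_fa <- abs(variation_pp(st$shares[[paste0("FA", lvl)]], base))[non_can]
    v_aa <- abs(variation_pp(st$shares[[paste0("AA", lvl)]], base))[non_can]
    expect_gt(sum(v_aa < v_fa), length(non_can) / 2)
  }
  # the cannulated artery's own share rises under its own perfusion
  expect_gt(st$shares$FA40[["Right femoral artery"]],
            base[["Right femoral artery"]])
  expect_gt(st$shares$FA60[["Right femoral artery"]],
            st$shares$FA40[["Right femoral artery"]])
  expect_gt(st$shares$AA60[["Right subclavian artery"]],
            base[["Right subclavian artery"]])
})

test_that("re-running the study reproduces byte-identical output tables", {
  st <- cached_study()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(st, d1)
  st2 <- run_study()
  write_study(st2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)), readLines(file.path(d1, f)),
                     label = paste("file", f))
  }
})

test_that("a single-cycle run still yields tables but flags periodicity", {
  cfg <- study_config(settings = solver_settings(n_cycles = 1))
  st <- run_study(cfg)
  expect_identical(nrow(st$perfusion), 15L)
  expect_true(all(is.na(st$diagnostics$periodicity)))
  expect_false(any(st$diagnostics$periodic_ok))
})

test_that("study outputs and the YAML config boundary round-trip", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "cardiac_output_lpm: 4.5",
    "pressure: {systolic_mmhg: 110, diastolic_mmhg: 70}",
    "solver: {n_cycles: 2}",
    "waveform: {systolic_fraction: 0.4}",
    "geometry:",
    "  desc_thoracic: {radius_mm: 11}"
  ), cfg_path)
  cfg <- read_study_config(cfg_path)
  expect_equal(cfg$targets$co, lpm(4.5), tolerance = 1e-12)
  expect_equal(cfg$targets$p_sys, mmhg(110), tolerance = 1e-9)
  expect_identical(cfg$settings$n_cycles, 2L)
  expect_equal(cfg$waveform_args$systolic_fraction, 0.4)
  i <- match("desc_thoracic", cfg$network$segments$id)
  expect_equal(cfg$network$segments$radius[i], 0.011, tolerance = 1e-12)
  # Windkessel table file round trip
  p <- cached_params()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_wk_table(p, path)
  back <- read_wk_table(path)
  expect_equal(back$Rd, p$Rd, tolerance = 1e-9)
  expect_identical(back$outlet, p$outlet)
})
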