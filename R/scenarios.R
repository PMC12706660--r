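#' Cycle-averaged flow shares
#'
#' Each outlet's final-cycle mean flow as a percentage of the total outflow.
#'
#' @param result a `simulation_result`.
#' @return named numeric vector, outlet name -> share in percent (sums to
#'   100 up to quadrature error).
#' @export
flow_shares <- function(result) {
  qbar <- cycle_average(result, "outlet_flow")
  total <- sum(qbar)
  if (total <= 0) stop("zero (or negative) total outflow; cannot form shares")
  100 * qbar / total
}

#' Share variation in percentage points
#'
#' The tables' "Variation" convention: scenario share minus baseline share
#' for the same outlet, in percentage points.
#'
#' @param scenario_shares,baseline_shares named share vectors (percent) over
#'   the same outlet set.
#' @return named numeric vector of differences, percentage points.
#' @export
variation_pp <- function(scenario_shares, baseline_shares) {
  if (!setequal(names(scenario_shares), names(baseline_shares)))
    stop("outlet mismatch between scenario and baseline shares")
  scenario_shares - baseline_shares[names(scenario_shares)]
}

#' Relative change in percent
#'
#' The narrative convention: `100 * (scenario - baseline) / baseline`,
#' rendered to one decimal (half away from zero), sign preserved. E.g. a
#' share falling from 0.9% to 0.5% is a 44.4% decrease.
#'
#' @param scenario_share,baseline_share shares in percent (scalars or
#'   equal-length vectors); every baseline share must be > 0.
#' @return relative change(s), percent, rounded to one decimal.
#' @export
relative_change_pct <- function(scenario_share, baseline_share) {
  if (any(baseline_share <= 0))
    stop("relative change undefined for zero baseline share")
  round_half_up(100 * (scenario_share - baseline_share) / baseline_share, 1)
}

#' Instantaneous cardiac/LVAD perfusion split
#'
#' At the instant `t_es` within the final cycle, the cardiac inlet's
#' percentage of the total instantaneous inflow (heart plus pump) and its
#' complement. By default `t_es` is the end of the systolic ejection
#' fraction (the end of peak-flow deceleration); the instant is
#' configurable since different analyses place "end-systole" differently.
#'
#' @param result a `simulation_result`.
#' @param t_es time of evaluation, s, within the final cycle (relative to
#'   cycle start). Default: end of the inlet waveform's systolic fraction.
#' @return named numeric vector `c(cardiac = ..., lvad = ...)`, percent.
#' @export
end_systolic_split <- function(result, t_es = NULL) {
  wf <- result$inlet
  if (is.null(t_es)) t_es <- wf$systolic_fraction * wf$period
  if (t_es < 0 || t_es > wf$period)
    stop("t_es must lie within one cycle [0, T]")
  q_heart <- wf$fun(t_es)
  total <- q_heart + result$lvad_flow
  if (total <= 0)
    stop("undefined split: total instantaneous inflow is not positive at t_es")
  c(cardiac = 100 * q_heart / total, lvad = 100 * result$lvad_flow / total)
}

#' Study configuration
#'
#' Bundles everything [run_study()] needs: the network, the waveform
#' parameters, calibration targets, solver settings and the scenario set.
#' The default replicates the five-condition comparison: baseline (heart
#' 5 L/min), then femoral/axillary perfusion at 40% (heart 3 + pump
#' 2 L/min) and 60% (heart 2 + pump 3 L/min) support, with the total
#' perfusion held at 5 L/min throughout.
#'
#' @param network an `arterial_network`.
#' @param targets a [calibration_targets()] object.
#' @param settings a [solver_settings()].
#' @param period cardiac period, s.
#' @param waveform_args further arguments passed to [inlet_waveform()].
#' @param scenarios named list of scenario definitions; each has `heart`
#'   (mean cardiac flow, m^3/s) and optionally `site` + `lvad` (pump flow).
#' @return an object of class `study_config`.
#' @export
study_config <- function(network = build_default_network(),
                         targets = default_targets(),
                         settings = solver_settings(),
                         period = 0.8, waveform_args = list(),
                         scenarios = default_scenarios(targets$co)) {
  structure(list(network = network, targets = targets, settings = settings,
                 period = period, waveform_args = waveform_args,
                 scenarios = scenarios),
            class = "study_config")
}

#' @rdname study_config
#' @param co total perfusion, m^3/s.
#' @export
default_scenarios <- function(co = lpm(5)) {
  list(
    baseline = list(heart = co),
    FA40 = list(heart = 0.6 * co, site = "right_femoral",  lvad = 0.4 * co),
    FA60 = list(heart = 0.4 * co, site = "right_femoral",  lvad = 0.6 * co),
    AA40 = list(heart = 0.6 * co, site = "right_axillary", lvad = 0.4 * co),
    AA60 = list(heart = 0.4 * co, site = "right_axillary", lvad = 0.6 * co)
  )
}

.scenario_waveform <- function(config, mean_flow) {
  do.call(inlet_waveform,
          c(list(mean_flow = mean_flow, period = config$period),
            config$waveform_args))
}

#' Run the full cannulation-site comparison study
#'
#' Calibrates the Windkessel outlets once on the baseline condition, freezes
#' the parameters, runs every scenario with the frozen set, and assembles
#' the comparison outputs: a perfusion table in the reference layout (per
#' outlet: baseline share, each scenario's share and variation), per-
#' scenario WSS metrics tables, and periodicity / volume-conservation
#' diagnostics. The pipeline is fully deterministic (no randomness
#' anywhere), so repeated runs reproduce byte-identical tables.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, the perfusion table, WSS
#'   metrics, calibrated parameters, calibration report and diagnostics log
#'   are written there as delimited text.
#' @return an object of class `lvad_study`: `calibration` (params + report),
#'   `results` (named list of `simulation_result`), `shares`, `perfusion`
#'   (rendered table), `wss` (named list of metrics tables), `diagnostics`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  base_wf <- .scenario_waveform(config, config$targets$co)
  cal <- calibrate_windkessel(config$network, config$targets,
                              waveform = base_wf,
                              settings = config$settings)
  params <- freeze_params(cal$params)

  results <- list(); shares <- list(); wss <- list(); diag <- list()
  for (nm in names(config$scenarios)) {
    sc <- config$scenarios[[nm]]
    wf <- .scenario_waveform(config, sc$heart)
    graft <- if (!is.null(sc$site)) lvad_graft(sc$site, sc$lvad) else NULL
    res <- tryCatch(
      run_simulation(config$network, wf, params, lvad = graft,
                     settings = config$settings, scenario = nm),
      error = function(e) stop("simulation stage failed in scenario '", nm,
                               "': ", conditionMessage(e)))
    results[[nm]] <- res
    shares[[nm]] <- flow_shares(res)
    wss[[nm]] <- wss_metrics_table(res)
    split <- tryCatch(end_systolic_split(res), error = function(e) c(
      cardiac = NA_real_, lvad = NA_real_))
    diag[[nm]] <- data.frame(
      scenario = nm,
      periodicity = if (config$settings$n_cycles >= 2L)
        periodicity_check(res) else NA_real_,
      conservation = conservation_check(res),
      es_split_cardiac = split[["cardiac"]],
      es_split_lvad = split[["lvad"]],
      stringsAsFactors = FALSE)
  }
  diagnostics <- do.call(rbind, diag)
  rownames(diagnostics) <- NULL
  diagnostics$periodic_ok <- !is.na(diagnostics$periodicity) &
    diagnostics$periodicity < 0.01

  perfusion <- .render_perfusion(shares)

  study <- structure(
    list(calibration = cal, params = params, results = results,
         shares = shares, perfusion = perfusion, wss = wss,
         diagnostics = diagnostics, config = config),
    class = "lvad_study")

  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

# one-decimal rendering of a share column with largest-remainder
# reconciliation, so every rendered column sums to exactly 100.0 as in the
# reference table
.render_shares <- function(s) {
  tenth <- round_half_up(s, 1) * 10
  deficit <- round(1000 - sum(tenth))
  if (deficit != 0) {
    resid <- s * 10 - tenth
    ord <- order(if (deficit > 0) -resid else resid)
    pick <- ord[seq_len(abs(deficit))]
    tenth[pick] <- tenth[pick] + sign(deficit)
  }
  tenth / 10
}

# perfusion table in the reference layout, one-decimal rendering
.render_perfusion <- function(shares) {
  base <- shares$baseline
  out <- data.frame(outlet = names(base),
                    baseline = .render_shares(base),
                    stringsAsFactors = FALSE)
  for (nm in setdiff(names(shares), "baseline")) {
    s <- shares[[nm]][names(base)]
    out[[tolower(nm)]] <- .render_shares(s)
    out[[paste0(tolower(nm), "_variation")]] <-
      round_half_up(variation_pp(s, base), 1)
  }
  rownames(out) <- NULL
  out
}

#' Write study outputs as delimited text
#'
#' @param study an `lvad_study`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$perfusion, file.path(out_dir, "perfusion_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(study$wss))
    utils::write.table(study$wss[[nm]],
                       file.path(out_dir, paste0("wss_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  write_wk_table(study$params, file.path(out_dir, "windkessel_params.tsv"))
  write_calibration_report(study$calibration$report,
                           file.path(out_dir, "calibration_report.txt"))
  utils::write.table(study$diagnostics, file.path(out_dir, "diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Export a time-series as delimited text
#'
#' One row per time sample; columns are time, per-segment flows and
#' per-node pressures, with headers matching segment/node ids.
#'
#' @param result a `simulation_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  d <- data.frame(time = result$time, t(result$Q), t(result$P),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.lvad_study <- function(x, ...) {
  cat("LVAD cannulation-site study:", length(x$results), "scenario(s)\n")
  print(x$calibration$report)
  cat("\nPerfusion table (%):\n")
  print(x$perfusion, row.names = FALSE)
  invisible(x)
}
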