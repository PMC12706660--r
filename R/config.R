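#' Read a study configuration from YAML
#'
#' Structured text configuration for the whole pipeline. All keys are
#' optional; anything omitted falls back to the package defaults. Clinical
#' units are used at this boundary (L/min, mmHg, mm) and converted exactly.
#'
#' Recognised keys:
#' \preformatted{
#' fluid:      {density: 1050, viscosity: 0.0035}
#' waveform:   {period: 0.8, systolic_fraction: 0.375,
#'              notch_fraction: 0.05, notch_depth: 0.1}
#' pressure:   {systolic_mmhg: 120, diastolic_mmhg: 80}
#' cardiac_output_lpm: 5
#' solver:     {dt: 0.001, n_cycles: 3}
#' geometry:   {segment_id: {radius_mm: ..., length_mm: ...}, ...}
#' scenarios:  {label: {heart_lpm: ..., site: ..., lvad_lpm: ...}, ...}
#' }
#'
#' @param path path to a YAML file.
#' @return a [study_config()] object.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fl <- cfg$fluid
  fluid <- fluid_properties(
    density = fl$density %||% 1050,
    viscosity = fl$viscosity %||% 0.0035)

  overrides <- NULL
  if (!is.null(cfg$geometry)) {
    overrides <- lapply(cfg$geometry, function(g) {
      out <- list()
      if (!is.null(g$radius_mm)) out$radius <- g$radius_mm * 1e-3
      if (!is.null(g$length_mm)) out$length <- g$length_mm * 1e-3
      out
    })
  }
  network <- build_default_network(overrides = overrides, fluid = fluid)

  co <- lpm(cfg$cardiac_output_lpm %||% 5)
  pr <- cfg$pressure
  targets <- calibration_targets(
    shares = reference_shares("baseline"),
    p_sys = mmhg(pr$systolic_mmhg %||% 120),
    p_dia = mmhg(pr$diastolic_mmhg %||% 80),
    co = co)

  sv <- cfg$solver
  settings <- solver_settings(dt = sv$dt %||% 1e-3,
                              n_cycles = sv$n_cycles %||% 3L)

  wf <- cfg$waveform
  period <- wf$period %||% 0.8
  waveform_args <- list()
  for (k in c("systolic_fraction", "notch_fraction", "notch_depth"))
    if (!is.null(wf[[k]])) waveform_args[[k]] <- wf[[k]]

  scenarios <- default_scenarios(co)
  if (!is.null(cfg$scenarios)) {
    scenarios <- lapply(cfg$scenarios, function(s) {
      out <- list(heart = lpm(s$heart_lpm))
      if (!is.null(s$site)) {
        out$site <- s$site
        out$lvad <- lpm(s$lvad_lpm %||% 0)
      }
      out
    })
  }

  study_config(network = network, targets = targets, settings = settings,
               period = period, waveform_args = waveform_args,
               scenarios = scenarios)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
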