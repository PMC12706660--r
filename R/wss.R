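#' Poiseuille wall shear stress series
#'
#' Signed axial wall shear stress of fully developed laminar flow in a
#' cylinder: \eqn{\tau(t) = 4 \mu Q(t) / (\pi r^3)}. The sign follows the
#' flow direction; in the lumped model the three-dimensional directional
#' content of WSS collapses to this signed scalar.
#'
#' @param Q flow series, m^3/s (signed).
#' @param radius lumen radius, m (> 0).
#' @param viscosity dynamic viscosity, Pa.s.
#' @return shear stress series, Pa.
#' @export
wall_shear_series <- function(Q, radius, viscosity = 0.0035) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  4 * viscosity * Q / (pi * radius^3)
}

#' Time-averaged wall shear stress
#'
#' Cycle average of the magnitude of the wall shear stress,
#' \eqn{\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\tau|\,dt} (trapezoidal rule).
#'
#' @param tau shear series over one full cycle, Pa.
#' @param time matching time grid, s (defaults to a uniform grid of unit
#'   span).
#' @return TAWSS, Pa (non-negative).
#' @export
tawss <- function(tau, time = NULL) {
  if (length(tau) < 2L) stop("need a full cycle of shear samples")
  if (is.null(time)) time <- seq(0, 1, length.out = length(tau))
  trapz_mean(time, abs(tau))
}

#' Oscillatory shear index
#'
#' \deqn{\mathrm{OSI} = \frac{1}{2}\left(1 -
#'   \frac{|\int \tau\,dt|}{\int |\tau|\,dt}\right)}
#' OSI is 0 for strictly unidirectional shear and 0.5 for purely oscillatory
#' zero-mean shear. For identically zero shear the formula is 0/0; by
#' convention the package returns 0 (no oscillation).
#'
#' @inheritParams tawss
#' @return OSI, dimensionless in \[0, 0.5\].
#' @export
osi <- function(tau, time = NULL) {
  if (length(tau) < 2L) stop("need a full cycle of shear samples")
  if (is.null(time)) time <- seq(0, 1, length.out = length(tau))
  denom <- trapz(time, abs(tau))
  if (denom == 0) return(0)
  0.5 * (1 - abs(trapz(time, tau)) / denom)
}

#' Per-segment WSS metrics table
#'
#' Computes the Poiseuille shear closure on every segment's final-cycle flow
#' series and summarises TAWSS, OSI and the signed shear range. Rows are
#' ordered by segment id for deterministic output.
#'
#' @param result a `simulation_result`.
#' @param network optional `arterial_network`; defaults to the network stored
#'   in the result.
#' @return data frame: `segment`, `radius` (m), `tawss` (Pa), `osi`,
#'   `tau_min`, `tau_max` (Pa).
#' @export
wss_metrics_table <- function(result, network = result$network) {
  w <- result$final_window
  tt <- result$time[w]
  seg <- network$segments
  mu <- network$fluid$viscosity
  rows <- lapply(order(seg$id), function(i) {
    tau <- wall_shear_series(result$Q[seg$id[i], w], seg$radius[i], mu)
    data.frame(segment = seg$id[i], radius = seg$radius[i],
               tawss = tawss(tau, tt), osi = osi(tau, tt),
               tau_min = min(tau), tau_max = max(tau),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discretization-independence study
#'
#' Lumped-model analogue of a mesh-refinement study: reruns a scenario with
#' the time step halved and each aortic trunk segment subdivided in two
#' (identical total geometry; per-segment resistance and inertance are
#' additive in length, so the refined network is the same physical model at
#' finer resolution), then compares matched per-segment TAWSS values.
#' Sub-segment metrics are mapped back to their parent segment by averaging.
#'
#' @param network ungrafted `arterial_network`.
#' @param waveform inlet [inlet_waveform()].
#' @param params calibrated [wk_table()].
#' @param lvad optional [lvad_graft()].
#' @param settings base [solver_settings()]; the refined run halves `dt`.
#' @param refine_factor sub-segments per trunk segment in the refined run.
#' @return list: `max_rel_diff_pct` (maximum relative TAWSS difference, %),
#'   and the matched per-segment table `comparison`.
#' @export
discretization_study <- function(network, waveform, params, lvad = NULL,
                                 settings = solver_settings(),
                                 refine_factor = 2L) {
  coarse <- run_simulation(network, waveform, params, lvad = lvad,
                           settings = settings)
  fine_net <- refine_network(network, trunk_segments(network), refine_factor)
  fine_settings <- solver_settings(dt = settings$dt / 2,
                                   n_cycles = settings$n_cycles,
                                   coupling = settings$coupling,
                                   coupling_tolerance = settings$coupling_tolerance)
  fine <- run_simulation(fine_net, waveform, params, lvad = lvad,
                         settings = fine_settings)

  m_c <- wss_metrics_table(coarse)
  m_f <- wss_metrics_table(fine)
  parent <- attr(fine$network, "parent_segment")
  # collapse the graft stub naming: ids absent from the parent map (the graft
  # segment added after refinement) map to themselves
  pm <- parent[m_f$segment]
  pm[is.na(pm)] <- m_f$segment[is.na(pm)]
  agg <- tapply(m_f$tawss, pm, mean)
  cmp <- data.frame(segment = m_c$segment,
                    tawss_coarse = m_c$tawss,
                    tawss_fine = as.numeric(agg[m_c$segment]),
                    stringsAsFactors = FALSE)
  cmp$rel_diff_pct <- 100 * abs(cmp$tawss_fine - cmp$tawss_coarse) /
    pmax(cmp$tawss_coarse, .Machine$double.eps)
  list(max_rel_diff_pct = max(cmp$rel_diff_pct), comparison = cmp)
}
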