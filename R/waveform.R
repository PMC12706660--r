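#' Generate a pulsatile aortic inlet waveform
#'
#' Builds the periodic volumetric-flow waveform prescribed at the ascending
#' aorta: a half-sine ejection over the systolic fraction of the cycle, an
#' optional brief end-systolic reverse notch (aortic-valve closure), and zero
#' diastolic flow. The systolic peak is chosen in closed form so that the
#' cycle average equals `mean_flow` exactly:
#' \deqn{\bar Q = \frac{2}{\pi} Q_p (f_s - f_n d)}
#' where \eqn{f_s} is the systolic fraction, \eqn{f_n} the notch fraction and
#' \eqn{d} the notch depth relative to the peak.
#'
#' @param mean_flow cycle-averaged flow, m^3/s (use [lpm()] to convert);
#'   the default cardiac output is 5 L/min.
#' @param period cardiac period T, s. Default 0.8 s (75 bpm).
#' @param systolic_fraction fraction of the period occupied by ejection,
#'   in (0, 1).
#' @param notch_fraction fraction of the period occupied by the reverse
#'   notch immediately after ejection (0 disables the notch).
#' @param notch_depth notch peak as a fraction of the systolic peak.
#' @param n_samples number of stored sample points over one period.
#' @return an object of class `flow_waveform` with elements `period`,
#'   `mean_flow`, `peak_flow`, `fun` (a vectorised function of time, periodic
#'   over `period`), and `time`/`flow` sample vectors covering one period.
#' @examples
#' wf <- inlet_waveform(lpm(5))
#' as_lpm(wf$mean_flow)
#' @export
inlet_waveform <- function(mean_flow = lpm(5), period = 0.8,
                           systolic_fraction = 0.375,
                           notch_fraction = 0.05, notch_depth = 0.1,
                           n_samples = 1000L) {
  if (!is.numeric(mean_flow) || length(mean_flow) != 1L || mean_flow < 0)
    stop("mean_flow must be a single non-negative number")
  if (period <= 0) stop("period must be positive")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("parameter error: systolic fraction must lie in (0, 1)")
  if (notch_fraction < 0 || systolic_fraction + notch_fraction >= 1)
    stop("parameter error: systole plus notch must fit within one period")
  if (notch_depth < 0) stop("parameter error: notch depth must be >= 0")

  fs <- systolic_fraction; fn <- notch_fraction; d <- notch_depth
  # closed-form cycle mean of the half-sine pieces
  shape_mean <- (2 / pi) * (fs - fn * d)
  peak <- if (mean_flow == 0) 0 else mean_flow / shape_mean

  fun <- function(t) {
    ph <- (t / period) %% 1
    q <- numeric(length(ph))
    sys <- ph < fs
    q[sys] <- peak * sin(pi * ph[sys] / fs)
    if (fn > 0 && d > 0) {
      ntc <- !sys & ph < fs + fn
      q[ntc] <- -d * peak * sin(pi * (ph[ntc] - fs) / fn)
    }
    q
  }

  time <- seq(0, period, length.out = n_samples + 1L)
  structure(
    list(period = period, mean_flow = mean_flow, peak_flow = peak,
         systolic_fraction = fs, notch_fraction = fn, notch_depth = d,
         fun = fun, time = time, flow = fun(time)),
    class = "flow_waveform")
}

#' Constant (non-pulsatile) flow waveform
#'
#' A degenerate waveform holding `mean_flow` at every instant. Useful for
#' steady-state verification runs and for fully pump-supported conditions.
#'
#' @inheritParams inlet_waveform
#' @return a `flow_waveform` object.
#' @export
constant_waveform <- function(mean_flow, period = 0.8, n_samples = 1000L) {
  if (!is.numeric(mean_flow) || length(mean_flow) != 1L || mean_flow < 0)
    stop("mean_flow must be a single non-negative number")
  if (period <= 0) stop("period must be positive")
  fun <- function(t) rep(mean_flow, length(t))
  time <- seq(0, period, length.out = n_samples + 1L)
  structure(
    list(period = period, mean_flow = mean_flow, peak_flow = mean_flow,
         systolic_fraction = 1, notch_fraction = 0, notch_depth = 0,
         fun = fun, time = time, flow = fun(time)),
    class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat("Pulsatile flow waveform: T =", x$period, "s, mean =",
      format(as_lpm(x$mean_flow), digits = 4), "L/min, peak =",
      format(as_lpm(x$peak_flow), digits = 4), "L/min\n")
  invisible(x)
}

#' Define an LVAD outflow graft
#'
#' The extracorporeal pump is modelled as a constant-flow source delivered
#' through a short graft cannula into a named graft site of the network.
#'
#' @param site graft-site label (`"right_axillary"` or `"right_femoral"` on
#'   the default network).
#' @param flow_rate constant pump flow, m^3/s (non-negative).
#' @return an object of class `lvad_graft`.
#' @export
lvad_graft <- function(site, flow_rate) {
  if (!is.character(site) || length(site) != 1L)
    stop("site must be a single graft-site label")
  if (!is.numeric(flow_rate) || length(flow_rate) != 1L || flow_rate < 0)
    stop("flow_rate must be a single non-negative number")
  structure(list(site = site, flow_rate = flow_rate), class = "lvad_graft")
}

#' Attach an LVAD graft to a network
#'
#' Adds a graft stub (a source node plus a short cannula segment, 30 mm long,
#' 2.5 mm radius) feeding the named graft site, and records the constant pump
#' flow to be injected at the source node during simulation. The cardiac
#' inlet is unchanged and the input network is not mutated.
#'
#' @param network an `arterial_network`.
#' @param graft an [lvad_graft()].
#' @return a new `arterial_network` with the graft attached.
#' @export
apply_lvad_graft <- function(network, graft) {
  stopifnot(inherits(network, "arterial_network"), inherits(graft, "lvad_graft"))
  if (!graft$site %in% names(network$graft_sites))
    stop("lookup error: unknown graft site '", graft$site, "'")
  if (!is.null(network$lvad)) stop("network already carries an LVAD graft")
  site_node <- network$graft_sites[[graft$site]]
  stub <- data.frame(id = "lvad_graft", from = "lvad_source", to = site_node,
                     length = 0.030, radius = 0.0025, group = "graft",
                     stringsAsFactors = FALSE)
  seg <- rbind(network$segments[, c("id", "from", "to", "length", "radius", "group")],
               stub)
  out <- arterial_network(seg, network$inlet_node, network$outlets,
                          network$graft_sites, network$fluid)
  attr(out, "parent_segment") <- attr(network, "parent_segment")
  out$lvad <- list(site = graft$site, flow_rate = graft$flow_rate,
                   source_node = "lvad_source")
  out
}
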