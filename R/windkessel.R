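#' Three-element Windkessel parameters
#'
#' The outlet boundary model: a proximal (characteristic) resistance `Rp` in
#' series with a parallel compliance `C` / distal resistance `Rd` pair
#' discharging to the distal reference pressure `Pv`.
#'
#' @param Rp proximal resistance, Pa.s/m^3 (>= 0).
#' @param C compliance, m^3/Pa (> 0).
#' @param Rd distal resistance, Pa.s/m^3 (> 0).
#' @param Pv distal (venous) reference pressure, Pa. Default 0.
#' @return an object of class `wk_params`.
#' @export
wk_params <- function(Rp, C, Rd, Pv = 0) {
  if (!is.numeric(Rp) || Rp < 0) stop("parameter error: Rp must be >= 0")
  if (!is.numeric(C) || C <= 0) stop("parameter error: C must be > 0")
  if (!is.numeric(Rd) || Rd <= 0) stop("parameter error: Rd must be > 0")
  structure(list(Rp = Rp, C = C, Rd = Rd, Pv = Pv), class = "wk_params")
}

#' Implicit Windkessel time step
#'
#' Advances the compliance-chamber pressure `Pc` of a three-element
#' Windkessel by one backward-Euler step of
#' \deqn{C\,\frac{dP_c}{dt} = Q - \frac{P_c - P_v}{R_d}}
#' under the vessel-side flow `Q` held over the step, and returns the
#' interface pressure \eqn{P = R_p Q + P_c^{new}}. The implicit update is
#' unconditionally stable for any `dt`.
#'
#' @param params a [wk_params()] object.
#' @param state compliance-chamber pressure `Pc`, Pa (scalar).
#' @param Q vessel-side inflow, m^3/s.
#' @param dt time step, s (> 0).
#' @return list with elements `P` (interface pressure, Pa) and `Pc` (updated
#'   chamber pressure, Pa).
#' @export
wk_step <- function(params, state, Q, dt) {
  stopifnot(inherits(params, "wk_params"))
  if (dt <= 0) stop("dt must be positive")
  den <- params$Rd * params$C + dt
  Pc_new <- (params$Rd * params$C * state + params$Rd * dt * Q +
               dt * params$Pv) / den
  list(P = params$Rp * Q + Pc_new, Pc = Pc_new)
}

#' DC (zero-frequency) resistance of a Windkessel
#'
#' Under sustained constant flow the compliance carries no current and the
#' interface sees `Rp + Rd`. Used by the calibration to size total outlet
#' resistances from mean-pressure/mean-flow targets.
#'
#' @param params a [wk_params()] object.
#' @return `Rp + Rd`, Pa.s/m^3.
#' @export
wk_dc_resistance <- function(params) {
  stopifnot(inherits(params, "wk_params"))
  params$Rp + params$Rd
}

#' Linearised Windkessel step relation
#'
#' Algebraic reduction of the backward-Euler update: for the current chamber
#' state and step size, the interface pressure is an affine function of the
#' step flow, \eqn{P = aQ + b}, with
#' \deqn{a = R_p + \frac{R_d\,dt}{R_d C + dt}, \qquad
#'       b = \frac{R_d C\,P_c + dt\,P_v}{R_d C + dt}.}
#' This is what lets the network solver couple every outlet implicitly
#' ("tightly") in a single linear solve per time step: each outlet
#' contributes one affine relation, eliminated into the nodal system.
#'
#' @inheritParams wk_step
#' @return list with coefficients `a` (Pa.s/m^3) and `b` (Pa); for any `Q`,
#'   `a*Q + b` equals the `P` returned by [wk_step()].
#' @export
wk_linearization <- function(params, state, dt) {
  stopifnot(inherits(params, "wk_params"))
  if (dt <= 0) stop("dt must be positive")
  den <- params$Rd * params$C + dt
  list(a = params$Rp + params$Rd * dt / den,
       b = (params$Rd * params$C * state + dt * params$Pv) / den)
}

#' Windkessel parameter table for a network's outlets
#'
#' One row per outlet: `outlet`, `Rp`, `C`, `Rd`, `Pv` (SI units). This is
#' the object produced by the calibration and consumed by the solver.
#'
#' @param outlet character vector of outlet names.
#' @param Rp,C,Rd,Pv numeric vectors (recycled to length of `outlet`).
#' @return data frame of class `wk_table`.
#' @export
wk_table <- function(outlet, Rp, C, Rd, Pv = 0) {
  if (any(Rp < 0) || any(C <= 0) || any(Rd <= 0))
    stop("parameter error: require Rp >= 0, C > 0, Rd > 0")
  out <- data.frame(outlet = outlet, Rp = Rp, C = C, Rd = Rd, Pv = Pv,
                    stringsAsFactors = FALSE)
  class(out) <- c("wk_table", "data.frame")
  out
}

#' Serialize Windkessel parameters to/from a tabular file
#'
#' @param params a [wk_table()].
#' @param path path of a tab-separated file (outlet, Rp, C, Rd, Pv).
#' @return `read_wk_table()` returns a `wk_table`; the writer returns `path`
#'   invisibly.
#' @export
write_wk_table <- function(params, path) {
  utils::write.table(as.data.frame(params), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_wk_table
#' @export
read_wk_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  wk_table(d$outlet, d$Rp, d$C, d$Rd, d$Pv)
}

#' Freeze a calibrated parameter set
#'
#' Returns an immutable view of the Windkessel table: the calibrated
#' parameters are locked before being reused across LVAD scenarios, so every
#' scenario is guaranteed to run with bitwise-identical outlet boundaries.
#' Any attempted element assignment raises an error.
#'
#' @param params a [wk_table()] with at least one row.
#' @return the same table with class `frozen_wk_table` prepended.
#' @export
freeze_params <- function(params) {
  if (!inherits(params, "wk_table")) stop("params must be a wk_table")
  if (nrow(params) == 0L) stop("cannot freeze an empty parameter set")
  class(params) <- c("frozen_wk_table", class(params))
  params
}

.frozen_error <- function() {
  stop("contract violation: calibrated Windkessel parameters are frozen; ",
       "derive a fresh wk_table instead of mutating", call. = FALSE)
}

#' @export
`$<-.frozen_wk_table` <- function(x, name, value) .frozen_error()
#' @export
`[<-.frozen_wk_table` <- function(x, i, j, value) .frozen_error()
#' @export
`[[<-.frozen_wk_table` <- function(x, i, value) .frozen_error()
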