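#' Calibration targets
#'
#' Target flow divisions and inlet pressures for the baseline (no-LVAD)
#' state. Shares are percentages of total outflow and must cover every
#' outlet; mean arterial pressure is derived with the standard clinical
#' formula MAP = P_dia + (P_sys - P_dia)/3.
#'
#' @param shares named numeric vector: outlet name -> target share, %.
#'   Must sum to 100 within 0.1.
#' @param p_sys,p_dia systolic and diastolic inlet pressure targets, Pa
#'   (use [mmhg()]); defaults 120/80 mmHg.
#' @param co cardiac output, m^3/s; default 5 L/min.
#' @param pv distal reference pressure, Pa.
#' @return an object of class `calibration_targets`.
#' @export
calibration_targets <- function(shares, p_sys = mmhg(120), p_dia = mmhg(80),
                                co = lpm(5), pv = 0) {
  if (is.null(names(shares)) || any(names(shares) == ""))
    stop("shares must be a named vector keyed by outlet name")
  if (any(shares <= 0)) stop("all target shares must be > 0")
  if (abs(sum(shares) - 100) > 0.1)
    stop("target shares must sum to 100% within 0.1 (got ",
         format(sum(shares)), ")")
  if (p_sys <= p_dia) stop("p_sys must exceed p_dia")
  structure(list(shares = shares, p_sys = p_sys, p_dia = p_dia,
                 co = co, pv = pv,
                 map = p_dia + (p_sys - p_dia) / 3,
                 pulse = p_sys - p_dia),
            class = "calibration_targets")
}

#' Initial Windkessel parameters from target shares
#'
#' Ohmic sizing of the per-outlet Windkessel triples: each outlet's total
#' path resistance should satisfy (MAP - Pv) / (s_i * CO); the upstream
#' Poiseuille path resistance is subtracted (clamped at a small positive
#' floor) to give the outlet resistance R_i, split as Rp = kappa * R_i,
#' Rd = (1 - kappa) * R_i. Compliances follow a single global washout time
#' constant, C_i = tau / Rd_i.
#'
#' @param targets a [calibration_targets()] object.
#' @param network an `arterial_network` whose outlets the shares must cover.
#' @param kappa proximal fraction of the outlet resistance, approximating
#'   the vessel's characteristic impedance. Default 0.06, chosen so that the
#'   proximal-resistance pulse leaves enough headroom for the compliance
#'   calibration to reach a 40 mmHg pulse pressure in a network whose
#'   segments carry explicit inertance.
#' @param tau global Windkessel time constant Rd*C, s. Default 1.5.
#' @return a [wk_table()] with one row per outlet, in network outlet order.
#'   If any outlet resistance had to be clamped, the affected outlets are
#'   recorded in the `"clamped"` attribute and a warning is raised.
#' @export
initial_params_from_shares <- function(targets, network, kappa = 0.06,
                                       tau = 1.5) {
  stopifnot(inherits(targets, "calibration_targets"),
            inherits(network, "arterial_network"))
  nm <- outlet_names(network)
  miss <- setdiff(nm, names(targets$shares))
  if (length(miss))
    stop("coverage error: no target share for outlet(s): ",
         paste(miss, collapse = ", "))
  s <- targets$shares[nm] / 100
  r_total <- (targets$map - targets$pv) / (s * targets$co)
  r_up <- path_resistance(network, network$outlets$node)
  floor_r <- 1e-6 * min(r_total)
  r_out <- r_total - r_up
  clamped <- nm[r_out < floor_r]
  if (length(clamped)) {
    warning("outlet resistance clamped at floor for: ",
            paste(clamped, collapse = ", "))
    r_out <- pmax(r_out, floor_r)
  }
  Rd <- (1 - kappa) * r_out
  out <- wk_table(nm, Rp = kappa * r_out, C = tau / Rd, Rd = Rd,
                  Pv = targets$pv)
  attr(out, "clamped") <- clamped
  out
}

#' Calibrate Windkessel parameters to flow-division and pressure targets
#'
#' Fixed-point calibration of the baseline (no-LVAD) state: repeatedly run
#' the transient simulation, measure the achieved final-cycle flow shares and
#' the inlet systolic/diastolic pressures, and update
#' \itemize{
#'   \item each distal resistance multiplicatively,
#'     `Rd_i <- Rd_i * (achieved_i / target_i)^relax`;
#'   \item all resistances by the ratio `MAP_target / MAP_achieved`;
#'   \item all compliances by the pulse-pressure ratio achieved/target.
#' }
#' Iteration stops when the largest share error is at most `tol` percentage
#' points and both pressures are within 2 mmHg of target, or after
#' `max_iter` evaluations (then the report carries `converged = FALSE`; no
#' error is raised).
#'
#' Systolic pressure is the final-cycle maximum at the inlet node; diastolic
#' pressure is the minimum over the diastolic phase (after valve closure).
#' The brief end-systolic undershoot is excluded: with rigid segments the
#' flow deceleration at end-ejection produces an exaggerated incisura that a
#' compliant aortic wall would buffer, and counting it as "diastolic" would
#' make any textbook pulse-pressure target unreachable.
#'
#' @param network an `arterial_network` (ungrafted baseline).
#' @param targets a [calibration_targets()] object.
#' @param waveform optional inlet waveform; defaults to the package waveform
#'   at the targets' cardiac output.
#' @param tol share tolerance, percentage points. Default 0.1.
#' @param max_iter maximum number of simulation evaluations. Default 20.
#' @param settings a [solver_settings()].
#' @param kappa,tau passed to [initial_params_from_shares()].
#' @param relax exponent damping the multiplicative share update.
#' @param params optional starting [wk_table()] (skips the Ohmic
#'   initialisation).
#' @return list with elements `params` (a [wk_table()]) and `report` (a
#'   `calibration_report`: achieved shares, max share error in pp, achieved
#'   pressures, iterations used, converged flag, and the error history).
#' @export
calibrate_windkessel <- function(network, targets, waveform = NULL,
                                 tol = 0.1, max_iter = 20L,
                                 settings = solver_settings(),
                                 kappa = 0.06, tau = 1.5, relax = 1,
                                 params = NULL) {
  stopifnot(inherits(network, "arterial_network"))
  if (is.null(waveform)) waveform <- inlet_waveform(mean_flow = targets$co)
  if (is.null(params))
    params <- initial_params_from_shares(targets, network, kappa, tau)
  nm <- outlet_names(network)
  s_tgt <- targets$shares[nm]
  p_tol <- mmhg(2)

  history <- numeric(0)
  achieved <- NULL; p_sys_a <- NA_real_; p_dia_a <- NA_real_
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    res <- run_simulation(network, waveform, params, settings = settings)
    qbar <- cycle_average(res, "outlet_flow")
    achieved <- 100 * qbar / sum(qbar)
    pr <- inlet_pressures(res)
    p_sys_a <- pr[["systolic"]]; p_dia_a <- pr[["diastolic"]]
    err <- max(abs(achieved - s_tgt))
    history <- c(history, err)
    if (err <= tol && abs(p_sys_a - targets$p_sys) <= p_tol &&
        abs(p_dia_a - targets$p_dia) <= p_tol) {
      converged <- TRUE
      break
    }
    if (it == max_iter) break
    # multiplicative share update on the distal resistances
    f_share <- (achieved / s_tgt)^relax
    Rd_new <- params$Rd * f_share
    # uniform resistance rescale to hit mean pressure
    pulse_a <- p_sys_a - p_dia_a
    map_a <- p_dia_a + pulse_a / 3
    f_map <- (targets$map - targets$pv) / (map_a - targets$pv)
    # compliance rescale to hit pulse pressure
    f_c <- pulse_a / targets$pulse
    params <- wk_table(nm,
                       Rp = params$Rp * f_map,
                       C = pmax(params$C * f_c, .Machine$double.xmin),
                       Rd = Rd_new * f_map,
                       Pv = params$Pv)
  }

  report <- structure(
    list(achieved_shares = achieved, target_shares = s_tgt,
         max_share_error = max(abs(achieved - s_tgt)),
         p_sys = p_sys_a, p_dia = p_dia_a,
         p_sys_target = targets$p_sys, p_dia_target = targets$p_dia,
         iterations = iters, converged = converged,
         error_history = history, tol = tol),
    class = "calibration_report")
  list(params = params, report = report)
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Windkessel calibration:",
      if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "evaluation(s)\n")
  cat(sprintf("  max share error: %.3f pp (tol %.2f)\n",
              x$max_share_error, x$tol))
  cat(sprintf("  inlet pressure:  %.1f/%.1f mmHg (target %.0f/%.0f)\n",
              as_mmhg(x$p_sys), as_mmhg(x$p_dia),
              as_mmhg(x$p_sys_target), as_mmhg(x$p_dia_target)))
  invisible(x)
}

#' Write a calibration report as a plain-text log
#'
#' @param report a `calibration_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  writeLines("", con)
  d <- data.frame(outlet = names(report$achieved_shares),
                  target = unname(report$target_shares),
                  achieved = unname(report$achieved_shares))
  utils::write.table(format(d, digits = 6), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
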