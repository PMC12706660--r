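#' Solver settings
#'
#' @param dt time step, s. Default 1 ms.
#' @param n_cycles number of cardiac cycles to simulate; the final cycle is
#'   used for analysis. Default 3.
#' @param coupling `"monolithic"` (default) eliminates each outlet's
#'   linearised Windkessel relation into the nodal system, solving the
#'   vessel/outlet coupling exactly in one linear solve per step;
#'   `"subiteration"` is a validation mode that instead exchanges outlet
#'   pressure and flow repeatedly until the normalised pressure residual
#'   falls below `coupling_tolerance`. Both must agree to the residual level.
#' @param coupling_tolerance normalised pressure residual for the
#'   sub-iteration mode. Default 1e-4.
#' @param max_subiter cap on sub-iterations per time step.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 1e-3, n_cycles = 3L,
                            coupling = c("monolithic", "subiteration"),
                            coupling_tolerance = 1e-4, max_subiter = 500L) {
  if (dt <= 0) stop("dt must be positive")
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  structure(list(dt = dt, n_cycles = as.integer(n_cycles),
                 coupling = match.arg(coupling),
                 coupling_tolerance = coupling_tolerance,
                 max_subiter = as.integer(max_subiter)),
            class = "solver_settings")
}

# match the Windkessel table rows to the network outlets (by name)
.match_wk <- function(network, wk) {
  i <- match(network$outlets$name, wk$outlet)
  if (anyNA(i))
    stop("coverage error: no Windkessel parameters for outlet(s): ",
         paste(network$outlets$name[is.na(i)], collapse = ", "))
  as.data.frame(wk)[i, , drop = FALSE]
}

#' Run a transient lumped-parameter simulation
#'
#' Integrates the 0D arterial network in time. Each vessel segment obeys the
#' resistance-inertance pressure-drop law \eqn{\Delta P = RQ + L\,dQ/dt}
#' (backward Euler); each node enforces flow conservation; the cardiac inlet
#' carries the prescribed waveform; an optional LVAD graft injects a constant
#' flow; and every outlet contributes its linearised three-element Windkessel
#' relation, so the vessel/outlet coupling is solved implicitly within a
#' single sparse linear system per time step. Walls are rigid: all system
#' compliance lives in the Windkessel chambers.
#'
#' Chamber pressures are initialised at the steady operating point of the
#' cycle-mean flows (configurable via `init_state`), which keeps the start-up
#' transient small enough for a three-cycle run to reach a periodic solution.
#'
#' @param network an `arterial_network` (optionally already grafted).
#' @param inlet a [inlet_waveform()] flow waveform.
#' @param wk a [wk_table()] (or frozen table) covering every outlet.
#' @param lvad optional [lvad_graft()] to attach before running.
#' @param settings a [solver_settings()] object.
#' @param init_state optional named numeric vector of initial chamber
#'   pressures `Pc` per outlet name, Pa.
#' @param scenario optional label stored in the result.
#' @return an object of class `simulation_result`: `time` (s), signed
#'   per-segment flows `Q` (m^3/s; positive along the stored from->to
#'   orientation), nodal pressures `P` (Pa), outlet flows `Q_out`, the inlet
#'   flow series `Q_in`, the constant LVAD flow, the final-cycle sample
#'   window, and the network/settings used.
#' @export
run_simulation <- function(network, inlet, wk, lvad = NULL,
                           settings = solver_settings(), init_state = NULL,
                           scenario = NULL) {
  stopifnot(inherits(network, "arterial_network"),
            inherits(inlet, "flow_waveform"))
  if (!is.null(lvad)) network <- apply_lvad_graft(network, lvad)
  wk <- .match_wk(network, wk)

  seg <- network$segments
  nodes <- network_nodes(network)
  nn <- length(nodes); ns <- nrow(seg); no <- nrow(network$outlets)
  ni <- match(network$inlet_node, nodes)
  from_i <- match(seg$from, nodes); to_i <- match(seg$to, nodes)
  out_i <- match(network$outlets$node, nodes)

  dt <- settings$dt
  T_ <- inlet$period
  nt_cycle <- round(T_ / dt)
  N <- settings$n_cycles * nt_cycle
  t_grid <- (0:N) * dt

  q_lvad <- 0; lvad_i <- NA_integer_
  if (!is.null(network$lvad)) {
    q_lvad <- network$lvad$flow_rate
    lvad_i <- match(network$lvad$source_node, nodes)
  }

  # per-segment step impedance Z = R + L/dt; conductance geff = 1/Z
  Ldt <- seg$inertance / dt
  Z <- seg$resistance + Ldt
  geff <- 1 / Z

  # outlet linearisation coefficients (constant over the run: dt fixed)
  den <- wk$Rd * wk$C + dt
  a_out <- wk$Rp + wk$Rd * dt / den

  # nodal conductance matrix (constant)
  A <- matrix(0, nn, nn)
  for (s in seq_len(ns)) {
    f <- from_i[s]; t2 <- to_i[s]; g <- geff[s]
    A[f, f] <- A[f, f] + g; A[t2, t2] <- A[t2, t2] + g
    A[f, t2] <- A[f, t2] - g; A[t2, f] <- A[t2, f] - g
  }
  for (k in seq_len(no)) A[out_i[k], out_i[k]] <- A[out_i[k], out_i[k]] + 1 / a_out[k]
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("assembly error: singular nodal system (disconnected node?): ",
         conditionMessage(e)))

  # steady (DC) solution at cycle-mean inflows, for initial conditions
  g0 <- 1 / seg$resistance
  A0 <- matrix(0, nn, nn)
  for (s in seq_len(ns)) {
    f <- from_i[s]; t2 <- to_i[s]
    A0[f, f] <- A0[f, f] + g0[s]; A0[t2, t2] <- A0[t2, t2] + g0[s]
    A0[f, t2] <- A0[f, t2] - g0[s]; A0[t2, f] <- A0[t2, f] - g0[s]
  }
  aDC <- wk$Rp + wk$Rd
  for (k in seq_len(no)) A0[out_i[k], out_i[k]] <- A0[out_i[k], out_i[k]] + 1 / aDC[k]
  b0 <- numeric(nn)
  b0[ni] <- b0[ni] + inlet$mean_flow
  if (!is.na(lvad_i)) b0[lvad_i] <- b0[lvad_i] + q_lvad
  b0 <- b0 + drop(rowsum_scatter(wk$Pv / aDC, out_i, nn))
  P0 <- drop(solve(A0, b0))
  Q0 <- (P0[from_i] - P0[to_i]) * g0
  Qout0 <- (P0[out_i] - wk$Pv) / aDC
  Pc0 <- wk$Pv + Qout0 * wk$Rd
  if (!is.null(init_state)) {
    j <- match(network$outlets$name, names(init_state))
    if (anyNA(j)) stop("init_state must name every outlet")
    Pc0 <- unname(init_state[j])
  }

  qin <- inlet$fun(t_grid)

  Qmat <- matrix(NA_real_, ns, N + 1L, dimnames = list(seg$id, NULL))
  Pmat <- matrix(NA_real_, nn, N + 1L, dimnames = list(nodes, NULL))
  Qout_mat <- matrix(NA_real_, no, N + 1L,
                     dimnames = list(network$outlets$name, NULL))
  Qmat[, 1L] <- Q0; Pmat[, 1L] <- P0; Qout_mat[, 1L] <- Qout0

  Pc <- Pc0
  Qold <- Q0
  RdC <- wk$Rd * wk$C
  subiter <- settings$coupling == "subiteration"
  if (subiter) {
    # conservative relaxation from the worst outlet gain a / Z_terminal
    term_seg <- vapply(out_i, function(o)
      which(to_i == o | from_i == o)[1], integer(1))
    gain <- max(a_out / Z[term_seg])
    omega <- min(1, 1 / (1 + gain))
  }

  for (k in seq_len(N)) {
    b_wk <- (RdC * Pc + dt * wk$Pv) / den
    b <- numeric(nn)
    h <- geff * Ldt * Qold                      # inertial history source
    b <- b - rowsum_scatter(h, from_i, nn) + rowsum_scatter(h, to_i, nn)
    b[ni] <- b[ni] + qin[k + 1L]
    if (!is.na(lvad_i)) b[lvad_i] <- b[lvad_i] + q_lvad
    b <- b + rowsum_scatter(b_wk / a_out, out_i, nn)

    if (!subiter) {
      P <- drop(Ainv %*% b)
    } else {
      P <- .subiterate_step(A, b, out_i, a_out, b_wk, nn,
                            settings$coupling_tolerance,
                            settings$max_subiter, omega,
                            P_guess = Pmat[, k])
    }
    if (any(!is.finite(P)))
      stop("numerical failure: non-finite pressure at step ", k)

    Qnew <- geff * (P[from_i] - P[to_i]) + geff * Ldt * Qold
    Qout <- (P[out_i] - b_wk) / a_out
    Pc <- (RdC * Pc + wk$Rd * dt * Qout + dt * wk$Pv) / den

    Qmat[, k + 1L] <- Qnew; Pmat[, k + 1L] <- P; Qout_mat[, k + 1L] <- Qout
    Qold <- Qnew
  }

  final_window <- (N + 1L - nt_cycle):(N + 1L)
  structure(
    list(time = t_grid, Q = Qmat, P = Pmat, Q_out = Qout_mat, Q_in = qin,
         lvad_flow = q_lvad, network = network, inlet = inlet,
         settings = settings, wk = wk, Pc = Pc,
         final_window = final_window, n_per_cycle = nt_cycle,
         scenario = scenario),
    class = "simulation_result")
}

# scatter-add values into an n-vector at (possibly duplicated) indices
rowsum_scatter <- function(values, idx, n) {
  out <- numeric(n)
  agg <- rowsum(values, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# loose 0D coupling: Dirichlet outlet pressures relaxed against the
# Windkessel affine relation until the normalised residual converges
.subiterate_step <- function(A, b, out_i, a_out, b_wk, nn, tol, max_it,
                             omega, P_guess) {
  P_out <- P_guess[out_i]
  for (it in seq_len(max_it)) {
    # impose current outlet pressures as Dirichlet rows
    A2 <- A; b2 <- b
    for (j in seq_along(out_i)) {
      o <- out_i[j]
      A2[o, ] <- 0; A2[o, o] <- 1
      b2[o] <- P_out[j]
    }
    P <- drop(solve(A2, b2))
    # flow the network delivers into each outlet, then the Windkessel's reply
    Qout <- .net_inflow(A, b, P, out_i, a_out, b_wk, P_out)
    P_new <- a_out * Qout + b_wk
    res <- max(abs(P_new - P_out)) / max(abs(P), 1)
    P_out <- (1 - omega) * P_out + omega * P_new
    if (res < tol) break
  }
  P[out_i] <- P_out
  P
}

# net flow the network delivers into each outlet node, from the KCL row with
# the Windkessel's own diagonal term removed
.net_inflow <- function(A, b, P, out_i, a_out, b_wk, P_out) {
  row_flux <- drop(A[out_i, , drop = FALSE] %*% P)   # includes +P_out/a term
  wk_term <- P_out / a_out
  src <- b[out_i]                                     # includes +b_wk/a term
  # KCL at outlet: (network outflow) + P/a = src  =>  network inflow =
  # -(row_flux - wk_term) + (src - b_wk/a_out)
  (src - b_wk / a_out) - (row_flux - wk_term)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Simulation result", if (!is.null(x$scenario)) paste0("[", x$scenario, "]"),
      ":", ncol(x$Q) - 1L, "steps of", x$settings$dt, "s (",
      x$settings$n_cycles, "cycles )\n")
  cat("  mean inlet flow:",
      format(as_lpm(trapz_mean(x$time[x$final_window], x$Q_in[x$final_window])),
             digits = 4), "L/min; LVAD:", format(as_lpm(x$lvad_flow), digits = 4),
      "L/min\n")
  invisible(x)
}

#' Cycle-averaged signals over the final cycle
#'
#' Trapezoidal mean over the final-cycle analysis window of the outlet flows,
#' segment flows, or nodal pressures.
#'
#' @param result a `simulation_result`.
#' @param signal which signal family to average.
#' @return named numeric vector of means.
#' @export
cycle_average <- function(result,
                          signal = c("outlet_flow", "segment_flow",
                                     "node_pressure")) {
  signal <- match.arg(signal)
  w <- result$final_window
  if (length(w) < 2L) stop("final-cycle window shorter than 2 samples")
  tt <- result$time[w]
  m <- switch(signal, outlet_flow = result$Q_out,
              segment_flow = result$Q, node_pressure = result$P)
  apply(m[, w, drop = FALSE], 1L, function(y) trapz_mean(tt, y))
}

#' Cycle-to-cycle periodicity of the outlet flows
#'
#' Maximum over outlets of the relative L2 difference between the last two
#' simulated cycles. A value below 1% is treated as a converged periodic
#' solution.
#'
#' @param result a `simulation_result` with at least 2 cycles.
#' @return maximum relative cycle-to-cycle change (dimensionless).
#' @export
periodicity_check <- function(result) {
  if (result$settings$n_cycles < 2L)
    stop("periodicity check needs at least 2 simulated cycles")
  n <- result$n_per_cycle
  w_last <- result$final_window
  w_prev <- w_last - n
  d <- result$Q_out[, w_last, drop = FALSE] - result$Q_out[, w_prev, drop = FALSE]
  ref <- sqrt(rowSums(result$Q_out[, w_last, drop = FALSE]^2))
  num <- sqrt(rowSums(d^2))
  rel <- ifelse(ref > 0, num / ref, ifelse(num > 0, Inf, 0))
  max(rel)
}

#' Systolic and diastolic inlet pressure
#'
#' Reads the simulated arterial pressure at the cardiac inlet over the final
#' cycle: systolic pressure is the maximum; diastolic pressure is the
#' minimum over the diastolic phase, i.e. after the systolic ejection and
#' valve-closure notch of the inlet waveform. The end-systolic undershoot is
#' excluded deliberately: in a rigid-segment lumped model the ejection
#' deceleration produces an exaggerated incisura that a compliant proximal
#' aorta would absorb.
#'
#' @param result a `simulation_result`.
#' @return named numeric vector `c(systolic = ..., diastolic = ...)`, Pa.
#' @export
inlet_pressures <- function(result) {
  w <- result$final_window
  p_in <- result$P[result$network$inlet_node, w]
  wf <- result$inlet
  phase <- ((result$time[w] - result$time[w[1]]) / wf$period) %% 1
  dia <- phase >= wf$systolic_fraction + wf$notch_fraction | phase == 0
  c(systolic = max(p_in), diastolic = min(p_in[dia]))
}

#' Volume conservation over the final cycle
#'
#' Relative mismatch between the volume entering the network (cardiac inlet
#' plus LVAD) and the volume leaving through the outlets over the final
#' cycle. With rigid segments and periodic Windkessel chambers this should be
#' well below 0.5%.
#'
#' @param result a `simulation_result`.
#' @return relative volume error (dimensionless).
#' @export
conservation_check <- function(result) {
  w <- result$final_window
  tt <- result$time[w]
  T_ <- tt[length(tt)] - tt[1]
  v_in <- trapz(tt, result$Q_in[w]) + result$lvad_flow * T_
  v_out <- sum(apply(result$Q_out[, w, drop = FALSE], 1L,
                     function(y) trapz(tt, y)))
  abs(v_in - v_out) / v_in
}
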