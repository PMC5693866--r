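#' Integrate the deterministic model
#'
#' Solves the six-state ODE system with a stiff-capable solver
#' (`deSolve::lsoda`), restarting the integration at every schedule
#' breakpoint so input discontinuities are handled exactly. In the symmetric
#' exchange variant the internal aTc state is slaved algebraically to the
#' input at every segment start.
#'
#' @param model a [toggle_model].
#' @param state0 initial state, named 6-vector from [cell_state()].
#' @param schedule an [inducer_schedule].
#' @param t_end end time (min), > `t0`.
#' @param t0 start time (min).
#' @param sample_dt output grid spacing (min).
#' @param rtol,atol solver tolerances.
#' @return A `toggle_trajectory`: list with `times`, `states` (matrix, one row
#'   per time), `inputs` (matrix of applied u), and the schedule.
#' @export
integrate_toggle <- function(model, state0, schedule, t_end, t0 = 0,
                             sample_dt = 1, rtol = 1e-6, atol = 1e-9) {
  stopifnot(inherits(model, "toggle_model"),
            inherits(schedule, "inducer_schedule"))
  if (t_end <= t0) stop("integrate_toggle: t_end must exceed t0")
  state0 <- state0[state_names()]
  if (any(is.na(state0)) || any(state0 < 0))
    stop("integrate_toggle: invalid initial state")
  p <- model$params; ex <- model$exchange

  seg_bounds <- unique(c(t0, schedule_events(schedule, t0, t_end), t_end))
  out_times <- unique(sort(c(seq(t0, t_end, by = sample_dt), seg_bounds)))

  deriv <- function(t, y, parms) {
    y[y < 0] <- 0
    list(unname(ode_rhs(y, parms$u, p, ex)))
  }

  rows <- list(); inp <- list()
  y <- state0
  for (i in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[i]; b <- seg_bounds[i + 1L]
    u <- schedule_value(schedule, a)
    if (ex$variant == "symmetric") y[["aTc_in"]] <- u$u_aTc
    tt <- out_times[out_times >= a & out_times <= b]
    if (length(tt) < 2L) tt <- c(a, b)
    sol <- deSolve::lsoda(y, tt, deriv, parms = list(u = u),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("integrate_toggle: solver failure at t = ",
           signif(max(sol[, 1]), 6), " min")
    m <- sol[, -1, drop = FALSE]
    m[m < 0] <- 0
    keep <- if (i < length(seg_bounds) - 1L) seq_len(nrow(m) - 1L) else
      seq_len(nrow(m))
    rows[[i]] <- m[keep, , drop = FALSE]
    inp[[i]] <- matrix(c(u$u_aTc, u$u_IPTG), nrow = length(keep), ncol = 2,
                       byrow = TRUE)
    y <- m[nrow(m), ]
  }
  states <- do.call(rbind, rows)
  colnames(states) <- state_names()
  inputs <- do.call(rbind, inp)
  colnames(inputs) <- c("u_aTc", "u_IPTG")
  times <- out_times[seq_len(nrow(states))]
  structure(list(times = times, states = states, inputs = inputs,
                 schedule = schedule),
            class = "toggle_trajectory")
}

#' @export
print.toggle_trajectory <- function(x, ...) {
  cat("Toggle trajectory:", length(x$times), "samples, t in [",
      min(x$times), ",", max(x$times), "] min\n")
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("  final state: LacI = %.4g, TetR = %.4g a.u.\n",
              fin[["LacI"]], fin[["TetR"]]))
  invisible(x)
}

#' @export
as.data.frame.toggle_trajectory <- function(x, ...) {
  data.frame(t_min = x$times, x$states, x$inputs)
}

#' @export
plot.toggle_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states[, c("LacI", "TetR")], type = "l",
                    lty = 1, col = c("firebrick", "forestgreen"),
                    xlab = "time (min)", ylab = "fluorescence (a.u.)", ...)
  graphics::legend("topright", c("LacI-RFP", "TetR-GFP"), lty = 1,
                   col = c("firebrick", "forestgreen"), bty = "n")
  invisible(x)
}

#' Write / read a trajectory as CSV
#' @param traj a `toggle_trajectory`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Reduced protein-plane vector field
#'
#' Protein dynamics with the fast mRNA subsystem at quasi-steady state
#' (`mRNA = f/g_m`) and internal inducers at their input-determined steady
#' values (equal to the external concentrations for both exchange variants),
#' so that phase-plane objects live in the (LacI, TetR) plane. Explicit
#' internal inducer levels can be supplied to evaluate the frozen field along
#' an inducer orbit. Vectorized over `LacI`/`TetR`.
#'
#' @param LacI,TetR protein coordinates (a.u.).
#' @param u list/vector with `u_aTc`, `u_IPTG`.
#' @param model a [toggle_model].
#' @param aTc_in,IPTG_in optional internal inducer levels overriding the
#'   steady values.
#' @return List with components `dLacI`, `dTetR` (a.u./min).
#' @export
reduced_rhs <- function(LacI, TetR, u, model, aTc_in = NULL, IPTG_in = NULL) {
  p <- model$params
  a <- if (is.null(aTc_in)) u[["u_aTc"]] else aTc_in
  i <- if (is.null(IPTG_in)) u[["u_IPTG"]] else IPTG_in
  list(dLacI = p$k_p_L * transcription_rate_L(TetR, a, p) / p$g_m_L -
         p$g_p_L * LacI,
       dTetR = p$k_p_T * transcription_rate_T(LacI, i, p) / p$g_m_T -
         p$g_p_T * TetR)
}

# d/dx of the decreasing Hill function
hill_neg_deriv <- function(x, theta, eta) {
  h <- hill_neg(x, theta, eta)
  -(eta / theta) * (x / theta)^(eta - 1) * h^2
}

# derivative of the regulation functions w.r.t. their repressor argument
d_transcription_L_dTetR <- function(TetR, aTc_in, p) {
  c_a <- hill_neg(aTc_in, p$theta_aTc, p$eta_aTc)
  p$k_m_L * hill_neg_deriv(TetR * c_a, p$theta_TetR, p$eta_TetR) * c_a
}
d_transcription_T_dLacI <- function(LacI, IPTG_in, p) {
  c_i <- hill_neg(IPTG_in, p$theta_IPTG, p$eta_IPTG)
  p$k_m_T * hill_neg_deriv(LacI * c_i, p$theta_LacI, p$eta_LacI) * c_i
}

# 4x4 Jacobian of the gene-expression subsystem at fixed internal inducers
jacobian_full <- function(state, p) {
  fLp <- d_transcription_L_dTetR(state[["TetR"]], state[["aTc_in"]], p)
  fTp <- d_transcription_T_dLacI(state[["LacI"]], state[["IPTG_in"]], p)
  J <- matrix(0, 4, 4,
              dimnames = list(state_names()[1:4], state_names()[1:4]))
  J["mRNA_L", "mRNA_L"] <- -p$g_m_L
  J["mRNA_L", "TetR"] <- fLp
  J["mRNA_T", "mRNA_T"] <- -p$g_m_T
  J["mRNA_T", "LacI"] <- fTp
  J["LacI", "mRNA_L"] <- p$k_p_L
  J["LacI", "LacI"] <- -p$g_p_L
  J["TetR", "mRNA_T"] <- p$k_p_T
  J["TetR", "TetR"] <- -p$g_p_T
  J
}

# 2x2 Jacobian of the reduced protein field
jacobian_reduced <- function(LacI, TetR, u, model) {
  p <- model$params
  fLp <- d_transcription_L_dTetR(TetR, u[["u_aTc"]], p)
  fTp <- d_transcription_T_dLacI(LacI, u[["u_IPTG"]], p)
  matrix(c(-p$g_p_L, p$k_p_L * fLp / p$g_m_L,
           p$k_p_T * fTp / p$g_m_T, -p$g_p_T),
         2, 2, byrow = TRUE,
         dimnames = list(c("dLacI", "dTetR"), c("LacI", "TetR")))
}

# lift a protein-plane point to the full 6-state (mRNA at QSS, inducers = u)
lift_state <- function(LacI, TetR, u, model) {
  p <- model$params
  cell_state(mRNA_L = transcription_rate_L(TetR, u[["u_aTc"]], p) / p$g_m_L,
             mRNA_T = transcription_rate_T(LacI, u[["u_IPTG"]], p) / p$g_m_T,
             LacI = LacI, TetR = TetR,
             aTc_in = u[["u_aTc"]], IPTG_in = u[["u_IPTG"]])
}

#' Deterministic steady state reached from a given start
#'
#' Integrates the model under constant inputs until the relative state change
#' over `window` minutes falls below `tol`, then returns the final state.
#' Used to pre-equilibrate cells under an experiment's first condition.
#'
#' @param model a [toggle_model].
#' @param u list/vector with `u_aTc`, `u_IPTG`.
#' @param from initial `(LacI, TetR)`; mRNAs start at quasi-steady state.
#' @param t_max integration cap (min).
#' @param window,tol convergence window (min) and relative tolerance.
#' @return Named 6-vector.
#' @export
steady_state <- function(model, u, from = c(LacI = 10, TetR = 1000),
                         t_max = 20000, window = 500, tol = 1e-8) {
  sched <- constant_schedule(u[["u_aTc"]], u[["u_IPTG"]])
  y <- lift_state(from[["LacI"]], from[["TetR"]], u, model)
  t <- 0
  repeat {
    tr <- integrate_toggle(model, y, sched, t_end = window, sample_dt = window)
    y2 <- tr$states[nrow(tr$states), ]
    if (max(abs(y2 - y) / pmax(abs(y), 1e-6)) < tol) return(y2)
    y <- y2
    t <- t + window
    if (t >= t_max)
      stop("steady_state: no convergence within t_max")
  }
}
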