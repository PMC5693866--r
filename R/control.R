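#' Controller configuration
#'
#' Settings of the dual-branch controller: one branch adjusts aTc to steer
#' LacI-RFP, the other adjusts IPTG to steer TetR-GFP. Integral gains are
#' interpreted per minute of accumulated error (the default values are the
#' published controller gains read against the minute-based integral clock;
#' multiplying them by 60 destabilizes the loop, see the methods vignette);
#' bounds and basal levels are the admissible inducer ranges.
#' When targets are `NULL`, [run_closed_loop()] uses the saddle-point
#' coordinates of the model at the basal inputs.
#'
#' @param mode `"PI"` or `"bangbang"`.
#' @param target_LacI,target_TetR setpoints (a.u.), or `NULL` for the saddle.
#' @param K_P_L,K_P_T proportional gains (ng/mL per a.u.; mM per a.u.).
#' @param K_I_L,K_I_T integral gains (per min).
#' @param u0_aTc,u0_IPTG basal inputs (ng/mL, mM).
#' @param u_min_aTc,u_max_aTc,u_min_IPTG,u_max_IPTG admissible input bounds.
#' @param t_d start of the integral window (min): error accumulated before
#'   `t_d` is discarded to limit start-up windup.
#' @param dt_meas measurement/actuation interval (min).
#' @param measure_hook optional function(state) returning the measured
#'   `c(LacI, TetR)`; default reads the plant state directly.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(mode = c("PI", "bangbang"),
                              target_LacI = NULL, target_TetR = NULL,
                              K_P_L = 3.3e-2, K_I_L = 1.32e-4,
                              K_P_T = 1.65e-2, K_I_T = 4.6e-4,
                              u0_aTc = 20, u0_IPTG = 0.25,
                              u_min_aTc = 0, u_max_aTc = 50,
                              u_min_IPTG = 0, u_max_IPTG = 0.5,
                              t_d = 120, dt_meas = 5,
                              measure_hook = NULL) {
  mode <- match.arg(mode)
  if (u_min_aTc < 0 || u_min_IPTG < 0 ||
      u_min_aTc >= u_max_aTc || u_min_IPTG >= u_max_IPTG)
    stop("controller_config: bounds must satisfy 0 <= u_min < u_max")
  if (t_d < 0) stop("controller_config: t_d must be >= 0")
  if (dt_meas <= 0) stop("controller_config: dt_meas must be > 0")
  structure(list(mode = mode, target_LacI = target_LacI,
                 target_TetR = target_TetR,
                 K_P_L = K_P_L, K_I_L = K_I_L,
                 K_P_T = K_P_T, K_I_T = K_I_T,
                 u0_aTc = u0_aTc, u0_IPTG = u0_IPTG,
                 u_min_aTc = u_min_aTc, u_max_aTc = u_max_aTc,
                 u_min_IPTG = u_min_IPTG, u_max_IPTG = u_max_IPTG,
                 t_d = t_d, dt_meas = dt_meas,
                 measure_hook = measure_hook),
            class = "controller_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Dual PI control law
#'
#' Computes the applied inducer concentrations from the current tracking
#' errors and the accumulated integral terms:
#' `u_aTc = clamp(u0_aTc + K_P_L (LacI* - LacI) + K_I_L I_L)` and
#' symmetrically for IPTG with TetR. The integral contribution is exactly
#' zero while `t <= t_d`; the caller accumulates `I` by the trapezoidal rule
#' on the measurement grid starting at `t_d`.
#'
#' @param t current time (min).
#' @param LacI_meas,TetR_meas measured levels (a.u.).
#' @param integ_L,integ_T accumulated error integrals (a.u. min).
#' @param cfg a [controller_config] with `mode = "PI"` and resolved targets.
#' @return Named vector `c(u_aTc, u_IPTG)` within bounds.
#' @export
pi_law <- function(t, LacI_meas, TetR_meas, integ_L, integ_T, cfg) {
  stopifnot(cfg$mode == "PI")
  iL <- if (t > cfg$t_d) integ_L else 0
  iT <- if (t > cfg$t_d) integ_T else 0
  u_aTc <- cfg$u0_aTc + cfg$K_P_L * (cfg$target_LacI - LacI_meas) +
    cfg$K_I_L * iL
  u_IPTG <- cfg$u0_IPTG + cfg$K_P_T * (cfg$target_TetR - TetR_meas) +
    cfg$K_I_T * iT
  c(u_aTc = clamp(u_aTc, cfg$u_min_aTc, cfg$u_max_aTc),
    u_IPTG = clamp(u_IPTG, cfg$u_min_IPTG, cfg$u_max_IPTG))
}

#' Bang-bang control law
#'
#' Applies the maximal inducer concentration when the measured level is
#' strictly below target, and the minimal one otherwise (equality takes the
#' minimal branch).
#'
#' @inheritParams pi_law
#' @param cfg a [controller_config] with `mode = "bangbang"`.
#' @return Named vector `c(u_aTc, u_IPTG)`.
#' @export
bangbang_law <- function(LacI_meas, TetR_meas, cfg) {
  stopifnot(cfg$mode == "bangbang")
  c(u_aTc = if (cfg$target_LacI > LacI_meas) cfg$u_max_aTc else cfg$u_min_aTc,
    u_IPTG = if (cfg$target_TetR > TetR_meas) cfg$u_max_IPTG else
      cfg$u_min_IPTG)
}

resolve_targets <- function(cfg, model) {
  if (is.null(cfg$target_LacI) || is.null(cfg$target_TetR)) {
    eq <- find_equilibria(model, c(u_aTc = cfg$u0_aTc, u_IPTG = cfg$u0_IPTG))
    sad <- eq[eq$stability == "unstable", ]
    if (nrow(sad) != 1L)
      stop("controller targets unset and the model has no unique saddle at ",
           "the basal inputs")
    if (is.null(cfg$target_LacI)) cfg$target_LacI <- sad$LacI
    if (is.null(cfg$target_TetR)) cfg$target_TetR <- sad$TetR
  }
  cfg
}

#' Closed-loop control of a virtual cell
#'
#' Couples a controller to a deterministic or stochastic plant. Every
#' `dt_meas` minutes the plant's protein levels are read (optionally through
#' a measurement hook), the control law is evaluated, and the resulting
#' inducer concentrations are held constant until the next measurement.
#'
#' @param model a [toggle_model].
#' @param cfg a [controller_config].
#' @param state0 initial plant state (named 6-vector).
#' @param t_end run length (min).
#' @param plant `"ode"` (deterministic) or `"ssa"` (stochastic).
#' @param seed RNG seed (required for the stochastic plant).
#' @param sample_dt plant trajectory output spacing (min).
#' @return A `closed_loop_record`: list with `meas_times`, `measured` (n x 2),
#'   `applied` (n x 2), `integrals` (n x 2), the concatenated plant
#'   trajectory (`times`, `states`), the resolved `cfg` and run metadata.
#' @export
run_closed_loop <- function(model, cfg, state0, t_end,
                            plant = c("ode", "ssa"), seed = NULL,
                            sample_dt = 1) {
  plant <- match.arg(plant)
  stopifnot(inherits(cfg, "controller_config"))
  if (plant == "ssa" && is.null(seed))
    stop("run_closed_loop: the stochastic plant requires a seed")
  cfg <- resolve_targets(cfg, model)
  dt <- cfg$dt_meas
  n_steps <- floor(t_end / dt)
  meas_times <- seq(0, by = dt, length.out = n_steps + 1L)

  read_meas <- function(state) {
    if (is.null(cfg$measure_hook)) c(state[["LacI"]], state[["TetR"]])
    else cfg$measure_hook(state)
  }

  measured <- matrix(NA_real_, n_steps + 1L, 2,
                     dimnames = list(NULL, c("LacI", "TetR")))
  applied <- matrix(NA_real_, n_steps + 1L, 2,
                    dimnames = list(NULL, c("u_aTc", "u_IPTG")))
  integrals <- matrix(0, n_steps + 1L, 2,
                      dimnames = list(NULL, c("I_L", "I_T")))
  traj_t <- list(); traj_x <- list()

  y <- state0[state_names()]
  iL <- 0; iT <- 0
  e_prev <- NULL
  for (k in seq_len(n_steps + 1L)) {
    tk <- meas_times[k]
    m <- read_meas(y)
    e <- c(cfg$target_LacI - m[1], cfg$target_TetR - m[2])
    # trapezoidal accumulation on the measurement grid, starting at t_d
    if (!is.null(e_prev) && (tk - dt) >= cfg$t_d) {
      iL <- iL + 0.5 * (e_prev[1] + e[1]) * dt
      iT <- iT + 0.5 * (e_prev[2] + e[2]) * dt
    }
    e_prev <- e
    measured[k, ] <- m
    integrals[k, ] <- c(iL, iT)
    u <- if (cfg$mode == "PI") pi_law(tk, m[1], m[2], iL, iT, cfg)
         else bangbang_law(m[1], m[2], cfg)
    applied[k, ] <- u
    if (k > n_steps) break
    sched <- constant_schedule(u[["u_aTc"]], u[["u_IPTG"]])
    if (plant == "ode") {
      tr <- integrate_toggle(model, y, sched, t_end = dt,
                             sample_dt = sample_dt)
      y <- tr$states[nrow(tr$states), ]
      keep <- seq_len(nrow(tr$states) - 1L)
      traj_t[[k]] <- tk + tr$times[keep]
      traj_x[[k]] <- tr$states[keep, , drop = FALSE]
    } else {
      run <- simulate_ssa(model, y, sched, t_end = dt,
                          seed = child_seed(seed, k),
                          sample_dt = sample_dt)
      y <- run$final_state
      keep <- seq_len(nrow(run$states) - 1L)
      traj_t[[k]] <- tk + run$times[keep]
      traj_x[[k]] <- run$states[keep, , drop = FALSE]
    }
  }
  traj_t[[n_steps + 2L]] <- meas_times[n_steps + 1L]
  traj_x[[n_steps + 2L]] <- matrix(y, 1,
                                   dimnames = list(NULL, state_names()))
  structure(list(meas_times = meas_times, measured = measured,
                 applied = applied, integrals = integrals,
                 times = unlist(traj_t),
                 states = do.call(rbind, traj_x),
                 cfg = cfg, plant = plant, seed = seed, model = model),
            class = "closed_loop_record")
}

#' @export
print.closed_loop_record <- function(x, ...) {
  cat("Closed-loop record:", x$cfg$mode, "controller,", x$plant, "plant,",
      max(x$meas_times), "min,", length(x$meas_times), "control steps\n")
  cat(sprintf("  targets: LacI* = %.4g, TetR* = %.4g a.u.\n",
              x$cfg$target_LacI, x$cfg$target_TetR))
  invisible(x)
}

#' @export
plot.closed_loop_record <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$times, x$states[, c("LacI", "TetR")], type = "l",
                    lty = 1, col = c("firebrick", "forestgreen"),
                    xlab = "time (min)", ylab = "fluorescence (a.u.)")
  graphics::abline(h = c(x$cfg$target_LacI, x$cfg$target_TetR),
                   col = c("firebrick", "forestgreen"), lty = 3)
  graphics::matplot(x$meas_times, x$applied, type = "s", lty = 1,
                    col = c("purple", "orange"),
                    xlab = "time (min)", ylab = "applied input")
  invisible(x)
}

#' Write a closed-loop record as CSV
#' @param record a `closed_loop_record`.
#' @param path file path.
#' @export
write_closed_loop_csv <- function(record, path) {
  df <- data.frame(t_min = record$meas_times, record$measured,
                   record$applied, record$integrals)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Label the committed state of a cell
#'
#' A cell is committed to a stable equilibrium when its (LacI, TetR) point is
#' within relative distance `threshold` of that equilibrium in log
#' coordinates. The label names the nearest stable equilibrium:
#' `"RFP-dominant"` (LacI-high) or `"GFP-dominant"` (TetR-high).
#'
#' @param LacI,TetR protein coordinates (a.u.).
#' @param equilibria an `equilibrium_report` (from [find_equilibria()]).
#' @param threshold relative log-space distance for commitment.
#' @return List with `label`, `committed`, `distance` (to nearest stable eq).
#' @export
commitment_label <- function(LacI, TetR, equilibria, threshold = 0.1) {
  st <- equilibria[equilibria$stability == "stable", ]
  if (!nrow(st)) stop("commitment_label: no stable equilibria supplied")
  z <- log(pmax(c(LacI, TetR), 1e-6))
  d <- apply(st[, c("LacI", "TetR")], 1, function(q) {
    zq <- log(pmax(as.numeric(q), 1e-6))
    sqrt(sum((z - zq)^2)) / sqrt(sum(zq^2))
  })
  k <- which.min(d)
  lab <- if (st$LacI[k] >= st$TetR[k]) "RFP-dominant" else "GFP-dominant"
  list(label = lab, committed = unname(d[k]) < threshold,
       distance = unname(d[k]))
}

#' Open-loop periodic forcing of a cell population
#'
#' Simulates `n_cells` independent stochastic cells under a periodic
#' alternating-inducer schedule until `t_release`, after which the inputs
#' revert to the basal reference levels until `t_end`. Each cell is then
#' labelled with the stable equilibrium (at basal inputs) it has been
#' attracted to.
#'
#' @param model a [toggle_model].
#' @param schedule a periodic [inducer_schedule] (e.g. [forcing_schedule()]).
#' @param n_cells population size.
#' @param t_end total run length (min).
#' @param t_release time at which forcing stops (min, <= t_end).
#' @param seed master seed.
#' @param state0 initial state; default is the GFP-dominant steady state at
#'   basal inputs (cells pre-grown under IPTG).
#' @param u_basal basal inputs applied after release.
#' @param param_sampler optional per-cell parameter sampler (heterogeneity).
#' @param sample_dt output grid spacing (min).
#' @return A `forcing_record`: list with the population runs, per-cell fate
#'   `labels` data frame, the basal-input `equilibria`, and metadata.
#' @export
run_periodic_forcing <- function(model, schedule, n_cells, t_end, t_release,
                                 seed, state0 = NULL,
                                 u_basal = c(u_aTc = 20, u_IPTG = 0.25),
                                 param_sampler = NULL, sample_dt = 2) {
  stopifnot(inherits(schedule, "inducer_schedule"),
            !is.null(schedule$period), t_release <= t_end)
  # composite schedule: forcing pattern until t_release, then basal
  ev <- c(0, schedule_events(schedule, 0, t_release))
  u <- schedule_value(schedule, ev)
  if (t_release < t_end) {
    t_start <- c(ev, t_release)
    ua <- c(u$u_aTc, u_basal[["u_aTc"]])
    ui <- c(u$u_IPTG, u_basal[["u_IPTG"]])
    keep <- !duplicated(t_start, fromLast = TRUE)
    comp <- inducer_schedule(t_start[keep], ua[keep], ui[keep])
  } else {
    comp <- inducer_schedule(ev, u$u_aTc, u$u_IPTG)
  }
  if (is.null(state0))
    state0 <- steady_state(model, u_basal,
                           from = c(LacI = 1, TetR = protein_scales(model)[["TetR"]]))
  pop <- simulate_population(model, n_cells, state0, comp, t_end, seed,
                             sample_dt = sample_dt,
                             param_sampler = param_sampler)
  eq <- find_equilibria(model, u_basal)
  labels <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    fin <- pop[[i]]$final_state
    cl <- commitment_label(fin[["LacI"]], fin[["TetR"]], eq)
    data.frame(cell = i, label = cl$label, committed = cl$committed,
               distance = cl$distance)
  }))
  structure(list(population = pop, labels = labels, equilibria = eq,
                 schedule = schedule, composite_schedule = comp,
                 t_release = t_release, t_end = t_end, seed = seed,
                 u_basal = u_basal, state0 = state0),
            class = "forcing_record")
}

#' @export
print.forcing_record <- function(x, ...) {
  cat("Periodic forcing record:", attr(x$population, "n"), "cells, release at",
      x$t_release, "min, end at", x$t_end, "min\n")
  print(table(x$labels$label))
  invisible(x)
}
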