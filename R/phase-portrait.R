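# maximal quasi-steady protein levels: full induction of each branch
protein_scales <- function(model) {
  p <- model$params
  c(LacI = p$k_p_L * (p$k_m0_L + p$k_m_L) / (p$g_m_L * p$g_p_L),
    TetR = p$k_p_T * (p$k_m0_T + p$k_m_T) / (p$g_m_T * p$g_p_T))
}

#' Nullclines of the reduced protein field
#'
#' Zero-level curves of each component of [reduced_rhs()] in the
#' (LacI, TetR) plane: the LacI-nullcline (dLacI/dt = 0) parameterized along
#' a TetR grid, and the TetR-nullcline (dTetR/dt = 0) along a LacI grid.
#' Each vertex is found by bracketing and root polishing on the grid line;
#' the one-dimensional problem is monotone so the root is unique.
#'
#' @param model a [toggle_model].
#' @param u list/vector with `u_aTc`, `u_IPTG`.
#' @param n vertices per curve.
#' @param upper optional `(LacI, TetR)` upper bounds of the grid; defaults to
#'   1.2x the full-induction levels.
#' @return A `toggle_nullclines` object: list of two data frames `lacI` and
#'   `tetR` with columns `LacI`, `TetR`.
#' @export
nullclines <- function(model, u, n = 200, upper = NULL) {
  if (n < 2L) stop("nullclines: empty grid")
  sc <- protein_scales(model)
  if (is.null(upper)) upper <- 1.2 * sc
  grid_T <- seq(0, upper[["TetR"]], length.out = n)
  grid_L <- seq(0, upper[["LacI"]], length.out = n)
  hi_L <- 2 * upper[["LacI"]]; hi_T <- 2 * upper[["TetR"]]
  lac_L <- vapply(grid_T, function(Tv) {
    f <- function(L) reduced_rhs(L, Tv, u, model)$dLacI
    stats::uniroot(f, c(0, hi_L), tol = 1e-10)$root
  }, numeric(1))
  tet_T <- vapply(grid_L, function(Lv) {
    f <- function(Tv) reduced_rhs(Lv, Tv, u, model)$dTetR
    stats::uniroot(f, c(0, hi_T), tol = 1e-10)$root
  }, numeric(1))
  structure(list(lacI = data.frame(LacI = lac_L, TetR = grid_T),
                 tetR = data.frame(LacI = grid_L, TetR = tet_T),
                 u = as.list(u)),
            class = "toggle_nullclines")
}

#' @export
print.toggle_nullclines <- function(x, ...) {
  cat("Toggle nullclines at u_aTc =", x$u$u_aTc, "ng/mL, u_IPTG =",
      x$u$u_IPTG, "mM;", nrow(x$lacI), "vertices per curve\n")
  invisible(x)
}

# one damped-Newton run on the reduced field; returns c(LacI, TetR) or NULL
newton_reduced <- function(x0, u, model, tol = 1e-10, max_iter = 100) {
  x <- x0
  for (it in seq_len(max_iter)) {
    f <- reduced_rhs(x[1], x[2], u, model)
    fv <- c(f$dLacI, f$dTetR)
    nf <- sqrt(sum(fv^2))
    if (nf < tol) return(x)
    J <- jacobian_reduced(x[1], x[2], u, model)
    step <- tryCatch(solve(J, -fv), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      xn <- x + lam * step
      if (all(xn >= 0)) {
        fn <- reduced_rhs(xn[1], xn[2], u, model)
        if (sqrt(fn$dLacI^2 + fn$dTetR^2) < nf) break
      }
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)
    }
    x <- xn
  }
  f <- reduced_rhs(x[1], x[2], u, model)
  if (sqrt(f$dLacI^2 + f$dTetR^2) < tol) x else NULL
}

#' Find and classify all equilibria at fixed inputs
#'
#' Multi-start damped-Newton root finding on the reduced protein field over a
#' log-spaced grid, with deduplication; every root is lifted to the full
#' six-variable state and classified by the eigenvalues of the 4x4
#' gene-expression Jacobian (internal inducers are slaved to the inputs).
#' A point is labelled stable iff all eigenvalue real parts are below
#' -1e-9 per minute; otherwise it is a saddle/unstable point.
#'
#' @param model a [toggle_model].
#' @param u list/vector with `u_aTc`, `u_IPTG`.
#' @param n_starts number of Newton starts (>= 25).
#' @param dedup_tol relative distance below which two roots are merged.
#' @return An `equilibrium_report`: data frame with the six state variables,
#'   `max_re_eig` and `stability`, plus attributes `u`, `eigenvalues`.
#' @export
find_equilibria <- function(model, u, n_starts = 64, dedup_tol = 1e-3) {
  if (n_starts < 25) stop("find_equilibria: n_starts must be >= 25")
  sc <- protein_scales(model)
  m <- ceiling(sqrt(n_starts))
  gL <- 10^seq(-2, log10(10 * sc[["LacI"]]), length.out = m)
  gT <- 10^seq(-2, log10(10 * sc[["TetR"]]), length.out = m)
  starts <- as.matrix(expand.grid(LacI = gL, TetR = gT))
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    r <- newton_reduced(starts[i, ], u, model)
    if (is.null(r)) next
    dup <- FALSE
    for (q in roots) {
      if (sqrt(sum((r - q)^2)) < dedup_tol * max(sqrt(sum(q^2)), 1)) {
        dup <- TRUE; break
      }
    }
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (!length(roots))
    stop("find_equilibria: no roots found (check parameters)")
  p <- model$params
  eig_list <- list()
  rows <- lapply(roots, function(r) {
    st <- lift_state(r[1], r[2], u, model)
    ev <- eigen(jacobian_full(st, p), only.values = TRUE)$values
    eig_list[[length(eig_list) + 1L]] <<- ev
    data.frame(t(st), max_re_eig = max(Re(ev)),
               stability = if (max(Re(ev)) < -1e-9) "stable" else "unstable")
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$LacI), , drop = FALSE]
  rownames(rep) <- NULL
  structure(rep, class = c("equilibrium_report", "data.frame"),
            u = as.list(u), eigenvalues = eig_list)
}

#' @export
print.equilibrium_report <- function(x, ...) {
  u <- attr(x, "u")
  cat("Equilibria at u_aTc =", u$u_aTc, "ng/mL, u_IPTG =", u$u_IPTG, "mM:",
      sum(x$stability == "stable"), "stable,",
      sum(x$stability == "unstable"), "unstable\n")
  print.data.frame(x[, c("LacI", "TetR", "max_re_eig", "stability")],
                   digits = 4)
  invisible(x)
}

#' Write an equilibrium report as CSV
#' @param report an `equilibrium_report`.
#' @param path file path.
#' @export
write_equilibria_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Separatrix between the two basins of attraction
#'
#' Requires the system to be bistable at `u` (two stable points and one
#' saddle). The curve is the stable manifold of the reduced-field saddle,
#' traced by backward-time integration from small offsets along the stable
#' eigenvector on both sides of the saddle.
#'
#' @param model a [toggle_model].
#' @param u list/vector with `u_aTc`, `u_IPTG`.
#' @param t_back backward-integration horizon (min).
#' @param n_points samples per branch.
#' @return A `toggle_separatrix`: data frame of (LacI, TetR) vertices ordered
#'   along the curve, with the saddle row flagged; attribute `saddle`.
#' @export
separatrix <- function(model, u, t_back = 3000, n_points = 400) {
  eq <- find_equilibria(model, u)
  n_st <- sum(eq$stability == "stable")
  n_un <- sum(eq$stability == "unstable")
  if (n_st != 2L || n_un != 1L)
    stop("separatrix: system not bistable at u (found ", n_st, " stable, ",
         n_un, " unstable equilibria)")
  sad <- eq[eq$stability == "unstable", ]
  x_sad <- c(sad$LacI, sad$TetR)
  J <- jacobian_reduced(x_sad[1], x_sad[2], u, model)
  ei <- eigen(J)
  k <- which.min(Re(ei$values))
  if (Re(ei$values[k]) >= 0)
    stop("separatrix: saddle has no stable eigendirection")
  v <- Re(ei$vectors[, k]); v <- v / sqrt(sum(v^2))
  eps <- 1e-3 * max(sqrt(sum(x_sad^2)), 1)
  sc <- protein_scales(model)
  bound <- 20 * max(sc)
  back <- function(t, y, parms) {
    f <- reduced_rhs(max(y[1], 0), max(y[2], 0), u, model)
    list(c(-f$dLacI, -f$dTetR))
  }
  trace_branch <- function(x0) {
    tt <- seq(0, t_back, length.out = n_points)
    sol <- deSolve::lsoda(x0, tt, back, parms = NULL,
                          rtol = 1e-8, atol = 1e-10)
    m <- sol[, -1, drop = FALSE]
    ok <- m[, 1] >= 0 & m[, 2] >= 0 & m[, 1] <= bound & m[, 2] <= bound
    stop_at <- if (all(ok)) nrow(m) else which(!ok)[1] - 1L
    m[seq_len(max(stop_at, 1L)), , drop = FALSE]
  }
  b1 <- trace_branch(x_sad + eps * v)
  b2 <- trace_branch(x_sad - eps * v)
  curve <- rbind(b1[rev(seq_len(nrow(b1))), , drop = FALSE],
                 matrix(x_sad, 1), b2)
  df <- data.frame(LacI = curve[, 1], TetR = curve[, 2],
                   is_saddle = FALSE)
  df$is_saddle[nrow(b1) + 1L] <- TRUE
  structure(df, class = c("toggle_separatrix", "data.frame"),
            saddle = x_sad, u = as.list(u))
}

#' Time-averaged protein vector field under periodic forcing
#'
#' For a periodic inducer schedule: (1) the input-driven internal-inducer
#' subsystem (autonomous, independent of the proteins) is relaxed onto its
#' periodic orbit by iterating the exact piecewise-exponential period map
#' until the relative sup-norm change over one period drops below `orbit_tol`
#' (at least 5 and at most `max_periods` iterations); (2) the reduced protein
#' field is averaged over one period along that orbit on a rectangular grid;
#' (3) null points of the averaged field are located by a sign-change scan
#' along the grid followed by root polishing. Cells whose commitment dynamics
#' are slower than the forcing effectively follow this averaged field.
#'
#' @param model a [toggle_model].
#' @param schedule a *periodic* [inducer_schedule].
#' @param n grid resolution per axis.
#' @param upper optional `(LacI, TetR)` grid upper bounds.
#' @param m_samples time samples per period used for the average.
#' @param orbit_tol,max_periods periodic-orbit convergence controls.
#' @return A `toggle_avg_field`: list with `grid_L`, `grid_T`, matrices
#'   `dLacI`, `dTetR` (rows = LacI grid), `null_points` data frame, and the
#'   inducer orbit samples.
#' @export
time_averaged_field <- function(model, schedule, n = 200, upper = NULL,
                                m_samples = 240, orbit_tol = 1e-6,
                                max_periods = 50) {
  stopifnot(inherits(schedule, "inducer_schedule"))
  if (is.null(schedule$period))
    stop("time_averaged_field: schedule is not periodic")
  per <- schedule$period
  ex <- model$exchange; p <- model$params

  # exact piecewise-exponential flow of the exchange subsystem over [0, per)
  phase_starts <- schedule$t_start
  phase_ends <- c(phase_starts[-1], per)
  advance <- function(x, t0, t1) {
    u <- schedule_value(schedule, t0)
    dt <- t1 - t0
    if (ex$variant == "symmetric") {
      a <- u$u_aTc
      i <- u$u_IPTG + (x[2] - u$u_IPTG) * exp(-ex$k_IPTG * dt)
    } else {
      ka <- if (u$u_aTc > x[1]) ex$k_aTc_in else ex$k_aTc_out
      ki <- if (u$u_IPTG > x[2]) ex$k_IPTG_in else ex$k_IPTG_out
      a <- u$u_aTc + (x[1] - u$u_aTc) * exp(-ka * dt)
      i <- u$u_IPTG + (x[2] - u$u_IPTG) * exp(-ki * dt)
    }
    c(a, i)
  }
  period_map <- function(x) {
    for (j in seq_along(phase_starts))
      x <- advance(x, phase_starts[j], phase_ends[j])
    x
  }
  x <- unlist(schedule_value(schedule, 0), use.names = FALSE)
  for (it in seq_len(max_periods)) {
    xn <- period_map(x)
    rel <- max(abs(xn - x) / pmax(abs(x), 1e-12))
    x <- xn
    if (it >= 5 && rel < orbit_tol) break
  }
  if (rel >= orbit_tol)
    stop("time_averaged_field: inducer orbit did not converge in ",
         max_periods, " periods")

  # sample the orbit at m_samples times across one period
  ts <- seq(0, per, length.out = m_samples + 1L)[-(m_samples + 1L)]
  orbit <- matrix(NA_real_, m_samples, 2)
  xo <- x; t_prev <- 0
  for (k in seq_len(m_samples)) {
    xo <- advance_through(schedule, xo, t_prev, ts[k], ex)
    orbit[k, ] <- xo
    t_prev <- ts[k]
  }
  colnames(orbit) <- c("aTc_in", "IPTG_in")

  # separable structure: average each regulation function along the orbit
  sc <- protein_scales(model)
  if (is.null(upper)) upper <- 1.2 * sc
  grid_L <- seq(0, upper[["LacI"]], length.out = n)
  grid_T <- seq(0, upper[["TetR"]], length.out = n)
  avg_fL <- function(Tv) {  # mean over orbit of f_L(Tv, aTc(t))
    M <- vapply(seq_len(m_samples), function(k)
      transcription_rate_L(Tv, orbit[k, 1], p), numeric(length(Tv)))
    if (is.matrix(M)) rowMeans(M) else mean(M)
  }
  avg_fT <- function(Lv) {
    M <- vapply(seq_len(m_samples), function(k)
      transcription_rate_T(Lv, orbit[k, 2], p), numeric(length(Lv)))
    if (is.matrix(M)) rowMeans(M) else mean(M)
  }
  fL_T <- avg_fL(grid_T)  # length n, indexed by TetR
  fT_L <- avg_fT(grid_L)  # length n, indexed by LacI
  dLacI <- outer(grid_L, p$k_p_L * fL_T / p$g_m_L,
                 function(L, v) v) - p$g_p_L * grid_L
  dTetR <- outer(p$k_p_T * fT_L / p$g_m_T, grid_T,
                 function(v, Tv) v) - matrix(grid_T, n, n, byrow = TRUE) *
    p$g_p_T
  # null points: the averaged nullclines are explicit graphs
  # L = N_L(T) and T = N_T(L); roots of g(T) = N_T(N_L(T)) - T
  N_L <- function(Tv) p$k_p_L * avg_fL(Tv) / (p$g_m_L * p$g_p_L)
  N_T <- function(Lv) p$k_p_T * avg_fT(Lv) / (p$g_m_T * p$g_p_T)
  g <- function(Tv) N_T(N_L(Tv)) - Tv
  gt <- seq(1e-6, 2 * upper[["TetR"]], length.out = max(n, 200))
  gv <- g(gt)
  roots_T <- numeric(0)
  for (k in seq_len(length(gt) - 1L)) {
    if (gv[k] == 0) roots_T <- c(roots_T, gt[k])
    else if (gv[k] * gv[k + 1L] < 0)
      roots_T <- c(roots_T,
                   stats::uniroot(g, c(gt[k], gt[k + 1L]), tol = 1e-10)$root)
  }
  roots_T <- roots_T[!duplicated(round(roots_T / max(roots_T, 1), 6))]
  null_points <- data.frame(LacI = N_L(roots_T), TetR = roots_T)
  structure(list(grid_L = grid_L, grid_T = grid_T,
                 dLacI = dLacI, dTetR = dTetR,
                 null_points = null_points,
                 orbit = data.frame(t_min = ts, orbit),
                 schedule = schedule),
            class = "toggle_avg_field")
}

# advance the exchange state through all schedule phases between t0 and t1
advance_through <- function(schedule, x, t0, t1, ex) {
  evs <- schedule_events(schedule, t0, t1)
  pts <- c(t0, evs, t1)
  for (j in seq_len(length(pts) - 1L)) {
    a <- pts[j]; b <- pts[j + 1L]
    if (b <= a) next
    u <- schedule_value(schedule, a)
    if (ex$variant == "symmetric") {
      x <- c(u$u_aTc,
             u$u_IPTG + (x[2] - u$u_IPTG) * exp(-ex$k_IPTG * (b - a)))
    } else {
      ka <- if (u$u_aTc > x[1]) ex$k_aTc_in else ex$k_aTc_out
      ki <- if (u$u_IPTG > x[2]) ex$k_IPTG_in else ex$k_IPTG_out
      x <- c(u$u_aTc + (x[1] - u$u_aTc) * exp(-ka * (b - a)),
             u$u_IPTG + (x[2] - u$u_IPTG) * exp(-ki * (b - a)))
    }
  }
  x
}

#' @export
print.toggle_avg_field <- function(x, ...) {
  cat("Time-averaged protein field (period",
      x$schedule$period, "min):", nrow(x$null_points), "null point(s)\n")
  if (nrow(x$null_points)) print(x$null_points, digits = 4)
  invisible(x)
}

#' Write a vector-field grid as CSV (x, y, dx, dy)
#' @param field a `toggle_avg_field`.
#' @param path file path.
#' @export
write_field_csv <- function(field, path) {
  n <- length(field$grid_L)
  df <- data.frame(LacI = rep(field$grid_L, times = n),
                   TetR = rep(field$grid_T, each = n),
                   dLacI = as.vector(field$dLacI),
                   dTetR = as.vector(field$dTetR))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
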