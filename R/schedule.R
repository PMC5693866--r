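#' Piecewise-constant external inducer schedule
#'
#' External aTc and IPTG concentrations as a step function of time. Interval
#' `i` is half-open, `[t_start[i], t_start[i+1])`; after the last breakpoint
#' the last value holds, unless `period` is given, in which case the whole
#' pattern repeats cyclically with that period.
#'
#' @param t_start strictly increasing interval start times (min); the first
#'   must be 0.
#' @param u_aTc external aTc per interval (ng/mL).
#' @param u_IPTG external IPTG per interval (mM).
#' @param period optional cycle length (min); must be > max(t_start).
#' @return An object of class `inducer_schedule`.
#' @export
inducer_schedule <- function(t_start, u_aTc, u_IPTG, period = NULL) {
  t_start <- as.numeric(t_start)
  u_aTc <- as.numeric(u_aTc)
  u_IPTG <- as.numeric(u_IPTG)
  n <- length(t_start)
  if (n < 1L || length(u_aTc) != n || length(u_IPTG) != n)
    stop("inducer_schedule: t_start, u_aTc, u_IPTG must have equal length >= 1")
  if (t_start[1] != 0) stop("inducer_schedule: first breakpoint must be t = 0")
  if (n > 1L && any(diff(t_start) <= 0))
    stop("inducer_schedule: breakpoints must be strictly increasing")
  if (any(u_aTc < 0) || any(u_IPTG < 0))
    stop("inducer_schedule: concentrations must be nonnegative")
  if (!is.null(period)) {
    period <- as.numeric(period)
    if (length(period) != 1L || !is.finite(period) || period <= max(t_start))
      stop("inducer_schedule: period must exceed the last breakpoint")
  }
  structure(list(t_start = t_start, u_aTc = u_aTc, u_IPTG = u_IPTG,
                 period = period),
            class = "inducer_schedule")
}

#' Constant-input schedule
#' @param u_aTc,u_IPTG external concentrations (ng/mL, mM).
#' @export
constant_schedule <- function(u_aTc, u_IPTG) {
  inducer_schedule(0, u_aTc, u_IPTG)
}

#' Two-phase cyclic forcing protocol
#'
#' The alternating-inducer stimulation used for dynamic stabilization: a phase
#' of IPTG alone followed by a phase of aTc alone, repeated with period
#' `t_IPTG + t_aTc`. The reference protocols are 120 min of 0.5 mM IPTG then
#' 30 min of 50 ng/mL aTc, and the slower 180/30 variant.
#'
#' @param t_IPTG,t_aTc phase durations (min).
#' @param c_IPTG IPTG concentration during the IPTG phase (mM).
#' @param c_aTc aTc concentration during the aTc phase (ng/mL).
#' @return A periodic `inducer_schedule`.
#' @export
forcing_schedule <- function(t_IPTG = 120, t_aTc = 30,
                             c_IPTG = 0.5, c_aTc = 50) {
  stopifnot(t_IPTG > 0, t_aTc > 0)
  inducer_schedule(t_start = c(0, t_IPTG),
                   u_aTc = c(0, c_aTc),
                   u_IPTG = c(c_IPTG, 0),
                   period = t_IPTG + t_aTc)
}

#' Evaluate a schedule
#'
#' @param schedule an `inducer_schedule`.
#' @param t times (min), each >= 0; vectorized.
#' @return A list with numeric vectors `u_aTc` and `u_IPTG`.
#' @export
schedule_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "inducer_schedule"), all(t >= 0))
  if (!is.null(schedule$period)) t <- t %% schedule$period
  idx <- findInterval(t, schedule$t_start)  # half-open [t_i, t_{i+1})
  list(u_aTc = schedule$u_aTc[idx], u_IPTG = schedule$u_IPTG[idx])
}

#' Switching times of a schedule within a window
#'
#' All times in `(t0, t1)` at which the inputs change value, including cyclic
#' repeats of the breakpoints for periodic schedules. Integrators restart at
#' these times.
#'
#' @param schedule an `inducer_schedule`.
#' @param t0,t1 window bounds (min).
#' @return Sorted numeric vector of event times.
#' @export
schedule_events <- function(schedule, t0, t1) {
  stopifnot(inherits(schedule, "inducer_schedule"), t1 >= t0)
  br <- schedule$t_start
  if (is.null(schedule$period)) {
    ev <- br
  } else {
    per <- schedule$period
    k <- seq.int(floor(t0 / per), ceiling(t1 / per))
    ev <- as.vector(outer(br, k * per, `+`))
  }
  sort(ev[ev > t0 & ev < t1])
}

#' Inspect a two-phase forcing protocol
#'
#' Reports the per-cycle phase durations and their ratio (duration of the
#' IPTG phase over the duration of the aTc phase). The 120/30 reference
#' protocol has duty ratio 4.
#'
#' @param schedule a periodic `inducer_schedule` with two phases per cycle.
#' @return A list with `t_IPTG`, `t_aTc` (min) and `duty_ratio`.
#' @export
duty_ratio <- function(schedule) {
  stopifnot(inherits(schedule, "inducer_schedule"))
  if (is.null(schedule$period))
    stop("duty_ratio: schedule is not periodic")
  dur <- diff(c(schedule$t_start, schedule$period))
  on_IPTG <- schedule$u_IPTG > 0 & schedule$u_aTc == 0
  on_aTc <- schedule$u_aTc > 0 & schedule$u_IPTG == 0
  if (!any(on_IPTG) || !any(on_aTc))
    stop("duty_ratio: schedule lacks a pure-IPTG or pure-aTc phase")
  t_IPTG <- sum(dur[on_IPTG])
  t_aTc <- sum(dur[on_aTc])
  list(t_IPTG = t_IPTG, t_aTc = t_aTc, duty_ratio = t_IPTG / t_aTc)
}

#' Read / write a schedule as CSV
#'
#' Columns: `t_start_min`, `u_aTc_ng_per_ml`, `u_IPTG_mM`. A periodic
#' schedule stores its period in a `# period_min:` header comment.
#'
#' @param path file path.
#' @export
read_schedule_csv <- function(path) {
  lines <- readLines(path, n = 5L)
  period <- NULL
  m <- grep("^# *period_min:", lines, value = TRUE)
  if (length(m))
    period <- as.numeric(sub("^# *period_min: *", "", m[1]))
  d <- utils::read.csv(path, comment.char = "#")
  inducer_schedule(d$t_start_min, d$u_aTc_ng_per_ml, d$u_IPTG_mM,
                   period = period)
}

#' @rdname read_schedule_csv
#' @param schedule an `inducer_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "inducer_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(schedule$period))
    writeLines(sprintf("# period_min: %.10g", schedule$period), con)
  utils::write.csv(data.frame(t_start_min = schedule$t_start,
                              u_aTc_ng_per_ml = schedule$u_aTc,
                              u_IPTG_mM = schedule$u_IPTG),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.inducer_schedule <- function(x, ...) {
  cat("Inducer schedule:", length(x$t_start), "interval(s)",
      if (!is.null(x$period)) sprintf("(periodic, period %.4g min)", x$period)
      else "(aperiodic)", "\n")
  print(data.frame(t_start_min = x$t_start, u_aTc = x$u_aTc,
                   u_IPTG = x$u_IPTG))
  invisible(x)
}
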