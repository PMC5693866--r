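#' Specification of a heterogeneous cell population
#'
#' Describes how synthetic single-cell data are generated: population size,
#' phenotypic heterogeneity (per-cell multiplicative log-normal jitter on a
#' subset of kinetic parameters, median 1, given coefficient of variation)
#' and multiplicative log-normal measurement noise on the fluorescence
#' traces.
#'
#' @param n_cells number of cells (>= 1); the calibration default mirrors
#'   the 9-cell averaged experiments.
#' @param heterogeneity_cv CV of the per-cell parameter jitter.
#' @param jittered character vector of [toggle_params] field names jittered.
#' @param noise_cv CV of the measurement noise factors.
#' @param seed master seed for all draws.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 9, heterogeneity_cv = 0.1,
                            jittered = c("k_m_L", "k_m_T", "k_p_L", "k_p_T"),
                            noise_cv = 0.05, seed = 1) {
  if (n_cells < 1) stop("population_spec: n_cells must be >= 1")
  if (heterogeneity_cv < 0 || noise_cv < 0)
    stop("population_spec: CVs must be nonnegative")
  if (heterogeneity_cv > 0 && !length(jittered))
    stop("population_spec: jittered set empty while heterogeneity_cv > 0")
  if (!all(jittered %in% toggle_params_fields()))
    stop("population_spec: unknown parameter names in 'jittered'")
  structure(list(n_cells = as.integer(n_cells),
                 heterogeneity_cv = heterogeneity_cv,
                 jittered = jittered, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# sdlog of a log-normal with median 1 and coefficient of variation cv
lognorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Draw the kinetic parameters of one cell
#'
#' Multiplies each jittered field of `p` by an independent log-normal factor
#' with median 1 and CV `spec$heterogeneity_cv`. Deterministic given
#' `(spec$seed, cell_index)`.
#'
#' @param p a [toggle_params] object (the population median).
#' @param spec a [population_spec].
#' @param cell_index cell number (1-based).
#' @return A [toggle_params] object.
#' @export
sample_cell_params <- function(p, spec, cell_index) {
  stopifnot(inherits(p, "toggle_params"), inherits(spec, "population_spec"))
  if (spec$heterogeneity_cv == 0) return(p)
  old <- .Random.seed_backup()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(spec$seed, cell_index))
  sdl <- lognorm_sdlog(spec$heterogeneity_cv)
  fac <- stats::rlnorm(length(spec$jittered), meanlog = 0, sdlog = sdl)
  q <- unclass(p)
  q[spec$jittered] <- mapply(`*`, q[spec$jittered], fac)
  do.call(toggle_params, q)
}

# save/restore the global RNG state so samplers are pure in (seed, index)
.Random.seed_backup <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Apply multiplicative measurement noise to a fluorescence trace
#'
#' Each sample is multiplied by an independent log-normal factor with median
#' 1 and coefficient of variation `noise_cv`; output is always positive.
#'
#' @param trace positive numeric vector (a.u.).
#' @param noise_cv noise CV (0 returns the trace unchanged).
#' @param seed RNG seed.
#' @return Noisy trace, same length.
#' @export
add_measurement_noise <- function(trace, noise_cv, seed) {
  if (any(trace <= 0)) stop("add_measurement_noise: trace must be positive")
  if (noise_cv == 0) return(trace)
  old <- .Random.seed_backup()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  trace * stats::rlnorm(length(trace), 0,
                        lognorm_sdlog(noise_cv))
}

# schedules of the built-in calibration designs: step changes exercising
# both switch directions, as in the calibration experiments
calibration_schedule <- function(kind = c("step_up_aTc", "step_up_IPTG",
                                          "alternating")) {
  kind <- match.arg(kind)
  switch(kind,
         step_up_aTc = inducer_schedule(c(0, 240), u_aTc = c(0, 100),
                                        u_IPTG = c(1, 0)),
         step_up_IPTG = inducer_schedule(c(0, 240), u_aTc = c(100, 0),
                                         u_IPTG = c(0, 1)),
         alternating = inducer_schedule(c(0, 180, 420, 600),
                                        u_aTc = c(0, 100, 0, 100),
                                        u_IPTG = c(1, 0, 1, 0)))
}

#' Generate one synthetic calibration experiment
#'
#' Emulates a step-change calibration experiment: `n_cells` cells are
#' simulated under the schedule (stochastically, or deterministically with
#' per-cell parameter jitter), the LacI-RFP and TetR-GFP channels are
#' averaged across cells, and multiplicative measurement noise is applied to
#' the averaged traces. Cells start at the deterministic equilibrium under
#' the schedule's first condition, approached from the GFP-dominant state.
#'
#' @param model a [toggle_model] holding the generating (true) parameters.
#' @param schedule_kind `"step_up_aTc"`, `"step_up_IPTG"`, `"alternating"`,
#'   or an [inducer_schedule].
#' @param spec a [population_spec].
#' @param seed RNG seed for this experiment.
#' @param plant `"ode"` (deterministic cells) or `"ssa"` (stochastic cells).
#' @param t_end experiment length (min); default covers the schedule.
#' @param sample_dt fluorescence sampling interval (min).
#' @return A calibration experiment entry (see [calibration_dataset()]) with
#'   an extra `truth` element recording the generating parameters.
#' @export
gen_calibration_experiment <- function(model, schedule_kind, spec, seed,
                                       plant = c("ode", "ssa"),
                                       t_end = NULL, sample_dt = 6) {
  plant <- match.arg(plant)
  stopifnot(inherits(spec, "population_spec"))
  schedule <- if (inherits(schedule_kind, "inducer_schedule")) schedule_kind
              else calibration_schedule(schedule_kind)
  if (is.null(t_end)) t_end <- max(schedule$t_start) + 480
  times <- seq(0, t_end, by = sample_dt)
  acc_rfp <- 0; acc_gfp <- 0
  for (i in seq_len(spec$n_cells)) {
    p_i <- sample_cell_params(model$params, spec, i)
    m_i <- toggle_model(p_i, model$exchange)
    s0 <- experiment_init_state(m_i, schedule)
    if (plant == "ode") {
      tr <- integrate_toggle(m_i, s0, schedule, t_end,
                             sample_dt = sample_dt)
      rfp <- stats::approx(tr$times, tr$states[, "LacI"], times,
                           rule = 2)$y
      gfp <- stats::approx(tr$times, tr$states[, "TetR"], times,
                           rule = 2)$y
    } else {
      run <- simulate_ssa(m_i, s0, schedule, t_end,
                          seed = child_seed(seed, i),
                          sample_dt = sample_dt)
      rfp <- run$states[, "LacI"]; gfp <- run$states[, "TetR"]
    }
    acc_rfp <- acc_rfp + rfp; acc_gfp <- acc_gfp + gfp
  }
  rfp <- pmax(acc_rfp / spec$n_cells, 1e-9)
  gfp <- pmax(acc_gfp / spec$n_cells, 1e-9)
  rfp <- add_measurement_noise(rfp, spec$noise_cv, child_seed(seed, 9001))
  gfp <- add_measurement_noise(gfp, spec$noise_cv, child_seed(seed, 9002))
  list(schedule = schedule, times = times, rfp = rfp, gfp = gfp,
       n_cells = spec$n_cells,
       truth = list(params = model$params, exchange = model$exchange,
                    spec = spec, seed = seed, plant = plant))
}

#' Generate a full synthetic calibration dataset
#'
#' The default design mirrors the calibration campaign: one step change in
#' each switching direction, nine cells per experiment.
#'
#' @param model generating [toggle_model].
#' @param spec a [population_spec].
#' @param kinds schedule kinds, one experiment each.
#' @param seed master seed.
#' @inheritParams gen_calibration_experiment
#' @return A [calibration_dataset]; the generating truth of each experiment
#'   is kept in its `truth` element (sidecar for recovery tests).
#' @export
gen_calibration_dataset <- function(model = toggle_model(),
                                    spec = population_spec(),
                                    kinds = c("step_up_aTc", "step_up_IPTG"),
                                    seed = 1, plant = "ode",
                                    sample_dt = 6) {
  entries <- lapply(seq_along(kinds), function(k)
    gen_calibration_experiment(model, kinds[k], spec,
                               seed = child_seed(seed, 100 + k),
                               plant = plant, sample_dt = sample_dt))
  calibration_dataset(entries)
}
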