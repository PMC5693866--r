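# pack parameters for the compiled core, in toggle_params_fields() order
pack_params <- function(p) unlist(unclass(p))[toggle_params_fields()]

pack_exchange <- function(ex) {
  if (ex$variant == "symmetric")
    list(code = 0L, rates = c(ex$k_IPTG, 0, 0, 0))
  else
    list(code = 1L, rates = c(ex$k_aTc_in, ex$k_aTc_out,
                              ex$k_IPTG_in, ex$k_IPTG_out))
}

# input segments covering [t0, t_end] as parallel vectors
schedule_segments <- function(schedule, t0, t_end) {
  starts <- c(t0, schedule_events(schedule, t0, t_end))
  u <- schedule_value(schedule, starts)
  list(start = starts, u_aTc = u$u_aTc, u_IPTG = u$u_IPTG)
}

#' One step of the first-reaction Gillespie method
#'
#' Draws an exponential candidate waiting time for every reaction channel
#' with positive propensity (`tau_r = Exp(1)/a_r`) and fires the earliest.
#' Channels with zero propensity never fire. Uses R's global RNG stream.
#'
#' @param state named 6-vector; the four reaction species should be counts.
#' @param p a [toggle_params] object.
#' @return List with `tau` (min), `reaction` (index 1..8, or `NA` when every
#'   propensity is zero, signalling a frozen state) and the propensity vector.
#' @export
first_reaction_step <- function(state, p) {
  a <- propensities(state, p)
  active <- which(a > 0)
  if (!length(active))
    return(list(tau = Inf, reaction = NA_integer_, propensities = a))
  taus <- stats::rexp(length(active)) / a[active]
  k <- which.min(taus)
  list(tau = unname(taus[k]), reaction = unname(active[k]),
       propensities = a)
}

#' Stochastic simulation of a single cell
#'
#' Continuous-time Markov chain simulation of the gene-expression
#' pseudo-reactions by the first-reaction Gillespie method (compiled core).
#' Internal inducers advance deterministically between events via the exact
#' exponential solution of the exchange ODE; propensities are held constant
#' between events and recomputed after every event and at every schedule
#' breakpoint (candidate jumps crossing a breakpoint are rejected and the
#' clock advances to the breakpoint). The four species of the initial state
#' are rounded to integer counts.
#'
#' @param model a [toggle_model].
#' @param state0 initial state (named 6-vector).
#' @param schedule an [inducer_schedule].
#' @param t_end end time (min), > 0.
#' @param seed integer RNG seed; the run is bit-reproducible given the seed.
#' @param sample_dt uniform output grid spacing (min), > 0.
#' @param t0 start time (min).
#' @param store_jumps keep the per-event times and reaction indices (capped
#'   at `max_jump_store`).
#' @param max_jump_store cap on stored events.
#' @return A `stochastic_run`: list with `times`, `states` (matrix), `seed`,
#'   `n_events`, `final_state`, optional `jump_times`/`jump_reaction`, and
#'   `froze` (TRUE if an all-zero propensity state was ever reached).
#' @export
simulate_ssa <- function(model, state0, schedule, t_end, seed,
                         sample_dt = 1, t0 = 0, store_jumps = FALSE,
                         max_jump_store = 200000L) {
  stopifnot(inherits(model, "toggle_model"),
            inherits(schedule, "inducer_schedule"))
  if (t_end <= t0) stop("simulate_ssa: t_end must exceed t0")
  if (sample_dt <= 0) stop("simulate_ssa: sample_dt must be positive")
  state0 <- state0[state_names()]
  if (any(is.na(state0)) || any(state0 < 0))
    stop("simulate_ssa: invalid initial state")
  seg <- schedule_segments(schedule, t0, t_end)
  exp_ <- pack_exchange(model$exchange)
  set.seed(as.integer(seed))
  res <- ssa_first_reaction_cpp(unname(state0), t0, t_end,
                                seg$start, seg$u_aTc, seg$u_IPTG,
                                unname(pack_params(model$params)),
                                exp_$code, exp_$rates, sample_dt,
                                store_jumps, as.integer(max_jump_store))
  states <- res$sampled[, -1, drop = FALSE]
  colnames(states) <- state_names()
  out <- list(times = res$sampled[, 1], states = states,
              seed = as.integer(seed), n_events = res$n_events,
              froze = res$froze,
              final_state = stats::setNames(res$final_state, state_names()),
              schedule = schedule)
  if (store_jumps) {
    out$jump_times <- res$jump_times
    out$jump_reaction <- res$jump_reaction
  }
  structure(out, class = "stochastic_run")
}

#' @export
print.stochastic_run <- function(x, ...) {
  cat("Stochastic run (seed", x$seed, "):", format(x$n_events, big.mark = ","),
      "events over", max(x$times) - min(x$times), "min\n")
  fin <- x$final_state
  cat(sprintf("  final: LacI = %g, TetR = %g\n", fin[["LacI"]],
              fin[["TetR"]]))
  invisible(x)
}

#' @export
as.data.frame.stochastic_run <- function(x, ...) {
  data.frame(t_min = x$times, x$states)
}

#' Write a sampled stochastic run as CSV (seed recorded in the header)
#' @param run a `stochastic_run`.
#' @param path file path.
#' @export
write_run_csv <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", run$seed), con)
  utils::write.csv(as.data.frame(run), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic child seed for cell i under a master seed (kept below 2^31)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483629)
}

#' Simulate an independent population of stochastic cells
#'
#' Runs `n` independent stochastic single-cell simulations, optionally with
#' per-cell kinetic parameters drawn from a sampler (phenotypic
#' heterogeneity); cell seeds are derived deterministically from the master
#' seed.
#'
#' @param model a [toggle_model].
#' @param n number of cells (>= 1).
#' @param state0 initial state shared by all cells, or a function
#'   `(cell_index, model_i)` returning one.
#' @param schedule an [inducer_schedule].
#' @param t_end end time (min).
#' @param seed master seed.
#' @param sample_dt output grid spacing (min).
#' @param param_sampler optional function `(cell_index)` returning a
#'   [toggle_params] for that cell (e.g. from [sample_cell_params()]);
#'   `NULL` gives a homogeneous population.
#' @return A `stochastic_population`: list of `stochastic_run` objects with
#'   attributes `seed` and `n`.
#' @export
simulate_population <- function(model, n, state0, schedule, t_end, seed,
                                sample_dt = 2, param_sampler = NULL) {
  stopifnot(n >= 1)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    model_i <- model
    if (!is.null(param_sampler))
      model_i <- toggle_model(param_sampler(i), model$exchange)
    s0 <- if (is.function(state0)) state0(i, model_i) else state0
    runs[[i]] <- simulate_ssa(model_i, s0, schedule, t_end,
                              seed = child_seed(seed, i),
                              sample_dt = sample_dt)
  }
  structure(runs, class = "stochastic_population", seed = seed, n = n)
}

#' @export
print.stochastic_population <- function(x, ...) {
  cat("Stochastic population:", attr(x, "n"), "independent cells (master seed",
      attr(x, "seed"), ")\n")
  invisible(x)
}

#' Simulate method for toggle models
#'
#' `simulate()` on a [toggle_model] runs the stochastic interpretation:
#' one `stochastic_run` for `nsim = 1`, otherwise an independent population.
#'
#' @param object a [toggle_model].
#' @param nsim number of cells.
#' @param seed RNG seed (required).
#' @param state0 initial state.
#' @param schedule an [inducer_schedule].
#' @param t_end end time (min).
#' @param ... passed on to [simulate_ssa()] or [simulate_population()].
#' @export
simulate.toggle_model <- function(object, nsim = 1, seed = NULL, state0,
                                  schedule, t_end, ...) {
  if (is.null(seed)) stop("simulate.toggle_model: a seed is required")
  if (nsim == 1)
    simulate_ssa(object, state0, schedule, t_end, seed = seed, ...)
  else
    simulate_population(object, nsim, state0, schedule, t_end, seed = seed,
                        ...)
}
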