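# registry of named, seeded, reproducible in-silico experiments; each entry
# runs one analysis and writes its CSV outputs into out_dir
experiment_registry <- function() {
  list(
    calibration_traces = function(model, seed, out_dir, ...) {
      ds <- gen_calibration_dataset(model, population_spec(seed = seed),
                                    seed = seed)
      write_calibration_csv(ds, file.path(out_dir, "calibration_data.csv"))
      preds <- lapply(ds$experiments,
                      function(e) predict_experiment(model, e))
      for (i in seq_along(preds))
        utils::write.csv(preds[[i]],
                         file.path(out_dir,
                                   sprintf("model_trace_exp%d.csv", i)),
                         row.names = FALSE)
      ds
    },
    reference_equilibria = function(model, seed, out_dir,
                                u = c(u_aTc = 20, u_IPTG = 0.25), ...) {
      eq <- find_equilibria(model, u)
      write_equilibria_csv(eq, file.path(out_dir, "equilibria.csv"))
      nc <- nullclines(model, u)
      utils::write.csv(nc$lacI, file.path(out_dir, "nullcline_lacI.csv"),
                       row.names = FALSE)
      utils::write.csv(nc$tetR, file.path(out_dir, "nullcline_tetR.csv"),
                       row.names = FALSE)
      eq
    },
    pi_control_ssa = function(model, seed, out_dir, t_end = 900, ...) {
      cfg <- controller_config("PI")
      rec <- run_closed_loop(model, cfg,
                             state0 = saddle_state(model, cfg),
                             t_end = t_end, plant = "ssa", seed = seed)
      write_closed_loop_csv(rec, file.path(out_dir, "closed_loop.csv"))
      rec
    },
    follower_population = function(model, seed, out_dir, t_end = 900,
                                 n_follow = 16, ...) {
      cfg <- controller_config("bangbang")
      rec <- run_closed_loop(model, cfg,
                             state0 = saddle_state(model, cfg),
                             t_end = t_end, plant = "ssa", seed = seed)
      write_closed_loop_csv(rec, file.path(out_dir, "controlled_cell.csv"))
      # follower cells: open-loop replay of the controlled cell's inputs
      sched <- inducer_schedule(rec$meas_times[-length(rec$meas_times)],
                               rec$applied[-nrow(rec$applied), "u_aTc"],
                               rec$applied[-nrow(rec$applied), "u_IPTG"])
      pop <- simulate_population(model, n_follow, rec$states[1, ], sched,
                                 t_end, seed = child_seed(seed, 77))
      for (i in seq_len(n_follow))
        write_run_csv(pop[[i]],
                      file.path(out_dir, sprintf("follower_%02d.csv", i)))
      list(record = rec, followers = pop)
    },
    forcing_120_30 = function(model, seed, out_dir, n_cells = 16,
                                    t_end = 2400, t_release = 1500, ...) {
      fr <- run_periodic_forcing(model, forcing_schedule(120, 30),
                                 n_cells, t_end, t_release, seed)
      write_forcing_outputs(fr, out_dir)
      fr
    },
    avg_field_120_30 = function(model, seed, out_dir, ...) {
      fld <- time_averaged_field(model, forcing_schedule(120, 30))
      write_field_csv(fld, file.path(out_dir, "avg_field.csv"))
      utils::write.csv(fld$null_points,
                       file.path(out_dir, "null_points.csv"),
                       row.names = FALSE)
      fld
    },
    forcing_180_30 = function(model, seed, out_dir, n_cells = 16,
                                     t_end = 2700, t_release = 1680, ...) {
      fr <- run_periodic_forcing(model, forcing_schedule(180, 30),
                                 n_cells, t_end, t_release, seed)
      write_forcing_outputs(fr, out_dir)
      fr
    },
    duty_ratio_scan = function(model, seed, out_dir,
                               t_IPTG = c(60, 90, 120, 150, 180),
                               t_aTc = 30, ...) {
      rows <- lapply(t_IPTG, function(ti) {
        fld <- time_averaged_field(model, forcing_schedule(ti, t_aTc),
                                   n = 120)
        np <- fld$null_points
        data.frame(t_IPTG = ti, t_aTc = t_aTc, duty_ratio = ti / t_aTc,
                   n_null = nrow(np),
                   LacI = np$LacI[which.max(np$TetR)],
                   TetR = max(np$TetR))
      })
      scan <- do.call(rbind, rows)
      utils::write.csv(scan, file.path(out_dir, "duty_ratio_scan.csv"),
                       row.names = FALSE)
      scan
    },
    recovery = function(model, seed, out_dir, max_evals = 1500, ...) {
      spec <- population_spec(n_cells = 1, heterogeneity_cv = 0,
                              noise_cv = 0, seed = seed)
      ds <- gen_calibration_dataset(model, spec, seed = seed)
      free <- c("theta_LacI", "theta_TetR", "g_p_L", "g_p_T")
      truth <- unlist(unclass(model$params))[free]
      start <- modify_params(model, as.list(truth * c(2, 0.5, 1.8, 0.6)))
      fit <- fit_toggle(ds, start, free, lower = truth / 10,
                        upper = truth * 10, seed = seed,
                        max_evals = max_evals)
      rep <- recovery_report(truth, coef(fit), ds, start)
      utils::write.csv(rep, file.path(out_dir, "recovery_report.csv"),
                       row.names = FALSE)
      rep
    }
  )
}

saddle_state <- function(model, cfg) {
  eq <- find_equilibria(model, c(u_aTc = cfg$u0_aTc, u_IPTG = cfg$u0_IPTG))
  sad <- eq[eq$stability == "unstable", ]
  cell_state(mRNA_L = sad$mRNA_L, mRNA_T = sad$mRNA_T,
             LacI = sad$LacI, TetR = sad$TetR,
             aTc_in = sad$aTc_in, IPTG_in = sad$IPTG_in)
}

write_forcing_outputs <- function(fr, out_dir) {
  n <- attr(fr$population, "n")
  for (i in seq_len(n))
    write_run_csv(fr$population[[i]],
                  file.path(out_dir, sprintf("cell_%02d.csv", i)))
  utils::write.csv(fr$labels, file.path(out_dir, "fate_labels.csv"),
                   row.names = FALSE)
  write_equilibria_csv(fr$equilibria,
                       file.path(out_dir, "basal_equilibria.csv"))
  invisible(NULL)
}

#' List the registered in-silico experiments
#' @return Character vector of experiment names.
#' @export
list_experiments <- function() names(experiment_registry())

#' Run a registered in-silico experiment
#'
#' Dispatches to the simulation, phase-portrait, control or calibration
#' machinery, writes all outputs as CSV into `out_dir` together with a
#' plain-text run manifest (configuration echo plus seed) sufficient to
#' re-run the experiment bit-identically.
#'
#' @param name experiment name, one of [list_experiments()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @param model a [toggle_model]; defaults to the reference model.
#' @param ... experiment-specific overrides (e.g. `t_end`, `n_cells`).
#' @return The experiment's result object, invisibly.
#' @export
run_experiment <- function(name, out_dir, seed = 1,
                           model = toggle_model(), ...) {
  reg <- experiment_registry()
  if (!name %in% names(reg))
    stop("unknown experiment '", name, "'; registered: ",
         paste(names(reg), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  extra <- list(...)
  res <- reg[[name]](model = model, seed = seed, out_dir = out_dir, ...)
  manifest <- c(
    sprintf("experiment: %s", name),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("exchange_variant: %s", model$exchange$variant),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("togglectl"))),
    "parameters:",
    sprintf("  %s: %.10g", toggle_params_fields(),
            unlist(unclass(model$params))[toggle_params_fields()]),
    if (length(extra)) c("overrides:",
                         sprintf("  %s: %s", names(extra),
                                 vapply(extra, function(v)
                                   paste(format(v), collapse = ","),
                                   character(1))))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(res)
}
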