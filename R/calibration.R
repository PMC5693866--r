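#' Calibration dataset of averaged fluorescence time courses
#'
#' A list of calibration experiments. Each experiment is a list with an
#' [inducer_schedule], measurement `times` (min), averaged `rfp` (LacI
#' channel) and `gfp` (TetR channel) traces in a.u., and `n_cells`, the
#' number of cells averaged.
#'
#' @param experiments list of experiment entries as above.
#' @return An object of class `calibration_dataset`.
#' @export
calibration_dataset <- function(experiments) {
  for (e in experiments) {
    stopifnot(inherits(e$schedule, "inducer_schedule"),
              length(e$times) == length(e$rfp),
              length(e$times) == length(e$gfp))
    if (any(diff(e$times) <= 0))
      stop("calibration_dataset: times must be increasing")
    if (any(e$rfp <= 0) || any(e$gfp <= 0))
      stop("calibration_dataset: traces must be positive")
  }
  structure(list(experiments = experiments), class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat("Calibration dataset:", length(x$experiments), "experiment(s)\n")
  for (i in seq_along(x$experiments)) {
    e <- x$experiments[[i]]
    cat(sprintf("  [%d] %d time points over %g min (n = %s cells)\n", i,
                length(e$times), max(e$times),
                if (is.null(e$n_cells)) "?" else e$n_cells))
  }
  invisible(x)
}

#' Read / write calibration datasets as CSV
#'
#' Columns: `experiment_id`, `t_min`, `u_aTc`, `u_IPTG`, `rfp_au`, `gfp_au`.
#' On read, each experiment's schedule is reconstructed from the
#' piecewise-constant input columns.
#'
#' @param path file path.
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  experiments <- lapply(split(d, d$experiment_id), function(g) {
    g <- g[order(g$t_min), ]
    chg <- c(TRUE, diff(g$u_aTc) != 0 | diff(g$u_IPTG) != 0)
    t_start <- g$t_min[chg]
    if (t_start[1] != 0) t_start[1] <- 0
    list(schedule = inducer_schedule(t_start, g$u_aTc[chg], g$u_IPTG[chg]),
         times = g$t_min, rfp = g$rfp_au, gfp = g$gfp_au,
         n_cells = NA_integer_)
  })
  calibration_dataset(unname(experiments))
}

#' @rdname read_calibration_csv
#' @param dataset a `calibration_dataset`.
#' @export
write_calibration_csv <- function(dataset, path) {
  rows <- lapply(seq_along(dataset$experiments), function(i) {
    e <- dataset$experiments[[i]]
    u <- schedule_value(e$schedule, e$times)
    data.frame(experiment_id = i, t_min = e$times,
               u_aTc = u$u_aTc, u_IPTG = u$u_IPTG,
               rfp_au = e$rfp, gfp_au = e$gfp)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# initial state of an experiment: deterministic equilibrium under the first
# input condition, approached from the GFP-dominant corner (cells were
# pre-equilibrated under IPTG before runs)
experiment_init_state <- function(model, schedule) {
  u1 <- schedule_value(schedule, 0)
  u1 <- c(u_aTc = u1$u_aTc, u_IPTG = u1$u_IPTG)
  sc <- protein_scales(model)
  r <- newton_reduced(c(1, sc[["TetR"]]), u1, model, tol = 1e-8)
  if (is.null(r))
    return(steady_state(model, u1, from = c(LacI = 1, TetR = sc[["TetR"]])))
  lift_state(r[1], r[2], u1, model)
}

# model-predicted channel traces for one experiment
predict_experiment <- function(model, exp_entry, sample_dt = NULL) {
  tr <- integrate_toggle(model, experiment_init_state(model,
                                                      exp_entry$schedule),
                         exp_entry$schedule, t_end = max(exp_entry$times),
                         sample_dt = if (is.null(sample_dt))
                           max(diff(exp_entry$times)[1], 1) else sample_dt)
  rfp <- stats::approx(tr$times, tr$states[, "LacI"], exp_entry$times,
                       rule = 2)$y
  gfp <- stats::approx(tr$times, tr$states[, "TetR"], exp_entry$times,
                       rule = 2)$y
  data.frame(t_min = exp_entry$times, rfp = rfp, gfp = gfp)
}

#' Mean squared relative deviation objective
#'
#' The calibration objective: mean, over all experiments, channels and time
#' points, of the squared relative deviation between the deterministic model
#' prediction and the averaged measured fluorescence,
#' `mean(((model - data) / data)^2)`. Zero iff the model matches the data
#' exactly; integration failures return a large finite penalty so global
#' optimizers can proceed.
#'
#' @param par named numeric vector of parameter values (natural scale) to
#'   substitute into the model.
#' @param dataset a [calibration_dataset].
#' @param model a [toggle_model] providing all non-free parameters and the
#'   exchange variant.
#' @return Nonnegative scalar (or the penalty `1e10` on failure).
#' @export
objective_msrd <- function(par, dataset, model) {
  m <- tryCatch(modify_params(model, as.list(par)),
                error = function(e) NULL)
  if (is.null(m)) return(1e10)
  dev2 <- tryCatch({
    unlist(lapply(dataset$experiments, function(e) {
      pred <- predict_experiment(m, e)
      c(((pred$rfp - e$rfp) / e$rfp)^2, ((pred$gfp - e$gfp) / e$gfp)^2)
    }))
  }, error = function(e) NULL)
  if (is.null(dev2) || any(!is.finite(dev2))) return(1e10)
  mean(dev2)
}

#' Fit the toggle switch model to calibration data
#'
#' Global optimization of [objective_msrd()] by [cma_es()] in log10-parameter
#' space with box bounds, optionally with restarts; the best-ever point over
#' all restarts is returned. Non-free parameters (including the exchange
#' rates, which mirror the reference model's manually adjusted values unless
#' listed in `free`) are held at the values in `model`.
#'
#' @param dataset a [calibration_dataset].
#' @param model starting [toggle_model]; supplies fixed parameter values.
#' @param free character vector of [toggle_params] field names to fit.
#' @param lower,upper named bounds on the free parameters (natural scale);
#'   defaults span two decades around the model values.
#' @param seed RNG seed (fit is deterministic given the seed).
#' @param max_evals objective-evaluation budget per restart (>= 1000).
#' @param n_restarts independent CMA-ES restarts.
#' @param sigma0 initial step size in log10 space.
#' @return A `toggle_fit` with elements `par` (fitted values), `value`
#'   (objective at the optimum), `model` (updated), `free`, `bounds`, `logs`
#'   (per-restart convergence logs), `dataset`, `seed`.
#' @export
fit_toggle <- function(dataset, model = toggle_model(), free,
                       lower = NULL, upper = NULL, seed = 1,
                       max_evals = 4000, n_restarts = 1, sigma0 = 0.3) {
  stopifnot(inherits(dataset, "calibration_dataset"),
            all(free %in% toggle_params_fields()))
  if (max_evals < 1000) stop("fit_toggle: budget must be >= 1000 evaluations")
  p0 <- vapply(free, function(f) as.numeric(model$params[[f]]), numeric(1))
  if (is.null(lower)) lower <- p0 / 10
  if (is.null(upper)) upper <- p0 * 10
  lower <- rep_len(unlist(lower)[if (!is.null(names(lower))) free else TRUE],
                   length(free))
  upper <- rep_len(unlist(upper)[if (!is.null(names(upper))) free else TRUE],
                   length(free))
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(lower >= upper))
    stop("fit_toggle: bounds must be finite, positive, lower < upper")
  lo <- log10(lower); hi <- log10(upper)
  obj <- function(x) {
    objective_msrd(stats::setNames(10^x, free), dataset, model)
  }
  best <- NULL; logs <- list()
  for (r in seq_len(n_restarts)) {
    x0 <- if (r == 1) pmin(pmax(log10(p0), lo), hi) else
      lo + stats::runif(length(free)) * (hi - lo)
    res <- cma_es(obj, x0, sigma0 = sigma0, lower = lo, upper = hi,
                  max_evals = max_evals, seed = child_seed(seed, r))
    logs[[r]] <- res$log
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (best$value >= 1e10)
    stop("fit_toggle: model never integrable within bounds")
  par <- stats::setNames(10^best$par, free)
  structure(list(par = par, value = best$value,
                 model = modify_params(model, as.list(par)),
                 free = free,
                 bounds = data.frame(parameter = free, lower = lower,
                                     upper = upper),
                 logs = logs, dataset = dataset, seed = seed,
                 counts = best$counts, convergence = best$convergence),
            class = "toggle_fit")
}

#' @export
print.toggle_fit <- function(x, ...) {
  cat("Toggle switch model fit (CMA-ES,", x$counts, "evaluations)\n")
  cat(sprintf("  objective (mean sq. rel. deviation): %.6g\n", x$value))
  print(signif(x$par, 5))
  invisible(x)
}

#' @export
coef.toggle_fit <- function(object, ...) object$par

#' @export
summary.toggle_fit <- function(object, ...) {
  tab <- data.frame(parameter = object$free,
                    estimate = unname(object$par),
                    lower = object$bounds$lower,
                    upper = object$bounds$upper)
  structure(list(table = tab, value = object$value,
                 counts = object$counts,
                 convergence = object$convergence),
            class = "summary.toggle_fit")
}

#' @export
print.summary.toggle_fit <- function(x, ...) {
  cat("CMA-ES calibration summary\n")
  cat(sprintf("  objective: %.6g after %d evaluations (%s)\n", x$value,
              x$counts, x$convergence))
  print(x$table, digits = 5)
  invisible(x)
}

#' @export
predict.toggle_fit <- function(object, newdata = NULL, ...) {
  ds <- if (is.null(newdata)) object$dataset else newdata
  lapply(ds$experiments, function(e) predict_experiment(object$model, e))
}

#' @export
residuals.toggle_fit <- function(object, ...) {
  preds <- predict(object)
  unlist(lapply(seq_along(preds), function(i) {
    e <- object$dataset$experiments[[i]]
    c(rfp = (preds[[i]]$rfp - e$rfp) / e$rfp,
      gfp = (preds[[i]]$gfp - e$gfp) / e$gfp)
  }))
}

#' @export
plot.toggle_fit <- function(x, which = 1, ...) {
  e <- x$dataset$experiments[[which]]
  pred <- predict(x)[[which]]
  graphics::plot(e$times, e$rfp, col = "firebrick", pch = 1,
                 xlab = "time (min)", ylab = "fluorescence (a.u.)",
                 ylim = range(0, e$rfp, e$gfp, pred$rfp, pred$gfp), ...)
  graphics::points(e$times, e$gfp, col = "forestgreen", pch = 1)
  graphics::lines(pred$t_min, pred$rfp, col = "firebrick", lwd = 2)
  graphics::lines(pred$t_min, pred$gfp, col = "forestgreen", lwd = 2)
  graphics::legend("topright", c("RFP data", "GFP data", "model"),
                   col = c("firebrick", "forestgreen", "black"),
                   pch = c(1, 1, NA), lty = c(NA, NA, 1), bty = "n")
  invisible(x)
}

#' Parameter-recovery report
#'
#' Compares fitted against true (generating) parameter values and flags
#' practically unidentifiable ("sloppy") directions: a parameter is flagged
#' when perturbing its fitted value by +/-50% changes the calibration
#' objective by less than 0.01 (i.e. under 1% mean squared relative
#' deviation), meaning the data barely constrain it.
#'
#' @param true named vector of generating parameter values.
#' @param fitted named vector of fitted values (same names).
#' @param dataset the [calibration_dataset] used for the fit.
#' @param model the [toggle_model] holding the non-free parameters.
#' @param sloppy_tol objective-change threshold for the sloppiness flag.
#' @return Data frame with one row per parameter: `true`, `fitted`,
#'   `rel_error`, `sloppy`.
#' @export
recovery_report <- function(true, fitted, dataset, model,
                            sloppy_tol = 0.01) {
  stopifnot(setequal(names(true), names(fitted)))
  true <- true[names(fitted)]
  base <- objective_msrd(fitted, dataset, model)
  rows <- lapply(names(fitted), function(nm) {
    dv <- vapply(c(0.5, 1.5), function(fac) {
      pv <- fitted; pv[nm] <- pv[nm] * fac
      abs(objective_msrd(pv, dataset, model) - base)
    }, numeric(1))
    data.frame(parameter = nm, true = unname(true[nm]),
               fitted = unname(fitted[nm]),
               rel_error = unname(abs(fitted[nm] - true[nm]) / true[nm]),
               sloppy = max(dv) < sloppy_tol)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
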