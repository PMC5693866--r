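# small, fast noiseless dataset shared across calibration tests
calib_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- ref_model()
      spec <- population_spec(n_cells = 1, heterogeneity_cv = 0,
                              noise_cv = 0, seed = 1)
      cache <<- list(model = m,
                     data = gen_calibration_dataset(m, spec, seed = 1))
    }
    cache
  }
})

test_that("the objective is zero at the generating parameters and positive
           away from them", {
  fx <- calib_fixture()
  expect_lt(objective_msrd(c(theta_LacI = 31.94), fx$data, fx$model), 1e-8)
  v <- objective_msrd(c(theta_LacI = 60), fx$data, fx$model)
  expect_gt(v, 0)
  # unintegrable / invalid parameters give the large finite penalty
  expect_identical(objective_msrd(c(theta_LacI = -5), fx$data, fx$model),
                   1e10)
})

test_that("the objective is a mean: duplicating an experiment leaves it
           unchanged, scaling the data shifts it as computed", {
  fx <- calib_fixture()
  par <- c(theta_LacI = 45)
  v1 <- objective_msrd(par, fx$data, fx$model)
  dup <- calibration_dataset(rep(fx$data$experiments, 2))
  expect_equal(objective_msrd(par, dup, fx$model), v1, tolerance = 1e-12)
  # doubling the data with the model unchanged: mean(((m - 2d) / (2d))^2)
  scaled <- fx$data
  scaled$experiments <- lapply(scaled$experiments, function(e) {
    e$rfp <- 2 * e$rfp; e$gfp <- 2 * e$gfp; e
  })
  v2 <- objective_msrd(par, scaled, fx$model)
  m2 <- toggle_model(do.call(toggle_params,
                             modifyList(unclass(fx$model$params),
                                        as.list(par))),
                     fx$model$exchange)
  fit2 <- structure(list(model = m2, dataset = scaled),
                    class = "toggle_fit")
  manual <- mean(unlist(lapply(seq_along(scaled$experiments), function(i) {
    e <- scaled$experiments[[i]]
    pred <- predict(fit2, scaled)[[i]]
    c(((pred$rfp - e$rfp) / e$rfp)^2, ((pred$gfp - e$gfp) / e$gfp)^2)
  })))
  expect_equal(v2, manual, tolerance = 1e-10)
  expect_gt(v2, 0)
})

test_that("CMA-ES minimizes standard test functions deterministically", {
  r1 <- cma_es(function(x) sum(x^2), c(2, -1, 3), 1, max_evals = 4000,
               seed = 1)
  expect_lt(r1$value, 1e-12)
  r2 <- cma_es(function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2,
               c(-1.2, 1), 0.5, max_evals = 8000, seed = 1)
  expect_lt(r2$value, 1e-8)
  expect_equal(r2$par, c(1, 1), tolerance = 1e-3)
  # identical seed, identical convergence log
  a <- cma_es(function(x) sum((x - 3)^2), c(0, 0), 0.5, max_evals = 600,
              seed = 7)
  b <- cma_es(function(x) sum((x - 3)^2), c(0, 0), 0.5, max_evals = 600,
              seed = 7)
  expect_identical(a$log, b$log)
  # box bounds are honoured
  r3 <- cma_es(function(x) sum(x^2), c(2, 2), 0.5, lower = c(1, 1),
               upper = c(4, 4), max_evals = 2000, seed = 2)
  expect_equal(r3$par, c(1, 1), tolerance = 1e-6)
})

test_that("a two-parameter reduced fit recovers the truth within 5%", {
  fx <- calib_fixture()
  free <- c("k_m_L", "k_m_T")
  truth <- unlist(unclass(fx$model$params))[free]
  start <- toggle_model(
    do.call(toggle_params,
            modifyList(unclass(fx$model$params),
                       list(k_m_L = unname(truth[1]) * 3,
                            k_m_T = unname(truth[2]) * 0.4))),
    fx$model$exchange)
  fit <- fit_toggle(fx$data, start, free, lower = truth / 10,
                    upper = truth * 10, seed = 2, max_evals = 1000)
  expect_lt(max(abs(coef(fit) - truth) / truth), 0.05)
  expect_lt(fit$value, objective_msrd(truth * c(3, 0.4), fx$data,
                                      fx$model) + 1e-6)
  expect_s3_class(fit, "toggle_fit")
  expect_identical(names(coef(fit)), free)
  s <- summary(fit)
  expect_identical(nrow(s$table), 2L)
  res <- residuals(fit)
  expect_lt(stats::median(abs(res)), 0.05)
})

test_that("fits are deterministic given the seed", {
  fx <- calib_fixture()
  # a deliberately tiny problem so two full fits stay cheap
  short <- fx$data
  short$experiments <- lapply(short$experiments[1], function(e) {
    keep <- e$times <= 360 & (seq_along(e$times) %% 4 == 1)
    list(schedule = e$schedule, times = e$times[keep], rfp = e$rfp[keep],
         gfp = e$gfp[keep], n_cells = e$n_cells)
  })
  short <- calibration_dataset(short$experiments)
  f1 <- fit_toggle(short, fx$model, "k_m_L", lower = 1, upper = 80,
                   seed = 5, max_evals = 1000)
  f2 <- fit_toggle(short, fx$model, "k_m_L", lower = 1, upper = 80,
                   seed = 5, max_evals = 1000)
  expect_identical(f1$logs, f2$logs)
  expect_identical(coef(f1), coef(f2))
})

test_that("the recovery report measures errors and flags sloppy directions", {
  fx <- calib_fixture()
  truth <- c(theta_LacI = 31.94, g_p_L = 0.0165)
  rep0 <- recovery_report(truth, truth, fx$data, fx$model)
  expect_identical(nrow(rep0), 2L)
  expect_true(all(rep0$rel_error == 0))
  # a parameter with no leverage on the data is flagged sloppy: theta_aTc
  # under a schedule that never applies aTc
  m <- ref_model()
  sched <- constant_schedule(0, 1)
  spec <- population_spec(n_cells = 1, heterogeneity_cv = 0, noise_cv = 0,
                          seed = 3)
  e <- gen_calibration_experiment(m, sched, spec, seed = 3, t_end = 300)
  ds <- calibration_dataset(list(e))
  truth2 <- c(theta_aTc = 11.65, g_p_T = 0.0165)
  rep2 <- recovery_report(truth2, truth2, ds, m)
  expect_true(rep2$sloppy[rep2$parameter == "theta_aTc"])
  expect_false(rep2$sloppy[rep2$parameter == "g_p_T"])
})

test_that("calibration CSV round-trips traces and schedules", {
  fx <- calib_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_calibration_csv(fx$data, path)
  back <- read_calibration_csv(path)
  expect_length(back$experiments, length(fx$data$experiments))
  for (i in seq_along(back$experiments)) {
    a <- back$experiments[[i]]; b <- fx$data$experiments[[i]]
    expect_equal(a$times, b$times)
    expect_equal(a$rfp, b$rfp, tolerance = 1e-6)
    expect_equal(a$gfp, b$gfp, tolerance = 1e-6)
    expect_equal(schedule_value(a$schedule, c(0, 300, 600)),
                 schedule_value(b$schedule, c(0, 300, 600)))
  }
})
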