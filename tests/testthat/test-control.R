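test_that("the PI law returns basal inputs at zero error and clamps", {
  cfg <- controller_config("PI", target_LacI = 500, target_TetR = 300)
  expect_equal(pi_law(200, 500, 300, 0, 0, cfg),
               c(u_aTc = 20, u_IPTG = 0.25))
  # large negative LacI error (measurement far above target) clamps to 0
  expect_equal(pi_law(200, 1e5, 300, 0, 0, cfg)[["u_aTc"]], 0)
  # large positive error clamps at the maximum
  expect_equal(pi_law(200, -1e5, 300, 0, 0, cfg)[["u_aTc"]], 50)
  expect_equal(pi_law(200, 500, -1e6, 0, 0, cfg)[["u_IPTG"]], 0.5)
  expect_equal(pi_law(200, 500, 1e6, 0, 0, cfg)[["u_IPTG"]], 0)
})

test_that("the integral term is discarded before the windup window opens", {
  cfg <- controller_config("PI", target_LacI = 500, target_TetR = 300)
  with_int <- pi_law(119, 480, 290, 5000, 4000, cfg)
  no_int <- pi_law(119, 480, 290, 0, 0, cfg)
  expect_identical(with_int, no_int)              # t <= t_d: integral off
  after <- pi_law(121, 480, 290, 5000, 4000, cfg)
  expect_false(identical(after, no_int))          # t > t_d: integral acts
  expect_equal(after[["u_aTc"]],
               min(20 + cfg$K_P_L * 20 + cfg$K_I_L * 5000, 50))
})

test_that("the bang-bang law is a pure sign rule on the current error", {
  cfg <- controller_config("bangbang", target_LacI = 500, target_TetR = 300)
  expect_equal(bangbang_law(10, 10, cfg), c(u_aTc = 50, u_IPTG = 0.5))
  expect_equal(bangbang_law(1e4, 1e4, cfg), c(u_aTc = 0, u_IPTG = 0))
  # equality takes the minimal branch
  expect_equal(bangbang_law(500, 300, cfg), c(u_aTc = 0, u_IPTG = 0))
  # gains are irrelevant to the law
  cfg2 <- controller_config("bangbang", target_LacI = 500,
                            target_TetR = 300, K_P_L = 99, K_I_L = 99)
  expect_equal(bangbang_law(10, 10, cfg2), bangbang_law(10, 10, cfg))
})

test_that("closed-loop PI holds the cell near the saddle while the
           uncontrolled cell commits", {
  m <- ref_model()
  eq <- find_equilibria(m, ref_u)
  sad <- eq[eq$stability == "unstable", ]
  s0 <- cell_state(sad$mRNA_L, sad$mRNA_T, sad$LacI * 1.02, sad$TetR * 0.98,
                   sad$aTc_in, sad$IPTG_in)
  cfg <- controller_config("PI")
  rec <- run_closed_loop(m, cfg, s0, t_end = 1500, plant = "ode")
  expect_equal(rec$cfg$target_LacI, sad$LacI, tolerance = 1e-6)
  idx <- rec$meas_times >= cfg$t_d
  rel_err <- mean(abs(rec$measured[idx, "LacI"] - rec$cfg$target_LacI)) /
    rec$cfg$target_LacI
  expect_lt(rel_err, 0.5)
  dmin <- min(vapply(seq_len(nrow(rec$states)), function(i)
    dist_to_stable(rec$states[i, "LacI"], rec$states[i, "TetR"], eq),
    numeric(1)))
  expect_gt(dmin, 0.2)
  # same start, controller off (basal inputs): the cell commits
  tr <- integrate_toggle(m, s0, constant_schedule(20, 0.25), 3000,
                         sample_dt = 100)
  fin <- tr$states[nrow(tr$states), ]
  expect_lt(dist_to_stable(fin[["LacI"]], fin[["TetR"]], eq), 0.1)
})

test_that("closed-loop inputs always respect the admissible bounds", {
  m <- ref_model()
  eq <- find_equilibria(m, ref_u)
  sad <- eq[eq$stability == "unstable", ]
  s0 <- cell_state(sad$mRNA_L, sad$mRNA_T, sad$LacI, sad$TetR,
                   sad$aTc_in, sad$IPTG_in)
  for (mode in c("PI", "bangbang")) {
    cfg <- controller_config(mode)
    rec <- run_closed_loop(m, cfg, s0, t_end = 400, plant = "ssa", seed = 6)
    expect_true(all(rec$applied[, "u_aTc"] >= 0 &
                      rec$applied[, "u_aTc"] <= 50))
    expect_true(all(rec$applied[, "u_IPTG"] >= 0 &
                      rec$applied[, "u_IPTG"] <= 0.5))
    if (mode == "bangbang") {
      expect_true(all(rec$applied[, "u_aTc"] %in% c(0, 50)))
      expect_true(all(rec$applied[, "u_IPTG"] %in% c(0, 0.5)))
    }
  }
})

test_that("records with and without the windup window differ only through
           the early integral term", {
  m <- ref_model()
  eq <- find_equilibria(m, ref_u)
  sad <- eq[eq$stability == "unstable", ]
  s0 <- cell_state(sad$mRNA_L, sad$mRNA_T, sad$LacI * 1.05, sad$TetR * 0.95,
                   sad$aTc_in, sad$IPTG_in)
  rec_d <- run_closed_loop(m, controller_config("PI", t_d = 120), s0,
                           t_end = 120, plant = "ode")
  rec_n <- run_closed_loop(m, controller_config("PI", t_d = 1e9), s0,
                           t_end = 120, plant = "ode")
  # before t_d both laws apply the same (integral-free) inputs
  expect_equal(rec_d$applied, rec_n$applied, tolerance = 1e-10)
  rec0 <- run_closed_loop(m, controller_config("PI", t_d = 0), s0,
                          t_end = 120, plant = "ode")
  expect_false(isTRUE(all.equal(rec0$applied, rec_d$applied,
                                tolerance = 1e-10)))
})

test_that("120/30 forcing keeps all cells un-committed, then releases them
           into the RFP state", {
  m <- ref_model()
  fr <- run_periodic_forcing(m, forcing_schedule(120, 30), n_cells = 16,
                             t_end = 2400, t_release = 1500, seed = 1)
  st <- fr$equilibria[fr$equilibria$stability == "stable", ]
  band <- sort(log10(st$LacI / st$TetR))    # attractor log-ratios
  for (i in seq_len(16)) {
    r <- fr$population[[i]]
    idx <- r$times >= 300 & r$times <= 1500
    lr <- log10(pmax(r$states[idx, "LacI"], 1) /
                  pmax(r$states[idx, "TetR"], 1))
    expect_gt(min(lr), band[1] + 0.2)       # never reaches the GFP ratio
    expect_lt(max(lr), band[2] - 0.2)       # never reaches the RFP ratio
  }
  expect_true(all(fr$labels$label == "RFP-dominant"))
})

test_that("180/30 forcing releases the population into both basins", {
  m <- ref_model()
  fr <- run_periodic_forcing(m, forcing_schedule(180, 30), n_cells = 16,
                             t_end = 2700, t_release = 1680, seed = 1)
  expect_setequal(unique(fr$labels$label),
                  c("RFP-dominant", "GFP-dominant"))
})

test_that("quasi-static forcing lets every cell commit during stimulation", {
  m <- ref_model()
  # one very long IPTG phase: period >> commitment timescale
  slow <- forcing_schedule(1200, 30)
  fr <- run_periodic_forcing(m, slow, n_cells = 6, t_end = 1100,
                             t_release = 1100, seed = 4)
  # during the long IPTG phase all cells sit at the (transient) GFP state
  for (i in seq_len(6)) {
    fin <- fr$population[[i]]$final_state
    expect_gt(fin[["TetR"]], 5 * fin[["LacI"]])
  }
})

test_that("the averaged-field null point lies amid the forced population", {
  m <- ref_model()
  np <- time_averaged_field(m, forcing_schedule(120, 30),
                            n = 120)$null_points
  fr <- run_periodic_forcing(m, forcing_schedule(120, 30), n_cells = 16,
                             t_end = 1500, t_release = 1500, seed = 2)
  pts <- do.call(rbind, lapply(fr$population, function(r) {
    idx <- r$times >= 300
    r$states[idx, c("LacI", "TetR")][seq(1, sum(idx), by = 10), ]
  }))
  hull <- pts[grDevices::chull(pts), ]
  # point-in-convex-polygon: consistent orientation of all edge cross
  # products
  nh <- nrow(hull)
  crossp <- vapply(seq_len(nh), function(i) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1 else i + 1, ]
    (b[1] - a[1]) * (np$TetR[1] - a[2]) - (b[2] - a[2]) * (np$LacI[1] - a[1])
  }, numeric(1))
  expect_true(all(crossp <= 0) || all(crossp >= 0))
})
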