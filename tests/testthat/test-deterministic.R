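test_that("integration holds a stable equilibrium under constant input", {
  m <- ref_model()
  eq <- find_equilibria(m, ref_u)
  st <- eq[eq$stability == "stable", ][1, ]
  s0 <- cell_state(st$mRNA_L, st$mRNA_T, st$LacI, st$TetR, st$aTc_in,
                   st$IPTG_in)
  tr <- integrate_toggle(m, s0, constant_schedule(20, 0.25), 1000,
                         sample_dt = 100)
  dev <- abs(sweep(tr$states, 2, s0)) / pmax(abs(s0), 1e-6)
  expect_lt(max(dev), 1e-4)
})

test_that("sustained IPTG drives a low-expression start into the TetR state", {
  m <- ref_model()
  s0 <- cell_state(1, 1, 10, 10, 0, 0)
  tr <- integrate_toggle(m, s0, constant_schedule(0, 1), 2000,
                         sample_dt = 200)
  fin <- tr$states[nrow(tr$states), ]
  expect_gt(fin[["TetR"]], fin[["LacI"]])
  expect_gt(fin[["TetR"]], 500)
})

test_that("with transcription off the solver matches the linear closed form", {
  m <- ref_model()
  p <- edit_params(m$params, k_m0_L = 1e-300, k_m0_T = 1e-300,
                   k_m_L = 1e-300, k_m_T = 1e-300)
  m2 <- toggle_model(do.call(toggle_params, p), m$exchange)
  s0 <- cell_state(0, 0, 500, 300, 20, 0.25)
  tt <- c(100, 300, 600)
  tr <- integrate_toggle(m2, s0, constant_schedule(20, 0.25), 600,
                         sample_dt = 100, rtol = 1e-10, atol = 1e-12)
  for (t in tt) {
    row <- tr$states[which(abs(tr$times - t) < 1e-9)[1], ]
    expect_lt(abs(row[["LacI"]] - 500 * exp(-p$g_p_L * t)) /
                (500 * exp(-p$g_p_L * t)), 1e-6)
    expect_lt(abs(row[["TetR"]] - 300 * exp(-p$g_p_T * t)) /
                (300 * exp(-p$g_p_T * t)), 1e-6)
  }
})

test_that("integration restarts at breakpoints and tracks step inputs", {
  m <- ref_model()
  sched <- inducer_schedule(c(0, 200), u_aTc = c(0, 100), u_IPTG = c(1, 0))
  s0 <- steady_state(m, c(u_aTc = 0, u_IPTG = 1),
                     from = c(LacI = 10, TetR = 1000))
  tr <- integrate_toggle(m, s0, sched, 800, sample_dt = 10)
  expect_true(all(c(0, 200, 800) %in% tr$times))
  expect_equal(unname(tr$inputs[tr$times == 100, ]), c(0, 1))
  expect_equal(unname(tr$inputs[tr$times == 300, ]), c(100, 0))
  # the step change in inducers flips the circuit to the LacI state
  fin <- tr$states[nrow(tr$states), ]
  expect_gt(fin[["LacI"]], fin[["TetR"]])
})

test_that("reduced-field zeros coincide with full-system equilibria", {
  m <- ref_model()
  eq <- find_equilibria(m, ref_u)
  for (i in seq_len(nrow(eq))) {
    f <- reduced_rhs(eq$LacI[i], eq$TetR[i], ref_u, m)
    expect_lt(abs(f$dLacI), 1e-6)
    expect_lt(abs(f$dTetR), 1e-6)
  }
  f0 <- reduced_rhs(0, 0, ref_u, m)   # leakage production only
  expect_gt(f0$dLacI, 0)
  expect_gt(f0$dTetR, 0)
})

test_that("nullcline vertices are genuine zeros and cross at equilibria", {
  m <- ref_model()
  nc <- nullclines(m, ref_u, n = 120)
  for (i in seq_len(nrow(nc$lacI))) {
    expect_lt(abs(reduced_rhs(nc$lacI$LacI[i], nc$lacI$TetR[i], ref_u,
                              m)$dLacI), 1e-6)
  }
  for (i in seq_len(nrow(nc$tetR))) {
    expect_lt(abs(reduced_rhs(nc$tetR$LacI[i], nc$tetR$TetR[i], ref_u,
                              m)$dTetR), 1e-6)
  }
  # every equilibrium lies on both curves (within the grid resolution)
  eq <- find_equilibria(m, ref_u)
  stepT <- diff(nc$lacI$TetR)[1]
  stepL <- diff(nc$tetR$LacI)[1]
  for (i in seq_len(nrow(eq))) {
    dL <- min(sqrt((nc$lacI$LacI - eq$LacI[i])^2 +
                     (nc$lacI$TetR - eq$TetR[i])^2))
    dT <- min(sqrt((nc$tetR$LacI - eq$LacI[i])^2 +
                     (nc$tetR$TetR - eq$TetR[i])^2))
    expect_lt(dL, 30 * stepT)
    expect_lt(dT, 30 * stepL)
  }
  expect_error(nullclines(m, ref_u, n = 1), "grid")
})

test_that("under saturating aTc the LacI nullcline is flat at full induction", {
  m <- ref_model()
  p <- m$params
  nc <- nullclines(m, c(u_aTc = 1e7, u_IPTG = 0.25), n = 40)
  level <- p$k_p_L * (p$k_m0_L + p$k_m_L) / (p$g_m_L * p$g_p_L)
  expect_lt(max(abs(nc$lacI$LacI - level)) / level, 1e-4)
})

test_that("reference conditions give two stable points and one saddle", {
  m <- ref_model()
  eq <- find_equilibria(m, ref_u)
  expect_identical(sum(eq$stability == "stable"), 2L)
  expect_identical(sum(eq$stability == "unstable"), 1L)
  # the two attractors dominate in opposite channels
  st <- eq[eq$stability == "stable", ]
  expect_true(any(st$LacI > st$TetR) && any(st$TetR > st$LacI))
  expect_error(find_equilibria(m, ref_u, n_starts = 10), ">= 25")
})

test_that("saturating IPTG leaves a single TetR-dominant attractor", {
  m <- ref_model()
  eq <- find_equilibria(m, c(u_aTc = 0, u_IPTG = 1))
  expect_identical(nrow(eq), 1L)
  expect_identical(eq$stability, "stable")
  expect_gt(eq$TetR, eq$LacI)
})

test_that("a symmetric circuit has swap-symmetric equilibria", {
  m <- symmetric_model()
  eq <- find_equilibria(m, c(u_aTc = 0, u_IPTG = 0))
  expect_identical(nrow(eq), 3L)
  pts <- eq[, c("LacI", "TetR")]
  for (i in seq_len(nrow(pts))) {
    swapped <- c(pts$TetR[i], pts$LacI[i])
    d <- min(sqrt((pts$LacI - swapped[1])^2 + (pts$TetR - swapped[2])^2))
    expect_lt(d / max(sqrt(sum(swapped^2)), 1), 1e-6)
  }
  sad <- eq[eq$stability == "unstable", ]
  expect_equal(sad$LacI, sad$TetR, tolerance = 1e-6)
})

test_that("Newton equilibria agree with a dense brute-force field scan", {
  m <- ref_model()
  eq <- find_equilibria(m, ref_u)
  bf <- brute_force_equilibria(m, ref_u, n = 400)
  expect_identical(nrow(bf), nrow(eq))
  # one-to-one match within a few grid steps
  for (i in seq_len(nrow(eq))) {
    d <- sqrt((bf$LacI - eq$LacI[i])^2 + (bf$TetR - eq$TetR[i])^2)
    expect_lt(min(d), 8 * bf$step[1])
  }
})

test_that("stable points attract and the saddle repels nearby states", {
  m <- ref_model()
  eq <- find_equilibria(m, ref_u)
  sched <- constant_schedule(20, 0.25)
  for (i in which(eq$stability == "stable")) {
    s0 <- cell_state(eq$mRNA_L[i], eq$mRNA_T[i], eq$LacI[i] * 1.05,
                     eq$TetR[i] * 0.95, eq$aTc_in[i], eq$IPTG_in[i])
    tr <- integrate_toggle(m, s0, sched, 3000, sample_dt = 300)
    fin <- tr$states[nrow(tr$states), ]
    expect_lt(abs(fin[["LacI"]] - eq$LacI[i]) / eq$LacI[i], 1e-3)
  }
  sad <- eq[eq$stability == "unstable", ]
  s0 <- cell_state(sad$mRNA_L, sad$mRNA_T, sad$LacI * 1.05, sad$TetR * 0.95,
                   sad$aTc_in, sad$IPTG_in)
  tr <- integrate_toggle(m, s0, sched, 3000, sample_dt = 300)
  fin <- tr$states[nrow(tr$states), ]
  expect_gt(abs(fin[["LacI"]] - sad$LacI) / sad$LacI, 0.5)
})

test_that("the separatrix separates the two basins of attraction", {
  m <- ref_model()
  sep <- separatrix(m, ref_u)
  eq <- find_equilibria(m, ref_u)
  sad <- attr(sep, "saddle")
  expect_true(any(sep$is_saddle))
  expect_equal(as.numeric(sep[sep$is_saddle, c("LacI", "TetR")]),
               as.numeric(sad), tolerance = 1e-8)
  idx <- round(seq(15, nrow(sep) - 15, length.out = 6))
  for (i in idx) {
    pt <- as.numeric(sep[i, c("LacI", "TetR")])
    labs <- vapply(c(-1, 1), function(sgn) {
      p2 <- pmax(pt * c(1 + 0.08 * sgn, 1 - 0.08 * sgn), 0.01)
      s0 <- cell_state(0, 0, p2[1], p2[2], 20, 0.25)
      tr <- integrate_toggle(m, s0, constant_schedule(20, 0.25), 5000,
                             sample_dt = 500)
      fin <- tr$states[nrow(tr$states), ]
      commitment_label(fin[["LacI"]], fin[["TetR"]], eq)$label
    }, character(1))
    expect_identical(sort(labs), c("GFP-dominant", "RFP-dominant"))
  }
})

test_that("a symmetric circuit's separatrix is the diagonal", {
  m <- symmetric_model()
  sep <- separatrix(m, c(u_aTc = 0, u_IPTG = 0))
  expect_lt(max(abs(sep$LacI - sep$TetR) / pmax(sep$LacI + sep$TetR, 1)),
            1e-3)
})

test_that("separatrix demands a bistable system", {
  m <- ref_model()
  expect_error(separatrix(m, c(u_aTc = 0, u_IPTG = 1)), "1 stable")
})

test_that("inducer memory produces hysteresis across an aTc sweep", {
  m <- ref_model()
  atcs <- c(10, 22, 35)
  state <- steady_state(m, c(u_aTc = 0, u_IPTG = 0.25),
                        from = c(LacI = 10, TetR = 1000))
  up <- vapply(atcs, function(a) {
    state <<- steady_state(m, c(u_aTc = a, u_IPTG = 0.25),
                           from = c(LacI = state[["LacI"]],
                                    TetR = state[["TetR"]]))
    state[["LacI"]]
  }, numeric(1))
  down <- vapply(rev(atcs), function(a) {
    state <<- steady_state(m, c(u_aTc = a, u_IPTG = 0.25),
                           from = c(LacI = state[["LacI"]],
                                    TetR = state[["TetR"]]))
    state[["LacI"]]
  }, numeric(1))
  down <- rev(down)
  # committed states at the intermediate aTc differ between sweep directions
  expect_lt(up[2], 200)
  expect_gt(down[2], 1000)
  # extremes agree: outside the bistable region the branches coincide
  expect_equal(up[3], down[3], tolerance = 1e-3)
})

test_that("a constant schedule's time-averaged field is the reduced field", {
  m <- ref_model()
  sched <- inducer_schedule(c(0, 10), u_aTc = c(20, 20),
                            u_IPTG = c(0.25, 0.25), period = 20)
  fld <- time_averaged_field(m, sched, n = 40)
  for (i in c(5, 20, 35)) for (j in c(5, 20, 35)) {
    f <- reduced_rhs(fld$grid_L[i], fld$grid_T[j], ref_u, m)
    expect_equal(fld$dLacI[i, j], f$dLacI, tolerance = 1e-6)
    expect_equal(fld$dTetR[i, j], f$dTetR, tolerance = 1e-6)
  }
  expect_error(time_averaged_field(m, constant_schedule(1, 1)),
               "not periodic")
})

test_that("the 120/30 averaged field has a single null point, and the
           null point moves to the TetR corner as IPTG share grows", {
  m <- ref_model()
  fld <- time_averaged_field(m, forcing_schedule(120, 30), n = 200)
  expect_identical(nrow(fld$null_points), 1L)
  ratios <- c(2, 4, 6, 8)
  tet <- vapply(ratios, function(r) {
    f <- time_averaged_field(m, forcing_schedule(30 * r, 30), n = 100)
    np <- f$null_points
    np$TetR[which.max(np$TetR)]
  }, numeric(1))
  expect_true(all(diff(tet) > 0))
})
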