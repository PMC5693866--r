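# shared fixtures and independent oracles, all built in code

ref_model <- function() toggle_model()

ref_u <- c(u_aTc = 20, u_IPTG = 0.25)

# edit kinetic fields without revalidation (used to build degenerate
# fixtures such as zero-transcription or single-reaction models)
edit_params <- function(p, ...) {
  ch <- list(...)
  for (nm in names(ch)) p[[nm]] <- ch[[nm]]
  p
}

# fully symmetric circuit: both branches carry the LacI-branch kinetics
symmetric_model <- function() {
  d <- default_toggle_params()
  toggle_model(
    toggle_params(k_m0_L = d$k_m0_L, k_m0_T = d$k_m0_L,
                  k_m_L = d$k_m_L, k_m_T = d$k_m_L,
                  k_p_L = d$k_p_L, k_p_T = d$k_p_L,
                  g_m_L = d$g_m_L, g_m_T = d$g_m_L,
                  g_p_L = d$g_p_L, g_p_T = d$g_p_L,
                  theta_LacI = d$theta_LacI, theta_TetR = d$theta_LacI,
                  theta_aTc = 10, theta_IPTG = 10,
                  eta_LacI = 2, eta_TetR = 2, eta_aTc = 2, eta_IPTG = 2),
    default_exchange_params())
}

# log-space relative distance of a protein point to the nearest stable
# equilibrium of a report
dist_to_stable <- function(LacI, TetR, eq) {
  st <- eq[eq$stability == "stable", ]
  z <- log(pmax(c(LacI, TetR), 1e-6))
  min(apply(st[, c("LacI", "TetR")], 1, function(q) {
    zq <- log(pmax(as.numeric(q), 1e-6))
    sqrt(sum((z - zq)^2)) / sqrt(sum(zq^2))
  }))
}

# brute-force equilibrium scan of the reduced field on a dense grid:
# cells of the grid where both field components change sign, clustered by
# adjacency; independent of the Newton-based find_equilibria path
brute_force_equilibria <- function(model, u, n = 400, upper = NULL) {
  p <- model$params
  sc <- c(LacI = p$k_p_L * (p$k_m0_L + p$k_m_L) / (p$g_m_L * p$g_p_L),
          TetR = p$k_p_T * (p$k_m0_T + p$k_m_T) / (p$g_m_T * p$g_p_T))
  if (is.null(upper)) upper <- 1.2 * sc
  gL <- seq(0, upper[["LacI"]], length.out = n)
  gT <- seq(0, upper[["TetR"]], length.out = n)
  fL <- transcription_rate_L(gT, u[["u_aTc"]], p)       # by TetR index
  fT <- transcription_rate_T(gL, u[["u_IPTG"]], p)      # by LacI index
  dL <- outer(gL, p$k_p_L * fL / p$g_m_L, function(L, v) v) - p$g_p_L * gL
  dT <- outer(p$k_p_T * fT / p$g_m_T, gT, function(v, Tv) v) -
    matrix(gT, n, n, byrow = TRUE) * p$g_p_T
  sgnL <- sign(dL); sgnT <- sign(dT)
  mix <- function(s) {
    a <- s[-n, -n]; b <- s[-1, -n]; c2 <- s[-n, -1]; d <- s[-1, -1]
    (pmin(a, b, c2, d) < 0) & (pmax(a, b, c2, d) > 0)
  }
  cand <- which(mix(sgnL) & mix(sgnT), arr.ind = TRUE)
  if (!nrow(cand)) return(data.frame(LacI = numeric(0), TetR = numeric(0)))
  # cluster adjacent candidate cells (chebyshev distance <= 2)
  lab <- seq_len(nrow(cand))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(cand))) for (j in seq_len(nrow(cand))) {
      if (lab[i] != lab[j] &&
          max(abs(cand[i, ] - cand[j, ])) <= 2) {
        lab[lab == lab[j]] <- lab[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  centers <- t(vapply(unique(lab), function(l) {
    rows <- cand[lab == l, , drop = FALSE]
    c(mean(gL[rows[, 1]]), mean(gT[rows[, 2]]))
  }, numeric(2)))
  data.frame(LacI = centers[, 1], TetR = centers[, 2],
             step = c(diff(gL)[1], diff(gT)[1])[1])
}

# direct-method Gillespie reference for the next-event distribution from a
# fixed state: channel ~ categorical(a / sum a). Drawing the first event
# repeatedly from the same state gives iid samples, so a two-sample
# chi-square comparison against the first-reaction rule is valid.
direct_first_event_counts <- function(model, state, n_draws, seed) {
  set.seed(seed)
  a <- propensities(state, model$params)
  tabulate(sample.int(8, n_draws, replace = TRUE, prob = a / sum(a)), 8)
}

first_reaction_first_event_counts <- function(model, state, n_draws, seed) {
  set.seed(seed)
  idx <- vapply(seq_len(n_draws),
                function(i) first_reaction_step(state, model$params)$reaction,
                integer(1))
  tabulate(idx, 8)
}
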