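#' Names of the six dynamic state variables
#'
#' Order used throughout: the two mRNAs, the two repressor proteins (proxied
#' one-to-one by their fluorescent reporters, in a.u.), and the two internal
#' inducer concentrations (aTc in ng/mL, IPTG in mM).
#' @export
state_names <- function() {
  c("mRNA_L", "mRNA_T", "LacI", "TetR", "aTc_in", "IPTG_in")
}

#' Build a state vector
#'
#' @param mRNA_L,mRNA_T mRNA levels (a.u.).
#' @param LacI,TetR protein levels (a.u.).
#' @param aTc_in internal aTc (ng/mL).
#' @param IPTG_in internal IPTG (mM).
#' @return Named numeric vector of length 6.
#' @export
cell_state <- function(mRNA_L = 0, mRNA_T = 0, LacI = 0, TetR = 0,
                       aTc_in = 0, IPTG_in = 0) {
  x <- stats::setNames(as.numeric(c(mRNA_L, mRNA_T, LacI, TetR,
                                    aTc_in, IPTG_in)), state_names())
  if (any(!is.finite(x)) || any(x < 0))
    stop("cell_state: all state variables must be finite and nonnegative")
  x
}

#' Decreasing Hill function
#'
#' `h(x, theta, eta) = 1 / (1 + (x/theta)^eta)`: 1 at `x = 0`, 1/2 at
#' `x = theta`, monotone non-increasing in `x`. Vectorized over `x`.
#'
#' @param x nonnegative argument.
#' @param theta positive half-effect threshold.
#' @param eta Hill exponent (>= 1).
#' @export
hill_neg <- function(x, theta, eta) {
  if (any(x < 0)) stop("hill_neg: x must be nonnegative")
  if (theta <= 0) stop("hill_neg: theta must be positive")
  1 / (1 + (x / theta)^eta)
}

#' Gene regulation functions
#'
#' Transcription rate of each branch as a decreasing Hill function of the
#' *free* repressor, itself the total repressor scaled by a decreasing Hill
#' function of its allosteric inducer: aTc sequesters TetR (freeing the lacI
#' promoter), IPTG sequesters LacI (freeing the tetR promoter).
#'
#' @param TetR,LacI total repressor levels (a.u.).
#' @param aTc_in,IPTG_in internal inducer concentrations (ng/mL, mM).
#' @param p a [toggle_params] object.
#' @return Transcription rate (a.u./min).
#' @export
transcription_rate_L <- function(TetR, aTc_in, p) {
  free <- TetR * hill_neg(aTc_in, p$theta_aTc, p$eta_aTc)
  p$k_m0_L + p$k_m_L * hill_neg(free, p$theta_TetR, p$eta_TetR)
}

#' @rdname transcription_rate_L
#' @export
transcription_rate_T <- function(LacI, IPTG_in, p) {
  free <- LacI * hill_neg(IPTG_in, p$theta_IPTG, p$eta_IPTG)
  p$k_m0_T + p$k_m_T * hill_neg(free, p$theta_LacI, p$eta_LacI)
}

# derivative of each internal inducer: branch chosen by sign of (u - x);
# the boundary u == x uses the export branch (rate is zero either way).
exchange_deriv <- function(x_in, u, k_in, k_out) {
  ifelse(u > x_in, k_in, k_out) * (u - x_in)
}

#' Right-hand side of the full six-state model
#'
#' The four gene-expression ODEs (transcription with Hill regulation,
#' first-order translation and degradation/dilution) evaluated with the
#' *internal* inducer levels, plus the inducer membrane-exchange dynamics of
#' the declared variant. In the symmetric variant internal aTc is slaved
#' algebraically to the input (its derivative relaxes it immediately onto
#' `u_aTc`; integrators treat it as instantaneous by construction of
#' [integrate_toggle()]).
#'
#' @param state named 6-vector as from [cell_state()].
#' @param u list or vector with `u_aTc`, `u_IPTG`.
#' @param p a [toggle_params] object.
#' @param ex an [exchange_params] object.
#' @return Named numeric vector of the six time derivatives (per min).
#' @export
ode_rhs <- function(state, u, p, ex) {
  u_aTc <- u[["u_aTc"]]; u_IPTG <- u[["u_IPTG"]]
  dm_L <- transcription_rate_L(state[["TetR"]], state[["aTc_in"]], p) -
    p$g_m_L * state[["mRNA_L"]]
  dm_T <- transcription_rate_T(state[["LacI"]], state[["IPTG_in"]], p) -
    p$g_m_T * state[["mRNA_T"]]
  dP_L <- p$k_p_L * state[["mRNA_L"]] - p$g_p_L * state[["LacI"]]
  dP_T <- p$k_p_T * state[["mRNA_T"]] - p$g_p_T * state[["TetR"]]
  if (ex$variant == "symmetric") {
    # aTc_in == u_aTc algebraically; report zero drift at the slaved value
    da <- 0
    di <- ex$k_IPTG * (u_IPTG - state[["IPTG_in"]])
  } else if (ex$variant == "asymmetric") {
    da <- exchange_deriv(state[["aTc_in"]], u_aTc, ex$k_aTc_in, ex$k_aTc_out)
    di <- exchange_deriv(state[["IPTG_in"]], u_IPTG, ex$k_IPTG_in,
                         ex$k_IPTG_out)
  } else {
    stop("ode_rhs: unknown exchange variant '", ex$variant, "'")
  }
  c(mRNA_L = dm_L, mRNA_T = dm_T, LacI = unname(dP_L), TetR = unname(dP_T),
    aTc_in = da, IPTG_in = unname(di))
}

#' Reaction channels of the stochastic interpretation
#'
#' The continuous-time Markov chain has eight pseudo-reactions on the four
#' gene-expression species (inducers evolve deterministically): transcription
#' of each mRNA, translation of each protein, and first-order degradation of
#' all four. Propensities equal the deterministic rate laws.
#'
#' @param state named 6-vector (the four reaction species are read from it).
#' @param p a [toggle_params] object.
#' @return Numeric vector of 8 propensities (per min), named by reaction.
#' @export
propensities <- function(state, p) {
  if (any(state < 0)) stop("propensities: negative state")
  c(tx_mRNA_L = transcription_rate_L(state[["TetR"]], state[["aTc_in"]], p),
    tx_mRNA_T = transcription_rate_T(state[["LacI"]], state[["IPTG_in"]], p),
    tl_LacI = p$k_p_L * state[["mRNA_L"]],
    tl_TetR = p$k_p_T * state[["mRNA_T"]],
    deg_mRNA_L = p$g_m_L * state[["mRNA_L"]],
    deg_mRNA_T = p$g_m_T * state[["mRNA_T"]],
    deg_LacI = p$g_p_L * state[["LacI"]],
    deg_TetR = p$g_p_T * state[["TetR"]])
}

#' @rdname propensities
#' @return `stoichiometry()`: an 8 x 4 integer matrix of state changes on
#'   (mRNA_L, mRNA_T, LacI, TetR), one row per reaction.
#' @export
stoichiometry <- function() {
  m <- rbind(tx_mRNA_L  = c(1, 0, 0, 0),
             tx_mRNA_T  = c(0, 1, 0, 0),
             tl_LacI    = c(0, 0, 1, 0),
             tl_TetR    = c(0, 0, 0, 1),
             deg_mRNA_L = c(-1, 0, 0, 0),
             deg_mRNA_T = c(0, -1, 0, 0),
             deg_LacI   = c(0, 0, -1, 0),
             deg_TetR   = c(0, 0, 0, -1))
  colnames(m) <- state_names()[1:4]
  m
}
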