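#' Kinetic parameters of the toggle switch circuit
#'
#' Bundles all kinetic and Hill parameters of the two-gene mutual-repression
#' circuit: leakage and maximal transcription rates, translation rates,
#' mRNA/protein degradation-dilution rates, repressor and inducer Hill
#' thresholds, and Hill exponents. All rates are per minute; protein and
#' repressor thresholds are in arbitrary fluorescence units (a.u.), the aTc
#' threshold in ng/mL and the IPTG threshold in mM.
#'
#' @param k_m0_L,k_m0_T leakage transcription rates (a.u./min).
#' @param k_m_L,k_m_T maximal regulated transcription rates (a.u./min).
#' @param k_p_L,k_p_T translation rates (1/min).
#' @param g_m_L,g_m_T mRNA degradation/dilution rates (1/min).
#' @param g_p_L,g_p_T protein degradation/dilution rates (1/min).
#' @param theta_LacI,theta_TetR repressor half-repression thresholds (a.u.).
#' @param theta_aTc aTc sequestration threshold (ng/mL).
#' @param theta_IPTG IPTG sequestration threshold (mM).
#' @param eta_LacI,eta_TetR,eta_aTc,eta_IPTG Hill exponents (>= 1).
#' @return An object of class `toggle_params` (a validated named list).
#' @seealso [default_toggle_params()] for the fitted reference values.
#' @export
toggle_params <- function(k_m0_L, k_m0_T, k_m_L, k_m_T,
                          k_p_L, k_p_T, g_m_L, g_m_T, g_p_L, g_p_T,
                          theta_LacI, theta_TetR, theta_aTc, theta_IPTG,
                          eta_LacI = 2, eta_TetR = 2, eta_aTc = 2,
                          eta_IPTG = 2) {
  p <- list(k_m0_L = k_m0_L, k_m0_T = k_m0_T, k_m_L = k_m_L, k_m_T = k_m_T,
            k_p_L = k_p_L, k_p_T = k_p_T, g_m_L = g_m_L, g_m_T = g_m_T,
            g_p_L = g_p_L, g_p_T = g_p_T,
            theta_LacI = theta_LacI, theta_TetR = theta_TetR,
            theta_aTc = theta_aTc, theta_IPTG = theta_IPTG,
            eta_LacI = eta_LacI, eta_TetR = eta_TetR,
            eta_aTc = eta_aTc, eta_IPTG = eta_IPTG)
  p <- lapply(p, as.numeric)
  validate_toggle_params(p)
  structure(p, class = "toggle_params")
}

#' @rdname toggle_params
#' @export
toggle_params_fields <- function() {
  c("k_m0_L", "k_m0_T", "k_m_L", "k_m_T", "k_p_L", "k_p_T",
    "g_m_L", "g_m_T", "g_p_L", "g_p_T",
    "theta_LacI", "theta_TetR", "theta_aTc", "theta_IPTG",
    "eta_LacI", "eta_TetR", "eta_aTc", "eta_IPTG")
}

validate_toggle_params <- function(p) {
  fields <- toggle_params_fields()
  missing <- setdiff(fields, names(p))
  if (length(missing))
    stop("toggle_params: missing fields: ", paste(missing, collapse = ", "))
  rates <- fields[!startsWith(fields, "eta_")]
  for (f in rates) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("toggle_params: '", f, "' must be a strictly positive scalar")
  }
  etas <- fields[startsWith(fields, "eta_")]
  for (f in etas) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1)
      stop("toggle_params: Hill exponent '", f, "' must be >= 1")
  }
  invisible(p)
}

#' Reference fitted parameter set of the toggle switch
#'
#' The kinetic parameter values of the fitted deterministic model of the
#' LacI/TetR toggle switch. Under the reference inducer conditions
#' (aTc 20 ng/mL, IPTG 0.25 mM) this set yields two stable equilibria and one
#' saddle, i.e. a bistable switch.
#'
#' @return A `toggle_params` object.
#' @export
default_toggle_params <- function() {
  toggle_params(
    k_m0_L = 3.20e-2, k_m0_T = 1.19e-1,
    k_m_L = 8.30,     k_m_T = 2.06,
    k_p_L = 9.726e-1, k_p_T = 1.170,
    g_m_L = 1.386e-1, g_m_T = 1.386e-1,
    g_p_L = 1.65e-2,  g_p_T = 1.65e-2,
    theta_LacI = 31.94, theta_TetR = 30.0,
    theta_aTc = 11.65,  theta_IPTG = 9.06e-2,
    eta_LacI = 2, eta_TetR = 2, eta_aTc = 2, eta_IPTG = 2)
}

#' Inducer membrane-exchange parameters
#'
#' Rates of inducer transport across the cell membrane. Two variants exist:
#' `"symmetric"` treats internal aTc as algebraically equal to the external
#' concentration and IPTG as relaxing with a single rate `k_IPTG`;
#' `"asymmetric"` (the reference model) uses separate import/export rates for
#' each inducer, chosen by the sign of the concentration difference between
#' outside and inside.
#'
#' @param variant `"symmetric"` or `"asymmetric"`.
#' @param k_IPTG symmetric IPTG exchange rate (1/min); symmetric variant only.
#' @param k_aTc_in,k_aTc_out,k_IPTG_in,k_IPTG_out directional exchange rates
#'   (1/min); asymmetric variant only.
#' @return An object of class `exchange_params`.
#' @export
exchange_params <- function(variant = c("asymmetric", "symmetric"),
                            k_IPTG = NULL,
                            k_aTc_in = NULL, k_aTc_out = NULL,
                            k_IPTG_in = NULL, k_IPTG_out = NULL) {
  variant <- match.arg(variant)
  chk <- function(v, nm) {
    if (is.null(v))
      stop("exchange_params: variant '", variant, "' requires '", nm, "'")
    v <- as.numeric(v)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      stop("exchange_params: '", nm, "' must be a nonnegative scalar")
    v
  }
  if (variant == "symmetric") {
    if (!is.null(k_aTc_in) || !is.null(k_aTc_out) ||
        !is.null(k_IPTG_in) || !is.null(k_IPTG_out))
      stop("exchange_params: symmetric variant takes only 'k_IPTG'")
    ex <- list(variant = variant, k_IPTG = chk(k_IPTG, "k_IPTG"))
  } else {
    if (!is.null(k_IPTG))
      stop("exchange_params: asymmetric variant does not take 'k_IPTG'")
    ex <- list(variant = variant,
               k_aTc_in = chk(k_aTc_in, "k_aTc_in"),
               k_aTc_out = chk(k_aTc_out, "k_aTc_out"),
               k_IPTG_in = chk(k_IPTG_in, "k_IPTG_in"),
               k_IPTG_out = chk(k_IPTG_out, "k_IPTG_out"))
  }
  structure(ex, class = "exchange_params")
}

#' @rdname exchange_params
#' @param variant `"symmetric"` or `"asymmetric"`.
#' @export
default_exchange_params <- function(variant = c("asymmetric", "symmetric")) {
  variant <- match.arg(variant)
  if (variant == "asymmetric") {
    exchange_params("asymmetric",
                    k_aTc_in = 1.62e-1, k_aTc_out = 2.00e-2,
                    k_IPTG_in = 2.75e-2, k_IPTG_out = 1.11e-1)
  } else {
    exchange_params("symmetric", k_IPTG = 4.0e-2)
  }
}

#' Read / write model parameters as a flat YAML key-value file
#'
#' The file holds the `toggle_params` fields, plus an `exchange` block naming
#' the variant and its rates. Loading validates all invariants (positivity,
#' Hill exponents >= 1, variant-consistent exchange fields).
#'
#' @param path file path.
#' @return `read_toggle_config()` returns `list(params, exchange)`;
#'   `write_toggle_config()` returns `path` invisibly.
#' @export
read_toggle_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pf <- toggle_params_fields()
  pv <- raw[intersect(names(raw), pf)]
  params <- do.call(toggle_params, pv)
  ex <- raw[["exchange"]]
  if (is.null(ex)) stop("config '", path, "' lacks an 'exchange' block")
  exchange <- do.call(exchange_params, ex)
  list(params = params, exchange = exchange)
}

#' @rdname read_toggle_config
#' @param params a `toggle_params` object.
#' @param exchange an `exchange_params` object.
#' @export
write_toggle_config <- function(params, exchange, path) {
  stopifnot(inherits(params, "toggle_params"),
            inherits(exchange, "exchange_params"))
  out <- c(unclass(params), list(exchange = unclass(exchange)))
  yaml::write_yaml(out, path)
  invisible(path)
}
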