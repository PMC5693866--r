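#' Toggle switch model object
#'
#' Bundles the kinetic parameters and the inducer-exchange variant into one
#' model object used by the deterministic and stochastic simulators, the
#' phase-portrait tools, the controllers and the calibration machinery.
#'
#' @param params a [toggle_params] object; defaults to the fitted reference
#'   set.
#' @param exchange an [exchange_params] object; defaults to the asymmetric
#'   (reference) exchange model.
#' @return An object of class `toggle_model`.
#' @examples
#' m <- toggle_model()
#' m
#' @export
toggle_model <- function(params = default_toggle_params(),
                         exchange = default_exchange_params()) {
  stopifnot(inherits(params, "toggle_params"),
            inherits(exchange, "exchange_params"))
  structure(list(params = params, exchange = exchange),
            class = "toggle_model")
}

#' @export
print.toggle_model <- function(x, ...) {
  cat("LacI/TetR toggle switch model (", x$exchange$variant,
      " inducer exchange)\n", sep = "")
  p <- x$params
  cat(sprintf("  transcription: k_m0 = (%.3g, %.3g), k_m = (%.3g, %.3g) a.u./min\n",
              p$k_m0_L, p$k_m0_T, p$k_m_L, p$k_m_T))
  cat(sprintf("  translation:   k_p = (%.3g, %.3g) /min\n", p$k_p_L, p$k_p_T))
  cat(sprintf("  degradation:   g_m = (%.3g, %.3g), g_p = (%.3g, %.3g) /min\n",
              p$g_m_L, p$g_m_T, p$g_p_L, p$g_p_T))
  cat(sprintf("  Hill:          theta = (LacI %.4g, TetR %.4g, aTc %.4g, IPTG %.4g)\n",
              p$theta_LacI, p$theta_TetR, p$theta_aTc, p$theta_IPTG))
  cat(sprintf("                 eta   = (%.3g, %.3g, %.3g, %.3g)\n",
              p$eta_LacI, p$eta_TetR, p$eta_aTc, p$eta_IPTG))
  invisible(x)
}

# replace the jittered kinetic fields of a model (used by population sampler)
modify_params <- function(model, new_values) {
  p <- unclass(model$params)
  p[names(new_values)] <- new_values
  model$params <- do.call(toggle_params, p)
  model
}
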