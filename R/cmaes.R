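#' Covariance matrix adaptation evolution strategy (minimizer)
#'
#' A standard (mu/mu_w, lambda)-CMA-ES with weighted recombination,
#' cumulative step-size adaptation and rank-one plus rank-mu covariance
#' update, following Hansen's recommended parameter settings. Box constraints
#' are handled by evaluating the objective at the feasible projection of each
#' candidate plus a quadratic distance penalty. The run is deterministic
#' given the seed.
#'
#' @param fn objective function of a numeric vector; finite values required
#'   (return a large finite penalty for failed evaluations).
#' @param x0 initial mean.
#' @param sigma0 initial global step size.
#' @param lower,upper optional box bounds (recycled to `length(x0)`).
#' @param lambda population size; default `4 + floor(3 log n)`.
#' @param max_evals evaluation budget.
#' @param stop_fitness stop when the best value falls at or below this.
#' @param tol_sigma stop when `sigma` shrinks below `sigma0 * tol_sigma`.
#' @param seed RNG seed.
#' @return List with `par` (best-ever point, projected into bounds), `value`,
#'   `counts` (evaluations), `log` (one row per generation: best, sigma) and
#'   `convergence` message.
#' @export
cma_es <- function(fn, x0, sigma0, lower = NULL, upper = NULL,
                   lambda = NULL, max_evals = 1e4, stop_fitness = -Inf,
                   tol_sigma = 1e-12, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(x0)
  if (is.null(lower)) lower <- rep(-Inf, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  lambda <- max(4L, as.integer(lambda))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cs <- (mueff + 2) / (n + mueff + 5)
  ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  C <- diag(n); ps <- numeric(n); pc <- numeric(n)
  eig <- eigen(C, symmetric = TRUE)
  B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-30))

  pen_eval <- function(x) {
    if (any(!is.finite(x))) return(1e15)
    xf <- pmin(pmax(x, lower), upper)
    v <- fn(xf)
    if (length(v) != 1L || !is.finite(v)) v <- 1e12
    pen <- 1e6 * sum((x - xf)^2)
    if (!is.finite(pen)) pen <- 1e15
    v + pen
  }

  best_par <- m; best_val <- pen_eval(m)
  evals <- 1L
  gen <- 0L
  log_best <- numeric(0); log_sigma <- numeric(0)
  msg <- "max_evals reached"

  while (evals + lambda <= max_evals) {
    gen <- gen + 1L
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                 # N(0, C) samples
    X <- m + sigma * Y
    f <- apply(X, 2, pen_eval)
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_val) {
      best_val <- f[ord[1]]
      best_par <- X[, ord[1]]
    }
    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    yw <- drop(ysel %*% w)
    m <- m + sigma * yw

    # cumulative paths
    Cinvsqrt_yw <- B %*% ((1 / D) * crossprod(B, yw))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(Cinvsqrt_yw)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw

    # covariance update (rank-one + rank-mu)
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * ysel %*% (w * t(ysel))
    sigma <- sigma * exp(min(1, (cs / ds) * (sqrt(sum(ps^2)) / chiN - 1)))
    if (!is.finite(sigma) || any(!is.finite(m))) {
      msg <- "search state degenerated"
      break
    }

    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-30))

    log_best <- c(log_best, f[ord[1]])
    log_sigma <- c(log_sigma, sigma)
    if (best_val <= stop_fitness) { msg <- "stop_fitness reached"; break }
    if (sigma < sigma0 * tol_sigma) { msg <- "sigma collapsed"; break }
    if (!all(is.finite(C))) { msg <- "covariance degenerated"; break }
  }
  list(par = pmin(pmax(best_par, lower), upper), value = best_val,
       counts = evals,
       log = data.frame(generation = seq_along(log_best),
                        best = log_best, sigma = log_sigma),
       convergence = msg)
}
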