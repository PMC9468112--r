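#' Minimize an objective with CMA-ES
#'
#' Covariance matrix adaptation evolution strategy (the standard
#' (mu/mu_w, lambda) scheme with rank-one and rank-mu covariance updates,
#' step-size control by cumulative path length, and the default rank-based
#' population rule lambda = 4 + floor(3 log n)). The search runs in
#' coordinates normalized by `sigma0`, so one initial step corresponds to
#' one `sigma0` unit per coordinate. Box bounds are enforced by clamping
#' the evaluated point and adding a quadratic out-of-bounds penalty.
#'
#' The run is fully reproducible given `seed`. The first evaluation is
#' always `x0`, so the returned best is never worse than the start.
#'
#' @param objective function of a numeric vector returning a finite scalar.
#' @param x0 numeric start vector.
#' @param sigma0 initial step size per coordinate (scalar or vector).
#' @param lower,upper optional box bounds (must contain `x0`).
#' @param seed integer seed.
#' @param budget maximum number of objective evaluations.
#' @param stagnationTol relative best-value stagnation tolerance; the run
#'   stops (and is flagged converged) when the best value improves by less
#'   than this fraction of the total improvement so far over
#'   `stagnationGens` consecutive generations.
#' @param stagnationGens window length in generations (default 15).
#' @return list with `par`, `value`, `evals`, `trace` (best-so-far value
#'   after each evaluation), `converged`, `reason`. A run is flagged
#'   converged when it stops on stagnation, or when the sampling
#'   distribution has contracted to under a tenth of its initial scale
#'   by the time the budget ends (TolX-style criterion).
#' @examples
#' f <- function(x) sum((x - 3)^2)
#' cmaesMinimize(f, rep(0, 4), 1, seed = 1, budget = 1500)$par
#' @export
cmaesMinimize <- function(objective, x0, sigma0 = 1, lower = NULL,
                          upper = NULL, seed = 1L, budget = 1500L,
                          stagnationTol = 1e-3, stagnationGens = 15L) {
  n <- length(x0)
  stopifnot(budget >= 1L, n >= 1L)
  sigma0 <- rep_len(sigma0, n)
  if (any(sigma0 <= 0)) stop("sigma0 must be > 0")
  if (is.null(lower)) lower <- rep(-Inf, n)
  if (is.null(upper)) upper <- rep(Inf, n)
  if (any(x0 < lower) || any(x0 > upper)) stop("bounds must contain x0")

  ## objective in normalized coordinates, with bound handling
  loN <- (lower - x0) / sigma0
  hiN <- (upper - x0) / sigma0
  evals <- 0L
  trace <- numeric(0)
  bestF <- Inf
  bestX <- (x0 - x0) / sigma0
  fwrap <- function(z) {
    zc <- clampVec(z, loN, hiN)
    f <- objective(x0 + sigma0 * zc)
    if (!is.finite(f)) stop("objective returned a non-finite value")
    f <- f + 1e4 * sum((z - zc)^2)
    evals <<- evals + 1L
    if (f < bestF) {
      bestF <<- f
      bestX <<- zc
    }
    trace[evals] <<- bestF
    f
  }

  set.seed(deriveSeed(seed, 97L))
  f0 <- fwrap(rep(0, n))
  if (budget == 1L)
    return(list(par = x0 + sigma0 * bestX, value = bestF, evals = evals,
                trace = trace, converged = FALSE, reason = "budget"))

  lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- rep(0, n)
  sigma <- 1
  C <- diag(n)
  pc <- ps <- rep(0, n)
  eig <- list(vectors = diag(n), values = rep(1, n))
  genBest <- f0
  histBest <- f0
  converged <- FALSE
  reason <- "budget"

  while (evals + lambda <= budget) {
    B <- eig$vectors
    D <- sqrt(pmax(eig$values, 1e-20))
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)
    X <- m + sigma * Y
    fx <- apply(X, 2, fwrap)
    ord <- order(fx)
    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    yw <- as.numeric(ysel %*% w)
    m <- m + sigma * yw

    ## evolution paths
    Cinvsqrt_yw <- B %*% ((t(B) %*% yw) / D)
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * Cinvsqrt_yw
    hsig <- vnorm(ps) / sqrt(1 - (1 - cs)^(2 * (evals / lambda))) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * ysel %*% (w * t(ysel))
    sigma <- sigma * exp((cs / damps) * (vnorm(ps) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    eig <- list(vectors = eig$vectors, values = eig$values)

    ## stagnation check on the best-so-far value
    histBest <- c(histBest, bestF)
    if (length(histBest) > stagnationGens + 1L) {
      improv <- histBest[length(histBest) - stagnationGens] - bestF
      total <- f0 - bestF
      if (improv <= stagnationTol * max(total, 0) + 1e-14) {
        converged <- TRUE
        reason <- "stagnation"
        break
      }
    }
    if (sigma * max(D) < 1e-12) {
      converged <- TRUE
      reason <- "sigma"
      break
    }
  }
  ## a sampling distribution contracted to a tenth of its initial scale
  ## has collapsed onto an optimum even if the budget ended first (the
  ## TolX-style criterion of reference CMA-ES implementations)
  if (!converged && sigma < 0.1) {
    converged <- TRUE
    reason <- "contraction"
  }
  list(par = x0 + sigma0 * bestX, value = bestF, evals = evals,
       trace = trace, converged = converged, reason = reason)
}
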