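# (mu/mu_w, lambda) CMA-ES minimizer with rank-1 + rank-mu covariance update
# and cumulative step-size adaptation, following Hansen's published default
# parameterization. Written for low-dimensional (<= 63) stochastic
# objectives: the objective is called as fn(x, generation) so the caller can
# tie common random numbers to the generation index. Non-finite candidate
# values are assigned the worst finite value of their generation.

#' Covariance Matrix Adaptation Evolution Strategy
#'
#' Minimizes `fn` over a continuous parameter vector.
#'
#' @param par0 numeric starting point.
#' @param fn objective, called as `fn(x, generation)`; minimized.
#' @param sigma0 initial step size (default 0.3).
#' @param lambda population size (default `4 + floor(3 log n)`).
#' @param max_generations generation budget.
#' @param ftol stop when the best value improves by less than this over
#'   `patience` consecutive generations (default disabled).
#' @param patience generations without improvement tolerated under `ftol`.
#' @param seed RNG seed for the search distribution.
#' @return list with `par` (best-ever point), `value`, `trace`
#'   (best-so-far value per generation), `generations`.
#' @export
cmaES <- function(par0, fn, sigma0 = 0.3, lambda = NULL,
                  max_generations = 100L, ftol = 0, patience = 10L,
                  seed = 1L) {
  n <- length(par0)
  stopifnot(n >= 1)
  if (is.null(lambda)) lambda <- 4L + floor(3 * log(n))
  lambda <- max(4L, as.integer(lambda))
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

  m <- as.numeric(par0)
  sigma <- sigma0
  C <- diag(n); ps <- numeric(n); pc <- numeric(n)
  eig <- eigen(C, symmetric = TRUE)
  B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-20))

  best <- list(par = m, value = Inf)
  trace <- numeric(0)
  stall <- 0L
  gen <- 0L

  while (gen < max_generations) {
    gen <- gen + 1L
    # re-seed per generation: the objective may use the RNG itself (e.g. for
    # simulations), which must not perturb the search distribution's stream
    set.seed(as.integer((seed + 7919 * gen) %% 2147483647))
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                  # N(0, C) samples
    X <- m + sigma * Y
    f <- vapply(seq_len(lambda), function(i) {
      v <- tryCatch(fn(X[, i], gen), error = function(e) NA_real_)
      if (is.null(v) || !length(v)) NA_real_ else as.numeric(v)
    }, 0)
    worst <- if (all(!is.finite(f))) 0 else max(f[is.finite(f)])
    f[!is.finite(f)] <- worst + abs(worst) + 1
    ord <- order(f)
    if (f[ord[1]] < best$value - ftol) stall <- 0L else stall <- stall + 1L
    if (f[ord[1]] < best$value)
      best <- list(par = X[, ord[1]], value = f[ord[1]])
    trace[gen] <- best$value

    sel <- ord[seq_len(mu)]
    yw <- Y[, sel, drop = FALSE] %*% w
    m <- m + sigma * as.numeric(yw)
    # step-size path (C^{-1/2} y = B Z for sampled points)
    zw <- Z[, sel, drop = FALSE] %*% w
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(B %*% zw)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * gen)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * as.numeric(yw)
    Ymu <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ymu %*% (w * t(Ymu))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
    B <- eig$vectors; D <- sqrt(pmax(eig$values, 1e-20))
    if (ftol > 0 && stall >= patience) break
  }
  list(par = best$par, value = best$value, trace = trace, generations = gen)
}
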