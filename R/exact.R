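#' Exact stationary solution of a small l-TASEP lattice
#'
#' Enumerates every admissible ribosome configuration (A-sites pairwise at
#' least `L` apart), builds the generator matrix of the continuous-time
#' Markov chain under the same event rules as the simulator, and solves the
#' stationary master equation by linear algebra. Only feasible for small
#' lattices (the state count grows exponentially); intended as an exact
#' reference for validating stochastic simulation output.
#'
#' @param site_rates numeric vector of per-site rates `k_1..k_S` (the last
#'   entry acting as termination rate).
#' @param k0 initiation rate.
#' @param L footprint size in codons.
#' @return list with `n` (exact per-position A-site occupancy), `J` (exact
#'   production rate), `pi` (stationary probabilities) and `states` (list of
#'   A-site position vectors).
#' @export
exactOccupancy <- function(site_rates, k0, L) {
  S <- length(site_rates)
  stopifnot(S >= 1, L >= 1, k0 >= 0, all(site_rates > 0))
  if (S > 14) stop("state enumeration is only supported for S <= 14")

  # enumerate admissible configurations recursively
  states <- list(integer())
  grow <- function(cfg, from) {
    for (i in from:S) {
      nxt <- c(cfg, i)
      states[[length(states) + 1L]] <<- nxt
      if (i + L <= S) grow(nxt, i + L)
    }
  }
  grow(integer(), 1L)
  # keys for O(1) lookup ("s" prefix so the empty lattice has a valid name)
  keyOf <- function(cfg) paste(c("s", cfg), collapse = ",")
  idx <- stats::setNames(seq_along(states), vapply(states, keyOf, ""))

  ns <- length(states)
  Q <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    cfg <- states[[s]]
    m <- length(cfg)
    # initiation
    if (k0 > 0 && (m == 0 || cfg[1] > L)) {
      t <- idx[[keyOf(c(1L, cfg))]]
      Q[s, t] <- Q[s, t] + k0
    }
    for (j in seq_len(m)) {
      i <- cfg[j]
      if (i == S) {                                  # termination
        t <- idx[[keyOf(cfg[-j])]]
        Q[s, t] <- Q[s, t] + site_rates[i]
      } else if (j == m || cfg[j + 1] - i > L) {     # elongation
        nxt <- cfg; nxt[j] <- i + 1L
        t <- idx[[keyOf(nxt)]]
        Q[s, t] <- Q[s, t] + site_rates[i]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, ns))
  b <- c(rep(0, ns), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat[pi_hat < 0] <- 0
  pi_hat <- pi_hat / sum(pi_hat)

  n <- numeric(S)
  J <- 0
  for (s in seq_len(ns)) {
    cfg <- states[[s]]
    n[cfg] <- n[cfg] + pi_hat[s]
    if (length(cfg) && cfg[length(cfg)] == S)
      J <- J + pi_hat[s] * site_rates[S]
  }
  list(n = n, J = J, pi = pi_hat, states = states)
}
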