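# Synthetic-data generators used as statistical oracles for the analysis
# stages: a four-state junction Markov chain with known stationary
# populations and reversible rates, a biased two-state sampler matching the
# structure of a constant-force ensemble, and saturating-exponential
# fluorescence unwinding traces.

#' Four-state junction Markov model
#'
#' States CLOSED, FLIP5, FLIP3, OPEN on the stepwise-opening topology:
#' only CLOSED<->FLIP5, CLOSED<->FLIP3, FLIP5<->OPEN, FLIP3<->OPEN carry
#' rates (direct CLOSED<->OPEN jumps are excluded by construction, matching
#' the stepwise base-pair-opening mechanism; a flag re-enables them to test
#' handling of direct/ambiguous pathways).  Rates are constructed from a
#' stationary distribution by detailed balance, `k_ij = nu * min(1,
#' pi_j/pi_i)` on allowed edges, so the chain is reversible; on this 4-cycle
#' reversibility is equivalent to the Kolmogorov cycle criterion.
#'
#' @param pi Stationary distribution, named (CLOSED, FLIP5, FLIP3, OPEN) or
#'   unnamed in that order; normalized internally.
#' @param nu Base attempt rate (per unit time).
#' @param emission List with per-state mean distance channels and noise:
#'   `pairing`, `stack5`, `stack3` (numeric[4], one per state), `x` (mean
#'   end-to-end distance per state, nm), `sd` (Gaussian channel noise).
#'   `NULL` gives sensible defaults mimicking a junction pair.
#' @param context Nearest-neighbour context label carried by the series.
#' @param allow_direct Add CLOSED<->OPEN rates (off by default).
#' @return A `junction_markov_model`.
#' @export
junction_markov_model <- function(pi = c(0.4, 0.2, 0.2, 0.2), nu = 1,
                                  emission = NULL, context = "CC/GG",
                                  allow_direct = FALSE) {
  stopifnot(length(pi) == 4, all(pi > 0), nu > 0)
  pi <- pi / sum(pi)
  names(pi) <- JUNCTION_STATES
  edges <- rbind(
    c(1L, 2L), c(2L, 1L), c(1L, 3L), c(3L, 1L),
    c(2L, 4L), c(4L, 2L), c(3L, 4L), c(4L, 3L)
  )
  if (allow_direct) edges <- rbind(edges, c(1L, 4L), c(4L, 1L))
  Q <- matrix(0, 4, 4, dimnames = list(JUNCTION_STATES, JUNCTION_STATES))
  for (t in seq_len(nrow(edges))) {
    i <- edges[t, 1]; j <- edges[t, 2]
    Q[i, j] <- nu * min(1, pi[j] / pi[i])   # Metropolis rates: reversible
  }
  diag(Q) <- -rowSums(Q)
  if (is.null(emission)) {
    emission <- list(
      pairing = c(3.0, 6.5, 6.5, 12),
      stack5 = c(4.0, 10.0, 4.0, 11),
      stack3 = c(4.0, 4.0, 10.0, 11),
      x = c(1.9, 2.1, 2.1, 3.9),
      sd = 0.3
    )
  }
  m <- list(pi = pi, Q = Q, nu = nu, emission = emission, context = context,
            allow_direct = allow_direct)
  class(m) <- "junction_markov_model"
  m
}

#' Sample a junction-state time series from the Markov model
#'
#' Small-time-step discretization of the continuous-time chain: per step the
#' jump probability is `Q[i,j] * dt`; an error is raised when any total exit
#' probability exceeds 0.2 per step (discretization too coarse).
#' Deterministic for a fixed seed.
#'
#' @param model A [junction_markov_model()].
#' @param n_steps Number of steps.
#' @param dt Time step.
#' @param seed RNG seed.
#' @return List: `states` (character), `channels` (matrix with pairing_1,
#'   stack5_1, stack3_1 columns), `x` (end-to-end series, nm), `series`
#'   (a `junction_state_series`-shaped data.frame with the TRUE generating
#'   states, for oracle use).
#' @export
sample_junction_series <- function(model, n_steps, dt = 0.05, seed = 1) {
  P <- model$Q * dt
  diag(P) <- 0
  exit <- rowSums(P)
  if (any(exit > 0.2)) {
    stop("dt too large for discretized sampling (exit probability > 0.2)")
  }
  diag(P) <- 1 - exit
  cp <- t(apply(P, 1, cumsum))
  st <- integer(n_steps)
  with_local_seed(seed, {
    u <- runif(n_steps)
    s <- 1L
    for (t in seq_len(n_steps)) {
      s <- findInterval(u[t], cp[s, ]) + 1L
      st[t] <- s
    }
    em <- model$emission
    noise <- matrix(rnorm(3 * n_steps, 0, em$sd), n_steps, 3)
    channels <- cbind(
      pairing_1 = em$pairing[st] + noise[, 1],
      stack5_1 = em$stack5[st] + noise[, 2],
      stack3_1 = em$stack3[st] + noise[, 3]
    )
    x <- em$x[st] + rnorm(n_steps, 0, em$sd / 10)
  })
  states <- JUNCTION_STATES[st]
  series <- data.frame(
    frame = seq_len(n_steps),
    junction = 1L,
    state = factor(states, levels = JUNCTION_STATES),
    context = model$context,
    stringsAsFactors = FALSE
  )
  class(series) <- c("junction_state_series", "data.frame")
  attr(series, "pair_states") <- matrix(states, ncol = 1)
  attr(series, "contexts") <- model$context
  list(states = states, channels = channels, x = x, series = series)
}

#' Biased two-state sampler
#'
#' Samples end-to-end values from a two-state system whose unbiased
#' populations are 50/50, under the tilted ensemble `exp(+beta f x)`:
#' the exact input for checking that [reweight()] recovers the unbiased
#' populations.
#'
#' @param dx Separation of the two states' x values (state A at 0, B at dx).
#' @param beta_f Bias strength `f/kT` (inverse length units of `dx`).
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return Numeric vector of x samples.
#' @export
biased_two_state_sampler <- function(dx, beta_f, n, seed = 1) {
  stopifnot(n >= 1)
  p_high <- exp(beta_f * dx) / (1 + exp(beta_f * dx))
  with_local_seed(seed, {
    ifelse(runif(n) < p_high, dx, 0)
  })
}

#' Synthetic fluorescence unwinding trace
#'
#' `F(t) = baseline + amplitude * (1 - exp(-rate t)) + N(0, noise_sd)`,
#' mimicking the recovery of Cy3 emission as a helicase separates the
#' quenched duplex after ATP addition.
#'
#' @param amplitude Plateau amplitude (a.u.).
#' @param rate Observed rate constant (1/min).
#' @param baseline Pre-reaction fluorescence (a.u.).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param t_grid Time points (min), strictly increasing.
#' @param seed RNG seed.
#' @return A `kinetic_trace` data.frame: `time_min`, `fluorescence`; the
#'   generator parameters are kept in attributes.
#' @export
synth_unwinding_trace <- function(amplitude, rate, baseline = 0,
                                  noise_sd = 0, t_grid = seq(0, 60, by = 0.5),
                                  seed = 1) {
  if (rate <= 0) stop("rate must be positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (any(diff(t_grid) <= 0)) stop("time points must be strictly increasing")
  f <- baseline + amplitude * (1 - exp(-rate * t_grid))
  if (noise_sd > 0) {
    f <- f + with_local_seed(seed, rnorm(length(t_grid), 0, noise_sd))
  }
  out <- data.frame(time_min = t_grid, fluorescence = f)
  attr(out, "params") <- list(
    amplitude = amplitude, rate = rate, baseline = baseline,
    noise_sd = noise_sd, seed = seed
  )
  class(out) <- c("kinetic_trace", "data.frame")
  out
}

#' Stationary distribution of a rate matrix (oracle helper)
#'
#' Computed independently of the generator's construction, as the
#' normalized null vector of the transposed rate matrix.
#'
#' @param Q Rate matrix (rows sum to zero).
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(Q) {
  ev <- eigen(t(Q))
  i <- which.min(abs(ev$values))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}
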