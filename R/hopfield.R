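#' Generate random uncorrelated binary patterns
#'
#' Draws a P x N matrix of independent +/-1 entries (probability 1/2 each),
#' the standard random-pattern ensemble stored in a Hopfield network.
#'
#' @param N number of units (columns); must be >= 1.
#' @param P number of patterns (rows); may be 0 for an empty set.
#' @param seed integer seed; the result is reproducible for a fixed seed.
#' @return An object of class `pattern_set`: a P x N integer matrix of
#'   +/-1 values with attribute `seed`.
#' @export
generate_patterns <- function(N, P, seed = 1L) {
  if (length(N) != 1 || is.na(N) || N < 1) stop("N must be a positive integer")
  if (length(P) != 1 || is.na(P) || P < 0) stop("P must be a non-negative integer")
  set.seed(seed)
  m <- matrix(sample(c(-1L, 1L), N * P, replace = TRUE), nrow = P, ncol = N)
  structure(m, class = c("pattern_set", class(m)), seed = seed)
}

#' Hebbian coupling matrix from stored patterns
#'
#' Builds the symmetric Hopfield coupling matrix
#' \eqn{J_{ij} = \sum_\mu \xi_i^\mu \xi_j^\mu} (zero diagonal), so that the
#' network energy \eqn{H[\sigma] = -(1/N)\sigma^T J \sigma} is the sum of the
#' squared pattern overlaps. Off-diagonal entries take at most P + 1 distinct
#' values.
#'
#' @param patterns a `pattern_set` or P x N matrix of +/-1 values, P >= 1.
#' @return N x N symmetric numeric matrix with zero diagonal.
#' @export
hebbian_matrix <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 1) stop("pattern set is empty")
  stopifnot(all(patterns %in% c(-1, 1)))
  J <- crossprod(patterns) # sum_mu xi_i xi_j
  diag(J) <- 0
  J
}

#' Ising energy of a binary state
#'
#' Pair-sum convention:
#' \eqn{H[\sigma] = -(1/N) \sum_{i<j} \sigma_i J_{ij} \sigma_j
#'   = -(1/2N)\,\sigma^T J \sigma}; for a symmetric J this is invariant
#' under a global sign flip of the state. The same convention is used by
#' the Monte Carlo sampler, the zero-temperature descent and the MPF
#' inference, so inferred couplings are directly commensurate with
#' beta * J of the generator.
#'
#' @param state +/-1 vector of length N.
#' @param J N x N coupling matrix.
#' @return scalar energy.
#' @export
ising_energy <- function(state, J) {
  N <- nrow(J)
  if (length(state) != N) stop("state length does not match J")
  -as.numeric(state %*% J %*% state) / (2 * N)
}

#' Overlap between two binary configurations
#'
#' \eqn{q = (1/N)\sum_i a_i b_i}; related to the Hamming distance h by
#' q = 1 - 2h/N.
#'
#' @param a,b +/-1 vectors of equal length.
#' @return overlap in [-1, 1].
#' @export
overlap <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  sum(a * b) / length(a)
}

#' Hamming distance between two binary configurations
#' @param a,b +/-1 vectors of equal length.
#' @return number of differing coordinates.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  sum(a != b)
}

#' Monte Carlo configuration for Hopfield sampling
#'
#' @param beta inverse temperature (>= 0).
#' @param steps recorded Monte Carlo sweeps (1 sweep = N attempted flips).
#' @param burn_in initial sweeps discarded for thermalization.
#' @param seed integer seed.
#' @return a list of class `mc_config`.
#' @export
mc_config <- function(beta, steps = 20000L, burn_in = 1000L, seed = 1L) {
  stopifnot(beta >= 0, steps > 0, burn_in >= 0)
  structure(list(beta = beta, steps = as.integer(steps),
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "mc_config")
}

#' Finite-temperature Monte Carlo simulation of a binary network
#'
#' Samples the Gibbs distribution \eqn{p(\sigma) \propto \exp(-\beta H[\sigma])}
#' with \eqn{H = -(1/N)\sigma^T J \sigma} by Glauber (heat-bath)
#' single-spin-flip dynamics: each sweep attempts N flips at uniformly random
#' sites, accepting with probability \eqn{1/(1+e^{\beta \Delta H})}. One state
#' is recorded per sweep after the burn-in.
#'
#' @param J symmetric coupling matrix with zero diagonal.
#' @param cfg an [mc_config()].
#' @param init optional initial +/-1 state (default: random at `cfg$seed`).
#' @return A `state_series` object: a steps x N matrix of +/-1 integers with
#'   attributes `bin_duration` (1 Monte Carlo sweep) and `origin`.
#' @export
simulate_mc <- function(J, cfg, init = NULL) {
  stopifnot(inherits(cfg, "mc_config"))
  N <- nrow(J)
  if (ncol(J) != N) stop("J must be square")
  set.seed(cfg$seed)
  if (is.null(init)) init <- sample(c(-1L, 1L), N, replace = TRUE)
  stopifnot(length(init) == N)
  states <- .glauber_mc(J, as.integer(init), cfg$beta, cfg$steps, cfg$burn_in)
  state_series(states, bin_duration = 1,
               origin = sprintf("glauber beta=%g", cfg$beta))
}

#' Construct a binary state series
#'
#' Time-ordered T x N matrix of +/-1 network states, the substrate for
#' clustering and inference.
#'
#' @param states T x N matrix of +/-1 values.
#' @param bin_duration time units per row.
#' @param origin free-text provenance tag.
#' @return a `state_series` object.
#' @export
state_series <- function(states, bin_duration = 1, origin = "") {
  states <- as.matrix(states)
  if (nrow(states) < 1) stop("series must have at least one row")
  if (!all(states == 1L | states == -1L)) stop("entries must be +1 or -1")
  storage.mode(states) <- "integer"
  structure(states, class = c("state_series", class(states)),
            bin_duration = bin_duration, origin = origin)
}

#' Deterministic zero-temperature descent to a local energy minimum
#'
#' Sweeps the spins in a fresh random order and flips any spin that strictly
#' lowers the energy; stops when a full sweep makes no flip (a local minimum)
#' or after `max_sweeps` sweeps. Ties (zero energy change) are never
#' accepted, which guarantees termination.
#'
#' @param state +/-1 starting configuration.
#' @param J coupling matrix.
#' @param max_sweeps sweep cap.
#' @param seed integer seed for the sweep orders.
#' @return list with `state` (the endpoint), and `converged` (FALSE when the
#'   sweep cap was reached before a fixed point).
#' @export
zero_temperature_descent <- function(state, J, max_sweeps = 200L, seed = 1L) {
  stopifnot(length(state) == nrow(J))
  set.seed(seed)
  .zt_descent(J, as.integer(state), as.integer(max_sweeps))
}

#' Basin-of-attraction check for a clustering of sampled configurations
#'
#' For every configuration assigned to a cluster, runs the zero-temperature
#' descent and counts a success when the overlap of the descent endpoint with
#' the assigned centroid is strictly larger than the starting overlap. Ties
#' (including starts already at a local minimum) count as failures.
#'
#' Identical configurations assigned to the same cluster are descended once
#' and weighted by their multiplicity.
#'
#' @param series the `state_series` that was clustered.
#' @param clusters a `cluster_result` with assignments for the series rows
#'   (unassigned rows are skipped).
#' @param J the coupling matrix generating the dynamics.
#' @param seed integer seed for the descent sweep orders.
#' @param max_sweeps descent sweep cap.
#' @return list with `per_cluster` (success fraction per cluster), `pooled`
#'   (mean over clusters), `sd` (standard deviation over clusters), and
#'   `n_configs` (configurations used).
#' @export
basin_check <- function(series, clusters, J, seed = 1L, max_sweeps = 200L) {
  stopifnot(inherits(clusters, "cluster_result"))
  assign <- clusters$assignments
  keep <- !is.na(assign)
  if (!any(keep)) stop("no assigned configurations")
  states <- unclass(series)[keep, , drop = FALSE]
  asg <- assign[keep]
  # unique (state, cluster) pairs with multiplicities
  key <- paste(asg, apply(states, 1, paste, collapse = ""))
  first <- !duplicated(key)
  mult <- as.vector(table(key)[key[first]])
  ust <- states[first, , drop = FALSE]
  uasg <- asg[first]
  set.seed(seed)
  res <- .zt_descent_many(J, ust, as.integer(max_sweeps))
  fin <- res$states
  K <- nrow(clusters$centroids)
  per <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    idx <- which(uasg == k)
    if (length(idx) == 0) next
    cen <- clusters$centroids[k, ]
    q0 <- as.vector(ust[idx, , drop = FALSE] %*% cen) / ncol(ust)
    q1 <- as.vector(fin[idx, , drop = FALSE] %*% cen) / ncol(ust)
    succ <- q1 > q0
    per[k] <- sum(mult[idx] * succ) / sum(mult[idx])
  }
  used <- !is.na(per)
  list(per_cluster = per,
       pooled = mean(per[used]),
       sd = stats::sd(per[used]),
       n_configs = sum(keep))
}
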