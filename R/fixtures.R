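#' Planted-cluster binary series
#'
#' Draws `n_patterns` random +/-1 patterns of length `n` and emits `copies`
#' noisy copies of each (independent bit flips with probability
#' `flip_prob`), in shuffled time order.
#'
#' @param n_patterns number of planted patterns.
#' @param n dimension.
#' @param copies copies per pattern.
#' @param flip_prob per-bit flip probability.
#' @param seed integer seed.
#' @return list with `series` (a `state_series`), `patterns` (matrix) and
#'   `groups` (planted group of each row).
#' @export
fixture_planted_clusters <- function(n_patterns = 2, n = 50, copies = 100,
                                     flip_prob = 0.05, seed = 1L) {
  set.seed(seed)
  pat <- matrix(sample(c(-1L, 1L), n_patterns * n, replace = TRUE),
                n_patterns, n)
  rows <- pat[rep(seq_len(n_patterns), each = copies), , drop = FALSE]
  flips <- matrix(stats::runif(nrow(rows) * n) < flip_prob, nrow(rows), n)
  rows[flips] <- -rows[flips]
  ord <- sample.int(nrow(rows))
  list(series = state_series(rows[ord, , drop = FALSE],
                             origin = "planted-clusters"),
       patterns = pat,
       groups = rep(seq_len(n_patterns), each = copies)[ord])
}

#' Exact Gibbs samples from a small Ising model
#'
#' Enumerates all 2^N states of the energy H = -(1/(2N)) s' J s, computes the
#' Boltzmann weights exp(-beta H) exactly, and draws i.i.d. samples from
#' that distribution. Feasible for N <= 16; intended for N <= 10 oracle
#' checks.
#'
#' @param J symmetric coupling matrix (zero diagonal), N <= 16.
#' @param beta inverse temperature.
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return list with `series` (a `state_series`), `states` (2^N x N matrix
#'   of all configurations) and `probs` (their exact probabilities).
#' @export
fixture_small_ising <- function(J, beta = 1, n_samples = 1000, seed = 1L) {
  N <- nrow(J)
  if (N > 16) stop("exact enumeration limited to N <= 16")
  states <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), N)))
  dimnames(states) <- NULL
  H <- -rowSums((states %*% J) * states) / (2 * N)
  w <- exp(-beta * (H - min(H)))
  p <- w / sum(w)
  set.seed(seed)
  idx <- sample.int(nrow(states), n_samples, replace = TRUE, prob = p)
  list(series = state_series(states[idx, , drop = FALSE],
                             origin = "small-ising"),
       states = states, probs = p)
}

#' First-order Markov label sequence
#'
#' @param P row-stochastic transition matrix.
#' @param length sequence length.
#' @param seed integer seed.
#' @return a `label_sequence`.
#' @export
fixture_markov_chain <- function(P, length = 10000, seed = 1L) {
  markov_surrogate(P, length, seed = seed)
}

#' Second-order Markov chain with tunable history dependence
#'
#' Generates a chain over `alphabet` symbols where the next symbol depends
#' on the two previous ones: with probability `strength` it is a
#' deterministic function of the pair (a cyclic shift keyed by the symbol
#' two steps back), and with probability 1 - strength it is uniform over
#' the other symbols (so the chain never self-transitions). At
#' strength = 0 the chain is first-order (memoryless given the last
#' symbol); increasing strength adds genuine second-order memory.
#'
#' @param length sequence length.
#' @param alphabet number of symbols (>= 3).
#' @param strength memory parameter in [0, 1].
#' @param seed integer seed.
#' @return a `label_sequence`.
#' @export
fixture_second_order_chain <- function(length = 10000, alphabet = 4,
                                       strength = 0.9, seed = 1L) {
  stopifnot(alphabet >= 3, strength >= 0, strength <= 1)
  set.seed(seed)
  K <- alphabet
  v <- integer(length)
  v[1] <- sample.int(K, 1)
  v[2] <- sample.int(K - 1, 1)
  v[2] <- if (v[2] >= v[1]) v[2] + 1L else v[2] # avoid self-transition
  for (t in 3:length) {
    if (stats::runif(1) < strength) {
      nxt <- (v[t - 1] + v[t - 2]) %% K + 1L
      if (nxt == v[t - 1]) nxt <- nxt %% K + 1L
    } else {
      nxt <- sample.int(K - 1, 1)
      if (nxt >= v[t - 1]) nxt <- nxt + 1L
    }
    v[t] <- nxt
  }
  label_sequence(v, alphabet_size = K, self_transitions_removed = TRUE)
}
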