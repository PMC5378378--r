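#' Target magnetizations and spatial correlations of a binary series
#'
#' m_p is the time average of unit p; c_pq is the connected correlation
#' <s_p s_q> - m_p m_q over the whole series.
#'
#' @param series a `state_series` or +/-1 matrix with at least 2 rows.
#' @return list of class `target_statistics` with `m` (length N) and `c`
#'   (N x N symmetric; diagonal holds the variances and is ignored by the
#'   learning rule).
#' @export
target_statistics <- function(series) {
  S <- as.matrix(series)
  storage.mode(S) <- "double"
  if (nrow(S) < 2) stop("need at least 2 time bins")
  m <- colMeans(S)
  c2 <- crossprod(S) / nrow(S) - outer(m, m)
  structure(list(m = m, c = c2), class = "target_statistics")
}

#' Hyperparameters of the Rprop step-size adaptation
#'
#' @param eta_plus,eta_minus step growth/shrink factors (0 < eta_minus < 1 <
#'   eta_plus).
#' @param delta_max_j,delta_min_j,delta0_j step bounds and initial step for
#'   the inter-module couplings (mV).
#' @param delta_max_nu,delta_min_nu,delta0_nu the same for the external
#'   rates (kHz).
#' @return list of class `rprop_params`.
#' @export
rprop_params <- function(eta_plus = 1.2, eta_minus = 0.5,
                         delta_max_j = 0.05, delta_min_j = 1e-4,
                         delta0_j = 0.01,
                         delta_max_nu = 0.5, delta_min_nu = 1e-3,
                         delta0_nu = 0.1) {
  stopifnot(eta_minus > 0, eta_minus < 1, eta_plus > 1,
            delta_min_j <= delta0_j, delta0_j <= delta_max_j,
            delta_min_nu <= delta0_nu, delta0_nu <= delta_max_nu)
  structure(as.list(environment()), class = "rprop_params")
}

#' Initialize the pseudo-Boltzmann learning state
#'
#' @param n_modules number of modules.
#' @param nu_init initial external rate (kHz), scalar or per-module.
#' @param j_init initial coupling matrix; default small Gaussian around 0.
#' @param j_init_sd sd of the default initial couplings (mV).
#' @param hyper a [rprop_params()].
#' @param seed integer seed for the initial couplings.
#' @return list of class `learning_state`.
#' @export
learning_state <- function(n_modules, nu_init = 12, j_init = NULL,
                           j_init_sd = 1e-3 * 0.72,
                           hyper = rprop_params(), seed = 1L) {
  if (is.null(j_init)) {
    set.seed(seed)
    j_init <- matrix(stats::rnorm(n_modules^2, 0, j_init_sd),
                     n_modules, n_modules)
  }
  diag(j_init) <- 0
  structure(list(J = j_init,
                 nu_ext = rep(nu_init, length.out = n_modules),
                 step_j = matrix(hyper$delta0_j, n_modules, n_modules),
                 step_nu = rep(hyper$delta0_nu, n_modules),
                 prev_err_c = NULL, prev_err_m = NULL,
                 hyper = hyper, iter = 0L),
            class = "learning_state")
}

#' One pseudo-Boltzmann / Rprop update of couplings and external rates
#'
#' Per parameter: when the current and previous error have the same sign the
#' step is multiplied by eta_plus (capped at delta_max); opposite signs
#' shrink it by eta_minus (floored at delta_min); a zero product leaves it
#' unchanged. Parameters then move against the sign of the current error:
#' J_pq <- J_pq - sign(c_pq - c_pq^target) * step_pq, and likewise
#' nu_p <- nu_p - sign(m_p - m_p^target) * step_p. The first iteration
#' applies the sign update with unchanged steps. Self-couplings J_pp are
#' never updated (intra-module synapses are fixed by the architecture).
#'
#' @param state a `learning_state`.
#' @param err_c current correlation errors c - c_target (n x n matrix).
#' @param err_m current magnetization errors m - m_target (length n).
#' @return the updated `learning_state`.
#' @export
rprop_step <- function(state, err_c, err_m) {
  h <- state$hyper
  n <- nrow(state$J)
  diag(err_c) <- 0
  if (!is.null(state$prev_err_c)) {
    prod_c <- state$prev_err_c * err_c
    state$step_j <- ifelse(prod_c > 0,
                           pmin(h$eta_plus * state$step_j, h$delta_max_j),
                    ifelse(prod_c < 0,
                           pmax(h$eta_minus * state$step_j, h$delta_min_j),
                           state$step_j))
    prod_m <- state$prev_err_m * err_m
    state$step_nu <- ifelse(prod_m > 0,
                            pmin(h$eta_plus * state$step_nu, h$delta_max_nu),
                     ifelse(prod_m < 0,
                            pmax(h$eta_minus * state$step_nu, h$delta_min_nu),
                            state$step_nu))
  }
  upd <- -sign(err_c) * state$step_j
  diag(upd) <- 0
  state$J <- state$J + upd
  state$nu_ext <- state$nu_ext - sign(err_m) * state$step_nu
  state$prev_err_c <- err_c
  state$prev_err_m <- err_m
  state$iter <- state$iter + 1L
  state
}

#' Learn inter-module couplings to match target spatial correlations
#'
#' Pseudo-Boltzmann learning loop: at each iteration the network is
#' simulated with the current inter-module mean efficacies and external
#' rates, the first 5 * tau_SFA ms are discarded, the binarized module
#' activity is measured, and a Rprop step moves the couplings against the
#' sign of the correlation mismatch and the rates against the sign of the
#' magnetization mismatch. The quenched synaptic realization is frozen
#' across iterations; only the mean efficacies change.
#'
#' @param arch a [module_architecture()].
#' @param targets a [target_statistics()] with `m` of length n_modules.
#' @param n_iterations learning iterations.
#' @param duration simulated time per iteration (ms), excluding the
#'   5 * tau_SFA burn-in that is added and discarded.
#' @param seed integer seed (network realization and per-iteration drive).
#' @param state optional initial [learning_state()].
#' @param hyper a [rprop_params()].
#' @param bin binarization sampling step (ms).
#' @param dt integration step (ms).
#' @return list with `state` (final `learning_state`), `network` (with final
#'   couplings), `trajectory` (per-iteration RMS errors and correlation R2),
#'   `stats` (statistics of the final iteration), `failed` (TRUE when a
#'   simulation failed mid-loop; the trajectory up to the failure is kept).
#' @export
learn_correlations <- function(arch, targets, n_iterations = 100,
                               duration = 100e3, seed = 1L, state = NULL,
                               hyper = rprop_params(), bin = 20, dt = 0.1) {
  stopifnot(inherits(arch, "module_architecture"),
            inherits(targets, "target_statistics"),
            length(targets$m) == arch$n_modules)
  nm <- arch$n_modules
  if (is.null(state))
    state <- learning_state(nm, nu_init = arch$nu_ext, hyper = hyper,
                            seed = seed)
  net <- build_spiking_network(arch, inter_j = state$J, seed = seed)
  burn <- 5 * arch$tau_sfa
  off <- upper.tri(targets$c)
  traj <- data.frame(iter = integer(0), rms_c = numeric(0),
                     rms_m = numeric(0), r2 = numeric(0))
  stats_last <- NULL
  failed <- FALSE
  for (it in seq_len(n_iterations)) {
    net <- set_inter_couplings(net, state$J, state$nu_ext)
    sim <- try(simulate_spiking(net, duration + burn, dt = dt,
                                seed = seed + 1000L + it), silent = TRUE)
    if (inherits(sim, "try-error")) { failed <- TRUE; break }
    rates <- module_rates(sim, window = bin, bin = bin)
    words <- binarize(rates, theta_bin = arch$theta_bin)
    keep <- attr(rates, "time") > burn
    words <- state_series(unclass(words)[keep, , drop = FALSE],
                          bin_duration = bin)
    st <- target_statistics(words)
    stats_last <- st
    err_c <- st$c - targets$c
    err_m <- st$m - targets$m
    r2 <- stats::cor(st$c[off], targets$c[off])^2
    traj <- rbind(traj, data.frame(iter = it,
                                   rms_c = sqrt(mean(err_c[off]^2)),
                                   rms_m = sqrt(mean(err_m^2)),
                                   r2 = r2))
    state <- rprop_step(state, err_c, err_m)
  }
  net <- set_inter_couplings(net, state$J, state$nu_ext)
  list(state = state, network = net, trajectory = traj, stats = stats_last,
       targets = targets, failed = failed)
}

#' Maximal absolute centroid overlaps between two centroid sets
#'
#' For every centroid of `reference`, the maximum |overlap| against the
#' centroids of `other`.
#'
#' @param reference,other centroid matrices (or `cluster_result`s) with the
#'   same number of columns.
#' @return numeric vector, one value per reference centroid.
#' @export
centroid_census <- function(reference, other) {
  a <- if (inherits(reference, "cluster_result")) reference$centroids
       else as.matrix(reference)
  b <- if (inherits(other, "cluster_result")) other$centroids
       else as.matrix(other)
  q <- abs(a %*% t(b)) / ncol(a)
  apply(q, 1, max)
}

#' Validation report for a learned spiking network
#'
#' Combines the three quality checks for correlation learning: (a) squared
#' correlation between achieved and target pairwise correlations, (b) the
#' centroid overlap census between the spiking and reference cluster
#' structures, and (c) the mean absolute relative error of module-level
#' inferred couplings against the reference coupling matrix. Missing inputs
#' yield a partial report.
#'
#' @param achieved_stats `target_statistics` measured from the learned
#'   network.
#' @param targets the prescribed `target_statistics`.
#' @param clusters_spiking,clusters_reference optional `cluster_result`s.
#' @param inferred_j,reference_j optional coupling matrices for the
#'   inference check.
#' @param exact_tol overlaps at or above 1 - exact_tol count as |q| = 1.
#' @return list of class `learning_report`.
#' @export
validate_learning <- function(achieved_stats, targets,
                              clusters_spiking = NULL,
                              clusters_reference = NULL,
                              inferred_j = NULL, reference_j = NULL,
                              exact_tol = 1e-9) {
  off <- upper.tri(targets$c)
  rep <- list(r2 = stats::cor(achieved_stats$c[off], targets$c[off])^2)
  if (!is.null(clusters_spiking) && !is.null(clusters_reference)) {
    qs <- centroid_census(clusters_reference, clusters_spiking)
    rep$census_reference <- qs
    rep$n_exact_reference <- sum(qs >= 1 - exact_tol)
    rep$frac_exact_reference <- mean(qs >= 1 - exact_tol)
    qb <- centroid_census(clusters_spiking, clusters_reference)
    rep$census_spiking <- qb
    rep$n_exact_spiking <- sum(qb >= 1 - exact_tol)
  }
  if (!is.null(inferred_j) && !is.null(reference_j))
    rep$coupling_error <- coupling_error(inferred_j, reference_j)$mean_abs
  class(rep) <- "learning_report"
  rep
}
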