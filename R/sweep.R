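#' Complexity of the centroid dynamics across adaptation timescales
#'
#' For each value of tau_SFA (with g_SFA = 25/tau_SFA, so the adaptation
#' strength is constant), builds the same quenched network realization,
#' simulates it, binarizes the module activity, clusters the binary words,
#' reduces the dynamics to a centroid-label sequence with self-transitions
#' removed, and computes the relative complexity index R against Markov
#' surrogates. Simulated durations should grow with tau_SFA so each run
#' collects a comparable number of state transitions.
#'
#' @param arch a [module_architecture()]; its `tau_sfa` is overridden.
#' @param inter_j inter-module mean efficacies (mV).
#' @param taus tau_SFA values (ms).
#' @param durations simulated durations (ms), one per tau.
#' @param seed integer seed.
#' @param ms_params a [meanshift_params()] for the clustering.
#' @param n_surrogates Markov surrogates per run.
#' @param dt integration step (ms).
#' @return data.frame with one row per tau: `tau_sfa`, `n_clusters`,
#'   `length` (label-sequence length after self-transition removal),
#'   `S_LZ`, `C_LZ`, `R`.
#' @export
tau_sfa_sweep <- function(arch, inter_j, taus = c(62.5, 250, 1000, 4000),
                          durations = 240 * taus + 60e3, seed = 1L,
                          ms_params = meanshift_params(seed = seed),
                          n_surrogates = 10, dt = 0.1) {
  stopifnot(length(durations) == length(taus))
  out <- lapply(seq_along(taus), function(i) {
    a <- arch
    a$tau_sfa <- taus[i]
    a$g_sfa <- 25 / taus[i]
    net <- build_spiking_network(a, inter_j = inter_j, seed = seed)
    sim <- simulate_spiking(net, duration = durations[i], dt = dt,
                            seed = seed + i)
    words <- binarize(module_rates(sim), theta_bin = a$theta_bin)
    cl <- cluster_states(words, ms_params)
    lab <- remove_self_transitions(label_series(words, cl))
    rc <- relative_complexity(lab, n_surrogates = n_surrogates,
                              seed = seed + 100 + i)
    data.frame(tau_sfa = taus[i], n_clusters = nrow(cl$centroids),
               length = length(lab), S_LZ = rc$S_LZ, C_LZ = rc$C_LZ,
               R = rc$R)
  })
  do.call(rbind, out)
}
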