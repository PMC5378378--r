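#' Architecture of the multi-modular spiking network
#'
#' Defaults describe modules of 32 excitatory and 16 inhibitory leaky
#' integrate-and-fire neurons with spike-frequency adaptation, calibrated so
#' that an isolated module is approximately bistable between a low- and a
#' high-firing ("Down"/"Up") state separated by `theta_bin`, with
#' SFA-paced switching between them (residence times scale with `tau_sfa`).
#' The recurrent excitatory efficacy `j_ee` and the external drive `nu_ext`
#' are the calibrated working point of this clock-driven leaky integrator;
#' see the methods vignette for the calibration. Inter-module synapses
#' connect excitatory neurons only, with probability `c_inter`, and their
#' mean efficacies are free parameters (either sign), typically set by
#' correlation learning.
#'
#' Units: times in ms, potentials in mV, rates in kHz (events/ms) for the
#' external drive and Hz for module rates. `g_sfa` defaults to 25/tau_sfa so
#' that the product tau_sfa * g_sfa (the adaptation strength) is constant
#' across tau_sfa sweeps. The external drive per neuron is a single merged
#' Poisson train of aggregate rate `nu_ext` with jump `j_ext_e`/`j_ext_i`;
#' the train counts `c_ext_e`/`c_ext_i` are provenance metadata.
#'
#' @param n_modules number of modules.
#' @param n_e,n_i excitatory/inhibitory neurons per module.
#' @param tau_e,tau_i membrane time constants (ms).
#' @param t_ref_e,t_ref_i refractory periods (ms).
#' @param v_th,h_reset threshold and post-spike reset potential (mV).
#' @param c_ee,c_ie,c_ei,c_ii intra-module connection probabilities
#'   (post <- pre).
#' @param j_ee,j_ie,j_ei,j_ii intra-module mean efficacies (mV).
#' @param dmax_ee,dmax_ie,dmax_ei,dmax_ii intra-module maximal delays (ms).
#' @param d_min minimal delay (ms).
#' @param c_inter inter-module (E to E) connection probability.
#' @param dmax_inter inter-module maximal delay (ms).
#' @param nu_ext external Poisson rate per neuron (kHz), scalar or
#'   per-module.
#' @param j_ext_e,j_ext_i external synaptic jumps (mV).
#' @param c_ext_e,c_ext_i external train counts (metadata only).
#' @param tau_sfa adaptation (calcium) decay time (ms).
#' @param g_sfa adaptation strength (mV/ms per unit calcium); default
#'   25/tau_sfa.
#' @param theta_bin binarization threshold on the smoothed module rate (Hz).
#' @param rel_sd relative standard deviation of the synaptic weights.
#' @return a list of class `module_architecture`.
#' @export
module_architecture <- function(n_modules = 64L, n_e = 32L, n_i = 16L,
                                tau_e = 20, tau_i = 10,
                                t_ref_e = 2, t_ref_i = 1,
                                v_th = 20, h_reset = 15,
                                c_ee = 0.5, c_ie = 0.5, c_ei = 1, c_ii = 1,
                                j_ee = 2, j_ie = 1, j_ei = -2,
                                j_ii = -0.0012,
                                dmax_ee = 21, dmax_ie = 21, dmax_ei = 1,
                                dmax_ii = 1, d_min = 0.1,
                                c_inter = 0.5, dmax_inter = 50,
                                nu_ext = 2.5, j_ext_e = 0.320,
                                j_ext_i = 0.111,
                                c_ext_e = 600L, c_ext_i = 400L,
                                tau_sfa = 62.5, g_sfa = 25 / tau_sfa,
                                theta_bin = 40, rel_sd = 0.25) {
  stopifnot(n_modules >= 1, n_e >= 1, n_i >= 0, tau_e > 0, tau_i > 0,
            t_ref_e >= 0, t_ref_i >= 0, v_th > h_reset, tau_sfa > 0,
            g_sfa >= 0, d_min > 0,
            all(c(c_ee, c_ie, c_ei, c_ii, c_inter) >= 0),
            all(c(c_ee, c_ie, c_ei, c_ii, c_inter) <= 1))
  structure(as.list(environment()), class = "module_architecture")
}

#' Build a realization of the multi-modular spiking network
#'
#' Draws Bernoulli connectivity by class probability, synaptic weights
#' Gaussian around the class mean with `rel_sd` relative standard deviation
#' (the Gaussian multiplier is resampled until positive, so every weight
#' keeps the sign of its mean), and delays from a truncated exponential
#' between `d_min` and the class maximum. Inter-module synapses run between
#' excitatory neurons of different modules with probability `c_inter` and
#' mean efficacies from `inter_j`; their frozen multipliers are stored so
#' the mean efficacies can be changed later without redrawing the quenched
#' randomness (see [set_inter_couplings()]).
#'
#' @param arch a [module_architecture()].
#' @param inter_j n_modules x n_modules matrix of inter-module mean
#'   efficacies (mV), entry (p, q) acting onto module p from module q;
#'   default all zero.
#' @param seed integer seed.
#' @param i_dc optional constant current per neuron (mV/ms), for
#'   deterministic-drive experiments; default 0.
#' @return a list of class `spiking_network`.
#' @export
build_spiking_network <- function(arch, inter_j = NULL, seed = 1L,
                                  i_dc = 0) {
  stopifnot(inherits(arch, "module_architecture"))
  nm <- arch$n_modules
  if (is.null(inter_j)) inter_j <- matrix(0, nm, nm)
  stopifnot(all(dim(inter_j) == c(nm, nm)))
  set.seed(seed)
  c_intra <- matrix(c(arch$c_ee, arch$c_ei, arch$c_ie, arch$c_ii), 2, 2,
                    byrow = TRUE)
  j_intra <- matrix(c(arch$j_ee, arch$j_ei, arch$j_ie, arch$j_ii), 2, 2,
                    byrow = TRUE)
  dmax_intra <- matrix(c(arch$dmax_ee, arch$dmax_ei, arch$dmax_ie,
                         arch$dmax_ii), 2, 2, byrow = TRUE)
  syn <- .build_synapses(nm, arch$n_e, arch$n_i, c_intra, j_intra,
                         dmax_intra, arch$d_min, arch$c_inter, inter_j,
                         arch$dmax_inter, arch$rel_sd)
  per_mod <- arch$n_e + arch$n_i
  n <- nm * per_mod
  within_mod <- (seq_len(n) - 1) %% per_mod
  is_exc <- within_mod < arch$n_e
  module <- (seq_len(n) - 1) %/% per_mod
  nu <- rep(arch$nu_ext, length.out = nm)
  net <- list(arch = arch,
              n_neurons = n,
              syn = syn,
              module = as.integer(module),
              is_exc = is_exc,
              tau = ifelse(is_exc, arch$tau_e, arch$tau_i),
              t_ref = ifelse(is_exc, arch$t_ref_e, arch$t_ref_i),
              g_sfa = rep(arch$g_sfa, n),
              tau_sfa = rep(arch$tau_sfa, n),
              j_ext = ifelse(is_exc, arch$j_ext_e, arch$j_ext_i),
              i_dc = rep(i_dc, length.out = n),
              nu_ext_module = nu,
              inter_j = inter_j,
              seed = seed)
  class(net) <- "spiking_network"
  net
}

#' Update inter-module mean efficacies and external rates in place
#'
#' Recomputes the inter-module synaptic weights as mean * frozen Gaussian
#' multiplier, keeping the quenched connectivity, multipliers and delays of
#' the original realization. Used by the correlation-learning loop.
#'
#' @param net a `spiking_network`.
#' @param inter_j new n_modules x n_modules mean efficacies (mV).
#' @param nu_ext optional new per-module external rates (kHz).
#' @return the updated network.
#' @export
set_inter_couplings <- function(net, inter_j, nu_ext = NULL) {
  nm <- net$arch$n_modules
  stopifnot(all(dim(inter_j) == c(nm, nm)))
  pair <- net$syn$syn_pair
  sel <- pair >= 0
  p <- pair[sel] %/% nm + 1L
  q <- pair[sel] %% nm + 1L
  net$syn$syn_w[sel] <- inter_j[cbind(p, q)] * net$syn$syn_mult[sel]
  net$inter_j <- inter_j
  if (!is.null(nu_ext)) net$nu_ext_module <- rep(nu_ext, length.out = nm)
  net
}

#' Simulate the spiking network
#'
#' Clock-driven integration on a grid of step `dt`: exponential membrane and
#' calcium decay between events, delta-synaptic jumps delivered after their
#' (grid-rounded) delays, Poisson external jumps, threshold/reset with
#' refractory clamping. See [module_architecture()] for the model.
#'
#' @param net a `spiking_network`.
#' @param duration simulated time (ms).
#' @param dt integration step (ms); refused above 0.5 ms.
#' @param seed integer seed.
#' @param record_raster if TRUE, return every spike (time, neuron id).
#' @param count_bin width (ms) of the per-module excitatory spike-count
#'   bins always returned.
#' @return a list of class `spike_sim`: `counts` (bins x modules excitatory
#'   spike counts), `count_bin`, `raster` (data.frame or NULL), `duration`,
#'   `dt`, `net` metadata (n_e, theta_bin).
#' @export
simulate_spiking <- function(net, duration, dt = 0.1, seed = 1L,
                             record_raster = FALSE, count_bin = 1) {
  stopifnot(inherits(net, "spiking_network"), duration > 0)
  if (dt > 0.5) stop("dt > 0.5 ms refused: integration would be inaccurate")
  arch <- net$arch
  set.seed(seed)
  nu_per_neuron <- net$nu_ext_module[net$module + 1L]
  out <- .lif_simulate(net$n_neurons, net$syn$syn_ptr, net$syn$syn_target,
                       net$syn$syn_w, net$syn$syn_delay,
                       net$tau, net$t_ref, net$g_sfa, net$tau_sfa,
                       nu_per_neuron, net$j_ext, net$i_dc,
                       net$module, net$is_exc, arch$n_modules,
                       arch$v_th, arch$h_reset, duration, dt,
                       record_raster, count_bin)
  raster <- NULL
  if (record_raster)
    raster <- data.frame(time = out$raster$time, id = out$raster$id)
  structure(list(counts = out$ecounts, count_bin = out$rate_bin,
                 raster = raster, duration = duration, dt = dt,
                 n_e = arch$n_e, theta_bin = arch$theta_bin),
            class = "spike_sim")
}

#' Smoothed per-module excitatory population rates
#'
#' Rate of module p at sample time t = spike count of its excitatory
#' population in the trailing `window` ms, divided by (window * n_e), in Hz;
#' sampled every `bin` ms. With `bin == window` (the default) the samples
#' are non-overlapping averages.
#'
#' @param sim a `spike_sim`, or a bins x modules count matrix (then `n_e`
#'   and `count_bin` must be given).
#' @param window smoothing window (ms).
#' @param bin sampling step (ms).
#' @param n_e,count_bin required when `sim` is a raw count matrix.
#' @return a `rate_series`: T x n_modules matrix (Hz) with attributes `bin`
#'   and `window`.
#' @export
module_rates <- function(sim, window = 20, bin = 20, n_e = NULL,
                         count_bin = NULL) {
  if (window <= 0) stop("window must be positive")
  if (inherits(sim, "spike_sim")) {
    counts <- sim$counts
    count_bin <- sim$count_bin
    n_e <- sim$n_e
  } else {
    counts <- as.matrix(sim)
    if (is.null(n_e) || is.null(count_bin))
      stop("n_e and count_bin are required for a raw count matrix")
  }
  wsteps <- max(1L, round(window / count_bin))
  bsteps <- max(1L, round(bin / count_bin))
  nb <- nrow(counts)
  cs <- apply(counts, 2, cumsum)
  cs <- rbind(0, cs)
  ends <- seq(wsteps, nb, by = bsteps)
  rates <- (cs[ends + 1, , drop = FALSE] -
            cs[ends + 1 - wsteps, , drop = FALSE]) /
    (wsteps * count_bin / 1000) / n_e
  structure(rates, class = c("rate_series", class(rates)),
            bin = bin, window = window,
            time = ends * count_bin)
}

#' Binarize module rates into Up/Down state words
#'
#' +1 where the smoothed rate is at or above `theta_bin` Hz (the "Up"
#' state), -1 otherwise, giving a T x n_modules series of binary words.
#'
#' @param rates a `rate_series`.
#' @param theta_bin threshold (Hz).
#' @return a `state_series`.
#' @export
binarize <- function(rates, theta_bin = 40) {
  m <- ifelse(unclass(rates) >= theta_bin, 1L, -1L)
  state_series(m, bin_duration = attr(rates, "bin"),
               origin = sprintf("binarized theta=%g Hz", theta_bin))
}
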