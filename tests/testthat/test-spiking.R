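test_that("connectivity counts and weight statistics follow the
           architecture", {
  arch0 <- module_architecture(n_modules = 2, c_ee = 0, c_ie = 0, c_ei = 0,
                               c_ii = 0, c_inter = 0)
  net0 <- build_spiking_network(arch0, seed = 1)
  expect_equal(length(net0$syn$syn_w), 0)
  arch <- module_architecture(n_modules = 1, c_ee = 1, c_ie = 0, c_ei = 0,
                              c_ii = 0)
  net <- build_spiking_network(arch, seed = 2)
  w <- net$syn$syn_w
  expect_equal(length(w), 32 * 31)
  expect_true(all(w > 0)) # excitatory stays excitatory
  expect_lt(abs(mean(w) - arch$j_ee), 4 * 0.25 * arch$j_ee / sqrt(length(w)))
  expect_lt(abs(sd(w) - 0.25 * arch$j_ee), 0.05 * arch$j_ee)
  d <- net$syn$syn_delay
  expect_true(all(d >= arch$d_min & d <= arch$dmax_ee))
})

test_that("a silent network stays silent and coarse steps are refused", {
  arch <- module_architecture(n_modules = 1, nu_ext = 0)
  net <- build_spiking_network(arch, seed = 3)
  sim <- simulate_spiking(net, duration = 500, seed = 4,
                          record_raster = TRUE)
  expect_equal(nrow(sim$raster), 0)
  expect_equal(sum(sim$counts), 0)
  expect_error(simulate_spiking(net, 100, dt = 1), "refused")
})

test_that("a deterministically driven neuron fires at the closed-form rate
           and the rate converges in dt", {
  # single E neuron, no synapses, no SFA, constant current mu:
  # rate = 1 / (t_ref + tau * log((mu*tau - H) / (mu*tau - V_th)))
  arch <- module_architecture(n_modules = 1, n_e = 1, n_i = 0, c_ee = 0,
                              c_ei = 0, c_ie = 0, c_ii = 0, nu_ext = 0,
                              g_sfa = 0)
  mu <- 2 # mV/ms -> asymptote 40 mV
  isi_exact <- arch$t_ref_e +
    arch$tau_e * log((mu * arch$tau_e - arch$h_reset) /
                     (mu * arch$tau_e - arch$v_th))
  net <- build_spiking_network(arch, seed = 5, i_dc = mu)
  for (dt in c(0.1, 0.05)) {
    sim <- simulate_spiking(net, duration = 10000, dt = dt, seed = 6)
    rate <- sum(sim$counts) / 10 # Hz vs kHz: spikes per 10 s
    expect_equal(rate / 1000, 1 / isi_exact, tolerance = 0.02)
  }
})

test_that("refractoriness bounds inter-spike intervals and firing rates", {
  arch <- module_architecture(n_modules = 1)
  net <- build_spiking_network(arch, seed = 7)
  sim <- simulate_spiking(net, duration = 5000, seed = 8,
                          record_raster = TRUE)
  expect_gt(nrow(sim$raster), 0)
  per_mod <- arch$n_e + arch$n_i
  for (id in unique(sim$raster$id)) {
    tt <- sim$raster$time[sim$raster$id == id]
    tref <- if ((id - 1) %% per_mod < arch$n_e) arch$t_ref_e else arch$t_ref_i
    if (length(tt) > 1)
      expect_gte(min(diff(tt)), tref)
    expect_lte(length(tt) / 5, 1000 / tref) # rate ceiling in Hz
  }
})

test_that("steady firing is non-increasing in the adaptation strength", {
  rates <- sapply(c(0, 0.2, 0.4), function(g) {
    arch <- module_architecture(n_modules = 1, n_e = 1, n_i = 0, c_ee = 0,
                                c_ei = 0, c_ie = 0, c_ii = 0, nu_ext = 0,
                                tau_sfa = 250, g_sfa = g)
    net <- build_spiking_network(arch, seed = 9, i_dc = 2.5)
    sim <- simulate_spiking(net, duration = 5000, seed = 10)
    sum(sim$counts[-(1:1000), ])
  })
  expect_true(all(diff(rates) <= 0))
})

test_that("an isolated module is bistable around the binarization
           threshold", {
  arch <- module_architecture(n_modules = 1, tau_sfa = 250)
  net <- build_spiking_network(arch, seed = 11)
  sim <- simulate_spiking(net, duration = 40000, seed = 12)
  r <- as.vector(module_rates(sim))
  expect_gt(mean(r >= arch$theta_bin), 0.05) # both states visited
  expect_gt(mean(r < arch$theta_bin), 0.05)
  h <- hist(r, breaks = seq(-2.5, max(r) + 5, by = 5), plot = FALSE)
  pk_lo <- max(h$counts[h$mids < arch$theta_bin])
  pk_hi <- max(h$counts[h$mids >= arch$theta_bin])
  valley <- min(h$counts[h$mids >= 25 & h$mids <= 55])
  expect_lt(valley / min(pk_lo, pk_hi), 0.2) # bimodal with a dip
})

test_that("module rates and binarization do the window arithmetic", {
  counts <- matrix(0L, 40, 2) # 40 x 1 ms bins, 2 modules
  counts[1:20, 1] <- c(rep(2L, 12), rep(1L, 8)) # 32 spikes in 20 ms
  r <- module_rates(counts, window = 20, bin = 20, n_e = 32, count_bin = 1)
  expect_equal(r[1, 1], 32 / (0.020 * 32)) # 50 Hz
  expect_equal(r[2, 1], 0)
  expect_equal(as.vector(r[, 2]), c(0, 0))
  b <- binarize(r, theta_bin = 40)
  expect_equal(as.vector(unclass(b)), c(1L, -1L, -1L, -1L))
  expect_true(all(binarize(r * 0 + 60, 40) == 1L))
  expect_error(module_rates(counts, window = 0, n_e = 32, count_bin = 1))
})

test_that("learning can update inter-module efficacies without redrawing the
           quenched connectivity", {
  arch <- module_architecture(n_modules = 3)
  J0 <- matrix(0.01, 3, 3); diag(J0) <- 0
  net <- build_spiking_network(arch, inter_j = J0, seed = 13)
  sel <- net$syn$syn_pair >= 0
  expect_gt(sum(sel), 0)
  J1 <- matrix(-0.02, 3, 3); diag(J1) <- 0
  net1 <- set_inter_couplings(net, J1)
  expect_equal(net1$syn$syn_target, net$syn$syn_target)
  expect_equal(net1$syn$syn_delay, net$syn$syn_delay)
  expect_equal(net1$syn$syn_w[!sel], net$syn$syn_w[!sel])
  expect_equal(net1$syn$syn_w[sel] / net$syn$syn_w[sel],
               rep(-2, sum(sel)))
})
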