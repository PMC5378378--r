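test_that("the reduced parametrization expands to the summation-oracle J", {
  c1 <- c(1, -1, 1, -1)
  expect_equal(reduced_to_full(matrix(c1, 1), 0), matrix(0, 4, 4))
  cb <- rbind(c1, c(1, 1, -1, -1))
  w <- c(0.7, -0.3)
  J <- reduced_to_full(cb, w)
  for (i in 1:4) for (j in 1:4) {
    expected <- if (i == j) 0 else sum(w * cb[, i] * cb[, j])
    expect_equal(J[i, j], expected)
  }
})

test_that("the MPF objective equals its direct per-state reconstruction and
           the flat model gives N", {
  set.seed(41)
  N <- 5
  S <- matrix(sample(c(-1, 1), 20 * N, replace = TRUE), 20, N)
  o0 <- mpf_objective(rep(0, N * (N - 1) / 2), S, "full")
  expect_equal(o0$value, N)
  th <- rnorm(N * (N - 1) / 2, 0, 0.3)
  J <- matrix(0, N, N); J[upper.tri(J)] <- th; J <- J + t(J)
  # independent reconstruction: sum over states and single-flip neighbors
  # of exp((H[a] - H[b]) / 2), averaged over the data
  acc <- 0
  for (r in seq_len(nrow(S))) {
    Ha <- energy_oracle(S[r, ], J)
    for (k in seq_len(N)) {
      b <- S[r, ]; b[k] <- -b[k]
      acc <- acc + exp((Ha - energy_oracle(b, J)) / 2)
    }
  }
  o <- mpf_objective(th, S, "full")
  expect_equal(o$value, acc / nrow(S), tolerance = 1e-12)
})

test_that("analytic MPF gradients match central finite differences", {
  set.seed(42)
  N <- 6
  S <- matrix(sample(c(-1, 1), 30 * N, replace = TRUE), 30, N)
  fd_check <- function(theta, param, centroids = NULL) {
    o <- mpf_objective(theta, S, param, centroids)
    h <- 1e-5
    for (i in seq_along(theta)) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      fd <- (mpf_objective(tp, S, param, centroids)$value -
             mpf_objective(tm, S, param, centroids)$value) / (2 * h)
      expect_equal(o$gradient[i], fd, tolerance = 1e-5)
    }
  }
  fd_check(rnorm(N * (N - 1) / 2, 0, 0.4), "full")
  cb <- matrix(sample(c(-1, 1), 3 * N, replace = TRUE), 3, N)
  fd_check(rnorm(3, 0, 0.5), "reduced", cb)
  # and for the strict beta-not-in-data variant
  oex <- mpf_objective(rnorm(3, 0, 0.2), S, "reduced", cb,
                       exclude_data = TRUE)
  expect_true(is.finite(oex$value))
  expect_lte(oex$value, mpf_objective(rep(0, 3), S, "reduced", cb)$value +
               2 * N)
})

test_that("uniform exhaustive data yields near-zero couplings", {
  N <- 4
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), N)))
  fit <- infer_full(S)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$J)), 1e-6)
})

test_that("MPF agrees with exact maximum likelihood and its error shrinks
           with sample size", {
  set.seed(43)
  N <- 8
  Jt <- matrix(0, N, N)
  Jt[upper.tri(Jt)] <- rnorm(N * (N - 1) / 2, 0, 1)
  Jt <- Jt + t(Jt)
  err <- sapply(c(1000, 10000), function(n) {
    fx <- fixture_small_ising(Jt, beta = 1, n_samples = n, seed = 44)
    fit <- infer_full(fx$series)
    mean(abs(fit$J - Jt)[upper.tri(Jt)])
  })
  expect_lt(err[2], err[1]) # consistency with growing samples
  fx <- fixture_small_ising(Jt, beta = 1, n_samples = 20000, seed = 45)
  fit <- infer_full(fx$series)
  Jml <- ml_fit_exact(unclass(fx$series))
  expect_lt(mean(abs(fit$J - Jml)[upper.tri(Jt)]),
            0.15 * mean(abs(Jt[upper.tri(Jt)])))
})

test_that("a planted reduced model is recovered and beats full inference on
           small samples", {
  set.seed(46)
  N <- 20
  cb <- matrix(sample(c(-1, 1), 3 * N, replace = TRUE), 3, N)
  wt <- c(0.9, 0.7, 0.8)
  Jt <- reduced_to_full(cb, wt)
  ser <- simulate_mc(Jt, mc_config(1, steps = 8000, burn_in = 500, seed = 47))
  fit <- infer_reduced(ser, cb)
  expect_true(fit$converged)
  expect_equal(fit$weights, wt, tolerance = 0.12)
  full <- infer_full(ser)
  er <- coupling_error(fit$J, Jt)$mean_abs
  ef <- coupling_error(full$J, Jt)$mean_abs
  expect_lte(er, ef)
})

test_that("weight significance flags planted weights and not null ones", {
  set.seed(48)
  N <- 16
  cb <- matrix(sample(c(-1, 1), 3 * N, replace = TRUE), 3, N)
  wt <- c(0.9, 0, 0.8) # middle weight truly zero
  ser <- simulate_mc(reduced_to_full(cb, wt),
                     mc_config(1, steps = 6000, burn_in = 500, seed = 49))
  fit <- infer_reduced(ser, cb)
  sig <- weight_significance(fit, ser, n_boot = 50, block_length = 50,
                             seed = 50)
  expect_equal(sig$significant, c(TRUE, FALSE, TRUE))
  expect_error(weight_significance(fit, ser, n_boot = 5), "20")
  # structureless iid data: nothing significant
  S <- matrix(sample(c(-1L, 1L), 4000 * N, replace = TRUE), 4000, N)
  fit0 <- infer_reduced(state_series(S), cb)
  sig0 <- weight_significance(fit0, state_series(S), n_boot = 50,
                              block_length = 50, seed = 51)
  expect_false(any(sig0$significant))
})

test_that("relative coupling errors are normalized by the mean true
           magnitude", {
  Jt <- matrix(c(0, 1, -2, 1, 0, 3, -2, 3, 0), 3, 3)
  Ji <- Jt
  ce <- coupling_error(Ji, Jt)
  expect_equal(ce$mean_abs, 0)
  Ji[1, 2] <- Ji[2, 1] <- 2 # error 1 against mean |J| = 2
  ce <- coupling_error(Ji, Jt)
  expect_equal(ce$errors[1, 2], 0.5)
  expect_equal(ce$mean_abs, mean(abs(c(0.5, 0.5, 0, 0, 0, 0))))
  expect_error(coupling_error(Jt, 0 * Jt), "zero")
})
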