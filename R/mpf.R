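#' Expand a centroid-reduced Ising model to a full coupling matrix
#'
#' \eqn{J_{ij} = \sum_\mu \omega_\mu c_i^\mu c_j^\mu} with zero diagonal.
#' The scale is chosen so that, for centroids coinciding with the stored
#' patterns of a Hopfield generator, the fitted weights are commensurate
#' with the generating inverse temperature.
#'
#' @param centroids C x N matrix of +/-1 basis centroids.
#' @param weights length-C numeric vector of weights.
#' @return N x N symmetric matrix with zero diagonal.
#' @export
reduced_to_full <- function(centroids, weights) {
  centroids <- as.matrix(centroids)
  stopifnot(nrow(centroids) == length(weights))
  J <- t(centroids) %*% (weights * centroids)
  diag(J) <- 0
  J
}

# Deduplicate the rows of a +/-1 series into unique states with counts.
.mpf_prepare <- function(series) {
  S <- as.matrix(series)
  storage.mode(S) <- "double"
  N <- ncol(S)
  if (N <= 53) {
    key <- as.vector((S > 0) %*% 2^(seq_len(N) - 1))
  } else {
    key <- apply(S, 1, paste, collapse = "")
  }
  uk <- unique(key)
  uidx <- match(key, uk)
  Su <- S[match(uk, key), , drop = FALSE]
  w <- tabulate(uidx, nbins = length(uk))
  list(S = Su, w = w, uidx = uidx, Mtot = nrow(S), key = uk)
}

# Objective/gradient engine. theta parametrization:
#  - full: upper-triangle of symmetric J (zero diagonal)
#  - reduced: centroid weights omega, J = sum_mu omega_mu c c^T (zero diag)
# K(theta) = (1/M) sum_alpha w_alpha sum_k Gamma_{alpha -> flip k}, with
# Gamma_{a->b} = exp((H[a] - H[b]) / 2) and H = -(1/(2N)) s' J s, so the
# exponent for flipping spin k of state s is -(1/N) s_k (J s)_k.
.mpf_eval <- function(theta, prep, parametrization = c("full", "reduced"),
                      centroids = NULL, exclude_mask = NULL) {
  parametrization <- match.arg(parametrization)
  S <- prep$S; w <- prep$w; Mtot <- prep$Mtot
  N <- ncol(S)
  if (parametrization == "full") {
    J <- matrix(0, N, N)
    J[upper.tri(J)] <- theta
    J <- J + t(J)
    E <- S %*% J
  } else {
    Cb <- centroids
    E2 <- S %*% t(Cb)                       # state-centroid overlaps (x N)
    E <- (E2 * rep(theta, each = nrow(S))) %*% Cb - sum(theta) * S
  }
  X <- (-1 / N) * (S * E)
  if (max(X) > 700) stop("MPF objective overflow: rescale the parameters")
  G <- exp(X)
  if (!is.null(exclude_mask)) G <- G * exclude_mask
  value <- sum(w * rowSums(G)) / Mtot
  cfac <- -1 / (N * Mtot)
  A <- (w * G) * S
  if (parametrization == "full") {
    B <- crossprod(A, S)                    # B_ij = sum_a w G_ai s_i s_j
    Tm <- cfac * (B + t(B))
    diag(Tm) <- 0
    grad <- Tm[upper.tri(Tm)]
  } else {
    P <- A %*% t(centroids)
    Q <- S %*% t(centroids)
    grad <- cfac * (colSums(P * Q) - sum(w * rowSums(G)))
  }
  list(value = value, gradient = grad)
}

# mask[a, k] = 0 when flipping spin k of data state a lands on another data
# state (the strict "flows out of the data" variant), else 1.
.mpf_exclude_mask <- function(prep) {
  S <- prep$S
  N <- ncol(S)
  if (N > 53) stop("exclude_data requires at most 53 channels")
  pow <- 2^(seq_len(N) - 1)
  key <- as.vector((S > 0) %*% pow)
  keyset <- new.env(hash = TRUE, size = length(key))
  for (k in key) assign(as.character(k), TRUE, envir = keyset)
  mask <- matrix(1, nrow(S), N)
  for (k in seq_len(N)) {
    flipped <- key - sign(S[, k]) * pow[k]
    hit <- vapply(as.character(flipped), function(x)
      exists(x, envir = keyset, inherits = FALSE), logical(1))
    mask[hit, k] <- 0
  }
  mask
}

#' Minimum Probability Flow objective and gradient
#'
#' The MPF objective is the total probability outflow from the data under
#' single-spin-flip dynamics with transition rates
#' \eqn{\Gamma_{\alpha\to\beta} = \exp((H[\alpha]-H[\beta])/2)} (which
#' satisfy detailed balance for the Gibbs distribution of H), summed over
#' all single-flip neighbors of every data state and averaged over the data.
#' Minimizing it is a consistent, partition-function-free estimator of the
#' couplings.
#'
#' @param theta parameter vector: upper-triangle of J (`"full"`) or centroid
#'   weights omega (`"reduced"`).
#' @param data a `state_series` or +/-1 matrix.
#' @param parametrization `"full"` or `"reduced"`.
#' @param centroids C x N basis (required for `"reduced"`).
#' @param exclude_data if TRUE, flip neighbors that are themselves data
#'   states are excluded from the sum (the strict variant); by default all
#'   N single-flip neighbors of each state are summed.
#' @return list with `value` and `gradient`.
#' @export
mpf_objective <- function(theta, data, parametrization = c("full", "reduced"),
                          centroids = NULL, exclude_data = FALSE) {
  prep <- .mpf_prepare(data)
  mask <- if (exclude_data) .mpf_exclude_mask(prep) else NULL
  .mpf_eval(theta, prep, parametrization, centroids, mask)
}

.mpf_optimize <- function(prep, parametrization, centroids = NULL,
                          init = NULL, mask = NULL, maxit = 500,
                          pgtol = 1e-6) {
  npar <- if (parametrization == "full") {
    N <- ncol(prep$S); N * (N - 1) / 2
  } else nrow(centroids)
  if (is.null(init)) init <- rep(0, npar)
  trace_env <- new.env()
  trace_env$vals <- numeric(0)
  fn <- function(th) {
    r <- .mpf_eval(th, prep, parametrization, centroids, mask)
    trace_env$vals <- c(trace_env$vals, r$value)
    trace_env$last <- r
    trace_env$last_th <- th
    r$value
  }
  gr <- function(th) {
    if (!is.null(trace_env$last_th) && identical(th, trace_env$last_th))
      return(trace_env$last$gradient)
    .mpf_eval(th, prep, parametrization, centroids, mask)$gradient
  }
  o <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                    control = list(maxit = maxit, pgtol = pgtol,
                                   factr = 1e4))
  list(par = o$par, value = o$value, converged = o$convergence == 0,
       trace = trace_env$vals)
}

#' Infer the full pairwise coupling matrix by Minimum Probability Flow
#'
#' Minimizes the MPF objective over the upper triangle of a symmetric J
#' (zero diagonal, no external fields) by quasi-Newton descent with analytic
#' gradients, starting from zero couplings.
#'
#' @param data a `state_series` or +/-1 matrix with at least 2 distinct rows.
#' @param exclude_data see [mpf_objective()].
#' @param maxit optimizer iteration cap.
#' @param pgtol gradient tolerance.
#' @return an `mpf_fit` with elements `J` (the inferred matrix),
#'   `objective_trace`, `converged`, `data_size`.
#' @export
infer_full <- function(data, exclude_data = FALSE, maxit = 500, pgtol = 1e-6) {
  prep <- .mpf_prepare(data)
  if (nrow(prep$S) < 2) stop("need at least 2 distinct data states")
  mask <- if (exclude_data) .mpf_exclude_mask(prep) else NULL
  o <- .mpf_optimize(prep, "full", mask = mask, maxit = maxit, pgtol = pgtol)
  N <- ncol(prep$S)
  J <- matrix(0, N, N)
  J[upper.tri(J)] <- o$par
  J <- J + t(J)
  structure(list(J = J, parameters = o$par, objective = o$value,
                 objective_trace = o$trace, converged = o$converged,
                 data_size = prep$Mtot, parametrization = "full"),
            class = "mpf_fit")
}

#' Infer centroid weights of the reduced Ising model by MPF
#'
#' Parametrizes the coupling matrix on the basis of the cluster centroids,
#' \eqn{J_{ij} = \sum_\mu \omega_\mu c_i^\mu c_j^\mu}, after merging
#' mirror-pair centroids (which generate identical coupling terms), and
#' minimizes the MPF objective over the weights omega.
#'
#' @param data a `state_series` or +/-1 matrix.
#' @param clusters a `cluster_result` (typically mass-filtered), or a
#'   K x N centroid matrix.
#' @param exclude_data see [mpf_objective()].
#' @param maxit,pgtol optimizer settings.
#' @return an `mpf_fit` with `weights` (omega), `basis` (the deduplicated
#'   centroid matrix), `dedup_map`, `J` (the implied full matrix),
#'   `objective_trace`, `converged`.
#' @export
infer_reduced <- function(data, clusters, exclude_data = FALSE, maxit = 500,
                          pgtol = 1e-6) {
  centroids <- if (inherits(clusters, "cluster_result"))
    clusters$centroids else as.matrix(clusters)
  if (nrow(centroids) < 1) stop("no centroids")
  dd <- mirror_dedup(centroids)
  prep <- .mpf_prepare(data)
  mask <- if (exclude_data) .mpf_exclude_mask(prep) else NULL
  o <- .mpf_optimize(prep, "reduced", centroids = dd$basis, mask = mask,
                     maxit = maxit, pgtol = pgtol)
  structure(list(weights = o$par, basis = dd$basis, dedup_map = dd$map,
                 J = reduced_to_full(dd$basis, o$par), objective = o$value,
                 objective_trace = o$trace, converged = o$converged,
                 data_size = prep$Mtot, parametrization = "reduced"),
            class = "mpf_fit")
}

#' @export
print.mpf_fit <- function(x, ...) {
  cat(sprintf("mpf_fit (%s): %d parameters, objective %.6g, %s\n",
              x$parametrization,
              if (x$parametrization == "full") length(x$parameters)
              else length(x$weights),
              x$objective,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Bootstrap significance of the reduced-model weights
#'
#' Circular block bootstrap over the time series: resampled series are
#' concatenations of circular blocks of consecutive rows and the reduced
#' model is refitted to each resample (warm-started at the point fit).
#' A weight is flagged significant when |omega| exceeds the
#' Bonferroni-corrected normal critical value times its bootstrap standard
#' error: the C weights are C simultaneous hypotheses, and the centroids
#' were themselves selected from the same data, so the uncorrected 95%
#' interval is anti-conservative for the small weights. The uncorrected
#' percentile interval is returned for description.
#'
#' @param fit an `mpf_fit` from [infer_reduced()].
#' @param data the `state_series` the fit was computed from.
#' @param n_boot number of bootstrap resamples (>= 20).
#' @param block_length circular block length in time bins.
#' @param seed integer seed.
#' @param level familywise confidence level for the significance test.
#' @return list with `ci` (2 x C uncorrected percentile intervals), `se`
#'   (bootstrap standard errors), `z` (weight / se), `significant`
#'   (logical, Bonferroni-corrected), `boot_weights` (n_boot x C matrix).
#' @export
weight_significance <- function(fit, data, n_boot = 200, block_length = 100,
                                seed = 1L, level = 0.95) {
  if (n_boot < 20) stop("n_boot must be at least 20")
  stopifnot(inherits(fit, "mpf_fit"), fit$parametrization == "reduced")
  prep <- .mpf_prepare(data)
  Tn <- prep$Mtot
  C <- length(fit$weights)
  n_blocks <- ceiling(Tn / block_length)
  set.seed(seed)
  bw <- matrix(NA_real_, n_boot, C)
  for (b in seq_len(n_boot)) {
    starts <- sample.int(Tn, n_blocks, replace = TRUE)
    rows <- as.vector(outer(0:(block_length - 1), starts, `+`)) %% Tn + 1L
    rows <- rows[seq_len(Tn)]
    wb <- tabulate(prep$uidx[rows], nbins = nrow(prep$S))
    prep_b <- list(S = prep$S, w = wb, Mtot = Tn)
    o <- .mpf_optimize(prep_b, "reduced", centroids = fit$basis,
                       init = fit$weights, maxit = 200)
    bw[b, ] <- o$par
  }
  alpha <- 1 - level
  ci <- apply(bw, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  se <- apply(bw, 2, stats::sd)
  z <- fit$weights / se
  zcrit <- stats::qnorm(1 - alpha / (2 * C))
  list(ci = ci, se = se, z = z, significant = abs(z) > zcrit,
       boot_weights = bw)
}

#' Relative coupling errors between an inferred and a true matrix
#'
#' Per-entry error \eqn{(J^{inf}_{ij} - J_{ij}) / \langle |J_{ij}| \rangle},
#' normalized by the mean absolute value of the true off-diagonal entries.
#'
#' @param inferred,truth square matrices of equal dimension.
#' @return list with `errors` (off-diagonal error matrix, NA diagonal),
#'   `mean_abs` (mean absolute relative error), and `values` (the
#'   off-diagonal errors as a vector).
#' @export
coupling_error <- function(inferred, truth) {
  stopifnot(all(dim(inferred) == dim(truth)))
  off <- !diag(nrow = nrow(truth))
  norm <- mean(abs(truth[off]))
  if (norm == 0) stop("true couplings are identically zero")
  err <- (inferred - truth) / norm
  err[!off] <- NA
  list(errors = err, mean_abs = mean(abs(err[off])), values = err[off])
}
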