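# Independent oracles used across the suite. These deliberately use naive,
# brute-force formulations so they share no code path with the package.

# Pair-sum Ising energy by explicit double loop.
energy_oracle <- function(s, J) {
  N <- length(s)
  acc <- 0
  for (i in seq_len(N - 1))
    for (j in (i + 1):N)
      acc <- acc + s[i] * J[i, j] * s[j]
  -acc / N
}

# Hebbian couplings by explicit triple loop.
hebbian_oracle <- function(patterns) {
  N <- ncol(patterns)
  J <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    for (mu in seq_len(nrow(patterns)))
      J[i, j] <- J[i, j] + patterns[mu, i] * patterns[mu, j]
  }
  J
}

# Exhaustive-history LZ76 parser: each phrase is the shortest prefix of the
# remainder that does not occur as a substring (with overlap allowed) of the
# sequence up to the phrase's penultimate symbol.
lz76_reference <- function(v) {
  n <- length(v)
  if (n == 0) stop("empty")
  ch <- letters[as.integer(factor(v))] # one character per symbol
  phrases <- 0
  start <- 1
  while (start <= n) {
    len <- 1
    repeat {
      end <- start + len - 1
      if (end > n) break
      hist_str <- if (end > 1) paste(ch[1:(end - 1)], collapse = "") else ""
      phrase <- paste(ch[start:end], collapse = "")
      if (!grepl(phrase, hist_str, fixed = TRUE)) break
      len <- len + 1
    }
    phrases <- phrases + 1
    start <- start + len
  }
  phrases
}

# Exact maximum-likelihood Ising fit (pair couplings, no fields) by full
# enumeration of the 2^N states; feasible for N <= 10.
ml_fit_exact <- function(S, maxit = 300) {
  N <- ncol(S)
  states <- as.matrix(expand.grid(rep(list(c(-1, 1)), N)))
  dimnames(states) <- NULL
  up <- upper.tri(matrix(0, N, N))
  emp <- crossprod(S) / nrow(S)
  nll <- function(th) {
    J <- matrix(0, N, N); J[up] <- th; J <- J + t(J)
    H <- -rowSums((states %*% J) * states) / (2 * N)
    logZ <- log(sum(exp(-(H - min(H))))) + (-min(H))
    Hdata <- -rowSums((S %*% J) * S) / (2 * N)
    mean(Hdata) + logZ
  }
  grad <- function(th) {
    J <- matrix(0, N, N); J[up] <- th; J <- J + t(J)
    H <- -rowSums((states %*% J) * states) / (2 * N)
    w <- exp(-(H - min(H))); p <- w / sum(w)
    model <- t(states) %*% (p * states)
    g <- -(emp - model) / N
    g[up]
  }
  o <- stats::optim(rep(0, sum(up)), nll, grad, method = "L-BFGS-B",
                    control = list(maxit = maxit))
  J <- matrix(0, N, N); J[up] <- o$par; J + t(J)
}

# Complete-linkage agglomeration by direct search over cluster pairs.
complete_linkage_oracle <- function(d, cut) {
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  groups <- as.list(seq_len(n))
  repeat {
    best <- c(NA, NA); bestd <- Inf
    if (length(groups) == 1) break
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (a >= b) next
      link <- max(dm[groups[[a]], groups[[b]]])
      if (link < bestd) { bestd <- link; best <- c(a, b) }
    }
    if (bestd > cut) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (g in seq_along(groups)) out[groups[[g]]] <- g
  out
}

# Minimal hand-made cluster_result for unit tests.
make_clusters <- function(centroids, masses, assignments,
                          converged = TRUE) {
  structure(list(centroids = as.matrix(centroids), masses = masses,
                 assignments = as.integer(assignments),
                 params = neurolandscape::meanshift_params(),
                 converged = converged),
            class = "cluster_result")
}
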