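#' Reduce a state series to a sequence of centroid labels
#'
#' Each time bin is replaced by the index of its cluster centroid. Samples
#' left unassigned by the mass filtering (and rows of new data) are labeled
#' by the nearest centroid in Hamming distance, ties going to the centroid
#' of larger mass.
#'
#' @param series a `state_series` or +/-1 matrix.
#' @param clusters a `cluster_result` whose assignments cover the series
#'   (same number of rows), or whose centroids are used for
#'   nearest-centroid labeling otherwise.
#' @return a `label_sequence`: integer vector with attributes
#'   `alphabet_size` and `self_transitions_removed = FALSE`.
#' @export
label_series <- function(series, clusters) {
  stopifnot(inherits(clusters, "cluster_result"))
  K <- nrow(clusters$centroids)
  if (K == 0) stop("empty centroid set")
  S <- as.matrix(series)
  n <- nrow(S)
  labels <- if (length(clusters$assignments) == n)
    clusters$assignments else rep(NA_integer_, n)
  todo <- which(is.na(labels))
  if (length(todo) > 0) {
    # Hamming distance to each centroid; ties broken by larger mass
    ov <- S[todo, , drop = FALSE] %*% t(clusters$centroids) # larger = closer
    pref <- rep(clusters$masses, each = length(todo)) * 1e-9
    labels[todo] <- max.col(ov + matrix(pref, nrow = length(todo)),
                            ties.method = "first")
  }
  label_sequence(labels, alphabet_size = K)
}

#' Construct a label sequence
#' @param labels integer labels in 1..alphabet_size.
#' @param alphabet_size number of distinct centroids (defaults to
#'   max(labels)).
#' @param self_transitions_removed logical flag.
#' @return a `label_sequence`.
#' @export
label_sequence <- function(labels, alphabet_size = max(labels),
                           self_transitions_removed = FALSE) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1) || any(labels > alphabet_size))
    stop("labels must lie in 1..alphabet_size")
  structure(labels, class = "label_sequence",
            alphabet_size = as.integer(alphabet_size),
            self_transitions_removed = self_transitions_removed)
}

#' Collapse runs of repeated labels
#'
#' Removes self-transitions: consecutive duplicates are collapsed to a
#' single occurrence (idempotent). Runs of identical labels only add to the
#' compressibility of the sequence, so they are removed before the
#' complexity analysis.
#'
#' @param seq a `label_sequence`.
#' @return the collapsed `label_sequence`.
#' @export
remove_self_transitions <- function(seq) {
  if (length(seq) == 0) stop("empty sequence")
  v <- rle(as.integer(seq))$values
  label_sequence(v, alphabet_size = attr(seq, "alphabet_size"),
                 self_transitions_removed = TRUE)
}

#' Maximum-likelihood transition matrix of a label sequence
#'
#' Row-normalized bigram counts between all pairs of labels.
#'
#' @param seq a `label_sequence` of length >= 2.
#' @return list of class `transition_matrix` with `P` (row-stochastic;
#'   all-zero rows are left at zero and listed in `empty_rows`) and
#'   `counts`.
#' @export
transition_matrix <- function(seq) {
  if (length(seq) < 2) stop("need at least 2 symbols")
  K <- attr(seq, "alphabet_size")
  if (is.null(K)) K <- max(seq)
  v <- as.integer(seq)
  counts <- matrix(0, K, K)
  tab <- table(factor(v[-length(v)], levels = 1:K),
               factor(v[-1], levels = 1:K))
  counts <- matrix(as.numeric(tab), K, K)
  rs <- rowSums(counts)
  P <- counts / ifelse(rs == 0, 1, rs)
  structure(list(P = P, counts = counts, empty_rows = which(rs == 0)),
            class = "transition_matrix")
}

.stationary_distribution <- function(P, tol = 1e-12, maxit = 10000) {
  K <- nrow(P)
  pi0 <- rep(1 / K, K)
  for (i in seq_len(maxit)) {
    pi1 <- as.vector(pi0 %*% P)
    s <- sum(pi1)
    if (s == 0) return(NULL)
    pi1 <- pi1 / s
    if (max(abs(pi1 - pi0)) < tol) return(pi1)
    pi0 <- pi1
  }
  pi0
}

#' Generate a Markov surrogate label sequence
#'
#' Memoryless surrogate with the same transition probabilities: the first
#' symbol is drawn from the stationary distribution of P (power iteration);
#' subsequent symbols from the corresponding row. For a reducible chain the
#' start falls back to the empirical label frequencies, with a warning.
#'
#' @param tm a `transition_matrix` (or a row-stochastic matrix).
#' @param length surrogate length.
#' @param seed integer seed.
#' @param start_freq optional empirical label frequencies for the fallback.
#' @return a `label_sequence`.
#' @export
markov_surrogate <- function(tm, length, seed = 1L, start_freq = NULL) {
  P <- if (inherits(tm, "transition_matrix")) tm$P else as.matrix(tm)
  K <- nrow(P)
  rs <- rowSums(P)
  if (any(abs(rs[rs > 0] - 1) > 1e-8)) stop("P must be row-stochastic")
  set.seed(seed)
  pi0 <- .stationary_distribution(P)
  if (is.null(pi0) || any(rs == 0 & pi0 > 1e-12)) {
    warning("chain looks reducible; starting from empirical frequencies")
    pi0 <- if (is.null(start_freq)) rep(1 / K, K) else start_freq / sum(start_freq)
  }
  out <- integer(length)
  out[1] <- sample.int(K, 1, prob = pi0)
  for (t in seq_len(length - 1)) {
    row <- P[out[t], ]
    if (sum(row) == 0) row <- pi0 # dead-end state: restart from pi
    out[t + 1] <- sample.int(K, 1, prob = row)
  }
  label_sequence(out, alphabet_size = K,
                 self_transitions_removed = all(diag(P) == 0))
}

#' Normalized Lempel-Ziv (LZ76) complexity of a label sequence
#'
#' S_LZ is the number of phrases of the exhaustive-history LZ76 parsing;
#' the normalized complexity is
#' \eqn{C_{LZ} = S_{LZ} \log|S| / (|S| \log|A|)}, which tends to 1 for long
#' i.i.d. uniform sequences. With a one-symbol alphabet C_LZ is defined
#' as 0.
#'
#' @param seq a `label_sequence` (or integer vector).
#' @param alphabet_size |A|; defaults to the sequence attribute or the
#'   number of distinct symbols.
#' @return list with `S_LZ` (phrase count) and `C_LZ`.
#' @export
lz76_complexity <- function(seq, alphabet_size = NULL) {
  v <- as.integer(seq)
  if (length(v) == 0) stop("empty sequence")
  if (is.null(alphabet_size))
    alphabet_size <- attr(seq, "alphabet_size")
  if (is.null(alphabet_size)) alphabet_size <- length(unique(v))
  s_lz <- .lz76_count(v)
  if (alphabet_size < 2 || length(v) < 2)
    return(list(S_LZ = s_lz, C_LZ = 0))
  c_lz <- s_lz * log(length(v)) / (length(v) * log(alphabet_size))
  list(S_LZ = s_lz, C_LZ = c_lz)
}

#' Relative complexity index against Markov surrogates
#'
#' Fits the transition matrix of the sample, generates `n_surrogates`
#' equal-length memoryless Markov sequences with the same transition
#' probabilities, and returns
#' \eqn{R = (\bar C_{LZ}^{Markov} - C_{LZ}^{sample}) / \bar C_{LZ}^{Markov}}.
#' Positive R indicates memory beyond first-order Markov structure.
#'
#' @param sample a `label_sequence`.
#' @param n_surrogates number of surrogate sequences.
#' @param seed integer seed.
#' @return list of class `complexity_result` with `S_LZ`, `C_LZ`, `R`,
#'   `surrogate_C` and the fitted `transition_matrix`.
#' @export
relative_complexity <- function(sample, n_surrogates = 10, seed = 1L) {
  tm <- transition_matrix(sample)
  cs <- lz76_complexity(sample)
  freq <- tabulate(as.integer(sample), nbins = attr(sample, "alphabet_size"))
  surr <- vapply(seq_len(n_surrogates), function(b) {
    s <- markov_surrogate(tm, length(sample), seed = seed + b,
                          start_freq = freq)
    lz76_complexity(s, alphabet_size = attr(sample, "alphabet_size"))$C_LZ
  }, numeric(1))
  cm <- mean(surr)
  structure(list(S_LZ = cs$S_LZ, C_LZ = cs$C_LZ,
                 R = (cm - cs$C_LZ) / cm, surrogate_C = surr,
                 transition_matrix = tm),
            class = "complexity_result")
}

.triplet_counts <- function(v, K) {
  n <- length(v)
  idx <- (v[1:(n - 2)] - 1) * K^2 + (v[2:(n - 1)] - 1) * K + v[3:n]
  tabulate(idx, nbins = K^3)
}

#' Observed vs Markov-predicted triplet statistics
#'
#' Counts all overlapping label triplets, compares their empirical
#' probabilities with the first-order Markov prediction
#' pi(a) P(a,b) P(b,c) (pi = empirical unigram distribution), and with the
#' triplet distribution of a surrogate Markov sequence of the same length.
#' The Kullback-Leibler distance is computed over the triplets observed in
#' the sample, with add-one smoothing on the surrogate side. A same-length
#' truly Markov null sequence quantifies the finite-sample spread.
#'
#' @param seq a `label_sequence` of length >= 3.
#' @param min_count keep triplets occurring more than this many times.
#' @param n_null number of null Markov chains.
#' @param seed integer seed.
#' @return list with `triplets` (data.frame: a, b, c, count, p_obs,
#'   p_markov, p_surrogate), `kl` (sample vs surrogate), `kl_null` (null
#'   chain vs surrogate, one per null chain).
#' @export
triplet_stats <- function(seq, min_count = 10, n_null = 1, seed = 1L) {
  v <- as.integer(seq)
  if (length(v) < 3) stop("need at least 3 symbols")
  K <- attr(seq, "alphabet_size")
  if (is.null(K)) K <- max(v)
  n_tri <- length(v) - 2
  cnt <- .triplet_counts(v, K)
  tm <- transition_matrix(seq)
  piu <- tabulate(v, nbins = K) / length(v)
  idx <- which(cnt > min_count)
  a <- (idx - 1) %/% (K^2) + 1
  b <- ((idx - 1) %/% K) %% K + 1
  cc <- (idx - 1) %% K + 1
  p_obs <- cnt[idx] / n_tri
  p_markov <- piu[a] * tm$P[cbind(a, b)] * tm$P[cbind(b, cc)]
  freq <- tabulate(v, nbins = K)
  kl_of <- function(surr_cnt, support, obs_p) {
    sm <- (surr_cnt[support] + 1) / (sum(surr_cnt) + length(support))
    sum(obs_p * log(obs_p / sm))
  }
  surr <- markov_surrogate(tm, length(v), seed = seed, start_freq = freq)
  surr_cnt <- .triplet_counts(as.integer(surr), K)
  p_surrogate <- surr_cnt[idx] / n_tri
  kl <- kl_of(surr_cnt, idx, p_obs)
  kl_null <- vapply(seq_len(n_null), function(j) {
    nul <- markov_surrogate(tm, length(v), seed = seed + 100 + j,
                            start_freq = freq)
    ncnt <- .triplet_counts(as.integer(nul), K)
    nidx <- which(ncnt > min_count)
    if (length(nidx) == 0) return(NA_real_)
    kl_of(surr_cnt, nidx, ncnt[nidx] / n_tri)
  }, numeric(1))
  list(triplets = data.frame(a = a, b = b, c = cc, count = cnt[idx],
                             p_obs = p_obs, p_markov = p_markov,
                             p_surrogate = p_surrogate),
       kl = kl, kl_null = kl_null)
}

#' Merge centroids across runs into fuzzy centroids
#'
#' Pools the centroids of several clustering runs and groups them by
#' agglomerative complete-linkage clustering under Hamming distance, cut at
#' `cut_distance`. Each fuzzy centroid reports the runs that detected it
#' and its share of the total configuration mass.
#'
#' @param centroid_sets list of `cluster_result`s (or matrices; then
#'   `masses` default to 1).
#' @param cut_distance linkage cut (Hamming distance).
#' @return data.frame of class `fuzzy_catalog`: one row per fuzzy centroid
#'   with `n_runs_detected`, `detection_fraction`, `mass_share`,
#'   `representative` (row index into the pooled centroid matrix, attached
#'   as attribute `centroids`).
#' @export
merge_fuzzy_centroids <- function(centroid_sets, cut_distance = 2) {
  n_runs <- length(centroid_sets)
  stopifnot(n_runs >= 1)
  mats <- lapply(centroid_sets, function(x)
    if (inherits(x, "cluster_result")) x$centroids else as.matrix(x))
  masses <- lapply(centroid_sets, function(x)
    if (inherits(x, "cluster_result")) x$masses
    else rep(1, nrow(as.matrix(x))))
  all_c <- do.call(rbind, mats)
  all_m <- unlist(masses)
  run_id <- rep(seq_len(n_runs), vapply(mats, nrow, integer(1)))
  if (nrow(all_c) == 1) {
    grp <- 1L
  } else {
    d <- stats::dist(all_c, method = "manhattan") / 2 # Hamming on +/-1 rows
    hc <- stats::hclust(d, method = "complete")
    grp <- stats::cutree(hc, h = cut_distance)
  }
  total_mass <- sum(all_m)
  ord <- order(-as.vector(tapply(all_m, grp, sum)))
  out <- do.call(rbind, lapply(unique(grp)[ord], function(g) {
    sel <- grp == g
    data.frame(n_runs_detected = length(unique(run_id[sel])),
               detection_fraction = length(unique(run_id[sel])) / n_runs,
               mass_share = sum(all_m[sel]) / total_mass,
               representative = which(sel)[which.max(all_m[sel])])
  }))
  rownames(out) <- NULL
  attr(out, "centroids") <- all_c
  attr(out, "groups") <- grp
  class(out) <- c("fuzzy_catalog", class(out))
  out
}

#' Recovery of reference centroids across clustering runs
#'
#' A reference centroid counts as recovered by a run when some centroid of
#' that run has |overlap| above a data-derived threshold: the given
#' percentile of the run's own pairwise inter-centroid |overlaps|.
#'
#' @param reference reference centroid matrix (or `cluster_result`).
#' @param runs list of centroid matrices or `cluster_result`s.
#' @param percentile threshold percentile of within-run |overlaps|.
#' @return list with `fraction` (overall recovery fraction), `per_run`
#'   (recovery fraction per run) and `thresholds` (per-run threshold).
#' @export
centroid_recovery <- function(reference, runs, percentile = 0.95) {
  ref <- if (inherits(reference, "cluster_result")) reference$centroids
         else as.matrix(reference)
  res <- lapply(runs, function(r) {
    cen <- if (inherits(r, "cluster_result")) r$centroids else as.matrix(r)
    q <- abs(cen %*% t(cen)) / ncol(cen)
    offq <- q[upper.tri(q)]
    thr <- if (length(offq)) stats::quantile(offq, percentile) else 0
    qr <- abs(ref %*% t(cen)) / ncol(ref)
    list(rec = apply(qr, 1, max) > thr, thr = thr)
  })
  recs <- vapply(res, function(x) mean(x$rec), numeric(1))
  list(fraction = mean(unlist(lapply(res, `[[`, "rec"))),
       per_run = recs,
       thresholds = vapply(res, `[[`, numeric(1), "thr"))
}
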