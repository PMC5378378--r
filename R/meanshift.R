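#' Parameters of the modified mean-shift clustering
#'
#' @param n0 minimum neighbor count for the adaptive radius heuristic.
#' @param convergence_fraction stop when the fraction of position-changing
#'   updates among the last M (M = sample count) drops below this value.
#' @param refine_radius fixed Hamming radius of the second, mass-weighted
#'   pass over the centroids.
#' @param mass_cutoff minimal cluster mass as a fraction of all samples.
#' @param seed integer seed for the random sequential updates.
#' @param max_iterations cap on total updates; NULL means 200 * M.
#' @return a list of class `meanshift_params`.
#' @export
meanshift_params <- function(n0 = 10L, convergence_fraction = 0.01,
                             refine_radius = 2, mass_cutoff = 0.01,
                             seed = 1L, max_iterations = NULL) {
  stopifnot(n0 >= 1, convergence_fraction > 0, convergence_fraction < 1,
            mass_cutoff >= 0, mass_cutoff < 1)
  structure(list(n0 = as.integer(n0),
                 convergence_fraction = convergence_fraction,
                 refine_radius = refine_radius,
                 mass_cutoff = mass_cutoff,
                 seed = as.integer(seed),
                 max_iterations = max_iterations),
            class = "meanshift_params")
}

#' Adaptive flat-kernel radius for one point
#'
#' Computes, for point `point_index` of `data`, the standard deviation
#' sigma(n) of the distances to its n nearest neighbors, takes
#' n_min = argmin_n sigma(n) over n >= n0 (ties broken by the smallest n),
#' and returns the Hamming distance to the n_min-th nearest neighbor.
#'
#' @param point_index 1-based row index.
#' @param data matrix of +/-1 rows (the current point positions).
#' @param n0 minimum neighbor count.
#' @return radius as a Hamming distance.
#' @export
adaptive_radius <- function(point_index, data, n0 = 10L) {
  data <- as.matrix(data)
  if (nrow(data) < n0 + 1) stop("need at least n0 + 1 points")
  .ms_adaptive_radius(data, as.integer(point_index), as.integer(n0))
}

#' Single mean-shift update of one point on the hypercube
#'
#' Replaces the point by the componentwise sign of the (weighted) mean of
#' the points within the flat-kernel radius, excluding the moving sample
#' itself: a row of weight m stands for m samples, so the point's own row
#' still contributes m - 1 (for unit weights this is the plain "all other
#' points" rule). A coordinate whose weighted mean is exactly zero is left
#' unchanged; a point with no neighbors in the radius does not move.
#'
#' @param point_index 1-based row index of the point to update.
#' @param data matrix of +/-1 rows (current positions).
#' @param radius flat-kernel Hamming radius.
#' @param weights per-point masses (default all 1).
#' @return the updated +/-1 vector.
#' @export
ms_step <- function(point_index, data, radius, weights = NULL) {
  data <- as.matrix(data)
  M <- nrow(data)
  if (is.null(weights)) weights <- rep(1, M)
  x <- data[point_index, ]
  d <- as.vector(colSums(abs(t(data) - x)) / 2) # Hamming distances
  nb <- which(d <= radius)
  w <- weights[nb]
  w[nb == point_index] <- w[nb == point_index] - 1
  keep <- w > 0
  nb <- nb[keep]; w <- w[keep]
  if (length(nb) == 0) return(x)
  m <- colSums(data[nb, , drop = FALSE] * w) / sum(w)
  out <- x
  out[m > 0] <- 1L
  out[m < 0] <- -1L
  out
}

.group_positions <- function(pos, weights) {
  key <- apply(pos, 1, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(key, uk)
  centroids <- pos[match(uk, key), , drop = FALSE]
  masses <- tapply(weights, factor(idx, levels = seq_along(uk)), sum)
  list(centroids = centroids, masses = as.vector(masses), assignments = idx)
}

.cluster_result <- function(centroids, masses, assignments, params, converged) {
  structure(list(centroids = centroids, masses = masses,
                 assignments = assignments, params = params,
                 converged = converged),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d samples (%s)\n",
              nrow(x$centroids), length(x$assignments),
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Run the modified mean-shift clustering on a binary state series
#'
#' Iteratively picks a random point and moves it to the sign of the mean of
#' its in-radius neighbors, with the radius recomputed at every update by
#' the adaptive sigma(n) heuristic on the current (shifted) positions.
#' Stops when the fraction of position-changing updates over the last M
#' updates drops below `convergence_fraction`. Clusters are the groups of
#' initial points absorbed by the same final point.
#'
#' @param data a `state_series` or T x N matrix of +/-1 values (T >= 2).
#' @param params a [meanshift_params()].
#' @return a `cluster_result` with centroids, masses (summing to the number
#'   of samples), per-sample assignments and a convergence flag.
#' @export
run_meanshift <- function(data, params = meanshift_params()) {
  data <- as.matrix(data)
  M <- nrow(data)
  if (M < 2) stop("need at least 2 samples")
  max_it <- if (is.null(params$max_iterations)) 200 * M else params$max_iterations
  set.seed(params$seed)
  core <- .ms_core(data, rep(1, M), params$n0, params$convergence_fraction,
                   -1, as.integer(max_it), as.integer(M))
  g <- .group_positions(core$positions, rep(1, M))
  .cluster_result(g$centroids, g$masses, g$assignments, params,
                  core$converged)
}

#' Mass-weighted second-pass refinement of the centroids
#'
#' Re-runs the mean-shift over the centroid set with a fixed flat-kernel
#' radius (Hamming distance 2 by default), weighting each centroid by its
#' mass. Merged clusters pool their masses and the sample assignments are
#' re-indexed accordingly.
#'
#' @param result a `cluster_result`.
#' @param radius fixed Hamming radius of the pass.
#' @return the refined `cluster_result`.
#' @export
refine_centroids <- function(result, radius = 2) {
  stopifnot(inherits(result, "cluster_result"))
  K <- nrow(result$centroids)
  if (K < 1) stop("no centroids to refine")
  if (K == 1) return(result)
  p <- result$params
  set.seed(p$seed + 1L)
  core <- .ms_core(result$centroids, as.numeric(result$masses), p$n0,
                   p$convergence_fraction, radius, as.integer(200 * K),
                   as.integer(K))
  g <- .group_positions(core$positions, as.numeric(result$masses))
  remap <- g$assignments # old centroid k -> new centroid index
  new_assign <- ifelse(is.na(result$assignments), NA_integer_,
                       remap[result$assignments])
  .cluster_result(g$centroids, g$masses, new_assign, p,
                  result$converged && core$converged)
}

#' Drop clusters below a minimal mass fraction
#'
#' Clusters whose mass is below `cutoff` of the total sample count are
#' removed; their samples become unassigned (NA). Masses of the surviving
#' clusters are unchanged.
#'
#' @param result a `cluster_result`.
#' @param cutoff minimal mass fraction in [0, 1).
#' @return the filtered `cluster_result`.
#' @export
filter_clusters <- function(result, cutoff = 0.01) {
  stopifnot(inherits(result, "cluster_result"), cutoff >= 0, cutoff < 1)
  total <- sum(result$masses)
  keep <- which(result$masses / total >= cutoff | cutoff == 0)
  if (length(keep) == 0) {
    warning("all clusters removed by the mass cutoff")
    return(.cluster_result(result$centroids[0, , drop = FALSE], numeric(0),
                           rep(NA_integer_, length(result$assignments)),
                           result$params, result$converged))
  }
  remap <- rep(NA_integer_, nrow(result$centroids))
  remap[keep] <- seq_along(keep)
  new_assign <- ifelse(is.na(result$assignments), NA_integer_,
                       remap[result$assignments])
  .cluster_result(result$centroids[keep, , drop = FALSE],
                  result$masses[keep], new_assign, result$params,
                  result$converged)
}

#' Full clustering pipeline: mean-shift, refinement, mass filtering
#'
#' Runs [run_meanshift()], then [refine_centroids()] at the fixed refinement
#' radius, then [filter_clusters()] at the mass cutoff, and orders the
#' surviving clusters by decreasing mass.
#'
#' @param data a `state_series` or +/-1 matrix.
#' @param params a [meanshift_params()].
#' @return a `cluster_result`.
#' @export
cluster_states <- function(data, params = meanshift_params()) {
  res <- run_meanshift(data, params)
  res <- refine_centroids(res, radius = params$refine_radius)
  res <- filter_clusters(res, cutoff = params$mass_cutoff)
  ord <- order(res$masses, decreasing = TRUE)
  remap <- match(seq_along(ord), ord)
  .cluster_result(res$centroids[ord, , drop = FALSE], res$masses[ord],
                  ifelse(is.na(res$assignments), NA_integer_,
                         remap[res$assignments]),
                  res$params, res$converged)
}

#' Merge mirror-pair centroids into a common basis
#'
#' Centroid pairs (c, -c) generate the same Hopfield-like coupling term, so
#' they are merged into a single basis element for the reduced inference
#' model; exact duplicates are merged as well.
#'
#' @param centroids K x N matrix of +/-1 centroids.
#' @return list with `basis` (C x N matrix of representatives), `map`
#'   (length-K index of each centroid into the basis), and
#'   `n_mirror_paired` (number of centroids whose exact reflection is also
#'   present in the set).
#' @export
mirror_dedup <- function(centroids) {
  centroids <- as.matrix(centroids)
  K <- nrow(centroids)
  key <- apply(centroids, 1, paste, collapse = ",")
  negkey <- apply(-centroids, 1, paste, collapse = ",")
  canon <- ifelse(key < negkey, key, negkey)
  uk <- unique(canon)
  map <- match(canon, uk)
  basis <- centroids[match(uk, canon), , drop = FALSE]
  n_mirror <- sum(negkey %in% key & negkey != key)
  list(basis = basis, map = map, n_mirror_paired = n_mirror)
}

#' Mean-shift clustering of real-valued data
#'
#' Continuous-space variant: flat-kernel weighted means with Euclidean
#' distance and the same adaptive radius heuristic; a point counts as
#' unchanged when its displacement is below `displacement_threshold`.
#' Final points closer than the merge tolerance are grouped into clusters.
#' Plain-R implementation intended for modest sample sizes.
#'
#' @param data numeric matrix, rows = samples.
#' @param n0 minimum neighbor count for the adaptive radius.
#' @param convergence_fraction as in [meanshift_params()].
#' @param displacement_threshold minimal displacement, in data units.
#' @param merge_tol distance below which final points are merged.
#' @param seed integer seed.
#' @param max_iterations cap on total updates (default 200 * M).
#' @return a `cluster_result` (centroids are real-valued).
#' @export
run_meanshift_continuous <- function(data, n0 = 10L,
                                     convergence_fraction = 0.01,
                                     displacement_threshold = 1e-6,
                                     merge_tol = 1e-3, seed = 1L,
                                     max_iterations = NULL) {
  data <- as.matrix(data)
  M <- nrow(data)
  if (M < 2) stop("need at least 2 samples")
  pos <- data
  max_it <- if (is.null(max_iterations)) 200 * M else max_iterations
  set.seed(seed)
  changed <- integer(M)
  chpos <- 1L
  nch <- 0L
  converged <- FALSE
  for (t in seq_len(max_it)) {
    i <- sample.int(M, 1)
    d <- sqrt(colSums((t(pos) - pos[i, ])^2))
    ds <- sort(d[-i])
    n <- seq_along(ds)
    s1 <- cumsum(ds); s2 <- cumsum(ds^2)
    v <- s2 / n - (s1 / n)^2
    v[n < n0] <- Inf
    nmin <- which.min(v)
    r <- ds[nmin]
    nb <- setdiff(which(d <= r), i)
    moved <- 0L
    if (length(nb) > 0) {
      newx <- colMeans(pos[nb, , drop = FALSE])
      if (sqrt(sum((newx - pos[i, ])^2)) > displacement_threshold) {
        pos[i, ] <- newx
        moved <- 1L
      }
    }
    nch <- nch + moved - changed[chpos]
    changed[chpos] <- moved
    chpos <- chpos %% M + 1L
    if (t >= M && nch / M < convergence_fraction) { converged <- TRUE; break }
  }
  # group final points by single-linkage within merge_tol
  dmat <- as.matrix(stats::dist(pos))
  assign <- integer(M)
  k <- 0L
  for (i in seq_len(M)) {
    if (assign[i] == 0L) {
      k <- k + 1L
      stack <- i
      while (length(stack)) {
        j <- stack[[1]]; stack <- stack[-1]
        if (assign[j] == 0L) {
          assign[j] <- k
          stack <- c(stack, which(dmat[j, ] <= merge_tol & assign == 0L))
        }
      }
    }
  }
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(pos[assign == g, , drop = FALSE])))
  masses <- as.vector(table(factor(assign, levels = seq_len(k))))
  .cluster_result(centroids, masses, assign,
                  list(n0 = n0, convergence_fraction = convergence_fraction,
                       displacement_threshold = displacement_threshold,
                       seed = seed),
                  converged)
}
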