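test_that("adaptive radius matches the exhaustive sigma(n) scan", {
  # equidistant configuration: sigma(n) = 0 everywhere, radius = that distance
  base <- rep(1L, 20)
  pts <- rbind(base, t(sapply(1:14, function(i) {
    v <- base; v[i:(i + 4)] <- -1L; v # all at Hamming 5 from base
  })))
  expect_equal(adaptive_radius(1, pts, n0 = 10), 5)
  # random configuration vs direct scan
  set.seed(21)
  pts <- matrix(sample(c(-1L, 1L), 15 * 12, replace = TRUE), 15, 12)
  d <- sort(as.vector(colSums(abs(t(pts[-3, ]) - pts[3, ]) / 2)))
  sig <- sapply(seq_along(d), function(n) {
    x <- d[1:n]; sqrt(mean(x^2) - mean(x)^2)
  })
  sig[seq_along(d) < 4] <- Inf
  expect_equal(adaptive_radius(3, pts, n0 = 4), d[which.min(sig)])
  expect_error(adaptive_radius(1, pts[1:3, ], n0 = 10), "n0")
})

test_that("a mean-shift step is a neighborhood majority vote with the
           zero-mean coordinate rule", {
  v <- c(1L, -1L, 1L, -1L)
  data <- rbind(c(1L, 1L, 1L, 1L), v, v, v)
  expect_equal(ms_step(1, data, radius = 4), v) # unanimous neighbors
  # zero-mean coordinate keeps its value
  data <- rbind(c(1L, 1L), c(1L, -1L), c(-1L, 1L))
  expect_equal(ms_step(1, data, radius = 2), c(1L, 1L))
  # 3 neighbors, direct formula oracle
  x <- c(1L, 1L, -1L, -1L, 1L)
  nb <- rbind(c(1L, -1L, -1L, 1L, 1L), c(1L, 1L, -1L, 1L, -1L),
              c(-1L, 1L, -1L, 1L, 1L))
  data <- rbind(x, nb)
  m <- colMeans(nb)
  expected <- ifelse(m > 0, 1L, ifelse(m < 0, -1L, x))
  expect_equal(ms_step(1, data, radius = 5), expected)
  # mass-weighted vote: heavy row dominates, its own weight counts m - 1
  a <- c(1L, 1L, 1L, 1L); b <- c(1L, 1L, 1L, -1L)
  expect_equal(ms_step(2, rbind(a, b), radius = 1, weights = c(90, 10)), a)
})

test_that("identical points form a single cluster and planted clusters are
           recovered as majority votes", {
  pts <- matrix(rep(c(1L, -1L, 1L), 30), 30, 3, byrow = TRUE)
  res <- run_meanshift(pts, meanshift_params(seed = 1))
  expect_equal(nrow(res$centroids), 1)
  expect_equal(res$masses, 30)
  expect_equal(sum(res$masses), nrow(pts))
  fx <- fixture_planted_clusters(n_patterns = 2, n = 50, copies = 100,
                                 flip_prob = 0.05, seed = 31)
  cl <- cluster_states(fx$series, meanshift_params(seed = 32))
  expect_equal(nrow(cl$centroids), 2)
  # majority-vote oracle inside each planted group
  for (g in 1:2) {
    rows <- unclass(fx$series)[fx$groups == g, ]
    maj <- ifelse(colMeans(rows) > 0, 1L, -1L)
    expect_true(any(apply(cl$centroids, 1, function(cen) all(cen == maj))))
  }
  expect_lt(mean(is.na(cl$assignments)), 0.05) # only stray points filtered
})

test_that("clustering is equivariant under a global sign flip", {
  fx <- fixture_planted_clusters(n_patterns = 3, n = 30, copies = 60,
                                 flip_prob = 0.08, seed = 33)
  p <- meanshift_params(seed = 34)
  a <- cluster_states(fx$series, p)
  b <- cluster_states(state_series(-unclass(fx$series)), p)
  expect_equal(unname(-b$centroids), unname(a$centroids))
  expect_equal(b$masses, a$masses)
})

test_that("datasets already at separated density maxima are fixed points", {
  pats <- generate_patterns(40, 3, seed = 35)
  pts <- pats[rep(1:3, each = 12), ]
  res <- run_meanshift(pts, meanshift_params(seed = 36))
  expect_equal(nrow(res$centroids), 3)
  expect_equal(sort(res$masses), rep(12, 3))
  expect_true(all(res$centroids[order(res$centroids[, 1]), ] %in% c(-1, 1)))
  for (k in 1:3)
    expect_true(any(apply(res$centroids, 1, function(cen)
      all(cen == pats[k, ]))))
})

test_that("refinement merges nearby centroids by mass-weighted majority and
           leaves distant ones alone", {
  pats <- generate_patterns(30, 3, seed = 37) # mutually far apart
  cl <- make_clusters(pats, masses = c(10, 20, 30),
                      assignments = rep(1:3, times = c(10, 20, 30)))
  ref <- refine_centroids(cl, radius = 2)
  expect_equal(nrow(ref$centroids), 3)
  expect_equal(sum(ref$masses), 60)
  # Hamming-1 pair with masses 90/10 -> absorbed to the heavy centroid
  a <- rep(1L, 20); b <- a; b[5] <- -1L
  cl <- make_clusters(rbind(a, b), masses = c(90, 10),
                      assignments = rep(1:2, times = c(90, 10)))
  ref <- refine_centroids(cl, radius = 2)
  expect_equal(nrow(ref$centroids), 1)
  expect_equal(as.vector(ref$centroids), a)
  expect_equal(ref$masses, 100)
  expect_true(all(ref$assignments == 1))
})

test_that("mass filtering drops light clusters and unassigns their samples", {
  pats <- generate_patterns(25, 3, seed = 38)
  cl <- make_clusters(pats, masses = c(50, 30, 5),
                      assignments = rep(1:3, times = c(50, 30, 5)))
  f <- filter_clusters(cl, cutoff = 0.10) # 5/85 < 0.10
  expect_equal(nrow(f$centroids), 2)
  expect_equal(f$masses, c(50, 30))
  expect_equal(sum(is.na(f$assignments)), 5)
  expect_identical(filter_clusters(cl, 0)$masses, cl$masses)
  expect_warning(filter_clusters(cl, 0.99), "removed")
})

test_that("the continuous-space variant finds well-separated real-valued
           modes", {
  set.seed(39)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.1), rnorm(n, cy, 0.1))
  data <- rbind(blob(0, 0, 40), blob(5, 5, 40))
  res <- run_meanshift_continuous(data, n0 = 8, merge_tol = 0.5, seed = 40)
  expect_equal(nrow(res$centroids), 2)
  expect_equal(sort(res$masses), c(40, 40))
  cen <- res$centroids[order(res$centroids[, 1]), ]
  expect_lt(max(abs(cen - rbind(c(0, 0), c(5, 5)))), 0.2)
})

test_that("mirror deduplication merges reflected pairs only", {
  a <- c(1L, 1L, -1L, 1L); b <- c(-1L, 1L, 1L, 1L)
  dd <- mirror_dedup(rbind(a, -a, b))
  expect_equal(nrow(dd$basis), 2)
  expect_equal(dd$map[1], dd$map[2])
  expect_equal(dd$n_mirror_paired, 2)
  dd2 <- mirror_dedup(rbind(a, b))
  expect_equal(nrow(dd2$basis), 2)
  expect_equal(dd2$n_mirror_paired, 0)
})
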