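# Independent brute-force oracles, kept deliberately naive: plain loops and
# explicit formulas, no shared code with the implementation paths they check.

# lowest-|ppm| match of one target in one spectrum; NULL when no centroid
# is inside the tolerance
oracle_extract <- function(mz, intensity, target, tol_ppm) {
  best <- NULL
  for (i in seq_along(mz)) {
    ppm <- (mz[i] - target) / target * 1e6
    if (abs(ppm) > tol_ppm) next
    if (is.null(best) ||
        abs(ppm) < abs(best$ppm) - 0 ||
        (abs(ppm) == abs(best$ppm) &&
         (intensity[i] > best$intensity ||
          (intensity[i] == best$intensity && mz[i] < best$mz)))) {
      best <- list(mz = mz[i], intensity = intensity[i], ppm = ppm)
    }
  }
  best
}

# partition of m/z values into groups: connected components of the
# "within tol_ppm of each other (relative to the lower m/z)" relation
oracle_partition <- function(mz, tol_ppm) {
  n <- length(mz)
  lo <- outer(mz, mz, pmin)
  adj <- abs(outer(mz, mz, `-`)) / lo * 1e6 <= tol_ppm
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

# canonical form of a partition (for comparing membership vectors)
canonical_partition <- function(membership) {
  match(membership, unique(membership))
}

# descriptive statistics from first principles
oracle_stats <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- sort(v)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  sdev <- if (n > 1) sqrt(sum((v - m)^2) / (n - 1)) else NA_real_
  list(n_pixels = n, mean = m, median = med, sd = sdev,
       min = s[1], max = s[n], sum = sum(v))
}

random_polygon <- function(n_vertices, shape) {
  # star-shaped polygon around a random center: always simple, nonzero area
  cx <- runif(1, 1, shape[2] - 1)
  cy <- runif(1, 1, shape[1] - 1)
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 1.5, max(2, min(shape) / 2))
  cbind(pmin(pmax(cx + rad * cos(ang), 0), shape[2]),
        pmin(pmax(cy + rad * sin(ang), 0), shape[1]))
}
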