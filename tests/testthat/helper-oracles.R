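# Independent oracles and fixture builders used across the test files.

# Monte-Carlo estimate of the intersection area of a T-disk centred at
# (r, 0) with the origin-centred R-disk, by rejection sampling on the R-disk.
mc_lens_area <- function(r, T, R, n = 2e5) {
  pts <- sample_uniform_disk(n, R)
  inside <- (pts[, 1] - r)^2 + pts[, 2]^2 <= T^2
  p <- mean(inside)
  list(area = p * pi * R^2,
       se = sqrt(p * (1 - p) / n) * pi * R^2)
}

# Floyd-Warshall all-pairs shortest paths on a small undirected graph,
# written independently of igraph's BFS machinery.
fw_distances <- function(edges, n) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    dk <- d[i, k] + d[k, ]
    better <- dk < d[i, ]
    d[i, better] <- dk[better]
  }
  d
}

# Brute-force rich-club density: induced-subgraph edge count over pairs.
bf_rich_club <- function(edges, degrees, k) {
  vk <- which(degrees > k)
  if (length(vk) < 2) return(NA_real_)
  ink <- edges[, 1] %in% vk & edges[, 2] %in% vk
  2 * sum(ink) / (length(vk) * (length(vk) - 1))
}

# Discrete power-law sample with exponent gamma and cutoff xmin, via the
# continuous inverse-CDF approximation (accurate for the tail fit).
rpowerlaw_discrete <- function(n, gamma, xmin = 1) {
  u <- stats::runif(n)
  floor((xmin - 0.5) * u^(-1 / (gamma - 1)) + 0.5)
}

# Deterministic toy fixtures.
fixture_triangle <- function() {
  geomnet(x = c(0, 1, 0.5), y = c(0, 0, 1),
          edges = rbind(c(1, 2), c(2, 3), c(1, 3)))
}

fixture_star6 <- function() {
  th <- 2 * pi * (0:4) / 5
  geomnet(x = c(0, cos(th)), y = c(0, sin(th)),
          edges = cbind(1L, 2:6))
}

fixture_model20 <- function() {
  grow_network(N = 20, m = 2, R = 50, T = 12, seed = 420)
}

# Random small simple graph as an edge list (connected not guaranteed).
random_small_graph <- function(n, p = 0.5) {
  pairs <- t(utils::combn(n, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}
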