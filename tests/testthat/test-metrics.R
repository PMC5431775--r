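test_that("rich-club density matches direct counting and a brute-force oracle", {
  expect_equal(rich_club_phi(igraph::make_full_graph(5), 0), 1)
  star <- igraph::make_star(6, mode = "undirected")
  expect_true(is.na(rich_club_phi(star, 1)))   # only the hub qualifies
  expect_equal(rich_club_phi(star, 0), 5 / 15)
  # random small graphs vs the subgraph-density oracle, all thresholds
  set.seed(11)
  for (rep in 1:20) {
    el <- random_small_graph(7)
    if (nrow(el) < 1) next
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    deg <- igraph::degree(g)
    for (k in 0:max(deg))
      expect_equal(rich_club_phi(g, k), bf_rich_club(el, deg, k))
  }
})

test_that("double-edge swaps conserve the degree sequence", {
  tri <- as.igraph(fixture_triangle())
  set.seed(3)
  canon <- function(g) {
    el <- igraph::as_edgelist(g)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el[order(el[, 1], el[, 2]), ]
  }
  expect_equal(canon(degree_preserving_randomize(tri, 20)),
               canon(tri))   # no legal swap changes a triangle
  # 4-cycle: any outcome is a 2-regular simple graph
  cyc <- igraph::make_ring(4)
  for (i in 1:10) {
    g2 <- degree_preserving_randomize(cyc, 10)
    expect_equal(sort(igraph::degree(g2)), rep(2, 4))
    expect_false(igraph::any_loop(g2))
    expect_false(igraph::any_multiple(g2))
  }
  # a heterogeneous graph keeps its exact degree sequence
  net <- fixture_model20()
  g <- as.igraph(net)
  g2 <- degree_preserving_randomize(g, 10)
  expect_identical(sort(igraph::degree(g2)), sort(igraph::degree(g)))
})

test_that("rho is identically 1 when the null is the graph itself", {
  net <- fixture_model20()
  prof <- rho_profile(net, null_reps = 3, swap_mult = 0, min_nodes = 2)
  expect_true(all(abs(prof$rho[!is.na(prof$rho)] - 1) < 1e-12))
  expect_true(all(prof$null_spread[!is.na(prof$null_spread)] < 1e-12))
})

test_that("clustering conventions give their textbook values", {
  tri <- as.igraph(fixture_triangle())
  expect_equal(avg_clustering(tri), 1)
  tree <- igraph::make_tree(10, children = 2, mode = "undirected")
  expect_equal(avg_clustering(tree), 0)
  expect_equal(avg_clustering(tree, type = "global"), 0)
  # degree-below-2 nodes count as zero in the local mean
  path3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(avg_clustering(path3), 0)
})

test_that("distance statistics are exact", {
  path3 <- igraph::make_ring(3, circular = FALSE)
  ds <- distance_stats(path3)
  expect_identical(ds$diameter, 2L)
  expect_equal(ds$mean_distance, 4 / 3)
  k4 <- igraph::make_full_graph(4)
  ds <- distance_stats(k4)
  expect_identical(ds$diameter, 1L)
  expect_equal(ds$mean_distance, 1)
  # Floyd-Warshall oracle on a grown network
  net <- grow_network(N = 40, m = 2, R = 50, T = 12, seed = 6)
  d <- fw_distances(net$edges, length(net$x))
  ds <- distance_stats(net)
  expect_equal(ds$diameter, as.integer(max(d)))
  expect_equal(ds$mean_distance, mean(d[upper.tri(d)]))
  # disconnected input is rejected with the component count
  dis <- igraph::make_ring(3) + igraph::make_ring(4)
  expect_error(distance_stats(dis), "2 components")
})

test_that("discrete power-law MLE recovers a planted exponent", {
  set.seed(42)
  x <- rpowerlaw_discrete(1e5, gamma = 2.5)
  fit <- powerlaw_gamma_estimate(x)
  expect_gt(fit$gamma, 2.45)
  expect_lt(fit$gamma, 2.55)
  expect_gte(fit$n_tail, 50)
  # fixed-cutoff variant (generated with a matching cutoff, where the
  # inverse-CDF sampler is accurate)
  set.seed(43)
  x5 <- rpowerlaw_discrete(5e4, gamma = 2.5, xmin = 5)
  fit1 <- powerlaw_gamma_estimate(x5, xmin = 5, min_tail = 50)
  expect_equal(fit1$gamma, 2.5, tolerance = 0.05)
  expect_error(powerlaw_gamma_estimate(rep(4, 100)), "degenerate")
})

test_that("edge-length survival curve matches direct counting", {
  # lengths 1, 2, 2, 5 laid out on the axes
  net <- geomnet(x = c(0, 1, 3, 5, 0), y = c(0, 0, 0, 0, 5),
                 edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5)))
  cc <- edge_length_ccdf(net)
  expect_equal(cc$max_length, 5)
  expect_equal(cc$lengths, c(0.2, 0.4, 0.4, 1.0))
  expect_equal(cc$survival[1], 1)
  expect_equal(ccdf_at(cc, 0.3), 0.75)
  expect_equal(ccdf_at(cc, 1), 0)
  expect_true(all(diff(cc$survival) <= 0))
  expect_equal(plateau_fraction(cc), 0.25)
  # degenerate: all edges the same length
  sq <- geomnet(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
                edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  cc <- edge_length_ccdf(sq)
  expect_equal(unique(cc$lengths), 1)
  expect_equal(ccdf_at(cc, 0.999), 1)
  expect_equal(ccdf_at(cc, 1), 0)
  # geometry-free graphs are rejected
  g <- igraph::make_ring(5)
  expect_error(edge_length_ccdf(g), "coordinates")
})

test_that("small-world scan prefers the logarithmic law on planted input", {
  # synthetic diameters exactly 2 log10(N): slope in natural log is 2/ln 10
  tab <- data.frame(N = c(100, 1000, 10000),
                    mean_diameter = 2 * log10(c(100, 1000, 10000)))
  fit <- stats::lm(mean_diameter ~ log(N), data = tab)
  expect_equal(unname(coef(fit)[2]), 2 / log(10), tolerance = 1e-10)
  # a small scan of the model itself: diameters grow, log beats linear
  sc <- smallworld_scan(c(50, 150, 450), m = 3, R = 50, T = 12,
                        replicates = 2, seed = 31)
  expect_true(all(diff(sc$table$mean_diameter) >= 0))
  expect_lt(sc$rss_log, sc$rss_linear + 1e-9)
})
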