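test_that("trivial growth cases have exact structure", {
  net <- grow_network(N = 1, m = 3, R = 50, T = 12, seed = 1)
  expect_equal(length(net$x), 1L)
  expect_equal(nrow(net$edges), 0L)
  # T = 2R can never trigger a bridge, so the edge count is closed-form
  net <- grow_network(N = 4, m = 2, R = 50, T = 100, seed = 5)
  expect_equal(length(net$x), 4L)
  expect_equal(nrow(net$edges), 0L + 1L + 2L + 2L)
  expect_equal(net$n_bridge, 0L)
  expect_error(grow_network(N = 0, m = 3, R = 50, T = 12), "positive")
  expect_error(grow_network(N = 10, m = 3, R = 50, T = -1), "positive")
})

test_that("counting identities and connectivity hold on every run", {
  for (seed in 1:6) {
    T <- c(5, 12, 30, 100, 200, 12)[seed]
    net <- grow_network(N = 400, m = 3, R = 50, T = T, seed = seed)
    B <- net$n_bridge
    expect_identical(length(net$x), 400L + B)
    expect_identical(nrow(net$edges), sum(pmin(0:399, 3L)) + B)
    g <- as.igraph(net)
    expect_true(igraph::is_connected(g))
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
    # bridge nodes are born with two incident edges
    expect_true(all(net$degree[net$is_bridge] >= 2))
  }
})

test_that("a threshold at the disk diameter disables bridging entirely", {
  for (seed in 1:3) {
    net <- grow_network(N = 300, m = 3, R = 50, T = 100, seed = seed)
    expect_identical(net$n_bridge, 0L)
    # and coincides edge-for-edge with a much larger threshold at the
    # same seed (the no-threshold growing homophilic process)
    ref <- grow_network(N = 300, m = 3, R = 50, T = 1e9, seed = seed)
    expect_identical(net$edges, ref$edges)
    expect_identical(net$x, ref$x)
  }
})

test_that("runs are bit-reproducible under a fixed seed", {
  a <- grow_network(N = 150, m = 3, R = 50, T = 12, seed = 99)
  b <- grow_network(N = 150, m = 3, R = 50, T = 12, seed = 99)
  expect_identical(a, b)
})

test_that("candidate selection ranks by effective distance with a stable tie-break", {
  expect_identical(select_candidates(fixture_triangle(), c(100, 100), 3)[1:2],
                   c(3L, 2L))   # nearer corner first
  # hand-specified degrees: brute-force sort oracle
  net <- geomnet(x = c(0, 1, 2, 3, 4), y = rep(0, 5),
                 edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                               c(1, 3), c(2, 4), c(3, 5), c(1, 4)))
  p <- c(2.1, 0.5)
  deff <- sqrt((net$x - p[1])^2 + (net$y - p[2])^2) /
    sqrt(pmax(net$degree, 1))
  expect_identical(select_candidates(net, p, 3),
                   order(deff)[1:3])
  # ties broken by insertion order: two coincident degree-equal nodes
  tied <- geomnet(x = c(1, 1, 5), y = c(0, 0, 0),
                  edges = rbind(c(1, 3), c(2, 3)))
  expect_identical(select_candidates(tied, c(0, 0), 2), c(1L, 2L))
  # empty network
  empty <- geomnet(numeric(0), numeric(0),
                   matrix(integer(0), ncol = 2))
  expect_identical(select_candidates(empty, c(0, 0), 3), integer(0))
})

test_that("add_node applies the threshold rule per candidate", {
  # both candidates beyond reach: two bridges, four edges, no direct edge
  far <- geomnet(x = c(-40, 40), y = c(0, 0),
                 edges = rbind(c(1, 2)))
  res <- add_node(far, c(0, 30), m = 2, T = 12)
  expect_equal(res$bridges, 2L)
  expect_equal(length(res$net$x), 5L)
  expect_equal(nrow(res$net$edges), 1L + 4L)
  # the new node is not directly linked to either original node
  key <- apply(res$net$edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_false(any(key %in% c("1-3", "2-3")))
  # bridges sit at the midpoints
  expect_equal(sort(res$net$x[res$net$is_bridge]), c(-20, 20))
  expect_equal(res$net$y[res$net$is_bridge], c(15, 15))

  # both candidates within reach: two direct edges, no bridge
  near <- geomnet(x = c(-3, 3), y = c(0, 0), edges = rbind(c(1, 2)))
  res <- add_node(near, c(0, 2), m = 2, T = 12)
  expect_equal(res$bridges, 0L)
  expect_equal(length(res$net$x), 3L)
  expect_equal(nrow(res$net$edges), 3L)

  # mixed: one below, one above threshold
  mix <- geomnet(x = c(-2, 40), y = c(0, 0), edges = rbind(c(1, 2)))
  res <- add_node(mix, c(0, 0), m = 2, T = 12)
  expect_equal(res$bridges, 1L)
  expect_equal(length(res$net$x), 4L)      # new node + one bridge
  expect_equal(nrow(res$net$edges), 1L + 3L)
})

test_that("grow_network is one add_node per sampled point", {
  N <- 40
  set.seed(314)
  whole <- grow_network(N = N, m = 3, R = 50, T = 12, seed = 314)
  set.seed(314)
  net <- geomnet(numeric(0), numeric(0), matrix(integer(0), ncol = 2),
                 config = list(m = 3L, T = 12))
  for (i in seq_len(N)) {
    p <- sample_uniform_disk(1, 50)
    net <- add_node(net, p[1, ], m = 3, T = 12)$net
  }
  expect_equal(net$x, whole$x)
  expect_equal(net$is_bridge, whole$is_bridge)
  expect_equal(unname(net$edges), unname(whole$edges))
})

test_that("degree distribution is heavy-tailed regardless of threshold", {
  for (T in c(12, 100)) {
    net <- grow_network(N = 4000, m = 3, R = 50, T = T, seed = 8)
    fit <- powerlaw_gamma_estimate(net$degree)
    expect_gt(fit$gamma, 2.2)
    expect_lt(fit$gamma, 3.8)
  }
})
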