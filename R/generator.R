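#' Grow a geometric network with threshold-limited attachment
#'
#' Places `N` nodes one after another uniformly at random on the disk of
#' radius `R`. Each new node selects the `m` existing nodes closest in
#' effective distance (Euclidean distance over the square root of the
#' candidate's degree, floored at 1; see [effective_distance()]). A candidate
#' whose effective distance is strictly below the threshold `T` is connected
#' directly; otherwise a *bridge* node is created at the Euclidean midpoint
#' and connected to both endpoints in place of the direct edge. Bridge nodes
#' are ordinary nodes from then on: they count as candidates for later
#' arrivals and their degree enters the distance normalization. With
#' `T >= 2 R` no bridge can ever be needed and the process reduces to the
#' plain growing homophilic model.
#'
#' Candidates are ranked against the network state at the start of the step,
#' so bridges created within a step are never candidates for that same step;
#' ties in effective distance are broken by insertion order (oldest first).
#' The number of attachments made at the `i`-th random placement is
#' `min(i - 1, m)`: earlier bridge nodes are eligible *targets* but do not
#' add attachment slots, which keeps the edge-count identity exact.
#' A single RNG stream is consumed in the order (radius, angle) per node, so
#' runs are bit-reproducible given `seed`.
#'
#' The resulting graph is simple, connected, and satisfies the counting
#' identities `|V| = N + B` and `|E| = sum_i min(i - 1, m) + B`, where `B` is
#' the number of bridge nodes.
#'
#' @param N number of randomly placed nodes (bridge nodes come on top).
#' @param m number of attachment targets per new node (fewer while the
#'   network is smaller than `m`).
#' @param R disk radius.
#' @param T effective-distance threshold above which a bridge node is
#'   inserted. `T = 2 R` (the disk diameter) disables bridging.
#' @param seed optional integer seed; when supplied the run is reproducible.
#' @return an object of class `geomnet`: a list with elements
#'   \describe{
#'     \item{x, y}{node coordinates in insertion order (bridges interleaved).}
#'     \item{is_bridge}{logical flag per node.}
#'     \item{edges}{two-column integer matrix of undirected edges (1-based
#'       node ids equal to insertion order).}
#'     \item{degree}{integer node degrees.}
#'     \item{config}{the generating parameters `N`, `m`, `R`, `T`, `seed`.}
#'     \item{n_bridge}{total number of bridge nodes.}
#'   }
#' @examples
#' net <- grow_network(N = 200, m = 3, R = 50, T = 12, seed = 1)
#' net
#' sum(net$is_bridge)
#' @seealso [add_node()], [select_candidates()], [rho_profile()]
#' @export
grow_network <- function(N, m = 3, R = 50, T, seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer")
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer")
  if (!is.numeric(R) || length(R) != 1L || R <= 0)
    stop("'R' must be positive")
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("'T' must be positive")
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(N); m <- as.integer(m)
  thr <- as.numeric(T)

  cap <- N + 64L                      # node capacity, grown on demand
  ecap <- m * N + 64L                 # edge capacity
  x <- numeric(cap); y <- numeric(cap)
  deg <- integer(cap); brid <- logical(cap)
  ef <- integer(ecap); et <- integer(ecap)
  n <- 0L; ne <- 0L

  for (step in seq_len(N)) {
    rr <- R * sqrt(stats::runif(1))
    th <- 2 * pi * stats::runif(1)
    px <- rr * cos(th); py <- rr * sin(th)

    nold <- n
    # candidate ranking against the pre-step state
    if (nold > 0L) {
      idx <- seq_len(nold)
      deff <- sqrt((x[idx] - px)^2 + (y[idx] - py)^2) / sqrt(pmax(deg[idx], 1L))
      # the attachment count is min(m, random nodes so far): bridge nodes are
      # eligible targets but do not add attachment slots, so the edge-count
      # identity |E| = sum_i min(i-1, m) + B holds exactly on every run
      k <- min(m, step - 1L)
      cand <- order(deff, idx)[seq_len(k)]
    } else { cand <- integer(0); deff <- numeric(0) }

    nb_here <- sum(deff[cand] >= thr)
    need <- n + 1L + nb_here
    if (need > cap) {
      cap <- max(2L * cap, need)
      length(x) <- cap; length(y) <- cap
      x[is.na(x)] <- 0; y[is.na(y)] <- 0
      deg <- c(deg, integer(cap - length(deg)))
      brid <- c(brid, logical(cap - length(brid)))
    }
    if (ne + length(cand) + nb_here > ecap) {
      ecap <- max(2L * ecap, ne + 2L * m)
      ef <- c(ef, integer(ecap - length(ef)))
      et <- c(et, integer(ecap - length(et)))
    }

    n <- n + 1L
    new_id <- n
    x[new_id] <- px; y[new_id] <- py

    for (q in cand) {
      if (deff[q] < thr) {
        ne <- ne + 1L
        ef[ne] <- new_id; et[ne] <- q
        deg[new_id] <- deg[new_id] + 1L
        deg[q] <- deg[q] + 1L
      } else {
        n <- n + 1L
        x[n] <- (px + x[q]) / 2; y[n] <- (py + y[q]) / 2
        brid[n] <- TRUE
        ef[ne + 1L] <- new_id; et[ne + 1L] <- n
        ef[ne + 2L] <- n; et[ne + 2L] <- q
        ne <- ne + 2L
        deg[n] <- 2L
        deg[new_id] <- deg[new_id] + 1L
        deg[q] <- deg[q] + 1L
      }
    }
  }

  structure(list(
    x = x[seq_len(n)], y = y[seq_len(n)],
    is_bridge = brid[seq_len(n)],
    edges = cbind(from = ef[seq_len(ne)], to = et[seq_len(ne)]),
    degree = deg[seq_len(n)],
    config = list(N = N, m = m, R = R, T = thr, seed = seed),
    n_bridge = sum(brid[seq_len(n)])
  ), class = "geomnet")
}

#' Assemble a geometric network from its parts
#'
#' Low-level constructor used by the readers and tests; validates the basic
#' shape (simple undirected edges over `length(x)` nodes) but not the growth
#' invariants.
#'
#' @param x,y node coordinates.
#' @param edges two-column integer matrix of 1-based node id pairs.
#' @param is_bridge logical flag per node (default all `FALSE`).
#' @param config optional list of generating parameters.
#' @return a `geomnet` object.
#' @export
geomnet <- function(x, y, edges, is_bridge = NULL, config = NULL) {
  nv <- length(x)
  if (length(y) != nv) stop("'x' and 'y' must have equal length")
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("from", "to")))
  if (nrow(edges) && (min(edges) < 1L || max(edges) > nv))
    stop("edge endpoints out of range")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(key)) stop("parallel edges are not allowed")
  if (is.null(is_bridge)) is_bridge <- logical(nv)
  deg <- integer(nv)
  if (nrow(edges)) {
    tb <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = nv)
    deg <- as.integer(tb)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 is_bridge = as.logical(is_bridge),
                 edges = edges, degree = deg,
                 config = config, n_bridge = sum(is_bridge)),
            class = "geomnet")
}

#' Rank existing nodes by effective distance to a new point
#'
#' Returns up to `m` node ids sorted by ascending effective distance from
#' the point `p`, evaluated against the current state of the network (ties
#' broken by insertion order, oldest first). This is the candidate-selection
#' step of the growth process, exposed for inspection.
#'
#' @param net a `geomnet` object.
#' @param p a length-2 numeric `(x, y)` position.
#' @param m maximum number of candidates.
#' @return integer vector of node ids (1-based insertion order), possibly
#'   empty.
#' @export
select_candidates <- function(net, p, m) {
  stopifnot(inherits(net, "geomnet"))
  p <- .as_points(p)
  nv <- length(net$x)
  if (nv == 0L) return(integer(0))
  idx <- seq_len(nv)
  deff <- sqrt((net$x - p[1L])^2 + (net$y - p[2L])^2) /
    sqrt(pmax(net$degree, 1L))
  order(deff, idx)[seq_len(min(m, nv))]
}

#' Insert one node into a geometric network
#'
#' Applies a single growth step at position `p`: candidates are selected with
#' [select_candidates()], each below-threshold candidate is linked directly,
#' and each at-or-above-threshold candidate is replaced by a midpoint bridge
#' node carrying the two half-edges. Bridge edges are added unconditionally
#' (their length is never re-tested against the threshold).
#'
#' @param net a `geomnet` object.
#' @param p a length-2 numeric `(x, y)` position inside the disk.
#' @param m,T attachment count and threshold; default to the network's
#'   stored configuration.
#' @return a list with elements `net` (the grown network) and `bridges`
#'   (number of bridge nodes created in this step).
#' @export
add_node <- function(net, p, m = net$config$m, T = net$config$T) {
  stopifnot(inherits(net, "geomnet"))
  if (is.null(m) || is.null(T))
    stop("'m' and 'T' must be supplied when the network has no config")
  p <- .as_points(p)
  px <- p[1L]; py <- p[2L]
  nold <- length(net$x)
  # attachment slots are limited by the number of random (non-bridge) nodes,
  # matching grow_network(); bridges remain eligible as targets
  cand <- select_candidates(net, p, min(m, sum(!net$is_bridge)))
  deff <- if (nold)
    sqrt((net$x[cand] - px)^2 + (net$y[cand] - py)^2) /
      sqrt(pmax(net$degree[cand], 1L)) else numeric(0)

  x <- c(net$x, px); y <- c(net$y, py)
  brid <- c(net$is_bridge, FALSE)
  deg <- c(net$degree, 0L)
  ef <- net$edges[, 1L]; et <- net$edges[, 2L]
  new_id <- nold + 1L
  nb <- 0L
  for (j in seq_along(cand)) {
    q <- cand[j]
    if (deff[j] < T) {
      ef <- c(ef, new_id); et <- c(et, q)
      deg[new_id] <- deg[new_id] + 1L
      deg[q] <- deg[q] + 1L
    } else {
      x <- c(x, (px + x[q]) / 2); y <- c(y, (py + y[q]) / 2)
      brid <- c(brid, TRUE); deg <- c(deg, 2L)
      b <- length(x)
      ef <- c(ef, new_id, b); et <- c(et, b, q)
      deg[new_id] <- deg[new_id] + 1L
      deg[q] <- deg[q] + 1L
      nb <- nb + 1L
    }
  }
  out <- structure(list(
    x = x, y = y, is_bridge = brid,
    edges = cbind(from = as.integer(ef), to = as.integer(et)),
    degree = deg, config = net$config,
    n_bridge = sum(brid)
  ), class = "geomnet")
  list(net = out, bridges = nb)
}

#' @export
print.geomnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Geometric growing network: %d nodes (%d bridge), %d edges\n",
              length(x$x), x$n_bridge, nrow(x$edges)))
  if (!is.null(cfg))
    cat(sprintf("  parameters: N = %s, m = %s, R = %s, T = %s, seed = %s\n",
                cfg$N, cfg$m, cfg$R, cfg$T,
                if (is.null(cfg$seed)) "none" else cfg$seed))
  invisible(x)
}

#' Summary statistics of a geometric network
#'
#' @param object a `geomnet` object.
#' @param distances if `TRUE`, also compute exact diameter and mean shortest
#'   path (all-pairs BFS; quadratic in network size).
#' @param ... unused.
#' @return a list of class `summary.geomnet` with node/edge/bridge counts,
#'   degree summary, average local clustering, and optionally distance
#'   statistics.
#' @export
summary.geomnet <- function(object, distances = FALSE, ...) {
  g <- as.igraph.geomnet(object)
  out <- list(
    nodes = length(object$x),
    bridges = object$n_bridge,
    edges = nrow(object$edges),
    degree = summary(object$degree),
    clustering = avg_clustering(g),
    config = object$config
  )
  if (distances) {
    ds <- distance_stats(g)
    out$diameter <- ds$diameter
    out$mean_distance <- ds$mean_distance
  }
  class(out) <- "summary.geomnet"
  out
}

#' @export
print.summary.geomnet <- function(x, ...) {
  cat(sprintf("nodes: %d (bridges: %d), edges: %d\n",
              x$nodes, x$bridges, x$edges))
  cat(sprintf("average local clustering: %.4f\n", x$clustering))
  if (!is.null(x$diameter))
    cat(sprintf("diameter: %d, mean shortest path: %.4f\n",
                x$diameter, x$mean_distance))
  cat("degree summary:\n")
  print(x$degree)
  invisible(x)
}

#' @export
plot.geomnet <- function(x, edge_col = "grey70", node_cex = 0.4, ...) {
  plot(x$x, x$y, type = "n", asp = 1, xlab = "x", ylab = "y", ...)
  if (nrow(x$edges))
    graphics::segments(x$x[x$edges[, 1L]], x$y[x$edges[, 1L]],
                       x$x[x$edges[, 2L]], x$y[x$edges[, 2L]],
                       col = edge_col)
  graphics::points(x$x, x$y, pch = 19, cex = node_cex,
                   col = ifelse(x$is_bridge, "red", "steelblue"))
  invisible(x)
}

#' Convert a geometric network to an igraph graph
#'
#' Vertex attributes `x`, `y` and `is_bridge` carry the geometry.
#'
#' @param x a `geomnet` object.
#' @param ... unused.
#' @return an undirected simple [igraph::igraph] graph.
#' @export
as.igraph.geomnet <- function(x, ...) {
  g <- igraph::make_empty_graph(n = length(x$x), directed = FALSE)
  if (nrow(x$edges))
    g <- igraph::add_edges(g, as.vector(t(x$edges)))
  igraph::vertex_attr(g, "x") <- x$x
  igraph::vertex_attr(g, "y") <- x$y
  igraph::vertex_attr(g, "is_bridge") <- x$is_bridge
  g
}

# accept either a geomnet or an igraph in the metric functions
.as_graph <- function(net) {
  if (inherits(net, "geomnet")) return(as.igraph.geomnet(net))
  if (inherits(net, "igraph")) return(net)
  stop("expected a 'geomnet' or 'igraph' object")
}
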