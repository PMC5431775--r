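#' Rich-club coefficient at a degree threshold
#'
#' The rich-club coefficient `phi(k)` is the edge density of the subgraph
#' induced by the nodes of degree strictly greater than `k`:
#' `2 |E_k| / (|V_k| (|V_k| - 1))`. It is undefined (returned as `NA`) when
#' fewer than two nodes qualify.
#'
#' @param net a `geomnet` or `igraph` graph (undirected, simple).
#' @param k degree threshold(s); vectorized.
#' @return densities in `[0, 1]`, `NA` where fewer than 2 nodes qualify.
#' @examples
#' g <- igraph::make_full_graph(5)
#' rich_club_phi(g, 0)  # 1
#' @export
rich_club_phi <- function(net, k) {
  g <- .as_graph(net)
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  emin <- if (nrow(el)) pmin(deg[el[, 1L]], deg[el[, 2L]]) else numeric(0)
  vapply(k, function(kk) {
    nv <- sum(deg > kk)
    if (nv < 2) return(NA_real_)
    2 * sum(emin > kk) / (nv * (nv - 1))
  }, numeric(1))
}

#' Degree-preserving randomization by double-edge swaps
#'
#' Rewires the graph with repeated double-edge swaps (two edges exchange
#' endpoints), rejecting any swap that would create a self-loop or a parallel
#' edge, so the degree of every node is conserved exactly while higher-order
#' structure is destroyed. This is the null model against which the
#' normalized rich-club coefficient is measured.
#'
#' @param net a `geomnet` or `igraph` graph with at least 2 edges.
#' @param swap_mult number of swap attempts as a multiple of the edge count.
#' @return an [igraph::igraph] graph with the identical degree sequence.
#'   Uses R's RNG stream (seed with [set.seed()] for reproducibility).
#' @export
degree_preserving_randomize <- function(net, swap_mult = 10) {
  g <- .as_graph(net)
  ne <- igraph::ecount(g)
  if (ne < 2) stop("need at least 2 edges to swap")
  niter <- max(1L, as.integer(round(swap_mult * ne)))
  igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
}

#' Normalized rich-club profile against a degree-preserving null
#'
#' Computes `phi(k)` for the observed graph and for an ensemble of
#' degree-preserving randomizations, and reports the normalized coefficient
#' `rho(k) = phi(k) / phi_unc(k)` with `phi_unc` the null-ensemble mean.
#' `rho > 1` signals a rich club (hubs more interconnected than degree alone
#' explains); `rho < 1` its absence.
#'
#' Thresholds run from 0 up to the largest degree leaving at least
#' `min_nodes` qualifying nodes, which caps the null variance at extreme
#' degrees. Thresholds where `phi` is undefined, or where the null mean is
#' zero, are dropped from `rho`.
#'
#' @param net a `geomnet` or `igraph` graph.
#' @param null_reps number of null-model replicates.
#' @param swap_mult swap attempts per null replicate, as a multiple of the
#'   edge count; `swap_mult = 0` replicates the graph itself (so `rho` is
#'   identically 1, a useful self-check).
#' @param min_nodes smallest admissible size of the degree-filtered subgraph.
#' @return an object of class `rich_club_profile`: a data frame with columns
#'   `k`, `phi`, `phi_unc`, `rho`, `null_spread` (per-threshold standard
#'   deviation across null replicates).
#' @examples
#' set.seed(7)
#' net <- grow_network(N = 300, m = 3, R = 50, T = 100, seed = 7)
#' prof <- rho_profile(net, null_reps = 3)
#' head(prof)
#' @export
rho_profile <- function(net, null_reps = 10, swap_mult = 10, min_nodes = 10) {
  g <- .as_graph(net)
  deg <- igraph::degree(g)
  ks <- 0:max(1L, max(deg) - 1L)
  nqual <- vapply(ks, function(kk) sum(deg > kk), numeric(1))
  ks <- ks[nqual >= min_nodes]
  if (!length(ks)) stop("no degree threshold leaves enough qualifying nodes")

  phi <- rich_club_phi(g, ks)
  nullphi <- matrix(NA_real_, nrow = null_reps, ncol = length(ks))
  for (r in seq_len(null_reps)) {
    gr <- if (swap_mult > 0) degree_preserving_randomize(g, swap_mult) else g
    stopifnot(identical(sort(igraph::degree(gr)), sort(deg)))
    nullphi[r, ] <- rich_club_phi(gr, ks)
  }
  phi_unc <- colMeans(nullphi)
  spread <- apply(nullphi, 2L, stats::sd)
  rho <- ifelse(!is.na(phi) & !is.na(phi_unc) & phi_unc > 0,
                phi / phi_unc, NA_real_)
  out <- data.frame(k = ks, phi = phi, phi_unc = phi_unc, rho = rho,
                    null_spread = spread)
  class(out) <- c("rich_club_profile", "data.frame")
  out
}

#' @export
print.rich_club_profile <- function(x, ...) {
  cat(sprintf("Normalized rich-club profile over %d degree thresholds\n",
              nrow(x)))
  ok <- !is.na(x$rho)
  if (any(ok)) {
    top <- x[ok, ]
    top <- top[top$k >= stats::quantile(top$k, 0.9), ]
    cat(sprintf("  median rho over the top-decile thresholds: %.3f\n",
                stats::median(top$rho)))
  }
  NextMethod()
}

#' @export
plot.rich_club_profile <- function(x, ...) {
  ok <- !is.na(x$rho)
  plot(x$k[ok], x$rho[ok], type = "b", pch = 19, xlab = "degree threshold k",
       ylab = expression(rho(k)), ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Median normalized rich-club coefficient over the top-decile thresholds
#'
#' Convenience summary of a [rho_profile()]: the median of `rho(k)` over the
#' upper 10% of the defined thresholds, the regime where rich-club presence
#' or absence shows most clearly.
#'
#' @param profile a `rich_club_profile`.
#' @return a single number (`NA` if no threshold has a defined `rho`).
#' @export
rho_top_decile <- function(profile) {
  stopifnot(inherits(profile, "rich_club_profile"))
  ok <- !is.na(profile$rho)
  if (!any(ok)) return(NA_real_)
  p <- profile[ok, ]
  stats::median(p$rho[p$k >= stats::quantile(p$k, 0.9)])
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient (closed triangles
#' over wedges); nodes of degree below 2 contribute 0 in the default
#' convention. `type = "global"` instead returns the transitivity ratio
#' (3 x triangles / wedges), exposed so tabulated values can be checked
#' under either convention.
#'
#' @param net a `geomnet` or `igraph` graph.
#' @param type `"local"` (mean local, default) or `"global"` (transitivity).
#' @return a value in `[0, 1]`.
#' @export
avg_clustering <- function(net, type = c("local", "global")) {
  type <- match.arg(type)
  g <- .as_graph(net)
  if (type == "local")
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  else
    igraph::transitivity(g, type = "global")
}

#' Exact diameter and mean shortest-path length
#'
#' All-pairs unweighted BFS distances: the diameter is the maximum and the
#' mean is taken over distinct node pairs (each unordered pair counted
#' once).
#'
#' @param net a connected `geomnet` or `igraph` graph.
#' @return a list with `diameter` (integer) and `mean_distance`.
#' @export
distance_stats <- function(net) {
  g <- .as_graph(net)
  comp <- igraph::count_components(g)
  if (comp > 1)
    stop(sprintf("graph is disconnected (%d components); distances undefined",
                 comp))
  list(diameter = as.integer(igraph::diameter(g, unconnected = FALSE)),
       mean_distance = igraph::mean_distance(g))
}

# Hurwitz zeta sum_{i=0}^Inf (q + i)^(-s), s > 1, by direct summation with
# an Euler-Maclaurin tail correction
.hurwitz_zeta <- function(s, q, terms = 1000L) {
  k <- 0:(terms - 1L)
  head <- sum((q + k)^(-s))
  z <- q + terms
  head + z^(1 - s) / (s - 1) + 0.5 * z^(-s) + s * z^(-s - 1) / 12
}

#' Discrete power-law exponent by maximum likelihood
#'
#' Fits `P(X = x) = x^(-gamma) / zeta(gamma, xmin)` to the tail of a degree
#' sample. For each candidate lower cutoff the exponent is estimated by
#' maximizing the discrete likelihood (Hurwitz-zeta normalization), and the
#' cutoff minimizing the Kolmogorov--Smirnov distance between the fitted and
#' empirical tail distributions is selected.
#'
#' @param degrees positive integer sample (e.g. a degree sequence).
#' @param xmin optional fixed lower cutoff; when `NULL` it is selected by
#'   the KS scan over cutoffs leaving at least `min_tail` observations.
#' @param min_tail smallest admissible tail size.
#' @return an object of class `powerlaw_fit` with elements `gamma`, `xmin`,
#'   `ks` (the KS distance at the optimum) and `n_tail`.
#' @examples
#' set.seed(2)
#' x <- floor((runif(2000)^(-1 / 1.5)) * 0.5 + 0.5)  # approx gamma = 2.5
#' powerlaw_gamma_estimate(x)
#' @export
powerlaw_gamma_estimate <- function(degrees, xmin = NULL, min_tail = 50) {
  x <- as.numeric(degrees)
  x <- x[is.finite(x) & x >= 1]
  if (!length(x)) stop("no positive observations")
  if (length(unique(x)) < 2)
    stop("degenerate sample: all observations are equal")

  fit_at <- function(xm) {
    tail <- x[x >= xm]
    n <- length(tail)
    slx <- sum(log(tail))
    nll <- function(g) n * log(.hurwitz_zeta(g, xm)) + g * slx
    opt <- stats::optimize(nll, c(1.05, 8))
    g <- opt$minimum
    # KS distance on the tail
    ux <- sort(unique(tail))
    zx <- .hurwitz_zeta(g, xm)
    surv_th <- vapply(ux, function(v) .hurwitz_zeta(g, v + 1), numeric(1)) / zx
    cdf_th <- 1 - surv_th
    cdf_emp <- stats::ecdf(tail)(ux)
    list(gamma = g, xmin = xm, ks = max(abs(cdf_emp - cdf_th)), n_tail = n)
  }

  if (is.null(xmin)) {
    cands <- sort(unique(x))
    cands <- cands[vapply(cands, function(v) sum(x >= v), numeric(1)) >=
                     min_tail]
    if (!length(cands))
      stop(sprintf("fewer than %d observations above every candidate cutoff",
                   min_tail))
    fits <- lapply(cands, fit_at)
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
  } else {
    if (sum(x >= xmin) < min_tail)
      stop(sprintf("fewer than %d observations above the cutoff", min_tail))
    best <- fit_at(xmin)
  }
  structure(best, class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Discrete power-law fit: gamma = %.3f (xmin = %g, tail n = %d, KS = %.4f)\n",
    x$gamma, x$xmin, x$n_tail, x$ks))
  invisible(x)
}

#' Survival curve of normalized edge lengths
#'
#' Euclidean lengths of all edges, normalized by the longest observed edge,
#' summarized by their empirical complementary CDF. Networks whose growth
#' limits edge lengths artificially (small threshold) pile survival mass
#' near the cutoff, producing a plateau before the final drop that is absent
#' when only the domain geometry limits lengths.
#'
#' @param net a `geomnet`, or an `igraph` graph with numeric `x`/`y` vertex
#'   attributes.
#' @return an object of class `length_ccdf`: list with `lengths` (sorted
#'   normalized lengths), `survival` (`P(X >= lengths[i])`), and `max_length`
#'   (the normalization constant, in coordinate units).
#' @seealso [ccdf_at()], [plateau_fraction()]
#' @export
edge_length_ccdf <- function(net) {
  g <- .as_graph(net)
  xa <- igraph::vertex_attr(g, "x")
  ya <- igraph::vertex_attr(g, "y")
  if (is.null(xa) || is.null(ya) || anyNA(xa) || anyNA(ya))
    stop("network carries no node coordinates; edge lengths are undefined")
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!nrow(el)) stop("network has no edges")
  len <- sqrt((xa[el[, 1L]] - xa[el[, 2L]])^2 +
                (ya[el[, 1L]] - ya[el[, 2L]])^2)
  mx <- max(len)
  if (mx <= 0) stop("all edges have zero length")
  nl <- sort(len / mx)
  n <- length(nl)
  surv <- (n - match(nl, nl) + 1) / n   # P(X >= value), ties share the value

  structure(list(lengths = nl, survival = surv, max_length = mx),
            class = "length_ccdf")
}

#' Evaluate an edge-length CCDF
#'
#' Returns `P(X > q)` for the sample held by a [edge_length_ccdf()] object
#' (right-continuous survival function of the normalized lengths).
#'
#' @param obj a `length_ccdf`.
#' @param q normalized length(s) at which to evaluate; vectorized.
#' @return survival probabilities.
#' @export
ccdf_at <- function(obj, q) {
  stopifnot(inherits(obj, "length_ccdf"))
  vapply(q, function(v) mean(obj$lengths > v), numeric(1))
}

#' Fraction of edges in the upper normalized-length band
#'
#' The plateau statistic for comparing edge-length distributions: the share
#' of edges whose normalized length falls in `[lower, upper]`. A
#' threshold-limited network concentrates edges near its cutoff, so this
#' fraction is markedly larger than in a geometry-limited network.
#'
#' @param obj a `length_ccdf`.
#' @param lower,upper band limits on the normalized-length axis.
#' @return a fraction in `[0, 1]`.
#' @export
plateau_fraction <- function(obj, lower = 0.8, upper = 1.0) {
  stopifnot(inherits(obj, "length_ccdf"))
  mean(obj$lengths >= lower & obj$lengths <= upper)
}

#' @export
print.length_ccdf <- function(x, ...) {
  cat(sprintf(
    "Edge-length CCDF: %d edges, max length %.4f, upper-band [0.8, 1] fraction %.4f\n",
    length(x$lengths), x$max_length, plateau_fraction(x)))
  invisible(x)
}

#' @export
plot.length_ccdf <- function(x, log = "y", ...) {
  plot(x$lengths, x$survival, type = "s", log = log,
       xlab = "normalized edge length", ylab = "CCDF", ...)
  invisible(x)
}

#' Diameter growth across network sizes
#'
#' Grows networks of increasing size at fixed parameters, records the mean
#' diameter per size, and compares a logarithmic model
#' `diameter ~ a + b log N` against a linear one `diameter ~ a + b N` by
#' residual sum of squares. A better logarithmic fit is the small-world
#' signature.
#'
#' @param sizes ascending network sizes (number of random nodes).
#' @param m,R,T model parameters.
#' @param replicates independent runs per size.
#' @param seed optional seed for the whole scan.
#' @return an object of class `smallworld_scan`: list with `table` (data
#'   frame `N`, `mean_diameter`, `sd_diameter`), `log_fit` and `linear_fit`
#'   (lm objects), `rss_log`, `rss_linear`, and `log_slope`.
#' @export
smallworld_scan <- function(sizes, m = 3, R = 50, T = 12, replicates = 3,
                            seed = NULL) {
  if (is.unsorted(sizes)) stop("'sizes' must be ascending")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(sizes, function(nn) {
    d <- vapply(seq_len(replicates), function(i) {
      net <- grow_network(N = nn, m = m, R = R, T = T)
      distance_stats(net)$diameter
    }, integer(1))
    data.frame(N = nn, mean_diameter = mean(d), sd_diameter = stats::sd(d))
  })
  tab <- do.call(rbind, rows)
  log_fit <- stats::lm(mean_diameter ~ log(N), data = tab)
  lin_fit <- stats::lm(mean_diameter ~ N, data = tab)
  structure(list(table = tab, log_fit = log_fit, linear_fit = lin_fit,
                 rss_log = sum(stats::residuals(log_fit)^2),
                 rss_linear = sum(stats::residuals(lin_fit)^2),
                 log_slope = unname(stats::coef(log_fit)[2]),
                 params = list(m = m, R = R, T = T,
                               replicates = replicates)),
            class = "smallworld_scan")
}

#' @export
print.smallworld_scan <- function(x, ...) {
  cat("Small-world scan (mean diameter per size):\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  log-model slope: %.3f; RSS log %.4g vs linear %.4g\n",
              x$log_slope, x$rss_log, x$rss_linear))
  invisible(x)
}
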